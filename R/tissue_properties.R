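#' Load a tissue thermal/dielectric property table
#'
#' Reads a per-tissue property table (CSV or JSON) holding, for each tissue
#' label, the mass density \code{rho} (kg m^-3), electrical conductivity
#' \code{sigma} (S m^-1, metadata only), relative permittivity \code{eps_r}
#' (metadata only), thermal conductivity \code{k} (W m^-1 K^-1), specific heat
#' capacity \code{c} (J kg^-1 K^-1), baseline blood perfusion \code{omega}
#' (ml min^-1 kg^-1), metabolic heat \code{Q} (W kg^-1) and a logical
#' \code{active} flag marking tissues that take part in temperature
#' simulations (air cavities, lung and water are inactive and handled as
#' boundary conditions instead). Optional \code{k_star}/\code{omega_star}
#' columns carry the alternate "under thermal stress" values fitted from
#' clinical temperature measurements for fat, muscle and tumor.
#'
#' @param path path to a CSV (canonical) or JSON property table.
#' @return a \code{data.frame} of class \code{tissue_table}.
#' @seealso [default_tissue_table()] for the table shipped with the package.
#' @export
load_property_table <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("property table file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_property_table(tab)
}

#' The head-and-neck property table shipped with the package
#'
#' Tissue constants for 434 MHz hyperthermia planning in the head-and-neck
#' region, including the starred (thermal-stress) alternates for fat, muscle
#' and tumor. Tumor baseline perfusion is muscle perfusion scaled by 1.85.
#'
#' @return a \code{tissue_table} data.frame.
#' @export
default_tissue_table <- function() {
  path <- system.file("extdata", "tissue_properties_434mhz.csv",
                      package = "bolusplan", mustWork = TRUE)
  load_property_table(path)
}

validate_property_table <- function(tab) {
  required <- c("tissue", "rho", "sigma", "eps_r", "k", "c", "omega", "Q", "active")
  if (!is.data.frame(tab) || nrow(tab) == 0L) {
    stop("property table is empty or not tabular")
  }
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("property table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"k_star" %in% names(tab)) tab$k_star <- NA_real_
  if (!"omega_star" %in% names(tab)) tab$omega_star <- NA_real_
  tab$tissue <- as.character(tab$tissue)
  tab$active <- as.logical(tab$active)
  dup <- tab$tissue[duplicated(tab$tissue)]
  if (length(dup)) stop("duplicate tissue name(s): ", paste(unique(dup), collapse = ", "))
  num_cols <- c("rho", "sigma", "eps_r", "k", "c", "omega", "Q", "k_star", "omega_star")
  for (col in num_cols) {
    tab[[col]] <- as.numeric(tab[[col]])
    bad <- which(is.finite(tab[[col]]) & tab[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("negative value in column '%s' for tissue '%s'",
                   col, tab$tissue[bad[1]]))
    }
  }
  bad_rho <- which(!is.finite(tab$rho) | tab$rho <= 0)
  if (length(bad_rho)) {
    stop("non-positive density 'rho' for tissue '", tab$tissue[bad_rho[1]], "'")
  }
  # active tissues need the full thermal constant set
  act <- which(tab$active)
  for (col in c("k", "c", "omega", "Q")) {
    bad <- act[!is.finite(tab[[col]][act])]
    if (length(bad)) {
      stop(sprintf("active tissue '%s' lacks a finite '%s'", tab$tissue[bad[1]], col))
    }
  }
  bad_c <- act[tab$c[act] <= 0]
  if (length(bad_c)) stop("non-positive heat capacity for tissue '", tab$tissue[bad_c[1]], "'")
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Blood properties for the Pennes perfusion term
#'
#' @param rho_b blood density (kg m^-3).
#' @param c_b blood specific heat capacity (J kg^-1 K^-1).
#' @param T_b arterial blood temperature (degrees C); defaults to core 37.
#' @return a \code{blood_properties} list.
#' @export
blood_properties <- function(rho_b = 1050, c_b = 3617, T_b = 37) {
  stopifnot(is.finite(rho_b), rho_b > 0, is.finite(c_b), c_b > 0, is.finite(T_b))
  if (T_b < 30 || T_b > 40) stop("arterial blood temperature out of range [30, 40] degC")
  structure(list(rho_b = rho_b, c_b = c_b, T_b = T_b), class = "blood_properties")
}

#' Default temperature-dependent perfusion breakpoints
#'
#' Piecewise-linear scaling-factor (SF) curves: perfusion rises linearly by a
#' factor 8.9 for muscle and 2 for fat between 37 and 44 degrees C, and is held
#' constant outside the listed breakpoints. The tumor curve defaults to flat
#' SF = 1 (its 1.85x muscle elevation is already baked into the baseline
#' perfusion value); supply your own breakpoints to model a rising tumor curve.
#'
#' @return named list of two-column matrices \code{(T_degC, SF)}.
#' @export
default_sf_breakpoints <- function() {
  path <- system.file("extdata", "sf_breakpoints_default.json",
                      package = "bolusplan", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(raw, function(m) {
    m <- matrix(as.numeric(m), ncol = 2)
    colnames(m) <- c("T", "SF")
    m
  })
}

#' Construct a blood-perfusion model
#'
#' Two models are supported. \code{"constant_stress"} uses perfusion and
#' thermal-conductivity values fixed at elevated under-heating levels (the
#' starred table variant for fat, muscle and tumor) with SF identically 1.
#' \code{"temperature_dependent"} uses baseline (37 degC) properties and scales
#' perfusion by a piecewise-linear, temperature-dependent factor SF per tissue
#' (the Lang model), constant outside the breakpoint range.
#'
#' @param mode \code{"constant_stress"} or \code{"temperature_dependent"}.
#' @param sf_breakpoints named list of \code{(T, SF)} matrices; ignored in
#'   constant-stress mode. Each curve must pass through SF = 1 at 37 degC.
#' @param property_variant which property columns feed the solver:
#'   \code{"star"} (optimized under-stress values where available) or
#'   \code{"baseline"}. Defaults follow the mode.
#' @return a \code{perfusion_model} list.
#' @export
perfusion_model <- function(mode = c("temperature_dependent", "constant_stress"),
                            sf_breakpoints = default_sf_breakpoints(),
                            property_variant = NULL) {
  mode <- match.arg(mode)
  if (is.null(property_variant)) {
    property_variant <- if (mode == "constant_stress") "star" else "baseline"
  }
  property_variant <- match.arg(property_variant, c("baseline", "star"))
  if (mode == "constant_stress") {
    sf_breakpoints <- list()
  } else {
    for (tissue in names(sf_breakpoints)) {
      bp <- sf_breakpoints[[tissue]]
      if (!is.matrix(bp) || ncol(bp) != 2 || nrow(bp) < 1 || any(!is.finite(bp))) {
        stop("invalid SF breakpoints for tissue '", tissue, "'")
      }
      if (is.unsorted(bp[, 1], strictly = TRUE)) {
        stop("SF breakpoint temperatures must be strictly increasing ('", tissue, "')")
      }
      sf37 <- stats::approx(bp[, 1], bp[, 2], xout = 37, rule = 2)$y
      if (abs(sf37 - 1) > 1e-12) {
        stop("SF curve for '", tissue, "' must equal 1 at 37 degC")
      }
    }
  }
  structure(list(mode = mode, sf_breakpoints = sf_breakpoints,
                 property_variant = property_variant),
            class = "perfusion_model")
}

#' Temperature-dependent perfusion scaling factor
#'
#' Evaluates the SF curve of \code{model} for one tissue at temperature(s)
#' \code{T}: piecewise-linear between breakpoints, constant beyond them.
#' Tissues without breakpoints (and the constant-stress model) return SF = 1.
#'
#' @param model a [perfusion_model()].
#' @param tissue tissue label.
#' @param T temperature(s) in degrees C.
#' @return numeric vector of scaling factors (dimensionless).
#' @export
scaling_factor <- function(model, tissue, T) {
  stopifnot(inherits(model, "perfusion_model"))
  if (any(!is.finite(T))) stop("non-finite temperature passed to scaling_factor")
  if (model$mode == "constant_stress") return(rep(1, length(T)))
  bp <- model$sf_breakpoints[[tissue]]
  if (is.null(bp)) return(rep(1, length(T)))
  if (nrow(bp) == 1L) return(rep(bp[1, 2], length(T)))
  stats::approx(bp[, 1], bp[, 2], xout = T, rule = 2)$y
}

#' Volumetric perfusion heat-exchange coefficient
#'
#' Converts a tissue's perfusion rate to the volumetric coefficient of the
#' Pennes sink term \eqn{SF \rho_b c_b \rho \omega (T - T_b)}:
#' \code{sf * rho_b * c_b * rho * omega_SI} in W m^-3 K^-1, where
#' \code{omega_SI = omega * 1e-6 / 60} converts ml min^-1 kg^-1 to
#' m^3 s^-1 kg^-1.
#'
#' @param props one row of a \code{tissue_table} (or a list with \code{rho},
#'   \code{omega}).
#' @param blood a [blood_properties()] object.
#' @param sf scaling factor(s), dimensionless.
#' @return coefficient(s) in W m^-3 K^-1.
#' @export
perfusion_coefficient <- function(props, blood, sf = 1) {
  stopifnot(inherits(blood, "blood_properties"))
  omega <- props$omega
  rho <- props$rho
  if (any(!is.finite(c(omega, rho, sf)))) stop("non-finite input to perfusion_coefficient")
  sf * blood$rho_b * blood$c_b * rho * omega * 1e-6 / 60
}

# Effective per-tissue k/omega for a model's property variant: starred values
# replace baselines where present, only in "star" mode.
effective_properties <- function(props, model) {
  stopifnot(inherits(props, "tissue_table"))
  tab <- as.data.frame(props)
  if (model$property_variant == "star") {
    has_k <- is.finite(tab$k_star)
    has_w <- is.finite(tab$omega_star)
    tab$k[has_k] <- tab$k_star[has_k]
    tab$omega[has_w] <- tab$omega_star[has_w]
  }
  class(tab) <- c("tissue_table", "data.frame")
  tab
}
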