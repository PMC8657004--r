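#' Median target temperature T50
#'
#' T50 is the temperature exceeded by 50 percent of the voxels of the target
#' volume. Convention: the lower-interpolation 50th percentile of the target
#' voxel temperatures, i.e. with the n values sorted ascending, element
#' \code{ceiling(n / 2)}; for an even count this is the lower of the two
#' middle values.
#'
#' @param field a [temperature_field()] or a 3D temperature array.
#' @param ctv logical mask of the target volume.
#' @return T50 in degrees C.
#' @export
compute_t50 <- function(field, ctv) {
  T <- if (inherits(field, "temperature_field")) field$T else field
  vals <- T[ctv]
  if (!length(vals)) stop("empty target volume mask")
  if (any(is.na(vals))) stop("target volume includes voxels outside the solved domain")
  sort(vals)[ceiling(length(vals) / 2)]
}

#' Mean target SAR at the applied power
#'
#' @param sar a [sar_field()].
#' @param power_scale dimensionless power multiplier (e.g. from
#'   [tune_power()]); defaults to the field's own scale.
#' @param ctv logical target mask.
#' @return mean of \code{power_scale * sar} over the target (W kg^-1).
#' @export
compute_mean_sar <- function(sar, power_scale = NULL, ctv) {
  stopifnot(inherits(sar, "sar_field"))
  if (is.null(power_scale)) power_scale <- sar$power_scale
  if (!is.finite(power_scale) || power_scale < 0) stop("power_scale must be >= 0")
  vals <- sar$sar[ctv]
  if (!length(vals)) stop("empty target volume mask")
  power_scale * mean(vals)
}

#' CTV depth statistics
#'
#' Per-target-voxel depth is the Euclidean distance (mm) from the voxel center
#' to the nearest bolus-contact (skin) surface voxel center; the median depth
#' is the depth of half of the CTV volume.
#'
#' @param phantom a \code{voxel_phantom} with \code{ctv} and
#'   \code{bolus_contact} masks.
#' @return list with \code{median}, \code{min}, \code{max} depth in mm.
#' @export
compute_ctv_depth <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  ctv <- which(phantom$masks$ctv)
  if (!length(ctv)) stop("phantom has no CTV mask")
  depths <- depth_to_surface(phantom, ctv)
  list(median = stats::median(depths), min = min(depths), max = max(depths))
}

#' Maximum temperature in critical tissues
#'
#' @param field a [temperature_field()] or 3D array.
#' @param phantom a \code{voxel_phantom}.
#' @param tissues critical tissue labels to report (absent ones return NA).
#' @return named numeric vector of per-tissue maxima (degrees C).
#' @export
critical_tissue_max <- function(field, phantom,
                                tissues = c("spinal_cord", "brainstem",
                                            "sclera", "vitreous_humor")) {
  T <- if (inherits(field, "temperature_field")) field$T else field
  out <- stats::setNames(rep(NA_real_, length(tissues)), tissues)
  for (tis in tissues) {
    if (!tis %in% names(phantom$legend)) next
    sel <- phantom$labels == label_id(phantom, tis)
    if (any(sel)) out[tis] <- max(T[sel], na.rm = TRUE)
  }
  out
}

#' Tune total power to a healthy-tissue temperature cap
#'
#' Finds the power scale such that the steady-state maximum temperature over
#' the healthy mask (all thermally active voxels excluding the CTV) equals
#' \code{T_cap}. For the constant-stress model the temperature rise is linear
#' in power: two solves (zero and unit power) determine the exact scale as the
#' smallest scale at which any healthy voxel reaches the cap. For the
#' temperature-dependent model the healthy maximum is monotone in power and is
#' bracketed and bisected, warm-starting each nonlinear solve.
#'
#' @inheritParams solve_steady
#' @param sar a [sar_field()]; must not be identically zero on active tissue.
#' @param T_cap healthy-tissue temperature cap (degrees C), default 44.
#' @param tol tolerance on the achieved healthy maximum (degrees C).
#' @param max_iter bisection iteration cap.
#' @return list with \code{power_scale}, \code{field} (the tuned
#'   [temperature_field()]) and \code{max_healthy_T}.
#' @export
tune_power <- function(phantom, props, blood = blood_properties(),
                       model = perfusion_model("constant_stress"),
                       sar, bcs = bc_set(), T_cap = 44, tol = 0.01,
                       max_iter = 60L) {
  stopifnot(inherits(sar, "sar_field"))
  healthy <- phantom$masks$healthy
  if (is.null(healthy) || !any(healthy)) stop("phantom has no healthy mask")
  if (all(sar$sar == 0)) stop("SAR is identically zero: power cap unreachable")

  scaled <- function(p) sar_field(sar$sar, power_scale = p)
  max_healthy <- function(field) max(field$T[healthy], na.rm = TRUE)

  temp_dep <- model$mode == "temperature_dependent" && length(model$sf_breakpoints) > 0
  f0 <- solve_steady(phantom, props, blood, model, sar = NULL, bcs = bcs)
  m0 <- max_healthy(f0)
  if (m0 >= T_cap) {
    stop(sprintf("baseline healthy maximum %.2f degC already exceeds the %.2f degC cap", m0, T_cap))
  }

  if (!temp_dep) {
    f1 <- solve_steady(phantom, props, blood, model, sar = scaled(1), bcs = bcs)
    delta <- f1$T[healthy] - f0$T[healthy]
    base <- f0$T[healthy]
    pos <- which(delta > 0)
    if (!length(pos)) stop("SAR produces no healthy-tissue temperature rise")
    p_star <- min((T_cap - base[pos]) / delta[pos])
    Tfull <- f0$T + p_star * (f1$T - f0$T)
    field <- temperature_field(Tfull, iterations = f1$iterations, residual = f1$residual)
    return(list(power_scale = p_star, field = field,
                max_healthy_T = max(Tfull[healthy], na.rm = TRUE)))
  }

  # temperature-dependent: monotone bracket + bisection on the power scale
  warm <- NULL
  eval_p <- function(p) {
    f <- solve_steady(phantom, props, blood, model, sar = scaled(p), bcs = bcs,
                      T_init = warm)
    warm <<- f$T
    f
  }
  p_hi <- 1
  f_hi <- eval_p(p_hi)
  guard <- 0L
  while (max_healthy(f_hi) < T_cap && guard < 40L) {
    p_hi <- p_hi * 2; f_hi <- eval_p(p_hi); guard <- guard + 1L
  }
  if (max_healthy(f_hi) < T_cap) stop("could not bracket the power cap from above")
  p_lo <- 0
  best <- list(p = p_hi, field = f_hi, m = max_healthy(f_hi))
  for (it in seq_len(max_iter)) {
    if (abs(best$m - T_cap) <= tol) break
    p_mid <- (p_lo + p_hi) / 2
    f_mid <- eval_p(p_mid)
    m_mid <- max_healthy(f_mid)
    if (abs(m_mid - T_cap) < abs(best$m - T_cap)) {
      best <- list(p = p_mid, field = f_mid, m = m_mid)
    }
    if (m_mid < T_cap) p_lo <- p_mid else p_hi <- p_mid
  }
  if (abs(best$m - T_cap) > tol) {
    stop(sprintf("power tuning did not reach the cap within tolerance (max healthy T = %.3f)", best$m))
  }
  list(power_scale = best$p, field = best$field, max_healthy_T = best$m)
}

#' Full dose report for one treatment configuration
#'
#' Tunes power to the healthy-tissue cap and assembles the dose metrics used
#' by the water-bolus sweep: tuned power scale, target T50, mean target SAR at
#' tuned power, healthy-tissue maximum, critical-tissue maxima and CTV depth
#' statistics.
#'
#' @inheritParams tune_power
#' @param critical_tissues labels passed to [critical_tissue_max()].
#' @return one-row \code{data.frame} of class \code{dose_report}.
#' @export
dose_report <- function(phantom, props, blood = blood_properties(),
                        model = perfusion_model("constant_stress"),
                        sar, bcs = bc_set(), T_cap = 44, tol = 0.01,
                        critical_tissues = c("spinal_cord", "brainstem",
                                             "sclera", "vitreous_humor")) {
  tuned <- tune_power(phantom, props, blood, model, sar, bcs, T_cap = T_cap, tol = tol)
  ctv <- phantom$masks$ctv
  depths <- compute_ctv_depth(phantom)
  crit <- critical_tissue_max(tuned$field, phantom, critical_tissues)
  out <- data.frame(power_scale = tuned$power_scale,
                    t50 = compute_t50(tuned$field, ctv),
                    mean_sar = compute_mean_sar(sar, tuned$power_scale, ctv),
                    max_healthy_T = tuned$max_healthy_T,
                    depth_median = depths$median,
                    depth_min = depths$min,
                    depth_max = depths$max)
  for (tis in names(crit)) out[[paste0("critical_", tis)]] <- crit[[tis]]
  class(out) <- c("dose_report", "data.frame")
  out
}
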