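#' Water-bolus sweep configuration
#'
#' Defines the grid of circulating-water temperatures and heat-transfer
#' coefficients over which treatment simulations are run. The default grid is
#' the study design: ten water-bolus temperatures in 2.5 degC steps from 20 to
#' 42.5 degC crossed with nine heat-transfer coefficients spanning the
#' measured 59-520 W m^-2 K^-1 range (linearly spaced), i.e. 90 combinations.
#'
#' @param wb_temps water-bolus temperatures (degrees C), strictly increasing.
#' @param h_values heat-transfer coefficients (W m^-2 K^-1), positive.
#' @param models named list of [perfusion_model()] objects.
#' @param cases named list of cases, each \code{list(phantom =, sar =)}.
#' @param T_cap healthy-tissue cap (degrees C).
#' @param tol power-tuning tolerance (degrees C).
#' @param props tissue property table.
#' @param blood [blood_properties()].
#' @return a \code{sweep_config} list.
#' @export
sweep_config <- function(wb_temps = seq(20, 42.5, by = 2.5),
                         h_values = seq(59, 520, length.out = 9),
                         models = list(constant = perfusion_model("constant_stress"),
                                       tdep = perfusion_model("temperature_dependent")),
                         cases = list(),
                         T_cap = 44, tol = 0.01,
                         props = default_tissue_table(),
                         blood = blood_properties()) {
  if (is.unsorted(wb_temps, strictly = TRUE)) stop("wb_temps must be strictly increasing")
  if (any(h_values <= 0)) stop("h_values must be positive")
  if (is.null(names(models)) || is.null(names(cases)) && length(cases)) {
    stop("models and cases must be named")
  }
  structure(list(wb_temps = wb_temps, h_values = h_values, models = models,
                 cases = cases, T_cap = T_cap, tol = tol,
                 props = props, blood = blood),
            class = "sweep_config")
}

#' Number of (water-bolus temperature, h) combinations in a sweep
#' @param config a [sweep_config()].
#' @return integer grid cardinality per case and model.
#' @export
sweep_grid_size <- function(config) {
  length(config$wb_temps) * length(config$h_values)
}

#' Run the water-bolus temperature x heat-transfer-coefficient sweep
#'
#' For every (case, model, T_wb, h) grid point: sets a Robin bolus boundary
#' condition, tunes total power to the healthy-tissue cap and records the
#' [dose_report()]. Individual solver failures are recorded per point and the
#' sweep continues; a sweep in which every point failed raises an error.
#' Deterministic given the configuration. With a \code{checkpoint} CSV path,
#' completed points are skipped on rerun.
#'
#' @param config a [sweep_config()] with at least one case.
#' @param checkpoint optional CSV path for resumable execution.
#' @param verbose print per-point progress.
#' @return a \code{sweep_result}: list with \code{table} (one row per grid
#'   point) and \code{config}.
#' @export
run_sweep <- function(config, checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (!length(config$cases)) stop("sweep configuration has no cases")
  grid <- expand.grid(case = names(config$cases), model = names(config$models),
                      T_wb = config$wb_temps, h = config$h_values,
                      stringsAsFactors = FALSE)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
  }
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    key <- grid[g, ]
    if (!is.null(done)) {
      hit <- done$case == key$case & done$model == key$model &
        abs(done$T_wb - key$T_wb) < 1e-9 & abs(done$h - key$h) < 1e-9
      if (any(hit)) {
        rows[[g]] <- done[which(hit)[1], , drop = FALSE]
        next
      }
    }
    case <- config$cases[[key$case]]
    bcs <- bc_set(bolus = bc_robin(key$h, key$T_wb),
                  exterior = bc_adiabatic(),
                  inactive = bc_dirichlet(config$blood$T_b))
    rep_row <- tryCatch({
      dr <- dose_report(case$phantom, config$props, config$blood,
                        config$models[[key$model]], case$sar, bcs,
                        T_cap = config$T_cap, tol = config$tol)
      cbind(key, as.data.frame(dr), error = NA_character_)
    }, error = function(e) {
      cbind(key, data.frame(power_scale = NA_real_, t50 = NA_real_,
                            mean_sar = NA_real_, max_healthy_T = NA_real_,
                            depth_median = NA_real_, depth_min = NA_real_,
                            depth_max = NA_real_),
            error = conditionMessage(e))
    })
    rows[[g]] <- rep_row
    if (verbose) {
      message(sprintf("[%d/%d] %s/%s T_wb=%.1f h=%.0f -> T50=%s", g, nrow(grid),
                      key$case, key$model, key$T_wb, key$h,
                      format(rep_row$t50[1], digits = 4)))
    }
    if (!is.null(checkpoint)) {
      tab <- do.call(rbind_fill, rows[!vapply(rows, is.null, logical(1))])
      utils::write.csv(tab, checkpoint, row.names = FALSE)
    }
  }
  table <- do.call(rbind_fill, rows)
  if (all(!is.na(table$error))) {
    stop("every sweep grid point failed; first error: ", table$error[1])
  }
  structure(list(table = table, config = config), class = "sweep_result")
}

# rbind for data.frames with possibly different critical_* columns
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, c(dfs, make.row.names = FALSE))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d grid points (%d failed)\n", nrow(x$table),
              sum(!is.na(x$table$error))))
  invisible(x)
}

#' Summed stepwise T50 gradient over the water-bolus range
#'
#' Sums the consecutive T50 differences along the water-bolus temperature
#' series between 20 and 40 degrees C for one (case, model, h) slice; by
#' telescoping this equals \code{T50(40) - T50(20)}, which is asserted. Any
#' increasing series whose endpoints are 20 and 40 degC is accepted.
#'
#' @param result a \code{sweep_result}.
#' @param case,model,h slice selectors (h matched within 1e-6).
#' @param wb_range endpoints of the summed range (degrees C).
#' @return summed stepwise T50 difference (degrees C).
#' @export
delta_t50_gradient <- function(result, case, model, h, wb_range = c(20, 40)) {
  stopifnot(inherits(result, "sweep_result"))
  tab <- result$table
  sel <- tab$case == case & tab$model == model & abs(tab$h - h) < 1e-6 &
    tab$T_wb >= wb_range[1] - 1e-9 & tab$T_wb <= wb_range[2] + 1e-9
  slice <- tab[sel, ]
  slice <- slice[order(slice$T_wb), ]
  if (nrow(slice) < 2 || abs(min(slice$T_wb) - wb_range[1]) > 1e-9 ||
      abs(max(slice$T_wb) - wb_range[2]) > 1e-9) {
    stop(sprintf("incomplete water-bolus series for (%s, %s, h=%.6g) over %g..%g degC",
                 case, model, h, wb_range[1], wb_range[2]))
  }
  if (any(is.na(slice$t50))) {
    stop("missing T50 at grid point(s): T_wb = ",
         paste(slice$T_wb[is.na(slice$t50)], collapse = ", "))
  }
  total <- sum(diff(slice$t50))
  stopifnot(isTRUE(all.equal(total, slice$t50[nrow(slice)] - slice$t50[1])))
  total
}

#' Stratify sweep cases into shallow and deep target groups
#'
#' Partitions cases at a median-CTV-depth threshold (shallow strictly below
#' it, boundary values assigned to the deep group) and returns per-group mean
#' T50 and mean-SAR tables over the (model, T_wb, h) grid.
#'
#' @param result a \code{sweep_result}.
#' @param threshold depth threshold in mm (default 20).
#' @return list with \code{assignment} (per case), and \code{shallow} /
#'   \code{deep} aggregated tables (empty groups yield a warning and NULL).
#' @export
stratify_by_depth <- function(result, threshold = 20) {
  stopifnot(inherits(result, "sweep_result"))
  tab <- result$table[is.na(result$table$error), ]
  depth <- tapply(tab$depth_median, tab$case, function(v) v[1])
  assignment <- ifelse(depth < threshold, "shallow", "deep")
  groups <- list()
  for (grp in c("shallow", "deep")) {
    cases <- names(assignment)[assignment == grp]
    if (!length(cases)) {
      warning("no cases in the ", grp, " group")
      groups[[grp]] <- NULL
      next
    }
    sub <- tab[tab$case %in% cases, ]
    groups[[grp]] <- stats::aggregate(cbind(t50, mean_sar) ~ model + T_wb + h,
                                      data = sub, FUN = mean)
  }
  list(assignment = assignment, shallow = groups$shallow, deep = groups$deep)
}

#' T50 sensitivity to water-bolus temperature versus heat-transfer coefficient
#'
#' Quantifies the claim that target temperature coverage responds more
#' strongly to the circulating-water temperature than to the film coefficient:
#' returns the largest T50 span across the h axis (at any fixed T_wb) and the
#' largest span across the T_wb axis (at any fixed h).
#'
#' @param result a \code{sweep_result}.
#' @param case,model slice selectors.
#' @return named vector \code{c(span_h = , span_wb = )} in degrees C.
#' @export
t50_sensitivity <- function(result, case, model) {
  tab <- result$table
  tab <- tab[tab$case == case & tab$model == model & is.na(tab$error), ]
  if (!nrow(tab)) stop("no completed grid points for that slice")
  span <- function(v) diff(range(v))
  span_h <- max(tapply(tab$t50, tab$T_wb, span))
  span_wb <- max(tapply(tab$t50, tab$h, span))
  c(span_h = span_h, span_wb = span_wb)
}

#' Write sweep tables, heatmaps and a summary
#'
#' Writes per model: long-format \code{t50_heatmap_<model>.csv} and
#' \code{mean_sar_heatmap_<model>.csv} (one row per (case, T_wb, h)) with PNG
#' heatmaps of case means, a \code{critical_max_vs_wb.csv} table of mean
#' critical-tissue maxima versus water-bolus temperature, a
#' \code{delta_t50_vs_depth.csv} table of per-case summed T50 gradients
#' against median CTV depth, and \code{summary.md}.
#'
#' @param result a \code{sweep_result}.
#' @param outdir output directory (created if needed).
#' @param gradient_h h value at which the T50 gradient column is computed
#'   (default: the h closest to 292 W m^-2 K^-1 present in the grid).
#' @return invisibly, the vector of files written.
#' @export
render_report <- function(result, outdir, gradient_h = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  tab <- result$table
  if (!nrow(tab) || all(!is.na(tab$error))) stop("empty or fully failed sweep result")
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir)
  }
  ok <- tab[is.na(tab$error), ]
  files <- character(0)
  h_grid <- sort(unique(ok$h))
  if (is.null(gradient_h)) gradient_h <- h_grid[which.min(abs(h_grid - 292))]

  for (mod in unique(ok$model)) {
    sub <- ok[ok$model == mod, ]
    for (metric in c("t50", "mean_sar")) {
      base <- sprintf("%s_heatmap_%s", metric, mod)
      csv <- file.path(outdir, paste0(base, ".csv"))
      utils::write.csv(sub[, c("case", "model", "T_wb", "h", metric)], csv,
                       row.names = FALSE)
      files <- c(files, csv)
      agg <- stats::aggregate(sub[[metric]], by = list(T_wb = sub$T_wb, h = sub$h), FUN = mean)
      wb <- sort(unique(agg$T_wb)); hh <- sort(unique(agg$h))
      z <- matrix(NA_real_, length(wb), length(hh))
      z[cbind(match(agg$T_wb, wb), match(agg$h, hh))] <- agg$x
      png_path <- file.path(outdir, paste0(base, ".png"))
      grDevices::png(png_path, width = 640, height = 480)
      graphics::image(wb, hh, z, xlab = "water bolus temperature (degC)",
                      ylab = "heat-transfer coefficient (W m-2 K-1)",
                      main = sprintf("%s (%s model)", metric, mod),
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
      grDevices::dev.off()
      files <- c(files, png_path)
    }
  }

  crit_cols <- grep("^critical_", names(ok), value = TRUE)
  if (length(crit_cols)) {
    near <- ok[abs(ok$h - gradient_h) < 1e-9, ]
    if (nrow(near)) {
      crit <- stats::aggregate(near[crit_cols], by = list(model = near$model,
                                                          T_wb = near$T_wb),
                               FUN = function(v) mean(v, na.rm = TRUE))
      csv <- file.path(outdir, "critical_max_vs_wb.csv")
      utils::write.csv(crit, csv, row.names = FALSE)
      files <- c(files, csv)
    }
  }

  grad_rows <- list()
  for (cs in unique(ok$case)) for (mod in unique(ok$model)) {
    g <- tryCatch(delta_t50_gradient(result, cs, mod, gradient_h),
                  error = function(e) NA_real_)
    dm <- ok$depth_median[ok$case == cs][1]
    grad_rows[[paste(cs, mod)]] <- data.frame(case = cs, model = mod,
                                              depth_median = dm, h = gradient_h,
                                              delta_t50_sum = g)
  }
  csv <- file.path(outdir, "delta_t50_vs_depth.csv")
  utils::write.csv(do.call(rbind, grad_rows), csv, row.names = FALSE)
  files <- c(files, csv)

  md <- file.path(outdir, "summary.md")
  con <- file(md, "w")
  writeLines(c("# Water-bolus sweep summary", "",
               sprintf("- grid points: %d (%d failed)", nrow(tab), sum(!is.na(tab$error))),
               sprintf("- cases: %s", paste(unique(tab$case), collapse = ", ")),
               sprintf("- models: %s", paste(unique(tab$model), collapse = ", ")),
               sprintf("- water-bolus temperatures (degC): %s",
                       paste(sort(unique(tab$T_wb)), collapse = ", ")),
               sprintf("- heat-transfer coefficients (W m-2 K-1): %s",
                       paste(signif(sort(unique(tab$h)), 4), collapse = ", "))),
             con)
  close(con)
  files <- c(files, md)
  invisible(files)
}
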