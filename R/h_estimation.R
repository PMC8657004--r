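#' Fit the water-bolus heat-transfer coefficient to one probe record
#'
#' Bounded scalar least squares: minimizes
#' \code{SSR(h) = sum_t (T_sim(h, t, probe) - T_meas(t))^2} over
#' \code{h} in \code{bounds}, where \code{T_sim} comes from the transient
#' bioheat solve of the bench experiment configuration. Uses golden-section /
#' parabolic search ([stats::optimize()]). A fit whose minimizer sits at a
#' bound is flagged as non-converged rather than silently returned.
#'
#' Per-probe objective evaluations share the configuration's simulation cache:
#' the transient solve does not depend on the probe, so one solve per
#' candidate h serves all probes.
#'
#' @param record a [probe_record()].
#' @param config an [experiment_config()] whose probe layout contains the
#'   record's position.
#' @param bounds search interval for h (W m^-2 K^-1).
#' @param tol absolute tolerance on h passed to the optimizer.
#' @return a \code{h_fit} list: \code{probe_id}, \code{h_hat},
#'   \code{r_squared}, \code{objective} (SSR, degC^2), \code{bounds},
#'   \code{converged}.
#' @export
fit_h <- function(record, config, bounds = c(10, 1000), tol = 0.5) {
  stopifnot(inherits(record, "probe_record"), inherits(config, "experiment_config"))
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("bounds must be positive with lower < upper")
  }
  if (!isTRUE(all.equal(record$times, config$times))) {
    stop("record time grid does not match the experiment configuration")
  }
  dpos <- sweep(config$probe_positions, 2, record$position)
  j <- which.min(rowSums(dpos^2))
  if (sqrt(sum(dpos[j, ]^2)) > config$phantom$spacing / 2) {
    stop("record position not found in the experiment probe layout")
  }
  ssr <- function(h) {
    sim <- simulate_experiment_probes(config, h)[, j]
    sum((sim - record$temperatures)^2)
  }
  opt <- stats::optimize(ssr, interval = bounds, tol = tol)
  h_hat <- opt$minimum
  sst <- sum((record$temperatures - mean(record$temperatures))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  at_bound <- (h_hat - bounds[1]) < 2 * tol || (bounds[2] - h_hat) < 2 * tol
  structure(list(probe_id = record$probe_id, h_hat = h_hat,
                 r_squared = r2, objective = opt$objective,
                 bounds = bounds, converged = !at_bound),
            class = "h_fit")
}

#' @export
print.h_fit <- function(x, ...) {
  cat(sprintf("h_fit %s: h = %.1f W m-2 K-1, R2 = %.4f%s\n", x$probe_id, x$h_hat,
              x$r_squared, if (x$converged) "" else " [at bound]"))
  invisible(x)
}

#' Fit all probes of a bench experiment
#'
#' @param records list of [probe_record()].
#' @param config shared [experiment_config()].
#' @param ... passed to [fit_h()].
#' @return list of \code{h_fit} objects.
#' @export
fit_h_all <- function(records, config, ...) {
  lapply(records, fit_h, config = config, ...)
}

#' Summarize per-probe heat-transfer-coefficient fits
#'
#' Arithmetic mean, range and spread of the recovered coefficients over the
#' converged fits; flagged (bound-hitting) fits are excluded with a warning.
#'
#' @param fits list of \code{h_fit} objects.
#' @return list with \code{mean}, \code{min}, \code{max}, \code{sd} of h,
#'   \code{r_squared_mean}, \code{r_squared_sd}, \code{n}, \code{n_flagged}.
#' @export
summarize_h <- function(fits) {
  if (!length(fits)) stop("no fits to summarize")
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("all heat-transfer-coefficient fits were flagged")
  if (any(!ok)) {
    warning(sum(!ok), " flagged fit(s) excluded from the summary")
  }
  h <- vapply(fits[ok], `[[`, numeric(1), "h_hat")
  r2 <- vapply(fits[ok], `[[`, numeric(1), "r_squared")
  list(mean = mean(h), min = min(h), max = max(h),
       sd = if (length(h) > 1) stats::sd(h) else 0,
       r_squared_mean = mean(r2),
       r_squared_sd = if (length(r2) > 1) stats::sd(r2) else 0,
       n = sum(ok), n_flagged = sum(!ok))
}

#' Export h fits as a CSV table
#' @param fits list of \code{h_fit} objects.
#' @param path output CSV path.
#' @return the table invisibly.
#' @export
write_h_fits <- function(fits, path) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(probe_id = f$probe_id, h_hat = f$h_hat,
               r_squared = f$r_squared, converged = f$converged)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
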