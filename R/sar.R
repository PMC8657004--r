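#' SAR field container
#'
#' A specific-absorption-rate field on a phantom grid: \code{sar} in W kg^-1 at
#' nominal drive, plus a dimensionless \code{power_scale} so the deposited
#' power density is \code{power_scale * sar}.
#'
#' @param sar 3D numeric array (W kg^-1), non-negative, zero on inactive voxels.
#' @param power_scale dimensionless multiplier, default 1.
#' @return a \code{sar_field} object.
#' @export
sar_field <- function(sar, power_scale = 1) {
  if (any(sar < 0, na.rm = TRUE)) stop("SAR must be non-negative")
  if (!is.finite(power_scale) || power_scale < 0) stop("power_scale must be non-negative")
  structure(list(sar = sar, power_scale = power_scale), class = "sar_field")
}

#' Synthetic focal SAR distribution
#'
#' Builds a smooth stand-in for a phase/amplitude-optimized applicator SAR
#' pattern: an isotropic Gaussian focus plus an exponentially decaying
#' superficial component from the bolus-contact surface, zero on inactive
#' voxels, normalized so the focus voxel reads 100 W kg^-1 at nominal drive.
#' The superficial component is laterally localized around the focus axis
#' (Gaussian of width \code{surface_sigma}), emulating the near-field of the
#' aperture that illuminates the target rather than a uniform skin load.
#'
#' @param phantom a \code{voxel_phantom} with a \code{bolus_contact} mask.
#' @param focus world coordinate (mm) of the SAR focus; must lie in active
#'   tissue.
#' @param fwhm full width at half maximum of the Gaussian focus (mm).
#' @param surface_decay e-folding depth of the superficial component (mm).
#' @param surface_frac superficial amplitude at the surface relative to the
#'   focus peak (default 0.3).
#' @param surface_sigma lateral extent (mm) of the superficial component
#'   around the focus axis; default twice the focus fwhm, \code{Inf} for an
#'   unlocalized skin load.
#' @param sigma_weight scale the pattern by each tissue's electrical
#'   conductivity-to-density ratio relative to the focus tissue (default
#'   TRUE): absorbed power per unit mass is proportional to sigma/rho at a
#'   given field strength, so low-loss tissues such as fat and bone absorb a
#'   small fraction of the muscle/tumor SAR.
#' @param props tissue property table.
#' @return a \code{sar_field} with \code{power_scale = 1}.
#' @export
make_focal_sar <- function(phantom, focus, fwhm, surface_decay = 10,
                           surface_frac = 0.3, surface_sigma = 2 * fwhm,
                           sigma_weight = TRUE,
                           props = default_tissue_table()) {
  stopifnot(inherits(phantom, "voxel_phantom"), length(focus) == 3)
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (surface_decay <= 0) stop("surface_decay must be positive")
  d <- dim(phantom$labels)
  act <- active_mask(phantom, props)
  if (!any(act)) stop("phantom has no active tissue")
  xs <- axis_coords(phantom, 1); ys <- axis_coords(phantom, 2); zs <- axis_coords(phantom, 3)
  fi <- round((focus - phantom$origin) / phantom$spacing) + 1
  if (any(fi < 1) || any(fi > d) || !act[fi[1], fi[2], fi[3]]) {
    stop("focus must lie inside active tissue")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r2 <- outer(outer((xs - focus[1])^2, (ys - focus[2])^2, `+`), (zs - focus[3])^2, `+`)
  gaussian <- exp(-r2 / (2 * sigma^2))
  sup <- array(0, d)
  act_lin <- which(act)
  sup_val <- surface_frac * exp(-depth_to_surface(phantom, act_lin) / surface_decay)
  if (is.finite(surface_sigma)) {
    # lateral distance from the focus axis (component orthogonal to the
    # inward surface normal; for wrap-around contact, along the z axis)
    contact <- which(phantom$masks$bolus_contact)
    cw <- colMeans(world_coords(phantom, contact))
    bw <- colMeans(world_coords(phantom, act_lin))
    nrm <- bw - cw
    vw <- world_coords(phantom, act_lin)
    if (sqrt(sum(nrm^2)) > phantom$spacing / 2) {
      nrm <- nrm / sqrt(sum(nrm^2))
      rel <- sweep(vw, 2, focus)
      perp <- rel - outer(as.numeric(rel %*% nrm), nrm)
      lat2 <- rowSums(perp^2)
    } else {
      lat2 <- (vw[, 3] - focus[3])^2
    }
    sup_val <- sup_val * exp(-lat2 / (2 * surface_sigma^2))
  }
  sup[act_lin] <- sup_val
  sar <- gaussian + sup
  if (sigma_weight) {
    # absorbed power per mass ~ sigma/rho; reference = tissue at the focus
    row_of <- match(names(phantom$legend), props$tissue)
    ratio <- props$sigma[row_of] / props$rho[row_of]
    ratio[!is.finite(ratio)] <- 0
    ref <- ratio[match(phantom$labels[fi[1], fi[2], fi[3]], phantom$legend)]
    w <- array(0, d)
    w[act_lin] <- ratio[match(phantom$labels[act_lin], phantom$legend)] / ref
    sar <- sar * w
  }
  sar[!act] <- 0
  peak <- sar[fi[1], fi[2], fi[3]]
  sar <- sar * (100 / peak)
  sar[fi[1], fi[2], fi[3]] <- 100   # exact argmax at the focus voxel
  sar_field(sar)
}
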