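#' Voxel phantom construction
#'
#' A \code{voxel_phantom} is a labeled 3D integer grid plus named masks. Voxel
#' indices are 0-based in the external NIfTI representation; in R, array index
#' \code{i} has world coordinate \code{origin + (i - 1) * spacing} (mm, voxel
#' centers). Label 0 is exterior air; every non-zero label maps to a tissue in
#' the accompanying legend. The depth axis is the first array dimension: the
#' water bolus contacts the phantom on the low-x face of slab phantoms and on
#' the lateral surface of cylindrical phantoms.
#'
#' @name voxel_phantom
NULL

new_phantom <- function(labels, spacing, legend, origin = NULL) {
  if (is.null(origin)) origin <- rep(spacing / 2, 3)
  masks <- list()
  p <- structure(list(labels = labels, spacing = spacing, origin = origin,
                      legend = legend, masks = masks),
                 class = "voxel_phantom")
  p
}

label_id <- function(phantom, tissue) {
  id <- phantom$legend[tissue]
  if (any(is.na(id))) stop("tissue not in phantom legend: ",
                           paste(tissue[is.na(id)], collapse = ", "))
  unname(id)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel_phantom: %d x %d x %d voxels @ %.3g mm\n", d[1], d[2], d[3], x$spacing))
  cat("tissues:", paste(sprintf("%s=%d", names(x$legend), x$legend), collapse = ", "), "\n")
  for (m in names(x$masks)) cat(sprintf("  mask %-13s %d voxels\n", m, sum(x$masks[[m]])))
  invisible(x)
}

# world (mm) coordinates of all voxel centers along one axis
axis_coords <- function(phantom, axis) {
  n <- dim(phantom$labels)[axis]
  phantom$origin[axis] + (seq_len(n) - 1) * phantom$spacing
}

world_coords <- function(phantom, lin_idx) {
  ijk <- arrayInd(lin_idx, dim(phantom$labels))
  sweep(sweep(ijk - 1, 2, rep(phantom$spacing, 3), `*`), 2, phantom$origin, `+`)
}

# active = labeled voxel whose tissue is thermally active
active_mask <- function(phantom, props) {
  lab <- phantom$labels
  act_ids <- label_id(phantom, props$tissue[props$active & props$tissue %in% names(phantom$legend)])
  array(lab %in% act_ids, dim(lab))
}

# voxels of `mask` with at least one 6-neighbour outside the grid or labeled 0,
# restricted to the given axes (1=x, 2=y, 3=z)
exterior_boundary <- function(labels, mask = NULL, axes = 1:3) {
  d <- dim(labels)
  if (is.null(mask)) mask <- labels > 0L
  out <- array(FALSE, d)
  for (ax in axes) {
    for (dir in c(-1L, 1L)) {
      nb <- shift_array(labels, ax, dir, fill = 0L)
      out <- out | (mask & nb == 0L)
    }
  }
  out
}

# shift array by one voxel along axis; vacated entries get `fill`.
shift_array <- function(a, axis, dir, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n == 1L) return(out)
  if (dir > 0) {        # out[i] = a[i+1]
    idx_src[[axis]] <- 2:n
    idx_dst[[axis]] <- 1:(n - 1)
  } else {              # out[i] = a[i-1]
    idx_src[[axis]] <- 1:(n - 1)
    idx_dst[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

refresh_masks <- function(phantom, props) {
  act <- active_mask(phantom, props)
  ctv <- phantom$masks$ctv
  if (is.null(ctv)) ctv <- array(FALSE, dim(phantom$labels))
  phantom$masks$inactive <- array(phantom$labels > 0L, dim(phantom$labels)) & !act
  phantom$masks$healthy <- act & !ctv
  phantom$masks$ctv <- ctv
  phantom
}

#' Build a layered slab phantom
#'
#' Stacks tissue layers along the depth (x) axis of a rectangular domain. The
#' water-bolus contact mask covers the front (x = 0) face. The last layer may
#' have thickness \code{NA} to fill the remaining depth.
#'
#' @param size domain size in mm, length-3 \code{c(depth, width, height)}.
#' @param spacing isotropic voxel edge in mm.
#' @param layers named numeric vector of layer thicknesses in mm, front to
#'   back, e.g. \code{c(fat = 8, muscle = NA)}.
#' @param props tissue property table used to validate labels and set masks.
#' @return a \code{voxel_phantom} with \code{bolus_contact}, \code{healthy},
#'   \code{ctv} (empty) and \code{inactive} masks.
#' @export
make_layered_phantom <- function(size, spacing = 2,
                                 layers = c(fat = 8, muscle = NA),
                                 props = default_tissue_table()) {
  if (!is.numeric(spacing) || spacing <= 0) stop("grid spacing must be positive")
  if (length(size) != 3 || any(size < spacing)) stop("empty or degenerate domain")
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) stop("layers must be named by tissue")
  thick <- as.numeric(layers)
  if (any(!is.na(thick) & thick <= 0)) stop("layer thicknesses must be positive")
  if (anyNA(thick[-length(thick)])) stop("only the last layer may have NA thickness")
  known <- sum(thick, na.rm = TRUE)
  if (known > size[1] + 1e-9) stop("layer thicknesses exceed domain depth")
  if (is.na(thick[length(thick)])) thick[length(thick)] <- size[1] - known
  tissues <- names(layers)
  missing <- setdiff(tissues, props$tissue)
  if (length(missing)) stop("unknown tissue(s) in layers: ", paste(missing, collapse = ", "))

  dims <- pmax(1L, as.integer(round(size / spacing)))
  legend <- stats::setNames(seq_along(unique(tissues)), unique(tissues))
  labels <- array(0L, dims)
  x <- (seq_len(dims[1]) - 0.5) * spacing        # depth of voxel centers
  bounds <- cumsum(thick)
  layer_of <- findInterval(x, c(0, bounds), rightmost.closed = TRUE)
  layer_of[layer_of > length(tissues)] <- length(tissues)
  for (i in seq_len(dims[1])) {
    labels[i, , ] <- legend[tissues[layer_of[i]]]
  }
  p <- new_phantom(labels, spacing, legend)
  p$masks$bolus_contact <- array(FALSE, dims)
  p$masks$bolus_contact[1, , ] <- TRUE
  p$contact_faces <- list(c(1L, -1L))    # bolus couples through the front (-x) face
  p <- refresh_masks(p, props)
  p$masks$bolus_contact <- p$masks$bolus_contact & !p$masks$inactive
  p
}

#' Build a concentric-cylinder phantom
#'
#' Tissue rings around the z axis, e.g. a muscle cylinder with a bone core as a
#' crude neck stand-in. The bolus contact mask covers the lateral surface
#' (cap faces are exterior).
#'
#' @param radii named numeric vector of outer radii (mm), innermost first,
#'   strictly increasing, named by tissue.
#' @param length_mm cylinder length along z in mm.
#' @param spacing isotropic voxel edge in mm.
#' @param margin air margin around the cylinder in mm.
#' @param props tissue property table.
#' @return a \code{voxel_phantom}.
#' @export
make_cylinder_phantom <- function(radii, length_mm, spacing = 2, margin = 4,
                                  props = default_tissue_table()) {
  if (!is.numeric(spacing) || spacing <= 0) stop("grid spacing must be positive")
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) stop("radii must be named by tissue")
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be positive and strictly increasing")
  }
  missing <- setdiff(names(radii), props$tissue)
  if (length(missing)) stop("unknown tissue(s): ", paste(missing, collapse = ", "))
  rmax <- max(radii)
  side <- 2 * (rmax + margin)
  dims <- pmax(1L, as.integer(round(c(side, side, length_mm) / spacing)))
  legend <- stats::setNames(seq_along(unique(names(radii))), unique(names(radii)))
  cx <- (dims[1] / 2) * spacing
  cy <- (dims[2] / 2) * spacing
  xs <- (seq_len(dims[1]) - 0.5) * spacing - cx
  ys <- (seq_len(dims[2]) - 0.5) * spacing - cy
  r2 <- outer(xs^2, ys^2, `+`)
  ring <- array(0L, dims)
  plane <- matrix(0L, dims[1], dims[2])
  prev <- 0
  for (j in seq_along(radii)) {
    sel <- r2 > prev^2 & r2 <= radii[j]^2
    plane[sel] <- legend[names(radii)[j]]
    prev <- radii[j]
  }
  plane[r2 <= radii[1]^2] <- legend[names(radii)[1]]
  for (k in seq_len(dims[3])) ring[, , k] <- plane
  p <- new_phantom(ring, spacing, legend)
  p$masks$bolus_contact <- exterior_boundary(ring, axes = 1:2)
  p$contact_faces <- list(c(1L, -1L), c(1L, 1L), c(2L, -1L), c(2L, 1L))
  p <- refresh_masks(p, props)
  p$masks$bolus_contact <- p$masks$bolus_contact & !p$masks$inactive
  p
}

#' Place a spherical clinical target volume (CTV)
#'
#' Inserts a tumor-labeled sphere centered \code{center_depth} mm below the
#' bolus-contact surface and updates the \code{ctv}/\code{healthy} masks.
#' Depth is measured from the plane of the contact-surface voxel centers along
#' the inward surface normal (+x for slabs, radially inward for cylinders).
#'
#' @param phantom a \code{voxel_phantom}.
#' @param center_depth sphere-center depth below the contact surface (mm).
#' @param radius sphere radius (mm); must be positive and fit in active tissue.
#' @param tissue tumor tissue label (default \code{"tumor"}).
#' @param props tissue property table.
#' @return the phantom with tumor labels and updated masks.
#' @export
place_ctv <- function(phantom, center_depth, radius, tissue = "tumor",
                      props = default_tissue_table()) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (!is.finite(radius) || radius <= 0) stop("CTV radius must be positive (empty target)")
  if (!tissue %in% props$tissue) stop("unknown tumor tissue: ", tissue)
  d <- dim(phantom$labels)
  s <- phantom$spacing
  contact <- which(phantom$masks$bolus_contact)
  if (!length(contact)) stop("phantom has no bolus_contact mask")
  cw <- world_coords(phantom, contact)
  # inward normal: from the contact centroid toward the label centroid
  act <- which(phantom$labels > 0L)
  aw <- world_coords(phantom, act)
  surf_c <- colMeans(cw)
  body_c <- colMeans(aw)
  nrm <- body_c - surf_c
  if (sqrt(sum(nrm^2)) > s / 2) {
    # slab-like: step inward along the surface normal
    nrm <- nrm / sqrt(sum(nrm^2))
    center <- surf_c + nrm * center_depth
  } else {
    # cylinder-like (contact wraps around): step radially inward along +x
    r_eff <- mean(sqrt((cw[, 1] - body_c[1])^2 + (cw[, 2] - body_c[2])^2))
    center <- c(body_c[1] + r_eff - center_depth, body_c[2], body_c[3])
  }
  lo <- phantom$origin - s / 2
  hi <- phantom$origin + (d - 1) * s + s / 2
  if (any(center - radius < lo - 1e-9) || any(center + radius > hi + 1e-9)) {
    stop("CTV sphere extends outside active tissue")
  }
  xs <- axis_coords(phantom, 1); ys <- axis_coords(phantom, 2); zs <- axis_coords(phantom, 3)
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  inside <- r2 <= radius^2
  if (!any(inside)) stop("CTV sphere contains no voxels (radius below grid resolution)")
  was_active <- active_mask(phantom, props)
  if (any(inside & !was_active)) stop("CTV sphere extends outside active tissue")
  if (!tissue %in% names(phantom$legend)) {
    phantom$legend <- c(phantom$legend,
                        stats::setNames(max(phantom$legend) + 1L, tissue))
  }
  phantom$labels[inside] <- label_id(phantom, tissue)
  phantom$masks$ctv <- inside
  refresh_masks(phantom, props)
}

#' Insert a cylindrical critical structure
#'
#' Adds a tissue rod (e.g. a spinal-cord stand-in) parallel to the z axis at a
#' given depth below the contact surface, for critical-tissue monitoring.
#'
#' @param phantom a \code{voxel_phantom}.
#' @param tissue tissue label for the rod (e.g. \code{"spinal_cord"}).
#' @param center_depth rod-axis depth below the contact surface (mm).
#' @param radius rod radius (mm).
#' @param lateral lateral (y) offset of the rod axis from the slab center
#'   line (mm).
#' @param props tissue property table.
#' @return the phantom with the rod labeled and masks refreshed.
#' @export
place_rod <- function(phantom, tissue, center_depth, radius, lateral = 0,
                      props = default_tissue_table()) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (!is.finite(radius) || radius <= 0) stop("rod radius must be positive")
  if (!tissue %in% props$tissue) stop("unknown tissue: ", tissue)
  contact <- which(phantom$masks$bolus_contact)
  surf_x <- mean(world_coords(phantom, contact)[, 1])
  cx <- surf_x + center_depth
  cy <- mean(axis_coords(phantom, 2)) + lateral
  xs <- axis_coords(phantom, 1); ys <- axis_coords(phantom, 2)
  inside2d <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= radius^2
  inside <- array(FALSE, dim(phantom$labels))
  for (k in seq_len(dim(phantom$labels)[3])) inside[, , k] <- inside2d
  was_active <- active_mask(phantom, props)
  if (any(inside & !was_active)) stop("rod extends outside active tissue")
  if (any(inside & phantom$masks$ctv)) stop("rod overlaps the CTV")
  if (!tissue %in% names(phantom$legend)) {
    phantom$legend <- c(phantom$legend,
                        stats::setNames(max(phantom$legend) + 1L, tissue))
  }
  phantom$labels[inside] <- label_id(phantom, tissue)
  refresh_masks(phantom, props)
}

# per-voxel depth (mm): Euclidean distance to the nearest contact-surface voxel
# center, for the voxels in `lin_idx`. Chunked to bound memory.
depth_to_surface <- function(phantom, lin_idx, chunk = 4096L) {
  surf <- which(phantom$masks$bolus_contact)
  if (!length(surf)) stop("phantom lacks a bolus_contact surface mask")
  sw <- world_coords(phantom, surf)
  out <- numeric(length(lin_idx))
  for (start in seq(1L, length(lin_idx), by = chunk)) {
    idx <- lin_idx[start:min(start + chunk - 1L, length(lin_idx))]
    vw <- world_coords(phantom, idx)
    d2 <- outer(rowSums(vw^2), rowSums(sw^2), `+`) - 2 * vw %*% t(sw)
    out[start:(start + length(idx) - 1L)] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
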