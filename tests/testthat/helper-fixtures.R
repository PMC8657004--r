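# Shared fixtures: small phantoms and property variants built in code.

fixture_props <- function(zero_Q = FALSE) {
  tab <- default_tissue_table()
  if (zero_Q) tab$Q[tab$active] <- 0
  tab
}

# homogeneous muscle column for 1D comparisons (adiabatic sides)
muscle_column <- function(depth_mm = 120, spacing = 2, props = fixture_props()) {
  make_layered_phantom(c(depth_mm, spacing, spacing), spacing,
                       layers = c(muscle = NA), props = props)
}

# small treatment slab with a CTV plus spinal-cord and eye-like critical rods
treatment_slab <- function(ctv_depth, spacing = 2, side = 64, ctv_radius = 6,
                           rod = TRUE) {
  p <- make_layered_phantom(c(side, side, side), spacing, layers = c(muscle = NA))
  if (rod) {
    p <- place_rod(p, "spinal_cord", center_depth = 26, radius = 4)
    p <- place_rod(p, "sclera", center_depth = 6, radius = 3, lateral = 20)
  }
  place_ctv(p, center_depth = ctv_depth, radius = ctv_radius)
}

# sweep fixture cases: a skin-reaching shallow target and a deep target in a
# fat-over-muscle neck-like slab with superficial (eye) and deep (cord)
# critical structures
sweep_fixture_cases <- function(spacing = 2, side = 64) {
  mk <- function(depth, radius) {
    p <- make_layered_phantom(c(side, side, side), spacing,
                              layers = c(fat = 8, muscle = NA))
    p <- place_rod(p, "spinal_cord", center_depth = 26, radius = 4)
    p <- place_rod(p, "sclera", center_depth = 6, radius = 3, lateral = 20)
    p <- place_ctv(p, center_depth = depth, radius = radius)
    list(phantom = p, sar = treatment_sar(p, depth, fwhm = 15))
  }
  list(shallow = mk(8, 8), deep = mk(40, 6))
}

treatment_sar <- function(phantom, ctv_depth, fwhm = 15) {
  mid <- mean(bolusplan:::axis_coords(phantom, 2))
  midz <- mean(bolusplan:::axis_coords(phantom, 3))
  surf_x <- phantom$spacing / 2
  make_focal_sar(phantom, focus = c(surf_x + ctv_depth, mid, midz), fwhm = fwhm)
}

# coarse, short bench configuration for fast unit tests
fast_experiment_config <- function(...) {
  ph <- gel_slab_phantom(spacing = 4, size = c(48, 48, 48))
  experiment_config(phantom = ph,
                    times = seq(0, 600, by = 60), dt = 60,
                    probe_positions = default_probe_layout(
                      ph, depths = c(4, 8, 16), lateral = 0),
                    ...)
}

# brute-force T50 oracle: largest voxel value reached-or-exceeded by a strict
# majority of the target voxels
t50_oracle <- function(vals) {
  cand <- sort(unique(vals))
  best <- NA_real_
  for (v in cand) {
    if (sum(vals >= v) > length(vals) / 2) best <- v
  }
  best
}
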