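#' Water-bolus bench experiment on a muscle-equivalent phantom
#'
#' Emulates the heat-transfer-coefficient characterization bench: a
#' muscle-equivalent gel slab initially at room temperature with the water
#' bolus, circulating at a different temperature, in contact with its front
#' face. Fiber-optic probes record the transient temperature at fixed points
#' while heat soaks in through the contact surface. The gel carries muscle
#' thermal conductivity and heat capacity but no perfusion and no metabolic
#' heat.
#'
#' @name probe_experiment
NULL

#' Default gel slab for the bench experiment
#'
#' A homogeneous muscle-equivalent slab, 48 mm deep and 80 x 80 mm in
#' cross-section at 2 mm spacing, bolus contact on the front face.
#'
#' @param spacing voxel edge (mm).
#' @param size domain size (mm), depth first.
#' @return a \code{voxel_phantom}.
#' @export
gel_slab_phantom <- function(spacing = 2, size = c(48, 80, 80)) {
  make_layered_phantom(size, spacing, layers = c(muscle = NA))
}

#' Default probe layout for the bench experiment
#'
#' 21 measurement points: 7 depths below the contact face crossed with 3
#' lateral offsets, mirroring a six-probe / 21-point fiber-optic arrangement.
#'
#' @param phantom the gel slab phantom.
#' @param depths probe depths below the contact surface (mm).
#' @param lateral lateral offsets from the slab center line (mm).
#' @return matrix (n x 3) of world coordinates (mm).
#' @export
default_probe_layout <- function(phantom,
                                 depths = c(2, 4, 6, 8, 10, 14, 20),
                                 lateral = c(-15, 0, 15)) {
  mid_y <- mean(axis_coords(phantom, 2))
  mid_z <- mean(axis_coords(phantom, 3))
  surf_x <- mean(world_coords(phantom, which(phantom$masks$bolus_contact))[, 1])
  grid <- expand.grid(depth = depths, lat = lateral)
  cbind(surf_x + grid$depth, mid_y + grid$lat, rep(mid_z, nrow(grid)))
}

# gel variant of the property table: zero perfusion/metabolism everywhere
gel_properties <- function(props) {
  tab <- as.data.frame(props)
  tab$omega[tab$active] <- 0
  tab$Q[tab$active] <- 0
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Experiment configuration for transient simulation and h fitting
#'
#' Bundles everything the transient solver needs to reproduce the bench
#' record for a candidate heat-transfer coefficient: geometry, gel
#' properties, bolus and room temperatures, the time grid and the probe
#' positions. Non-contact faces exchange heat with room air through a small
#' convective coefficient \code{h_air}.
#'
#' @param phantom gel slab phantom.
#' @param props tissue property table (perfusion/metabolism are zeroed).
#' @param T_bolus circulating water temperature (degrees C).
#' @param T_init initial phantom (room) temperature (degrees C).
#' @param h_air convective coefficient of non-contact faces (W m^-2 K^-1).
#' @param T_room air temperature seen by non-contact faces (degrees C);
#'   defaults to \code{T_init}.
#' @param times record sample times (s), starting at 0.
#' @param dt solver time step (s).
#' @param probe_positions n x 3 matrix of probe world coordinates (mm).
#' @return an \code{experiment_config} list with a simulation cache.
#' @export
experiment_config <- function(phantom = gel_slab_phantom(),
                              props = default_tissue_table(),
                              T_bolus = 31.1, T_init = 19.6, h_air = 10,
                              T_room = T_init,
                              times = seq(0, 1200, by = 60), dt = 30,
                              probe_positions = default_probe_layout(phantom)) {
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  probe_positions <- matrix(as.numeric(probe_positions), ncol = 3)
  structure(list(phantom = phantom, props = gel_properties(props),
                 blood = blood_properties(),
                 T_bolus = T_bolus, T_init = T_init, h_air = h_air,
                 T_room = T_room,
                 times = times, dt = dt, probe_positions = probe_positions,
                 cache = new.env(parent = emptyenv())),
            class = "experiment_config")
}

# Simulate the experiment at coefficient h; returns matrix [time x probe] of
# temperatures at every configured probe. Results are memoised per h because
# the transient solve is probe-independent.
simulate_experiment_probes <- function(config, h) {
  key <- sprintf("h=%.10g", h)
  hit <- config$cache[[key]]
  if (!is.null(hit)) return(hit)
  bcs <- bc_set(bolus = bc_robin(h, config$T_bolus),
                exterior = bc_robin(config$h_air, config$T_room))
  sim <- solve_transient(config$phantom, config$props, config$blood,
                         model = perfusion_model("constant_stress",
                                                 property_variant = "baseline"),
                         sar = NULL, bcs = bcs,
                         T_init = config$T_init,
                         duration = max(config$times), dt = config$dt,
                         sample_times = config$times)
  out <- vapply(sim$fields, function(f) {
    sample_field(f$T, config$phantom, config$probe_positions)
  }, numeric(nrow(config$probe_positions)))
  out <- t(matrix(out, nrow = nrow(config$probe_positions)))
  config$cache[[key]] <- out
  out
}

#' Transient probe record
#'
#' @param probe_id identifier.
#' @param position world coordinate (mm), length 3.
#' @param times sample times (s), strictly increasing, starting at 0.
#' @param temperatures temperatures (degrees C), same length as times.
#' @return a \code{probe_record} list.
#' @export
probe_record <- function(probe_id, position, times, temperatures) {
  if (length(times) != length(temperatures)) stop("times/temperatures length mismatch")
  if (!length(times) || times[1] != 0) stop("probe record must start at t = 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(probe_id = probe_id, position = as.numeric(position),
                 times = as.numeric(times), temperatures = as.numeric(temperatures)),
            class = "probe_record")
}

#' Simulate the bench experiment and emit noisy probe records
#'
#' Runs the transient solver with a Robin bolus face at \code{h_true} and
#' \code{T_bolus}, zero SAR and zero perfusion, samples trilinearly at the
#' probe positions, and adds i.i.d. Gaussian measurement noise.
#'
#' @param config an [experiment_config()] (carries phantom, temperatures,
#'   time grid and probe positions).
#' @param h_true generating heat-transfer coefficient (W m^-2 K^-1).
#' @param noise_sd measurement noise standard deviation (degrees C).
#' @param seed RNG seed for the noise (ignored when \code{noise_sd = 0}).
#' @return list of [probe_record()] objects.
#' @export
simulate_probe_experiment <- function(config, h_true, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.finite(h_true) || h_true < 0) stop("h_true must be >= 0")
  clean <- simulate_experiment_probes(config, h_true)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    noisy <- clean + stats::rnorm(length(clean), sd = noise_sd)
  } else {
    noisy <- clean
  }
  lapply(seq_len(ncol(clean)), function(j) {
    probe_record(sprintf("P%02d", j), config$probe_positions[j, ],
                 config$times, noisy[, j])
  })
}

#' Write / read probe records as CSV
#'
#' Column layout: \code{probe_id,x_mm,y_mm,z_mm,time_s,temp_C}.
#'
#' @param records list of [probe_record()].
#' @param path CSV path.
#' @return \code{write_probe_records} returns the path invisibly;
#'   \code{read_probe_records} returns a list of records.
#' @export
write_probe_records <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(probe_id = r$probe_id, x_mm = r$position[1], y_mm = r$position[2],
               z_mm = r$position[3], time_s = r$times, temp_C = r$temperatures)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_records
#' @export
read_probe_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "x_mm", "y_mm", "z_mm", "time_s", "temp_C")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("probe CSV missing column(s): ", paste(missing, collapse = ", "))
  lapply(split(tab, tab$probe_id), function(g) {
    g <- g[order(g$time_s), ]
    probe_record(g$probe_id[1], c(g$x_mm[1], g$y_mm[1], g$z_mm[1]),
                 g$time_s, g$temp_C)
  })
}
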