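props0 <- fixture_props(zero_Q = TRUE)   # no metabolic heat: clean analytics
blood <- blood_properties()
const_base <- perfusion_model("constant_stress", property_variant = "baseline")

muscle_P <- function() {
  tab <- fixture_props()
  perfusion_coefficient(tab[tab$tissue == "muscle", ], blood_properties(), 1)
}

test_that("adiabatic perfusion-free operator conserves heat (zero row sums)", {
  gel <- bolusplan:::gel_properties(fixture_props())
  p <- make_layered_phantom(c(12, 12, 12), spacing = 4, layers = c(muscle = NA))
  asm <- assemble_system(p, gel, blood, const_base,
                         bcs = bc_set(bolus = bc_adiabatic(), exterior = bc_adiabatic()))
  expect_lt(max(abs(Matrix::rowSums(asm$A))), 1e-15)
})

test_that("single-voxel Robin balance matches the closed form", {
  p <- make_layered_phantom(c(2, 2, 2), spacing = 2, layers = c(muscle = NA))
  gel <- bolusplan:::gel_properties(fixture_props())
  sar <- sar_field(array(500, c(1, 1, 1)))
  h <- 120; Text <- 30
  bcs <- bc_set(bolus = bc_robin(h, Text), exterior = bc_adiabatic())
  f <- solve_steady(p, gel, blood, const_base, sar = sar, bcs = bcs)
  # one-voxel algebra: G (Text - T) + rho V SAR = 0 with the half-cell series
  # conductance G = A / (s/(2k) + 1/h)
  s <- 0.002; k <- 0.49; rho <- 1090
  G <- s^2 / (s / (2 * k) + 1 / h)
  T_expect <- Text + rho * s^3 * 500 / G
  expect_equal(f$T[1, 1, 1], T_expect, tolerance = 1e-10)
})

test_that("face conductivity uses the harmonic mean across tissue interfaces", {
  p <- make_layered_phantom(c(4, 2, 2), spacing = 2, layers = c(fat = 2, muscle = NA))
  gel <- bolusplan:::gel_properties(fixture_props())
  asm <- assemble_system(p, gel, blood, const_base,
                         bcs = bc_set(bolus = bc_adiabatic(), exterior = bc_adiabatic()))
  k_harm <- 2 * 0.21 * 0.49 / (0.21 + 0.49)
  expect_equal(k_harm, 0.294, tolerance = 1e-3)
  expect_equal(asm$A[1, 2], -k_harm * 0.002, tolerance = 1e-12)
})

test_that("uniform Dirichlet at blood temperature is an equilibrium", {
  p <- make_layered_phantom(c(16, 8, 8), spacing = 4, layers = c(muscle = NA),
                            props = props0)
  bcs <- bc_set(bolus = bc_dirichlet(37), exterior = bc_dirichlet(37))
  f <- solve_steady(p, props0, blood, const_base, bcs = bcs)
  expect_lt(max(abs(f$T - 37), na.rm = TRUE), 1e-9)
})

test_that("steady 1D profile matches the analytic Pennes solution within 1%", {
  p <- muscle_column(120, 2, props = props0)
  h <- 100; Text <- 25
  bcs <- bc_set(bolus = bc_robin(h, Text), exterior = bc_adiabatic())
  f <- solve_steady(p, props0, blood, const_base, bcs = bcs)
  k <- 0.49
  P <- muscle_P()
  delta <- sqrt(k / P)
  x <- (seq_len(dim(p$labels)[1]) - 0.5) * 0.002
  C <- h * (Text - 37) / (h + k / delta)
  Ta <- 37 + C * exp(-x / delta)
  expect_lt(max(abs(f$T[, 1, 1] - Ta)) / abs(C), 0.01)
})

test_that("the discretization is second order in the grid spacing", {
  errs <- vapply(c(4, 2), function(sp) {
    p <- muscle_column(120, sp, props = props0)
    bcs <- bc_set(bolus = bc_robin(100, 25), exterior = bc_adiabatic())
    f <- solve_steady(p, props0, blood, const_base, bcs = bcs)
    k <- 0.49; P <- muscle_P(); delta <- sqrt(k / P)
    x <- (seq_len(dim(p$labels)[1]) - 0.5) * sp / 1000
    C <- 100 * (25 - 37) / (100 + k / delta)
    max(abs(f$T[, 1, 1] - (37 + C * exp(-x / delta)))) / abs(C)
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 2.5)   # halving the spacing cuts the error ~4x
  expect_lt(errs[1] / errs[2], 6)
})

test_that("steady-state global energy balance closes", {
  p <- make_layered_phantom(c(24, 16, 16), spacing = 4, layers = c(muscle = NA))
  props <- fixture_props()                       # metabolic heat on
  sar_arr <- array(0, dim(p$labels)); sar_arr[3, 2, 2] <- 800
  sar <- sar_field(sar_arr)
  h <- 292; Twb <- 25
  bcs <- bc_set(bolus = bc_robin(h, Twb), exterior = bc_adiabatic())
  f <- solve_steady(p, props, blood, const_base, sar = sar, bcs = bcs)
  s <- 0.004; V <- s^3; k <- 0.49; rho <- 1090
  P <- muscle_P()
  total_source <- sum(rho * (sar_arr + 0.96) * V)
  perf_sink <- sum(P * (f$T - 37) * V)
  G_r <- s^2 / (s / (2 * k) + 1 / h)
  bnd_flux_out <- sum(G_r * (f$T[1, , ] - Twb))
  resid <- abs(total_source - perf_sink - bnd_flux_out) / total_source
  expect_lt(resid, 1e-6)
})

test_that("Robin limits reproduce Dirichlet and adiabatic conditions", {
  p <- muscle_column(60, 4, props = props0)
  f_dir <- solve_steady(p, props0, blood, const_base,
                        bcs = bc_set(bolus = bc_dirichlet(25), exterior = bc_adiabatic()))
  f_big <- solve_steady(p, props0, blood, const_base,
                        bcs = bc_set(bolus = bc_robin(1e6, 25), exterior = bc_adiabatic()))
  expect_lt(max(abs(f_dir$T - f_big$T), na.rm = TRUE), 0.01)

  f_ad <- solve_steady(p, props0, blood, const_base,
                       bcs = bc_set(bolus = bc_adiabatic(), exterior = bc_adiabatic()))
  f_h0 <- solve_steady(p, props0, blood, const_base,
                       bcs = bc_set(bolus = bc_robin(0, 25), exterior = bc_adiabatic()))
  expect_equal(f_h0$T, f_ad$T, tolerance = 1e-12)
})

test_that("doubling SAR doubles the temperature rise in the constant model", {
  p <- make_layered_phantom(c(24, 16, 16), spacing = 4, layers = c(muscle = NA),
                            props = props0)
  sar_arr <- array(0, dim(p$labels)); sar_arr[3, 2, 2] <- 400
  bcs <- bc_set(bolus = bc_robin(292, 37), exterior = bc_adiabatic())
  f1 <- solve_steady(p, props0, blood, const_base, sar = sar_field(sar_arr), bcs = bcs)
  f2 <- solve_steady(p, props0, blood, const_base, sar = sar_field(2 * sar_arr), bcs = bcs)
  expect_equal(f2$T - 37, 2 * (f1$T - 37), tolerance = 1e-7)
})

test_that("flat SF breakpoints reduce the nonlinear solve to the constant model", {
  p <- make_layered_phantom(c(24, 16, 16), spacing = 4, layers = c(muscle = NA))
  props <- fixture_props()
  sar_arr <- array(0, dim(p$labels)); sar_arr[3, 2, 2] <- 600
  flat <- perfusion_model("temperature_dependent", property_variant = "baseline",
                          sf_breakpoints = list(muscle = cbind(c(37, 44), c(1, 1))))
  bcs <- bc_set(bolus = bc_robin(292, 30), exterior = bc_adiabatic())
  f_lin <- solve_steady(p, props, blood, const_base, sar = sar_field(sar_arr), bcs = bcs)
  f_fix <- solve_steady(p, props, blood, flat, sar = sar_field(sar_arr), bcs = bcs, tol = 1e-6)
  expect_lt(max(abs(f_lin$T - f_fix$T), na.rm = TRUE), 1e-4)
})

test_that("transient stepping is consistent with its limits", {
  p <- muscle_column(48, 4, props = props0)
  gel <- bolusplan:::gel_properties(props0)
  bcs <- bc_set(bolus = bc_robin(300, 31.1), exterior = bc_adiabatic())

  tr0 <- solve_transient(p, gel, blood, const_base, bcs = bcs, T_init = 19.6,
                         duration = 0, dt = 10)
  expect_equal(max(abs(tr0$fields[[1]]$T - 19.6)), 0)

  tr <- solve_transient(p, gel, blood, const_base, bcs = bcs, T_init = 19.6,
                        duration = 80000, dt = 800,
                        sample_times = c(0, 600, 3000, 80000))
  stead <- solve_steady(p, gel, blood, const_base, bcs = bcs)
  expect_lt(max(abs(tr$fields[[4]]$T - stead$T)), 0.02)

  # maximum principle: source-free temperatures stay inside the data range and
  # the mean rises monotonically toward the bolus temperature
  means <- vapply(tr$fields, function(f) mean(f$T), numeric(1))
  expect_true(all(diff(means) > 0))
  allT <- unlist(lapply(tr$fields, function(f) range(f$T)))
  expect_true(all(allT >= 19.6 - 1e-9 & allT <= 31.1 + 1e-9))
})

test_that("explicit scheme enforces its stability bound and matches implicit", {
  p <- muscle_column(24, 4, props = props0)
  gel <- bolusplan:::gel_properties(props0)
  bcs <- bc_set(bolus = bc_robin(300, 31.1), exterior = bc_adiabatic())
  expect_error(solve_transient(p, gel, blood, const_base, bcs = bcs, T_init = 19.6,
                               duration = 600, dt = 200, scheme = "explicit"),
               "stability bound")
  te <- solve_transient(p, gel, blood, const_base, bcs = bcs, T_init = 19.6,
                        duration = 600, dt = 5, scheme = "explicit",
                        sample_times = c(0, 600))
  ti <- solve_transient(p, gel, blood, const_base, bcs = bcs, T_init = 19.6,
                        duration = 600, dt = 5, scheme = "implicit",
                        sample_times = c(0, 600))
  expect_lt(max(abs(te$fields[[2]]$T - ti$fields[[2]]$T)), 0.05)
})

test_that("trilinear sampling interpolates between voxel centers", {
  p <- make_layered_phantom(c(8, 8, 8), spacing = 4, layers = c(muscle = NA))
  arr <- array(0, dim(p$labels))
  arr[] <- seq_len(length(arr))      # linear-ish ramp
  v1 <- sample_field(arr, p, matrix(c(2, 2, 2), 1))     # first voxel center
  expect_equal(v1, arr[1, 1, 1])
  vmid <- sample_field(arr, p, matrix(c(4, 2, 2), 1))   # midpoint along x
  expect_equal(vmid, mean(arr[1:2, 1, 1]))
  expect_error(sample_field(arr, p, matrix(c(-5, 2, 2), 1)), "outside")
})
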