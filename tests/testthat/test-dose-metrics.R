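test_that("T50 follows the lower-interpolation percentile convention", {
  arr <- array(c(40, 41, 42, 43), c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  expect_equal(compute_t50(arr, mask), 41)
  expect_equal(compute_t50(array(43, c(3, 1, 1)), array(TRUE, c(3, 1, 1))), 43)
  shifted <- arr + 1.25
  expect_equal(compute_t50(shifted, mask), compute_t50(arr, mask) + 1.25)
  expect_error(compute_t50(arr, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("T50 agrees with the brute-force counting oracle on all small sets", {
  set.seed(101)
  for (n in 1:8) {
    for (rep in 1:40) {
      vals <- round(runif(n, 36, 45), 1)
      arr <- array(vals, c(n, 1, 1))
      expect_equal(compute_t50(arr, array(TRUE, c(n, 1, 1))), t50_oracle(vals),
                   info = paste("n =", n, "vals =", paste(vals, collapse = ",")))
    }
  }
})

test_that("mean target SAR scales linearly with the applied power", {
  arr <- array(50, c(2, 2, 2))
  s <- sar_field(arr)
  mask <- array(TRUE, c(2, 2, 2))
  expect_equal(compute_mean_sar(s, 2, mask), 100)
  expect_equal(compute_mean_sar(s, 0, mask), 0)
  expect_equal(compute_mean_sar(s, 1, mask), 2 * compute_mean_sar(s, 0.5, mask))
  expect_error(compute_mean_sar(s, 1, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("CTV depth statistics measure distance to the contact surface", {
  p <- make_layered_phantom(c(64, 24, 24), spacing = 2, layers = c(muscle = NA))
  # single voxel 10 mm beneath the surface voxel-center plane
  p$masks$ctv <- array(FALSE, dim(p$labels))
  p$masks$ctv[6, 6, 6] <- TRUE     # x = 11 mm; surface centers at x = 1 mm
  d <- compute_ctv_depth(p)
  expect_equal(d$median, 10)
  expect_equal(d$min, 10)
  expect_equal(d$max, 10)

  # slab target occupying depths 0..40 mm uniformly: median ~ 20 mm
  p$masks$ctv <- array(FALSE, dim(p$labels))
  p$masks$ctv[1:20, 6, 6] <- TRUE
  d2 <- compute_ctv_depth(p)
  expect_equal(d2$min, 0)                  # includes a surface voxel
  expect_lt(abs(d2$median - 20), 2.1)
  expect_error({q <- p; q$masks$bolus_contact[] <- FALSE; compute_ctv_depth(q)},
               "surface")
})

test_that("critical-tissue maxima report per-label peaks", {
  p <- make_layered_phantom(c(40, 24, 24), spacing = 2, layers = c(muscle = NA))
  p <- place_rod(p, "spinal_cord", center_depth = 30, radius = 3)
  arr <- array(37, dim(p$labels))
  out <- critical_tissue_max(arr, p)
  expect_equal(unname(out["spinal_cord"]), 37)
  expect_true(is.na(out["brainstem"]))
  hot <- which(p$labels == p$legend["spinal_cord"])[5]
  arr[hot] <- 41.3
  out2 <- critical_tissue_max(arr, p)
  expect_equal(unname(out2["spinal_cord"]), 41.3)
  expect_lte(max(out2, na.rm = TRUE), max(arr))
})

test_that("power tuning reaches the healthy cap and exploits linearity", {
  props0 <- fixture_props(zero_Q = TRUE)
  p <- make_layered_phantom(c(48, 32, 32), spacing = 4, layers = c(muscle = NA),
                            props = props0)
  p <- place_ctv(p, center_depth = 16, radius = 6, props = props0)
  sar <- treatment_sar(p, 16, fwhm = 12)
  bcs <- bc_set(bolus = bc_robin(292, 37), exterior = bc_adiabatic())
  mod <- perfusion_model("constant_stress", property_variant = "baseline")
  tuned <- tune_power(p, props0, blood_properties(), mod, sar, bcs)
  expect_lt(abs(tuned$max_healthy_T - 44), 0.01)
  # with T_ext = T_b and no metabolic heat the rise is linear in power:
  # the tuned scale equals (44 - 37) / (unit-power max healthy rise)
  f1 <- solve_steady(p, props0, blood_properties(), mod, sar = sar, bcs = bcs)
  rise <- max(f1$T[p$masks$healthy] - 37)
  expect_equal(tuned$power_scale, 7 / rise, tolerance = 1e-6)

  expect_error(tune_power(p, props0, blood_properties(), mod,
                          sar_field(array(0, dim(p$labels))), bcs),
               "identically zero")
  hot_bcs <- bc_set(bolus = bc_robin(292, 48), exterior = bc_adiabatic())
  expect_error(tune_power(p, props0, blood_properties(), mod, sar, hot_bcs),
               "cap")
})

test_that("rising healthy perfusion demands more power than the static curve", {
  props0 <- fixture_props(zero_Q = TRUE)
  p <- make_layered_phantom(c(48, 32, 32), spacing = 4, layers = c(muscle = NA),
                            props = props0)
  p <- place_ctv(p, center_depth = 16, radius = 6, props = props0)
  sar <- treatment_sar(p, 16, fwhm = 12)
  bcs <- bc_set(bolus = bc_robin(292, 30), exterior = bc_adiabatic())
  blood <- blood_properties()
  p_const <- tune_power(p, props0, blood,
                        perfusion_model("constant_stress", property_variant = "baseline"),
                        sar, bcs)$power_scale
  p_tdep <- tune_power(p, props0, blood,
                       perfusion_model("temperature_dependent"),
                       sar, bcs)$power_scale
  expect_gt(p_tdep, p_const)
})

test_that("the dose report collects consistent metrics", {
  props <- fixture_props()
  p <- treatment_slab(ctv_depth = 12, spacing = 4, side = 48, ctv_radius = 6)
  sar <- treatment_sar(p, 12)
  bcs <- bc_set(bolus = bc_robin(292, 30), exterior = bc_adiabatic())
  dr <- dose_report(p, props, model = perfusion_model("constant_stress"),
                    sar = sar, bcs = bcs)
  expect_s3_class(dr, "dose_report")
  expect_lt(abs(dr$max_healthy_T - 44), 0.01)
  expect_gt(dr$power_scale, 0)
  expect_true(dr$depth_min <= dr$depth_median && dr$depth_median <= dr$depth_max)
  expect_false(is.na(dr$critical_spinal_cord))
  expect_equal(dr$mean_sar,
               compute_mean_sar(sar, dr$power_scale, p$masks$ctv))
})
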