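# fabricate a sweep_result table for the pure-arithmetic operations
fake_result <- function(tab) {
  structure(list(table = tab, config = NULL), class = "sweep_result")
}

grid_tab <- function(case = "a", model = "constant", wb = seq(20, 40, 2.5),
                     h = 292, t50 = 41, depth = 10) {
  g <- expand.grid(case = case, model = model, T_wb = wb, h = h,
                   stringsAsFactors = FALSE)
  g$t50 <- rep_len(t50, nrow(g))
  g$mean_sar <- 100 - g$T_wb
  g$depth_median <- depth
  g$power_scale <- 1; g$max_healthy_T <- 44
  g$depth_min <- 0; g$depth_max <- 2 * depth
  g$error <- NA_character_
  g
}

test_that("the default sweep design has 90 bolus-temperature x h combinations", {
  cfg <- sweep_config()
  expect_equal(length(cfg$wb_temps), 10L)
  expect_equal(length(cfg$h_values), 9L)
  expect_equal(sweep_grid_size(cfg), 90L)
  expect_equal(cfg$wb_temps[1], 20)
  expect_equal(cfg$wb_temps[10], 42.5)
  expect_equal(range(cfg$h_values), c(59, 520))
  expect_error(sweep_config(wb_temps = c(30, 20)), "increasing")
  expect_error(sweep_config(h_values = c(-5, 10)), "positive")
})

test_that("a single-point sweep reproduces the direct dose report", {
  p <- treatment_slab(ctv_depth = 12, spacing = 4, side = 48, ctv_radius = 6)
  sar <- treatment_sar(p, 12)
  cfg <- sweep_config(wb_temps = 30, h_values = 292,
                      models = list(constant = perfusion_model("constant_stress")),
                      cases = list(only = list(phantom = p, sar = sar)))
  res <- run_sweep(cfg)
  expect_equal(nrow(res$table), 1L)
  direct <- dose_report(p, cfg$props, cfg$blood, cfg$models$constant, sar,
                        bc_set(bolus = bc_robin(292, 30), exterior = bc_adiabatic()))
  expect_equal(res$table$t50, direct$t50, tolerance = 1e-10)
  expect_equal(res$table$power_scale, direct$power_scale, tolerance = 1e-10)

  res2 <- run_sweep(cfg)        # rerun with the same config: identical output
  expect_identical(res$table, res2$table)
})

test_that("sweeps are resumable from a checkpoint", {
  p <- treatment_slab(ctv_depth = 12, spacing = 4, side = 48, ctv_radius = 6)
  sar <- treatment_sar(p, 12)
  cfg <- sweep_config(wb_temps = c(20, 30), h_values = 292,
                      models = list(constant = perfusion_model("constant_stress")),
                      cases = list(only = list(phantom = p, sar = sar)))
  ckpt <- withr::local_tempfile(fileext = ".csv")
  res <- run_sweep(cfg, checkpoint = ckpt)
  expect_true(file.exists(ckpt))
  done <- read.csv(ckpt)
  expect_equal(nrow(done), 2L)
  # poison one stored t50 to prove the rerun skips recomputation
  done$t50[1] <- -999
  write.csv(done, ckpt, row.names = FALSE)
  res2 <- run_sweep(cfg, checkpoint = ckpt)
  expect_equal(sort(res2$table$t50)[1], -999)
})

test_that("solver failures are recorded per point without aborting the sweep", {
  p <- treatment_slab(ctv_depth = 12, spacing = 4, side = 48, ctv_radius = 6)
  sar_ok <- treatment_sar(p, 12)
  sar_zero <- sar_field(array(0, dim(p$labels)))
  cfg <- sweep_config(wb_temps = 30, h_values = 292,
                      models = list(constant = perfusion_model("constant_stress")),
                      cases = list(good = list(phantom = p, sar = sar_ok),
                                   bad = list(phantom = p, sar = sar_zero)))
  res <- run_sweep(cfg)
  expect_equal(nrow(res$table), 2L)
  expect_true(any(!is.na(res$table$error)))
  expect_true(any(is.na(res$table$error)))

  cfg_bad <- sweep_config(wb_temps = 30, h_values = 292,
                          models = list(constant = perfusion_model("constant_stress")),
                          cases = list(bad = list(phantom = p, sar = sar_zero)))
  expect_error(run_sweep(cfg_bad), "failed")
})

test_that("the summed T50 gradient telescopes to the endpoint difference", {
  tab <- grid_tab(t50 = 41)                    # constant T50 -> zero gradient
  expect_equal(delta_t50_gradient(fake_result(tab), "a", "constant", 292), 0)

  set.seed(7)
  tab2 <- grid_tab(t50 = 40 + cumsum(runif(9, -0.3, 0.5)))
  g <- delta_t50_gradient(fake_result(tab2), "a", "constant", 292)
  expect_equal(g, tab2$t50[nrow(tab2)] - tab2$t50[1])

  tab3 <- grid_tab(wb = c(20, 30, 40))         # sparse series still spans 20..40
  expect_equal(delta_t50_gradient(fake_result(tab3), "a", "constant", 292), 0)

  tab4 <- grid_tab(wb = c(22.5, 30, 40))       # missing the 20 degC endpoint
  expect_error(delta_t50_gradient(fake_result(tab4), "a", "constant", 292),
               "incomplete")
  expect_error(delta_t50_gradient(fake_result(tab), "a", "constant", 111),
               "incomplete")
})

test_that("depth stratification splits at 20 mm with ties going deep", {
  tab <- rbind(grid_tab(case = "s", depth = 8), grid_tab(case = "d", depth = 20))
  st <- stratify_by_depth(fake_result(tab))
  expect_equal(unname(st$assignment["s"]), "shallow")
  expect_equal(unname(st$assignment["d"]), "deep")     # boundary rule: deep
  # one case per group: group means equal the per-case values
  expect_equal(sort(unique(st$shallow$t50)), sort(unique(tab$t50[tab$case == "s"])))

  allshallow <- fake_result(grid_tab(case = "s", depth = 5))
  expect_warning(st2 <- stratify_by_depth(allshallow), "deep")
  expect_null(st2$deep)
})

test_that("T50 sensitivity spans compare the two sweep axes", {
  tab <- expand.grid(case = "a", model = "m", T_wb = c(20, 30, 40),
                     h = c(100, 300, 500), stringsAsFactors = FALSE)
  tab$t50 <- 40 + 0.05 * (tab$T_wb - 20) / 2.5 + 0.001 * (tab$h - 100) / 100
  tab$error <- NA_character_
  sens <- t50_sensitivity(fake_result(tab), "a", "m")
  expect_lt(sens[["span_h"]], sens[["span_wb"]])
})

test_that("report rendering writes round-trippable tables", {
  tab <- rbind(grid_tab(case = "s", depth = 8, h = c(100, 292)),
               grid_tab(case = "d", depth = 30, h = c(100, 292)))
  tab$critical_spinal_cord <- 39
  res <- fake_result(tab)
  outdir <- withr::local_tempdir()
  files <- render_report(res, outdir)
  expect_true(file.exists(file.path(outdir, "t50_heatmap_constant.csv")))
  expect_true(file.exists(file.path(outdir, "mean_sar_heatmap_constant.csv")))
  expect_true(file.exists(file.path(outdir, "critical_max_vs_wb.csv")))
  expect_true(file.exists(file.path(outdir, "delta_t50_vs_depth.csv")))
  expect_true(file.exists(file.path(outdir, "summary.md")))
  back <- read.csv(file.path(outdir, "t50_heatmap_constant.csv"))
  expect_equal(nrow(back), nrow(tab))
  expect_equal(sort(back$t50), sort(tab$t50))
  grad <- read.csv(file.path(outdir, "delta_t50_vs_depth.csv"))
  expect_equal(nrow(grad), 2L)

  empty <- fake_result(tab[0, ])
  expect_error(render_report(empty, outdir), "empty")
})
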