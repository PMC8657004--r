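# bolusplan

Thermal dosimetry for superficial microwave hyperthermia, centered on one
planning question: **what temperature should the water bolus circulate at?**
During head-and-neck hyperthermia a phased-array applicator heats the target
to 40–44 °C while a water bolus couples the microwave power into the skin and
cools it. The bolus is characterized by its circulating-water temperature
T<sub>wb</sub> and its surface heat-transfer coefficient *h* (W m⁻² K⁻¹);
both shape the superficial temperature field and hence the dose a
shallow-seated tumor receives.

`bolusplan` is aimed at treatment-planning researchers and medical
physicists. It provides:

* a **Pennes bioheat solver** on labeled voxel phantoms
  (finite volume, 7-point stencil):

  c ρ ∂T/∂t = ∇·(k∇T) − SF ρ<sub>b</sub> c<sub>b</sub> ρ ω (T − T<sub>b</sub>) + ρ·SAR + ρ·Q

  with Robin (convective) water-bolus boundary conditions and two blood-
  perfusion models — a *constant thermal-stress* model (elevated starred
  constants, SF ≡ 1) and a *temperature-dependent* model (perfusion scaled
  piecewise-linearly by a factor SF reaching 2 for fat and 8.9 for muscle at
  44 °C);
* an **estimator for *h*** that fits transient bioheat simulations to
  fiber-optic probe records from a bench experiment (bounded scalar least
  squares, per probe, with R²);
* **power tuning** of a SAR field to a 44 °C healthy-tissue maximum, and the
  dose metrics T50 (temperature exceeded by half the target voxels), mean
  target SAR and CTV depth statistics;
* the **T<sub>wb</sub> × h sweep** with depth stratification (shallow < 20 mm
  median depth vs deep), summed T50 gradients, and CSV/PNG reporting;
* **synthetic-data generators**: layered and cylindrical tissue phantoms,
  spherical targets at controlled depth, conductivity-weighted focal SAR
  stand-ins, and noisy transient probe records.

Tissue constants (density, conductivity, heat capacity, perfusion, metabolic
heat, plus 434 MHz dielectric metadata) ship as a CSV/JSON table with both
baseline and thermal-stress variants.

## Worked example

```r
library(bolusplan)

# 1) Bench experiment: recover the bolus heat-transfer coefficient from a
#    transient record (gel slab at 19.6 degC, bolus at 31.1 degC)
cfg <- experiment_config()
records <- simulate_probe_experiment(cfg, h_true = 308)
fit <- fit_h(records[[2]], cfg, bounds = c(10, 1000))
print(fit)
#> h_fit P02: h = 307.9 W m-2 K-1, R2 = 1.0000

# 2) Dose report for a shallow skin-reaching target in a fat/muscle slab
p <- make_layered_phantom(c(64, 64, 64), spacing = 2, layers = c(fat = 8, muscle = NA))
p <- place_rod(p, "spinal_cord", center_depth = 26, radius = 4)
p <- place_ctv(p, center_depth = 8, radius = 8)
sar <- make_focal_sar(p, focus = c(9, 32, 32), fwhm = 15)
unlist(compute_ctv_depth(p))
#> median    min    max
#>      8      2     14

bcs <- bc_set(bolus = bc_robin(h = 292, T_ext = 30), exterior = bc_adiabatic())
report <- dose_report(p, default_tissue_table(),
                      model = perfusion_model("temperature_dependent"),
                      sar = sar, bcs = bcs)
round(as.data.frame(report), 3)
#>   power_scale    t50 mean_sar max_healthy_T depth_median depth_min depth_max
#> 1       3.594 45.789  251.653        43.995            8         2        14
#>   critical_spinal_cord ...
#> 1               39.724
```

Reading the numbers: the recovered film coefficient reproduces the value the
record was generated with. The dose report says total power had to be scaled
3.59× to drive the hottest healthy voxel to 44 °C (43.995 after tuning);
at that power half the target volume exceeds 45.8 °C and the mean target SAR
is 252 W kg⁻¹; the spinal-cord stand-in stays below 39.8 °C.

For a full sweep, build cases and run:

```r
cfg <- sweep_config(wb_temps = seq(20, 42.5, 2.5),
                    h_values = seq(59, 520, length.out = 9),
                    cases = list(shallow = list(phantom = p, sar = sar)))
res <- run_sweep(cfg)
render_report(res, "results/")
```

A thin command-line wrapper for the fit and sweep lives in
`inst/scripts/bolusplan`.

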