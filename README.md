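# chronopop

Radiocarbon **dates-as-data** palaeodemography in R: from a CARD-style
table of radiocarbon determinations to statistically defensible periods
of prehistoric population growth and decline.

## Who this is for

Archaeologists and human-population ecologists who have (or can simulate)
a regional radiocarbon database export and want the standard
dates-as-data inference chain as tested, scriptable functions rather than
a one-off GIS-plus-spreadsheet workflow: chronometric hygiene,
calibration, density/site-count proxies, taphonomic correction, and
trend-change detection.

## The method

If deposition tracks population, the temporal frequency of ^14^C-dated
samples proxies relative population size. chronopop runs a seven-step
procedure:

1. **Study area** — standard deviational ellipse (2 s.d.) around anchor
   sites; records outside are dropped.
2. **Chronometric hygiene** — remove duplicate lab numbers,
   palaeobiological/geological contexts, and anomalous records; never
   filter on age or error size.
3. **Calibration** — grid-based single-date calibration,
   $p(t) \propto N(a;\,\mu(t),\sqrt{e^2+\sigma(t)^2})$ against an
   IntCal-format curve; keep the median calibrated age.
4. **Proxies** — Sheather–Jones Gaussian KDE of the medians, and distinct
   dated sites (complete Smithsonian trinomials) per 100-year bin, both
   on the 0–15,000 cal BP grid (151 points).
5. **Taphonomic correction** — divide by the power-law relative survival
   $s(t) = ((t+b)/b)^c$ (defaults $b = 2176.4$, $c = -1.3925309$),
   keeping observed and corrected versions: four proxies per run.
   Optional 50%-subsample bootstrap envelopes.
6. **Trend fitting** — quasi-Poisson log-link GLM (global trend) and
   GCV-penalized spline GAM (local trend) of each proxy on time.
7. **Change detection** — finite-difference first derivative of the GAM
   fit with delta-method confidence intervals; maximal runs of grid
   points whose interval excludes zero are the significant periods of
   increase/decrease.

A synthetic-data module (`make_scenario()`, `make_card_like_table()`)
generates CARD-like tables from known population curves — with
taphonomic thinning, measurement error, and injectable hygiene
contaminants — so the whole chain can be validated against ground truth.

## Worked example

Simulate a 2,000-date CARD-like export from a population that doubles
between 6900 and 5200 cal BP (with taphonomic loss and contaminant
records), then run the full pipeline:

```r
library(chronopop)
dir <- tempfile("chronopop-demo-"); dir.create(dir)

sim <- make_card_like_table(
  make_scenario("step_growth"),
  n_dates = 2000, taph_loss = TRUE,
  contamination = list(duplicate = 0.03, anomalous = 0.02, context = 0.02),
  seed = 42
)
write_dates(sim$dates, file.path(dir, "dates.csv"))
write_curve(make_synthetic_curve(), file.path(dir, "curve.14c"))

report <- run_pipeline(run_config(
  dates = file.path(dir, "dates.csv"),
  curve = file.path(dir, "curve.14c"),
  out_dir = file.path(dir, "out"),
  seed = 42
))
print(report)
```

```
chronopop run report
  hygiene: 2140 -> 2000 records
  in study area: 2000; calibrated: 2000
  median cal BP range: 0 - 14946 (Q1 838, Q3 4555)
  derivative significance level used: alpha = 0.05
  kde_density (observed): GAM edf 9.42, dev.expl 0.99; 2 significant period(s)
      increase 15000-11700 cal BP
      increase 7800-0 cal BP
  kde_density (corrected): GAM edf 9.84, dev.expl 0.92; 6 significant period(s)
      increase 15000-12100 cal BP
      decrease 9000-7800 cal BP
      increase 7300-4700 cal BP
      decrease 4400-3200 cal BP
      increase 2800-1700 cal BP
      decrease 1400-0 cal BP
  site_count (observed): GAM edf 8.04, dev.expl 0.95; 2 significant period(s)
      increase 13900-12200 cal BP
      increase 7800-0 cal BP
  site_count (corrected): GAM edf 7.54, dev.expl 0.46; 2 significant period(s)
      increase 13600-12900 cal BP
      increase 7200-4700 cal BP
```

Reading it: hygiene removed exactly the 140 injected contaminants; every
proxy flags a significant increase overlapping the true 6900–5200 ramp
(e.g. 7200–4700 for corrected site counts — GAM smoothing widens the
edges). The *observed* proxies also trend upward toward the present
because taphonomic loss was simulated; the corrected series isolate the
demographic signal. The extra short periods in the corrected KDE panel
illustrate why count proxies are the sturdier guard against false
positives — see the methods vignette
(`vignettes/chronopop-methods.Rmd`).

Per-step functions (`apply_hygiene()`, `calibrate_batch()`,
`build_proxies()`, `fit_gam()`, `derivative()`, `significant_periods()`)
expose the same chain piecewise; `tidy()`/`glance()` give broom-style
summaries of fits, and `autoplot()`/`plot_trend_panel()` draw them.
`inst/scripts/chronopop-run.R` is a command-line wrapper over
`run_pipeline()`.

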