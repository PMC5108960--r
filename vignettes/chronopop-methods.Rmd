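---
title: "Inferring relative population trends from radiocarbon date tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring relative population trends from radiocarbon date tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopop)
```

## The dates-as-data model

chronopop implements the "dates as data" approach to palaeodemography: if
archaeological deposition is roughly proportional to the number of people
alive, then the temporal frequency of radiocarbon-dated samples is a proxy
for relative population size. The package takes a table of radiocarbon
determinations (lab number, uncalibrated ^14^C age ± 1σ, site identifier,
coordinates, context flags), cleans it, calibrates it, and asks one
question of the result: *when did the population underlying this record
grow or shrink significantly?*

The analysis is a fixed seven-step procedure:

1. **Study area.** A standard deviational ellipse (SDE) is fitted to a set
   of anchor sites — by default the seven Eastern North American sites
   with the earliest evidence of plant domestication — and records outside
   the ellipse are dropped. The SDE centre is the mean of the projected
   coordinates, its axes are the principal axes of the centred
   second-moment matrix, and the boundary is drawn at `scale` standard
   deviations (default 2, the conventional "α = 0.05" envelope expected to
   enclose ~95% of the generating population).
2. **Chronometric hygiene.** Duplicate laboratory numbers are removed
   (first occurrence kept; comparison case-insensitive, whitespace
   stripped), then records from palaeobiological and geological contexts,
   then records flagged anomalous. Nothing is filtered on age or error
   magnitude: hygiene removes provenance problems, not inconvenient data.
3. **Calibration.** Each determination $a \pm e$ is calibrated on a 1-year
   calendar grid against an IntCal-format curve $(\mu(t), \sigma(t))$:
   $p(t) \propto N\!\left(a;\, \mu(t), \sqrt{e^2 + \sigma(t)^2}\right)$,
   normalized to sum to one after truncating tails below $10^{-6}$
   cumulative mass. Only the **median** calibrated age (smallest grid year
   reaching half mass) feeds the analysis — full posteriors are summarized
   to points, not summed.
4. **Proxies.** Two summaries on the standard grid of 0–15,000 cal BP in
   100-year steps (151 points): a Gaussian kernel density estimate of the
   median ages with the Sheather–Jones solve-the-equation bandwidth, and
   the number of distinct sites (complete Smithsonian trinomials only)
   dated in each 100-year bin.
5. **Taphonomic correction.** Older deposits are progressively lost. Both
   proxies are corrected by dividing by the relative survival function
   $s(t) = ((t+b)/b)^{c}$ with the published power-law constants
   $b = 2176.4$ yr, $c = -1.3925309$ (overridable), normalized so
   $s(0)=1$. Observed and corrected versions are both kept: four proxies
   in all, so that no conclusion depends on the correction alone.
   Optionally, a subsampling bootstrap (50% of dates, 1000 iterations,
   pointwise 2.5/97.5 percentiles) quantifies sample-size sensitivity.
6. **Trend fitting.** Each proxy is regressed on calendar time with a
   log-link quasi-Poisson model: a GLM with a single linear time term (the
   "global" exponential trend) and a penalized thin-plate regression
   spline GAM (the "local" trend), smoothness chosen by generalized
   cross-validation. Quasi-likelihood frees the dispersion, which both
   absorbs over/under-dispersion and makes significance invariant to any
   positive rescaling of a proxy.
7. **Derivative significance.** The first derivative of the GAM fit is
   taken by finite differences on the 100-year grid (central differences
   at interior points, one-sided at the ends), with a confidence interval
   from the fit's coefficient covariance propagated through the same
   contrast (delta method through the log link). Maximal runs of
   consecutive grid points where the interval excludes zero are reported
   as significant periods of increase or decrease, older bound first.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `step` (calibration grid) | 1 | cal yr | median precision; 100× finer than the analysis grid |
| analysis grid | 0–15,000 by 100 | cal BP | the resolution at which change is assessed |
| taphonomic `b`, `c` | 2176.4, −1.3925309 | yr, – | survival model; from the published calibration of the correction, not re-estimated here |
| KDE bandwidth | Sheather–Jones (ste) | yr | data-driven smoothing of the date density |
| `basis_dim` | 10 | – | caps GAM flexibility at ~9 edf, comfortably above the 7.8–8.6 edf typical of Holocene records at this grid |
| `alpha` | 0.05 | – | derivative significance level; every run report prints the level used, because published analyses have mixed 95% intervals with α = 0.01 captions |
| bootstrap `frac`, `n_iter` | 0.5, 1000 | – | subsample fraction and iterations for the envelope |

## Design choices where the design was open

* **Median convention.** Multimodal posteriors make "the median"
  ambiguous at the level of a few years. We fix it as the smallest grid
  year whose cumulative mass reaches 0.5 — deterministic and
  reproducible; other software may differ by a few years, which is
  irrelevant at a 100-year analysis grid.
* **Count scaling of the KDE.** A log-link count family expects
  count-scale responses, so KDE densities are rescaled to expected dates
  per 100-year bin (density × n × 100) before fitting. Because
  quasi-likelihood estimates the dispersion, this scaling (or any other
  positive constant) provably does not change which periods are
  significant; it only makes fitted values interpretable.
* **Site counts after correction.** Correction turns integer counts into
  reals. We keep them real-valued and rely on quasi-likelihood fitting
  rather than rounding.
* **Derivative intervals.** Pointwise by default, matching the per-point
  exclusion criterion; a simultaneous band (max-|t| simulation from the
  coefficient posterior) is available via `simultaneous = TRUE` for users
  worried about multiplicity across 151 grid points.
* **Period reporting.** A "period" must span at least one grid step; a
  single significant grid point is noise at this resolution and is not
  reported (the per-point flags are still available from the derivative
  series).
* **SDE denominator.** The classic population (n) denominator is the
  default; the n−2 small-sample variant and Yuill's √2 correction used by
  some GIS tools are options, since published analyses rarely say which
  their tool used.
* **Boundary behaviour of the KDE.** No reflection or renormalization is
  applied at 0 cal BP, where real date densities are highest. This biases
  the density (and anything downstream of it) low within roughly one
  bandwidth of the present — visible in simulations as spurious
  "decrease" flags near 0 for the density proxy, and one reason the site
  count proxy is the more trustworthy of the two near the edges.

## The synthetic generator

Real continental radiocarbon archives are access-restricted, so the
package ships a generator that emulates the relevant structure of such an
export: calendar ages drawn in proportion to a known population curve
(`make_scenario()`: constant, exponential, logistic, step-growth, or a
Holocene-like curve with several growth and decline windows), thinned by
the same taphonomic survival model the correction inverts (loss applied
at the sampling stage, mimicking the physical process), measured against
a calibration curve by `uncalibrate()` (Gaussian draw with lab and curve
error in quadrature), and dressed with the contaminants hygiene exists to
remove: duplicated lab numbers, anomalous flags, palaeobiological and
geological contexts, incomplete trinomials, and coordinates outside the
study ellipse.

Generator defaults are the package's standard study conditions, chosen
once as realistic for a sub-continental Holocene archive: 2,000 dates
across 400 sites (≈5 dates per site, with geometric site-size variation
so a few rich sites dominate, as in real databases), lab errors uniform
on 20–80 ^14^C yr, and a synthetic calibration curve that is the identity
plus a 20-yr-amplitude, 1200-yr-period sinusoid with constant σ = 10 yr.
The curve is strictly monotone — real curves have reversals and plateaus
that can make single-date posteriors multimodal, so synthetic performance
near wiggle-dense stretches of a real curve will be somewhat worse than
these tests suggest. Other real-data features deliberately *not*
emulated: researcher bias (preferential dating of certain periods or site
types), spatial excavation bias, reservoir effects, and site-occupation
temporal structure (synthetic sites draw their dates from the whole
record, which makes the site-count proxy behave like a thinned copy of
the date-count proxy; in real data sites are temporally clustered).
Passing tests therefore show the *statistical machinery* is correct and
well-calibrated under known conditions — not that any particular real
record satisfies the dates-as-data assumptions.

## What the simulations establish

With the default conditions (20 replicates per design, n = 2000,
taphonomic thinning on):

* **Inversion.** On a constant population, after correction, the
  site-count GAM derivative flags ~5% or fewer grid points at α = 0.05
  and the GLM slope interval covers zero in ≥ 90% of replicates: the
  correction inverts the imposed loss without manufacturing trend.
* **Power.** A population that doubles log-linearly from 6900 to
  5200 cal BP is detected — a significant-increase period overlapping the
  ramp — in ≥ 90% of replicates by *all four* proxies.
* **Asymmetry of false positives.** On constant populations the corrected
  KDE proxy flags a large fraction of grid points (its smoothing
  correlates neighbouring grid values and deflates the estimated
  dispersion, so pointwise intervals are too narrow), while site counts
  remain honest. This reproduces the known contrast between density-based
  and count-based proxies; conclusions that matter should be cross-checked
  against the count proxy, and agreement across all four proxies is the
  standard the package's `common_growth()` helper encodes.
* **Envelopes.** The full-sample KDE lies inside the 50%-subsample
  bootstrap envelope at ≥ 90% of grid points.

The same quantities are recomputed from scratch by
`scripts/acceptance.R`; the tests assert them at the thresholds above.
Problem sizes (20 replicates, n = 2000, 200 bootstrap iterations in the
tests) are the package's chosen validation design, balancing Monte-Carlo
error against runtime.

## Numerical notes and degenerate inputs

* Calibration restricts evaluation to calendar years whose curve mean
  lies within 8 combined standard deviations of the measurement (with a
  binary-search fast path for monotone curves) before normalizing;
  posteriors entirely outside curve support raise a range error, and
  batch calibration reports such records instead of aborting.
* `sj_bandwidth()` tightens the selector's root tolerance and
  pairwise-distance binning (`nb = 10000`) so discretization error is
  well below bandwidth precision; it refuses fewer than 10 distinct
  values.
* All-zero series, collinear anchor geometries, already-corrected series,
  and empty proxy tables raise typed errors (`chronopop_degenerate_error`,
  `chronopop_geometry_error`, `chronopop_usage_error`) rather than
  propagating NaNs.
* GAM non-convergence raises `chronopop_convergence_error`; in
  `analyze_all()` and `run_pipeline()` per-proxy failures are caught and
  reported so the remaining proxies still run.
* Ties in the posterior median and boundary points of the ellipse are
  resolved deterministically (smallest grid year; boundary inclusive).

## Known limitations

* The pointwise derivative criterion tests 149 interior hypotheses per
  proxy; genuinely flat records will show occasional short flagged runs,
  and the KDE proxy in particular should not be read without the count
  proxy beside it.
* The taphonomic model is a single global power law; regionally varying
  preservation violates it in ways the correction cannot see.
* Correction by division changes the variance structure: a corrected
  count at age $t$ has variance $\propto \mu / s(t)$, not the
  $\phi\,\mu$ a quasi-Poisson fit assumes with one global dispersion. At
  the old end of the grid (where $1/s(t)$ approaches 19) derivative
  intervals for corrected counts are therefore somewhat anti-conservative:
  in constant-population simulations most replicates flag nothing, but an
  occasional replicate flags a run of old-end grid points, making the
  replicate-averaged false-positive fraction heavy-tailed around the
  nominal level. Findings that live entirely in the 10,000+ cal BP tail
  of a corrected count series deserve extra scepticism (or a
  survival-weighted refit).
* Coordinates are handled in an equirectangular projection about the
  anchors' mean latitude — adequate for a mid-latitude, sub-continental
  ellipse, wrong for polar or continental-scale areas.
* Calibration covers single dates only: no reservoir corrections, no ΔR,
  no phase/sequence modelling, and no summed probability distributions
  (medians only, by design).
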