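---
title: "Estimating epithelial ion fluxes from SIET scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating epithelial ion fluxes from SIET scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sietflux)
```

## The measurement and its model

The Scanning Ion-selective Electrode Technique (SIET) measures net ion
transport across an epithelium without touching it. An ion-selective
microelectrode is stepped perpendicular to the tissue between two points —
an inner point within ~5 µm of the surface and an outer point 50 µm further
out — inside the unstirred layer, the thin film of fluid where diffusion
rather than convection sets the concentration profile. A transporting
epithelium maintains a steady concentration gradient in that layer, the
electrode converts the local concentration into a voltage, and the
inner-minus-outer voltage difference therefore encodes the flux.

Each *cycle* is move–wait–sample at both excursion limits: a 4.0 s wait
(gradient re-establishment after the electrode's own stirring), a 0.5 s
sample, a 50 µm travel at 200 µm/s, and the same wait–sample at the far
point — 9.5 s per cycle under the defaults (`cycle_time(scan_protocol())`).
Three cycles form a measurement and two consecutive measurements are taken
per tissue site (~57 s). Sites are spaced 40 µm along the hindgut, covering
the posterior ileum and the rectum; the rectum is split into anterior and
posterior halves by site count (the extra site of an odd count goes to the
anterior half — a tie-break the data rarely exercises, fixed here once so
the partition is deterministic).

The application this package is organized around is cation transport across
the mosquito hindgut: Na⁺ and K⁺ fluxes in the ileum and rectum of adult
*Aedes aegypti*, and how they change when the heterodimeric glycoprotein
hormone GPA2/GPB5 (200 nM) is added to the bath. In controls the ileum
secretes Na⁺ and the whole hindgut absorbs K⁺; the hormone suppresses ileal
Na⁺ secretion by about three quarters and K⁺ absorption in the ileum and
anterior rectum by roughly two thirds and four fifths respectively.

## Electrode model

An ion-selective electrode is calibrated with two solutions spanning one
decade of concentration (15 and 150 mM); the *slope* `S` is the voltage
change per tenfold concentration change, fitted empirically per electrode
(`fit_slope()`). Typical fitted slopes are ~55.6 mV/decade for K⁺ and
~59.0 mV/decade for Na⁺ cocktails. No theoretical (temperature-derived)
Nernst slope is used anywhere: the empirical slope already absorbs
temperature and cocktail behaviour. Given three or more calibration points,
`electrode_calibration()` falls back to a least-squares fit of voltage on
log10 concentration, preserving the two-point contract otherwise.

The forward response (used only by the synthetic generator) is the
Nicolsky–Eisenman form

    V = V_high + S · log10( (C_primary + Σ_j k_j · C_j) / C_high )

where `k_j = 10^log10_k` weights each interfering ion. The K⁺ cocktail
rejects Na⁺, Ca²⁺ and Mg²⁺ by factors of 10^3.9, 10^4.9 and 10^4.9. For
the Na⁺ cocktail the package ships `log10_k(K) = −2.6` (with −3.5/−3.7 for
Ca²⁺/Mg²⁺) taken from a closely related cocktail formulation; the exact
cocktail's selectivity has not been measured, so this default is a
documented stand-in, not a measured constant.

Two simplifications are deliberate and global:

* **Concentrations stand in for activities.** Calibration and experimental
  salines have similar ionic strength, so activity coefficients cancel;
  there is no activity-coefficient parameter anywhere in the package.
* **Voltages are stored de-amplified.** Acquisition hardware amplifies
  1000-fold; `read_scan_csv(gain = 1000)` divides it out on ingest and all
  in-memory voltages are true electrode microvolts.

## From voltages to fluxes

For each site the per-cycle gradient is `V_inner − V_outer`, averaged over
all six cycles (grand mean; the mean-of-measurement-means is identical at
equal cycle counts, and the grand mean is the variance-efficient choice —
a `median` option exists for contraction-disturbed scans, off by default
since no cycle rejection is applied otherwise). The same quantity recorded
at a *reference site*, several hundred µm from the tissue, measures what
the gradient looks like with no epithelium nearby — ideally zero, in
practice a drift/noise signature — and is subtracted:

    ΔV = ΔV_site − ΔV_reference

Because the inner sample always precedes the outer sample by the same
4.75 s within a cycle, any drift that is linear in time and common to all
recordings contributes the identical offset to tissue and reference
gradients and cancels exactly in the subtraction.

The corrected gradient becomes a concentration gradient through the
calibration curve, expanded around the background concentration `C_B`:

    ΔC = C_B · (10^(ΔV/S) − 1)        [µmol cm⁻³]

and Fick's first law gives the flux across the Δx = 50 µm = 0.005 cm
excursion:

    J = D · ΔC / Δx                    [scaled to pmol cm⁻² s⁻¹]

with free-solution diffusion coefficients D = 1.92×10⁻⁵ cm² s⁻¹ (K⁺) and
1.55×10⁻⁵ cm² s⁻¹ (Na⁺). At the basal (haemolymph-facing) surface a
positive J — directed away from the tissue into the bath — is absorption
and a negative J is secretion; `estimate_fluxes(surface = "apical")` flips
the labels for lumen-facing scans without touching the numbers.

`C_B` is computed in one of two modes. `"measured"` (default) converts
every voltage sample of the scan to a concentration and averages — the
definition the flux equation is written for. `"nominal"` substitutes the
nominal bath concentration (3.4 mM K⁺; 20 mM Na⁺ in the
NMDG-substituted saline used to improve the Na⁺ signal:noise ratio) and is
the right choice when recordings lack an absolute calibration anchor, since
only voltage *differences* are then meaningful.

Each site also carries a signal:noise ratio `|ΔV_site| / |ΔV_reference|` —
the confidence that the gradient reflects transport rather than electrode
behaviour. Ratios below 1 are retained but flagged by `run_pipeline()`;
K⁺ scans typically sit at 3–6:1, ileal Na⁺ near 2:1, and rectal Na⁺ below
1:1, which is why rectal Na⁺ effects are the least trustworthy output of
this kind of experiment.

### Numerical accuracy of the inversion

The expansion `ΔC = C_B(10^(ΔV/S) − 1)` is exact when the outer sample
sits at the background concentration. The generator (next section) places
the *midpoint* of the excursion at the bath concentration, which is the
more physical reading of a linear unstirred-layer profile; against that
geometry the inversion carries a relative error of about `ΔC / (2 C_B)`.
For Na⁺ (C_B = 20 mM) this stays below 0.5% for any flux up to
500 pmol cm⁻² s⁻¹; for K⁺ (C_B = 3.4 mM) it reaches 0.5% near
120 pmol cm⁻² s⁻¹ and ~2% at 500. Fluxes in this preparation are an order
of magnitude below those bounds, so the error is irrelevant in practice,
but the property tests encode exactly these ranges rather than pretending
the inversion is exact.

Two further interactions are worth knowing:

* **Interferents bias the absolute concentration, barely the flux.**
  Behind a 10^−3.9 selectivity, 155 mM Na⁺ makes a K⁺ electrode read
  3.42 mM in a 3.4 mM solution (the inverted concentration overshoots by
  exactly `Σ k_j C_j`). The flux estimate is a *ratio* computation, so the
  residual bias is ~0.1–0.5%.
* **Drift inflates the measured C_B.** Reference subtraction removes drift
  from ΔV exactly, but `"measured"` C_B averages concentrations over the
  whole scan, so a drift of 30 µV/min adds ~0.45% to C_B (factor
  `10^(drift·t̄/S)`) and hence to every flux. At extreme drift
  (≥120 µV/min) this exceeds 1%; use `cb_mode = "nominal"` for heavily
  drifting electrodes.
* **Small-signal form.** For |ΔV/S| < 10⁻³ the chain is within 1% of the
  linearization `J ≈ D·C_B·ln(10)·ΔV/(S·Δx)`, a convenient sanity check on
  units.

## The synthetic-scan generator

`simulate_scan()` builds a complete synthetic preparation from known
ground truth so the entire chain can be validated by parameter recovery.
It emulates:

* a **linear steady-state concentration profile** in the unstirred layer:
  `C_inner − C_outer = J*·Δx/D`, midpoint at the bath concentration
  (planar diffusion; curvature from cylindrical geometry is ignored — the
  analysis' own Fick inversion over a 50 µm chord assumes planarity too);
* the **Nicolsky–Eisenman electrode response** with finite selectivity in
  the full bath composition;
* **linear voltage drift**, common-mode by default
  (`drift_uV_per_min`, default 30), with `drift_sd_uV_per_min` available
  to let each recording drift at its own rate — that is what makes
  reference correction *imperfect*, as real paired electrodes are;
* **Gaussian sampling noise** per 0.5 s voltage sample
  (`noise_sd_uV`, default 15 µV — sized so that simulated reference-site
  gradients scatter on the order the technique reports, i.e.
  per-preparation gradients of a few to a few tens of µV);
* the **protocol schedule**: sample times come from the same
  move–wait–sample arithmetic the analysis audits, reference recordings
  first (five measurements, ~5 min of recording), then sites in order with
  40 µm travel gaps. Exact within-cycle sample timing is not published at
  sub-second precision; the generator derives it from the protocol
  (inner sample at wait + half the sampling window, outer 4.75 s later),
  which fixes the drift geometry deterministically.

`default_experiment_config()` packages the study conditions: N = 10
preparations per arm; 5 ileum and 10 rectum sites (within the observed
4–5 and 6–18 ranges); control fluxes of −53.2 pmol cm⁻² s⁻¹ for ileal Na⁺
(the value the control gradient means invert to) and +26.7 for ileal and
anterior-rectum K⁺; under treatment the affected regions scale by the
reported effects (Na⁺ ileum ×0.25; K⁺ ileum ×0.32, anterior rectum ×0.21)
and the others are unchanged. Where no control value is published — Na⁺ in
the rectum halves, K⁺ in the posterior rectum — the defaults (+5, +5, +15)
are chosen once to match the qualitative description (slight rectal Na⁺
absorption; posterior-rectum K⁺ absorption below the anterior peak) and are
not tuned thereafter.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify about real data: peristaltic contractions
disturbing the unstirred layer (which bias real gradients downward),
two- or three-dimensional diffusion fields around curved tissue, electrode
positioning error, activity-coefficient differences, and electrode aging
within a scan beyond linear drift.

Determinism: every stochastic entry point takes a seed; identical truth
and seed give byte-identical datasets. `simulate_experiment(seed = NULL)`
draws from the current RNG stream, which is how a control/treatment pair
is simulated under one seed.

## Statistics

The preparation, not the site, is the unit of replication: site fluxes are
averaged per preparation and region first (`preparation_means()`), and all
inference runs on those means (site-level pooling would treat pseudo-
replicates as independent). Summaries are mean ± SEM; SEM is flagged `NA`
for a single preparation.

Percent change between conditions is computed on flux *magnitudes* —
`100·(|treatment| − |control|)/|control|` — so "secretion reduced 75%" and
"absorption reduced 68%" share one formula; a change of direction between
conditions (possible where fluxes cross zero, as rectal Na⁺ nearly does)
is reported as a separate `sign_reversal` flag rather than folded into the
percentage.

`anova_bonferroni()` runs a classical equal-variance one-way ANOVA
(`stats::aov`) followed by pooled-SD pairwise t tests, each raw p-value
multiplied by the comparison count and capped at 1 — the Bonferroni
post-test as implemented by the graphing software this workflow
historically used. The comparison count is explicit: `compare_treatments()`
defaults it to the number of regions compared, so testing the same
contrast in three regions triples each p-value. A `welch = TRUE` flag
switches to unequal-variance forms. Significance is declared at adjusted
p < 0.05 by default (`alpha`).

Two sampling facts shape how results should be read at these study sizes
(N = 10, 15 µV sample noise). First, the per-preparation corrected
gradient carries an SD of ~7 µV, dominated by the reference estimate (15
cycles) slightly more than the five-site tissue mean. Second, percent
change divides by the control mean, so its precision depends on the size
of the control gradient: the K⁺ comparisons (~49 µV corrected gradient)
recover their effects within a few points, while ileal Na⁺ (~22 µV) yields
single-batch percent-change estimates with an SD on the order of ten
points. A single simulated batch is therefore a noisy estimator of the Na⁺
effect size even when the pipeline is exactly correct — the same caveat
applies to any single N = 10 experiment.

## Problem sizes used in the tests

The shipped test suite validates the chain at deliberately small sizes:
single-preparation noise-free scans for exactness properties; 10 + 10
preparations with 5–10 sites for effect-size recovery; 12 full-pipeline
batches for the power check on the ileal Na⁺ comparison; 40 batches for
SEM-coverage consistency; and 500 two-group null replicates (drawn directly
at the preparation level) for type-I error control. These sizes make the
suite fast while keeping every statistical claim testable; scaling any of
them up only narrows the Monte-Carlo bands.

## Known limitations

* Rectal Na⁺ conclusions inherit sub-unity signal:noise; the pipeline
  flags but does not down-weight such sites.
* The Na⁺ selectivity default is borrowed from a related cocktail (above).
* `"measured"` C_B assumes an absolutely anchored calibration and a
  drift-free-ish scan; use `"nominal"` otherwise.
* The flux is a net transepithelial estimate at the scanned surface; it
  cannot separate transcellular from paracellular routes, nor resolve
  time-varying transport within a scan.
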