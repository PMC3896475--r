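# sietflux

Ion flux estimation from Scanning Ion-selective Electrode Technique (SIET)
recordings, for epithelial transport physiologists.

SIET steps an ion-selective microelectrode between two points 50 µm apart
inside the unstirred layer next to an epithelium. The voltage difference
between the points encodes the local concentration gradient of the measured
ion, and the gradient encodes the transepithelial flux. This package turns
raw per-site voltage recordings into corrected gradients, concentration
gradients, Fick's-law Na⁺/K⁺ fluxes, region-wise summaries, and
control-vs-hormone comparisons. It was built around scans of the adult
mosquito hindgut (posterior ileum and rectum) treated with the glycoprotein
hormone GPA2/GPB5, but the machinery is generic to any planar SIET
preparation.

## The computation

Per electrode, a two-point calibration fixes the Nernst slope `S` (µV per
tenfold concentration change). Per site, the cycle gradients
`ΔV = V_inner − V_outer` are averaged and corrected by the gradient
recorded at a reference site far from the tissue (removes electrode noise
and common drift). The corrected gradient then becomes a flux via

    ΔC = C_B · (10^(ΔV/S) − 1)        (µmol cm⁻³)
    J  = D · ΔC / Δx                   (pmol cm⁻² s⁻¹, Δx = 0.005 cm)

where `C_B` is the background ion concentration, and `D` the ion's
diffusion coefficient (1.92×10⁻⁵ cm² s⁻¹ for K⁺, 1.55×10⁻⁵ for Na⁺). At
the basal surface, positive `J` (toward the bath) is absorption; negative
is secretion. Statistics run on per-preparation regional means: one-way
ANOVA with Bonferroni-adjusted pairwise comparisons, plus percent change
in flux magnitude between conditions.

A synthetic-scan generator (`simulate_scan()`, `simulate_experiment()`)
emulates the electrode physics — Nicolsky–Eisenman response with finite
selectivity, linear drift, Gaussian sampling noise, and the
move–wait–sample protocol timing — from known ground-truth fluxes, so the
entire pipeline is validated by parameter recovery. See the methods
vignette (`vignettes/siet-flux-analysis.Rmd`) for the model, defaults and
their rationale.

## Worked example

The single-site chain, on the typical control K⁺ gradient means
(+36.3 µV at the tissue, −13.1 µV at the reference):

```r
library(sietflux)
dv <- correct_gradient(36.3, -13.1)             # 49.4 uV
dc <- concentration_gradient(dv, 3.4, 55600)    # 0.006963 umol/cm3
fick_flux(dc, 1.92e-5, 0.005)                   # 26.7 pmol/cm2/s: absorption
```

A full simulated experiment — 10 control and 10 hormone-treated
preparations, 5 ileum + 10 rectum sites each, 15 µV sample noise,
30 µV/min drift — analyzed end to end:

```r
cal  <- default_calibration("K")
ctrl <- default_experiment_config("K", "control")
trt  <- default_experiment_config("K", "GPA2/GPB5")
set.seed(1)
pm <- function(tr, lab) preparation_means(assign_regions(
  do.call(rbind, lapply(
    simulate_experiment(tr, cal, treatment_label = lab, seed = NULL),
    estimate_fluxes))))
compare_treatments(pm(ctrl, "control"), pm(trt, "GPA2/GPB5"))
```

```
            region control_mean treatment_mean percent_change bonferroni_p significant
1  anterior_rectum         25.4           6.61          -74.0     6.05e-11        TRUE
2            ileum         25.6           9.34          -63.5     8.06e-11        TRUE
3 posterior_rectum         14.1          16.55           17.7     1.62e-01       FALSE
```

Read: the treatment suppressed K⁺ absorption by ~74% in the anterior
rectum and ~64% in the ileum (both significant after Bonferroni
adjustment across the three regions), with no significant change in the
posterior rectum — the generator's truth for this run was a 79% and 68%
reduction and no posterior change, so the pipeline recovers the effects
within single-batch sampling error.

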