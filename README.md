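# astigvec

Vector analysis of astigmatism for longitudinal toric intraocular lens
(IOL) cohorts.

## The problem

After cataract surgery with a toric IOL, the cornea keeps drifting — on
average toward against-the-rule (ATR) astigmatism — while the lens inside
the eye does not. Deciding whether the lens still works years later
requires decomposing each eye's astigmatism into three vector quantities
and following them over time:

* **manifest refractive astigmatism** (whole eye, spectacle plane),
* **anterior corneal astigmatism** (keratometry: magnitude + steep
  meridian),
* **ocular residual astigmatism (ORA)** = refractive − corneal, as a
  vector difference at the corneal plane — in a pseudophakic eye this is
  mostly the toric IOL's correcting cylinder plus posterior cornea and IOL
  tilt/decentration.

Astigmatism is axial (period 180°), so the arithmetic happens in
**double-angle space**: `(u, v) = (C cos 2θ, C sin 2θ)`, where
astigmatisms add, subtract, and average linearly. Longitudinal endpoints
are the **Naeser polar values** `Rx = C cos 2(θ−90°)` (positive =
with-the-rule, negative = ATR) and `Ry = C sin 2(θ−90°)` (oblique).
Changes are tested per component with a paired *t* and bivariately with a
one-sample **Hotelling T²** on the paired differences
`(ΔRx, ΔRy)` — `T² = n d̄ᵀS⁻¹d̄`, `F = (n−p)/(p(n−1))·T² ~ F(p, n−p)` —
plus Monte-Carlo power analysis, double-angle plots with centroids and
χ²-quantile confidence ellipses, and a synthetic two-group cohort
generator parameterized from a published 5–10-year toric-IOL follow-up
study, so the entire chain runs and is tested offline.

## Worked example

```r
library(astigvec)

k  <- astig(1.8, 7)                 # keratometry: 1.8 D, steep meridian 7°
rx <- spherocyl(-0.25, -1.25, 95)   # manifest refraction, spectacle plane

naeser_polar(k)
#>          rx         ry
#> 1 -1.746532 -0.4354594         # Rx < 0: an ATR cornea

compute_ora(rx, k, analysis_config())    # refractive − corneal, corneal plane
#> <astig: 1 vector>
#>   magnitude_D meridian_deg
#> 1   0.5850234     101.1968

astig_classify(k)
#> [1] ATR
```

The residual 0.59 D is what the cornea's 1.8 D cylinder leaves uncorrected
by this eye's refraction — in a toric-IOL eye, the lens's doing.

A full synthetic cohort (two groups of 60 eyes, baseline + 5–10-year
follow-up, generated with the published group distributions) through the
whole pipeline:

```r
co  <- simulate_cohort(default_paper_config(), seed = 2024)
res <- summarize_cohort(co)

subset(res$components, group == "ATR" & component == "RX",
       c(measure, baseline_mean, followup_mean, p))
#>     measure baseline_mean followup_mean            p
#>  refractive    -0.2445768    -0.4994331 0.0007486480
#>     corneal    -0.7094727    -0.9033611 0.0001365234
#>         ora     0.4662576     0.4092812 0.2309380820

subset(res$bivariate, group == "ATR")
#>  group    measure        T2         F df1 df2            p  n
#>    ATR refractive 12.653988  6.219757   2  58 0.0035705713 60
#>    ATR    corneal 20.608717 10.129708   2  58 0.0001685972 60
#>    ATR        ora  2.517451  1.237391   2  58 0.2976847934 60
```

Read: in the ATR group the refractive and corneal `Rx` drift significantly
negative (an ATR shift of ≈ −0.2 D over ~6.6 years, paired-*t* and
Hotelling p ≪ 0.05) while the ORA — the lens's contribution — does not
change (p ≈ 0.23–0.30). That is the signature the pipeline is built to
detect: the cornea ages, the toric correction holds.

`res` also contains the visual-acuity table (`res$va`), per-timepoint
centroids and confidence ellipses (`res$centroids`, `res$ellipses`), and
the between-group baseline comparison (`res$baseline_characteristics`).
`plot_cohort(co, "plots/")` renders one double-angle plot per group ×
measure (baseline green squares, follow-up red circles, centroid markers,
dataset and centroid 95% ellipses).

## Command line

```sh
inst/cli/astigvec simulate --seed 1 --out cohort.csv
inst/cli/astigvec analyze  --in cohort.csv --out results.json --plots plots/ --vertex-mm 12
inst/cli/astigvec power    --effect-rx 0.20 --effect-ry 0.20 --n 60 --reps 10000 --seed 1
inst/cli/astigvec plot     --in cohort.csv --measure corneal --out corneal.svg
```

`analyze` also accepts a supplementary spreadsheet via
`--xlsx FILE --mapping FILE`, where the mapping is a plain-text
`canonical_column = sheet column` file (the layout of such files is never
assumed).

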