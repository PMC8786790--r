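---
title: "Vector analysis of astigmatism in longitudinal toric-IOL cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector analysis of astigmatism in longitudinal toric-IOL cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigvec)
```

## The problem

A toric intraocular lens (IOL) neutralizes the corneal astigmatism measured
at surgery, but the cornea keeps drifting — on average toward
against-the-rule (ATR) astigmatism — for decades afterwards. Whether the
lens "wears out" therefore depends on separating three astigmatism sources
per eye and per visit:

* **manifest refractive astigmatism** — the whole eye's astigmatic error,
  from the subjective/objective refraction at the spectacle plane;
* **anterior corneal astigmatism** — from keratometry (magnitude plus steep
  meridian);
* **ocular residual astigmatism (ORA)** — the vector difference
  *refractive − corneal* at the corneal plane. In a pseudophakic eye this
  is dominated by the toric IOL's correcting cylinder (plus IOL
  tilt/decentration and the posterior cornea), so a stable ORA with a
  drifting cornea is the signature of a lens that still works while the
  cornea moves underneath it.

`astigvec` implements this decomposition and the longitudinal statistics
around it for a two-timepoint (baseline vs. ~5–10-year follow-up),
two-group (preoperative ATR vs. WTR astigmatism) design, together with a
synthetic cohort generator so the entire chain is testable offline.

## Double-angle algebra and Naeser polar values

Astigmatism is axial: a cylinder at 10° equals one at 190°. Mapping each
astigmatism of magnitude $C$ and steep meridian $\theta$ to the point

$$(u, v) = (C\cos 2\theta,\; C\sin 2\theta)$$

makes the space Euclidean: astigmatisms add and subtract as ordinary
vectors, the centroid of a group is the componentwise mean, and a 90°
meridian rotation is a sign flip. The package's `astig` class stores
$(C, \theta)$ with $C \ge 0$ and $\theta \in [0, 180)$; `to_double_angle()`
/ `from_double_angle()` convert, `astig_combine()` adds or subtracts, and
`astig_centroid()` averages.

The univariate endpoints are the **Naeser polar values**

$$R_x = C\cos 2(\theta - 90°), \qquad R_y = C\sin 2(\theta - 90°),$$

i.e. the negated double-angle components. $R_x > 0$ means with-the-rule
(steep near 90°), $R_x < 0$ against-the-rule; $R_y$ captures the oblique
part. The source description fixes only the $R_x$ sign rule; we adopt the
$R_y$ sign that the same formula implies ($R_y > 0$ for a steep meridian of
135°) and flag it here, since conventions differ in the literature.

**Classification.** Steep meridian in $[60°, 120°]$ is WTR, in
$[0°, 30°] \cup [150°, 180°)$ ATR, otherwise oblique. The description of
the bands says only "between", leaving the boundary meridians ambiguous; we
assign 30°, 60°, 120°, 150° to the *non-oblique* class by default and
expose the choice (`boundary = "oblique"` flips it). Zero-magnitude
astigmatism has no meridian and `astig_classify()` refuses it rather than
guessing.

**Numerical choices.** Angles are stored in degrees and trigonometry is
done in radians; every meridian is reduced mod 180 on construction, with an
explicit guard for the floating-point case where a tiny negative angle
reduces to exactly 180. All-zero double-angle components map to the
canonical zero vector (0 D @ 0°) so equality and round-trips are well
defined; round-trip accuracy is enforced at 1e−9 D / 1e−7° in the test
suite, and `astig_combine()` is checked against an independent oracle that
represents each astigmatism as the traceless part of a 2×2 dioptric power
matrix and adds matrices.

## Plane conversion and ORA

A spectacle-plane refraction does not act at the cornea. `vertex_convert()`
moves each *principal meridian power* $F$ through the thin-lens effectivity
relation $F' = F/(1 - dF)$ (spectacle→corneal; inverse $F/(1+dF)$ going
back) and reassembles sphere/cylinder/axis from the two converted powers.
Converting the cylinder directly would be wrong: effectivity is nonlinear,
so the two principal powers must be converted separately — the axis never
changes, the cylinder magnitude does. The vertex distance $d$ is not stated
by the emulated study; we default to the conventional refraction-lane
**12 mm** and expose it in `analysis_config()` (and as `--vertex-mm` on the
command line).

`compute_ora()` is then literal: convert the manifest refraction to the
corneal plane, extract its astigmatism vector (`refractive_astig()`: in
minus-cylinder form the steep meridian lies 90° from the cylinder axis),
and subtract the keratometric vector in double-angle space. Following the
emulated design, summary tables present refractive astigmatism at the
*spectacle* plane and ORA at the *corneal* plane; this asymmetry is built
into `eye_measures()` / `summarize_cohort()` rather than left to the
caller.

Minus-cylinder is the canonical internal notation; plus-cylinder input is
transposed on ingestion (`as_minus_cyl()`), and `transpose_notation()`
itself is the exact involution, preserving the principal powers.

## The statistical model

Per group and measure, the change from baseline to follow-up is tested

* **per component** with a paired $t$ on $R_x$ and on $R_y$, and
* **bivariate** with a one-sample Hotelling $T^2$ on the paired differences
  $(\Delta R_x, \Delta R_y)$:
  $T^2 = n\,\bar d^{\,\top} S^{-1} \bar d$,
  $F = \frac{n-p}{p(n-1)}T^2 \sim F(p,\, n-p)$ with $p = 2$.

The emulated analysis calls the bivariate step "MANOVA"; for two timepoints
within eye the repeated-measures MANOVA reduces exactly to this one-sample
$T^2$ on differences, which is what `hotelling_paired()` implements (a
one-column input reproduces $t^2$, which the tests check). Degenerate
inputs follow the limiting conventions: all-zero differences give
$t = 0, p = 1$ (and $T^2 = 0, p = 1$); zero variance with nonzero mean
gives $p = 0$; a singular difference covariance is an error, not a
pseudo-inverse.

**Power.** `power_hotelling_sim()` estimates power by simulating cohorts of
differences from a bivariate normal and counting rejections, with a
binomial CI; `power_hotelling_exact()` is the noncentral-$F$ closed form
used as a cross-check. Simulation is the primary route because the study
whose design we emulate reports power figures (92.4% / 93.3% at a
0.20/0.20 D effect, $n = 60$) *without* reporting the difference covariance
they assumed — those printed percentages are therefore not reproducible,
and the package's acceptance checks substitute properties that do not
depend on the unknown covariance: size equals $\alpha$ at zero effect, and
power increases strictly in $n$ at the 0.20/0.20 D effect.

**Confidence ellipses.** `confidence_ellipse()` scales the sample
covariance eigendecomposition by the $\chi^2_2$ quantile at the chosen
level — the whole-dataset ellipse — or by that quantile divided by $n$ for
the centroid (mean) ellipse, the two overlays of the standard double-angle
plot tools. Collinear point sets are an error.

**Baseline characteristics.** Continuous variables use an unpaired $t$;
the source description does not say which variant, so the default is
Welch's unequal-variance form with `var_equal = TRUE` as the pooled option.
For 2×2 categoricals (sex, eye side) the description says "chi-square or
Fisher's exact where applicable" without saying which was used per row, so
`compare_baseline_characteristics()` reports **both** (Pearson without
continuity correction, and two-sided Fisher).

## What the synthetic generator emulates — and what it does not

`default_paper_config()` encodes the emulated study's published summary
statistics as generator truth: two groups of $n = 60$; ATR group age
$\mathcal N(73.12, 6.04^2)$, 36/60 male, follow-up interval
$\mathcal N(6.60, 1.42^2)$ years; WTR group age $\mathcal N(64.35,
8.09^2)$, 19/60 male, interval $\mathcal N(6.83, 1.67^2)$; baseline and
follow-up normals for the corneal and ORA Naeser components (e.g. ATR
corneal $R_x$: $-0.76 \pm 0.39$ at baseline, $-0.99 \pm 0.53$ at follow-up
— a $-0.23$ D ATR drift; WTR corneal $R_x$: $0.94 \pm 0.57$ vs
$0.91 \pm 0.55$, essentially no drift; ORA stable in both groups).

Per eye, `simulate_cohort()` draws each component's baseline/follow-up pair
jointly normal with the published marginal means and SDs and a within-eye
correlation $\rho$; drift enters through the follow-up means. The manifest
refraction is *derived*, not drawn: at the corneal plane its astigmatism is
the vector sum corneal ⊕ ORA plus measurement noise, combined with the
eye's drawn spherical equivalent and vertex-converted out to the spectacle
plane for storage. On a noiseless configuration, `compute_ora()` therefore
recovers the injected ORA exactly — the pipeline's round-trip identity.

Free parameters the tables do not determine, chosen once:

* $\rho = 0.7$ — the baseline/follow-up correlation is unreported; 0.7 is a
  plausible long-interval test–retest correlation for keratometry and is
  the single knob controlling the change-score SD (which the study also
  does not report). It is exposed in `simulation_config()`, and every
  acceptance use of it is property-based (rejection rates, monotonicity),
  not value-matching.
* measurement noise SD 0.10 D per double-angle component of the refraction,
  reflecting autorefractor repeatability.
* the follow-up interval is clamped to the design's 5–10-year window; the
  spherical equivalent is drawn once per eye and held across timepoints
  (a stable pseudophakic eye); logMAR acuities are drawn from the published
  per-timepoint normals; reliability indices are 8–9 because the cohort
  emulates data *after* the high-reliability filter.

Deliberate departures from strict realism: the generator does not truncate
each eye's baseline corneal vector to its group's classification band.
Group is the preoperative *design label*; enforcing
`classify(baseline) == group` would truncate the published normals and bias
the very means the parameter-recovery acceptance check (3 SE at
$n = 5000$/group) verifies. Real eyes also age nonlinearly, have
non-normal astigmatism tails, and correlate acuity with residual cylinder —
none of which is modeled. A green test therefore establishes that the
pipeline recovers what the generator injects under the published
first-and-second-moment structure, not that it would reproduce any
particular clinic's data.

## Eligibility filters

`reliability_filter()` keeps measurements with autorefractor reliability
index ≥ 8 (device range 5–9) and logs one structured line per exclusion.
`repeatability_check()` applies the two-examination keratometry rule —
cylinder within 0.5 D and steep meridian within 15° (axial distance, so
5° vs 175° passes at 10°). Both are idempotent and never drop silently.
Clinical eligibility that needs chart review (uneventful surgery, ocular
pathology) is out of scope and modeled only as metadata.

## Known limitations

* The study's printed power values and Table p-values cannot be reproduced
  without its per-eye data; the supplementary spreadsheet is a binary
  download unavailable offline, so the benchmark-reproduction check is
  implemented (`read_supplementary_xlsx()` + a column-mapping config,
  exercised on synthetic fixtures) but reported as not run.
* Keratometric-index and posterior-cornea measurement models are out of
  scope; ORA absorbs the posterior cornea by construction.
* Only two timepoints: `hotelling_paired()` is not a general
  repeated-measures MANOVA, and no nonparametric alternatives are offered
  (the emulated endpoints were approximately normal).
* Surgically induced astigmatism indices (Alpins correction index, angle of
  error) are intentionally absent: the emulated analysis does not compute
  them.
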