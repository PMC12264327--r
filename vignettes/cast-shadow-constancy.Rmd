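---
title: "Measuring color constancy in cast shadows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring color constancy in cast shadows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowconstancy)
```

## The problem

On a sunny day a surface inside a cast shadow is lit almost exclusively by
skylight, which differs from direct sunlight both in intensity (here by an
order of magnitude) and in chromaticity. Observers nevertheless judge
surface colors in shadows stably. This package implements the quantitative
machinery for studying that ability with the achromatic-setting method: an
observer adjusts the chromaticity and luminance of a test field embedded in
a scene until it looks like a full-white surface under the local
illumination, and the degree of color constancy is derived from how those
settings move when the skylight color changes.

The package models a two-projector scene: a fixed "sunlight" (CIE xy =
0.339, 0.353 at 41.9 cd/m^2) and one of five "skylights" — white (0.334,
0.345), yellow (0.377, 0.379), blue (0.259, 0.271), magenta (0.387, 0.258),
green (0.257, 0.395) — all near 3 cd/m^2. A central occluder casts a shadow
over the right test field, which therefore receives skylight only; the left
field receives the sum of both lights. The skylights span typical (blue,
yellow, white) and atypical (green, magenta) shadow illuminations, which is
what lets the analysis ask whether observers exploit prior knowledge about
natural shadow colors.

## Colorimetry

All chromatic computation runs through cone excitations,
`L = sum(E(lambda) * Lbar(lambda)) * dlambda` (rectangle rule at 1 nm on a
390–780 nm grid), and the MacLeod–Boynton projection

```
l = kL * L / (kL * L + kM * M)
s = kS * S / (kL * L + kM * M)
```

with the CVRL luminance weights for unit-peak 2-degree fundamentals
(`kL = 1.980647`, `kM = 1`) and `kS` fixed by the convention that the
equal-energy spectrum maps to `s = 1` exactly. `kS` is recomputed from
whatever fundamentals table is in use rather than hardcoded, so the `s = 1`
anchor holds for user-supplied tables too.

### Synthetic observer tables

No tabulated standard-observer data ship with the package; both bundled
tables are generated analytically by package code and carry `synthetic` in
their fixture filenames:

* **Cone fundamentals** (`synth_cone_fundamentals()`): Govardovskii A1
  pigment absorbance templates, converted to absorptance with axial optical
  densities 0.50/0.50/0.40 (L/M/S), filtered through parametric lens and
  macular pigment densities (exponential lens cutoff scaled to density 1.8
  at 400 nm; Gaussian macular pigment peaking at 0.35 at 460 nm), converted
  from quantal to energy units, and peak-normalized. The L cone is the
  0.56/0.44 mixture of the ser180/ala180 polymorph pigments 3.5 nm apart.
  The only calibration targets are the published corneal peak wavelengths
  (570.2, 542.8, 442.1 nm); absorbance peaks are solved to place the
  corneal peaks there. As an independent check — no parameter was fitted to
  it — the equal-energy white then lands at `l = 0.7064`, within 0.2% of
  the 0.7078 that the published convention assigns to that anchor. That
  residual is the accuracy limit of the analytic synthesis and is inherited
  by every absolute `l` value the package reports; all *differential*
  quantities (shift vectors, constancy indices) are insensitive to it.
* **Color matching functions** (`synth_cmf_1931()`): the multi-lobe
  piecewise-Gaussian fit to the CIE 1931 2-degree observer (Wyman, Sloan &
  Shirley 2013). Equal energy maps to (x, y) within 0.001 of (1/3, 1/3).
  Luminance is `683 * integral(E * ybar)` cd/m^2.

Because the scene generator *optimizes spectra against these same tables*,
target chromaticities are met in a self-consistent sense; absolute
agreement with instrument-measured colorimetry is limited by the ~1% CMF
fit accuracy, which is irrelevant to the within-package analyses.

The working grid is 390–780 nm at 1 nm. Printed-surface reflectances are
measured from 400 nm; they are extended down to 390 nm by constant
edge-value extrapolation, where the fundamentals retain less than 0.5% of
peak sensitivity, so the extension carries negligible weight.

## Scene synthesis

Only the illuminants' chromaticities and luminances are published, not
their spectra, so `make_skylight()` synthesizes a smooth nonnegative SPD
realizing each reference target:

* near-neutral targets use a **daylight-like basis** — the mean plus first
  two principal components of Planckian radiators between 4000 and
  25000 K, a fully analytic stand-in for the classical daylight
  characteristic vectors;
* targets outside that family's gamut (green, magenta) use a nonnegative
  mixture of 12 Gaussian bumps (centers every ~33 nm, 40 nm width). The `auto`
  basis switches to bumps whenever the daylight fit would need to clip more
  than 2% of its power negative.

Realized chromaticity must fall within 0.005 of target (achieved ~1e-8);
luminance is matched exactly by scaling. Six surface reflectances are drawn
as logistic-squashed low-order Fourier series on 400–780 nm, redrawn until
all pairs are separated by at least 0.06 in MacLeod–Boynton (l, s) under
the sunlight — a floor chosen so the surfaces are as visually distinct as
printed color samples need to be, while remaining within printable
reflectance ranges (values kept in [0.05, 0.9]).

## The observer model

The simulated observer is deliberately the *simplest* model whose analysis
recovers its parameter exactly. Its mean setting in MB chromaticity is

```
setting = w + d * (i - w)
```

where `i` is the chromaticity of the light at the test field, `w` the
observer's internal white point — the white-skylight test-field
chromaticity plus a per-observer bias drawn once (SD 0.003 in l, 0.05 in
s), modelling the fact that the task anchors on each observer's internal
criterion for white — and `d` the degree of constancy. Repeat noise is
independent Gaussian per axis (defaults `sigma_l = 0.002`, `sigma_s =
0.04`, the axes' natural scales differing by an order of magnitude);
luminance settings are a fraction (default 0.65) of the theoretical
full-white limit under the test-field light, with median-parameterized
log-normal noise (`sdlog = 0.08`) because settings are strictly positive.
Real observers' noise distributions are unknown; these defaults are
plausible magnitudes, not estimates, and the luminance domain is reported
descriptively only — no luminance constancy index is defined.

Under this model the constancy index below equals `d` exactly when noise is
zero, for every skylight and lighting: the analysis surface is analytic,
and parameter-recovery tests quantify estimator behavior under noise.

Scenario presets encode the three designs: `exp1` (3 observers, 2 lighting
blocks, 7 sessions, constancy drawn near 1.1 — the practiced-observer
regime), `exp2` (12 observers, no-outline vs outlined shadow, 2 sessions,
constancy near 0.85), and `grey_paper_followup` (constancy near zero, the
regime observed when chromatic surface cues are removed). A degree of
constancy is drawn per observer *per block*, since real observers differ
between blocks; biases are drawn once per observer.

## The constancy analysis

Because the MB diagram is not perceptually uniform, each axis is first
divided by the standard deviation (sample, n−1 convention) of the
white-skylight settings, per observer (`per_observer`) or pooled across
observers (`pooled`, for small-trial designs). Two documented choices:

* **Pooled SD convention.** Pooling uses the classical pooled
  within-observer SD, `sqrt(SS_within / (N - G))`, rather than the SD of
  the stacked settings: it reduces exactly to the per-observer SD when
  observers are homogeneous and does not conflate between-observer
  white-point offsets with setting scatter.
* **Scaling block.** The SD comes from the analyzed field's white-skylight
  settings within the matching lighting-by-outline block, the most
  conservative reading of "settings for the white skylight condition".

With `a_vec` the rescaled shift of mean settings (colored minus white
skylight) and `b_vec` the rescaled shift of the test-field illuminant, the
constancy index is

```
CI = a * cos(theta) / b  =  (a_vec . b_vec) / b^2
```

a Brunswick ratio incorporating the angle between perceptual and physical
shifts: 0 no constancy, 1 perfect, above 1 over-correction; anti-correlated
shifts give negative values, which are retained in all averages (the index
is signed by construction and clamping would bias means upward). Both
`a_vec` and `b_vec` are rescaled by the *same* axis scales — rescaling the
space, not just the settings — which also makes the index invariant to a
common multiple of the scales. Whether `b` should share the rescaling is a
genuinely open convention; the package's choice is yes, and passing
`axis_scale = c(1, 1)` to `ci_table()` gives the unscaled-space index for
comparison. The index is computed for the shadowed right field by default
(`field = "left"` is available); the white skylight is never a CI row,
since its illuminant shift is zero. Cell SEs are computed across sessions
(each session's setting against the mean white reference), matching
error-bar-across-settings reporting.

## Statistics

`paired_t_two_tailed()`, `welch_t()` and `rm_anova_two_way()` wrap the
classical tests (via `stats::t.test` and `stats::aov` with
`Error(subject/(A*B))` strata); the test suite checks them against
independently coded formula and sums-of-squares oracles. Degenerate-input
conventions, chosen where the classical formulas are 0/0:

* paired t with all differences zero returns `t = 0, p = 1` (identical
  vectors); constant *non-zero* differences error, as the statistic is
  infinite;
* RM-ANOVA effects with numerically zero sum of squares report
  `F = 0, p = 1`;
* Welch's t errors only when both groups are constant; its df is reported
  both exactly and rounded to integer for the conventional `t(df)` style.

For a 12-subject, 4 x 2 within-subject design the skylight effect is tested
on (3, 33) degrees of freedom — the conventional pattern for this design.

## Numerical choices and problem sizes

* Spectral integration: rectangle rule at 1 nm; integration oracles agree
  to 1e-9 relative.
* Illuminant optimizer: Nelder–Mead on basis weights (log-parameterized for
  the bump basis to keep SPDs nonnegative), multi-start under the supplied
  seed, deterministic given the seed; failure reports the achieved
  chromaticity rather than returning an out-of-tolerance illuminant.
* The CI's two algebraic forms agree to 1e-12; ties at `a = 0` report
  `theta = NA` and `CI = 0`.
* All simulation entry points require an explicit seed; identical config
  plus seed reproduces settings tables byte for byte.
* Test and recovery simulations use the paper-scale designs (3 observers,
  5 skylights, 7 repeats; 40 Monte-Carlo replicates per recovery point),
  sizes at which the whole suite runs in well under a minute while Monte
  Carlo SEs on recovered constancy are a few thousandths.

## What the simulation does and does not show

The generator reproduces the *structure* of the experiments: the scene's
photometry, the two-illuminant shadow geometry, session counts, and
observer heterogeneity in constancy and white criterion. It does not model
spatial context, adaptation dynamics, perceptual nonuniformity beyond the
SD rescaling, criterion drift across sessions, or the unknown distribution
of real setting noise. Passing recovery tests therefore validate the
*analysis pipeline* — that the index measures what it claims under its own
assumptions — not any claim about human vision; conclusions about real
observers require real settings tables, which the readers ingest through
the same CSV interface the simulator writes.

Known limitations: the synthetic fundamentals carry the ~0.2% absolute
offset described above; the CMF fit limits absolute xy accuracy to about
0.001; the daylight-like basis is Planckian, not the daylight
characteristic vectors, so synthesized near-neutral spectra are smoother
than real projector output; and the Welch comparison between naive and
non-naive groups inherits the 3-vs-9 imbalance of the design it mirrors.
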