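---
title: "Models and methods of the disc-facet degeneration pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the disc-facet degeneration pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discfacet)
```

`discfacet` analyzes paired imaging and biomechanical measurements from spinal
motion segments — disc, endplates and facet joints — and stratifies and
correlates them across a degeneration spectrum. This vignette documents the
models, their assumptions, the tunable parameters, and the numerical design
choices, in the order the pipeline runs. One unit system is used end to end:
N, mm, MPa, seconds; relaxation times in ms; permeability in mm⁴/(N·s).

## 1. T2 relaxometry with Rician noise-floor correction

MRI magnitude images carry Rician noise: the magnitude of a complex signal
whose two channels have independent Gaussian noise of SD σ. At low SNR the
expected magnitude does not decay to zero but to the Rayleigh floor
σ√(π/2), so a naive monoexponential (log-linear) fit of a multi-echo decay is
biased upward — dramatically so for short-T2 tissue sampled over a long echo
train. `fit_t2_noise_corrected()` fits

$$ I(TE) = \sqrt{ (S_0\, e^{-TE/T_2})^2 + 2\sigma^2 } $$

by least squares, using the expected squared-magnitude identity
$E[M^2] = A^2 + 2\sigma^2$ as a one-parameter noise-floor correction. σ is a
free parameter bounded below at 0.

Numerical choices:

- **Multi-start**: three Levenberg–Marquardt starts — the log-linear
  initializer's T2, half and double it — with solver tolerance 1e-8.
- **Cap**: T2 is bounded above at 10× the longest TE. A fit that converges
  onto the cap (a signal that does not decay measurably over the sampled TE
  range) is reported but flagged `converged = FALSE`, since the data cannot
  distinguish such T2 values.
- **ROI handling**: the NP T2 metric is fitted on the ROI-mean decay, not
  per pixel; T1 is computed per pixel and then ROI-averaged with
  `summarize_roi()` (which tracks non-finite exclusions). The asymmetry is
  deliberate: the T2 decay is the noisier measurement and averaging before
  fitting stabilizes it, while the two-point T1 estimate is cheap and exact
  per pixel.
- **Precision at study conditions**: at NP study conditions (T2 ≈ 40 ms,
  S0/σ = 20, a 25-echo 13.6–340 ms train) the corrected estimator is close to
  unbiased (|bias| < 1 ms versus > +100 ms for the log-linear fit), with a
  median relative error of 7–8 %. That spread is a property of the
  information in the acquisition, not of the optimizer: a Monte-Carlo
  Cramér–Rao calculation for this model and schedule bounds the SD of any
  unbiased T2 estimator at ≈ 4.4 ms, i.e. a median relative error of ≈ 7.5 %,
  and the full Rician maximum-likelihood estimator performs no better than
  the corrected least-squares fit. Users needing tighter per-disc precision
  must raise SNR or re-weight the echo schedule, not swap estimators.

## 2. Two-point variable-flip-angle T1 and the diffusion metric

The T1 acquisition uses two flip angles (5° and 26°) at TR = 15 ms. The
spoiled-gradient signal equation is linearized as y = S/sin α against
x = S/tan α, giving slope E1 = exp(−TR/T1) from the two points in closed form.
The estimate is `valid` only for E1 ∈ (0, 1); degenerate geometry (x₂ = x₁)
or noise pushing E1 outside the interval yields an invalid flagged result
rather than an error, so cohort assembly can propagate missingness. The
acquisition protocol names an inversion-recovery sequence, but a two-angle
protocol at short TR determines T1 through the VFA estimator and that
interpretation is adopted here as a package design decision.

Contrast uptake is quantified by `percent_t1_reduction()`:
100·(T1_pre − T1_post)/T1_pre. Gadodiamide shortens T1 in proportion to local
concentration, so a higher percent reduction means more trans-endplate
diffusion into the NP. Negative values (post > pre) are permitted and flagged.

## 3. Disc height index

`disc_height_index()` divides the mean of up to three disc-height chords
(anterior, middle, posterior) by the mean of the two adjacent vertebral body
lengths, from user-supplied landmarks; segmentation or landmark detection is
out of scope. Averaging three chords is the declared construction; supplying
fewer chords averages those given. The index is dimensionless and invariant
to rigid motion and global scale, which the tests verify on randomized
landmark sets. `normalize_dhi()` divides a longitudinal series by its
pre-operative value (which therefore maps to exactly 1) and is idempotent.

## 4. Disc compressive mechanics

The testing protocol applies 20 load-unload cycles between −0.5 N and −100 N
followed by a one-hour creep hold at −100 N (≈ 0.24 MPa over a typical
cervical disc area). `segment_cycles()` delimits cycles by excursions of
|force| above a hysteresis band around the low setpoint (±20 % of |−0.5 N|,
configurable), so sensor noise smaller than the band cannot split cycles; an
excursion must reach half the peak setpoint to count. The trailing at-peak
portion of the final excursion is the creep segment.

`normalize_stress_strain()` maps force to stress (|F|/area) and displacement
to strain (|d|/height) with compression positive, using MRI-derived geometry
(area = pixel count × resolution²; height = mid-sagittal area / AP width).
**Strain reference**: by default strain is referenced to the record's
displacement zero (the unloaded disc height), with per-segment re-zeroing
available as an option (`rezero = "segment"`). Referencing the unloaded state
is the package's own choice: re-zeroing each ramp shifts the strain origin by
the pre-load strain and would bias the transition strain by exactly that
offset, breaking the generator round-trip identity that anchors the test
suite.

`bilinear_fit()` fits the 20th loading ramp (loading limb only — the choice
of limb is a declared decision) with the continuous two-segment model
parameterized by the hinge basis {1, ε, (ε − t)₊}. Conditional on the
breakpoint t the model is linear, so the breakpoint is located by exhaustive
search over interior sample positions (≥ 3 points per segment) followed by
continuous refinement (golden-section, tolerance 1e-10) within the bracketing
inter-sample intervals; exact bilinear data are therefore recovered to ≤ 1e-6
even when the true transition falls between samples. Under the continuity
constraint the breakpoint abscissa coincides with the intersection of the two
fitted lines. Because the hinge coefficient may be zero at any breakpoint,
the two-segment SSE never exceeds the best single-line SSE; data
indistinguishable from one line are flagged `boundary_indeterminate` with
equal slopes. `creep_strain()` reports (|d_end| − |d_start|)/height over the
hold, positive in compression.

## 5. Facet cartilage Hertzian biphasic creep

Creep indentation (2 mm diameter sphere, −0.1 N, 15 min) is modeled with a
Hertzian biphasic law carrying three parameters: equilibrium compressive
(contact) modulus E_c, tensile modulus E_t > E_c, and hydraulic permeability
k. The realization implemented in `hbc_forward()` is: the interstitial fluid
initially supports the load fraction F₀ = 1 − E_c/E_t (the
tension-compression nonlinearity sets how much the solid matrix can
pressurize the fluid), decaying as F(t) = F₀·exp(−t/τ) with the poroelastic
timescale τ = a²/(E_t·k) evaluated at the current contact radius
a = √(R·d). At each time the displacement solves the Hertz relation
(4/3)·E_c/(1−ν²)·√R·d^{3/2} = P·(1 − F(t)) by damped fixed-point iteration
(relative tolerance 1e-9, damping 0.5 — the fixed-point map is decreasing in
d, so undamped iteration would oscillate). This kernel preserves the three
reported parameters, the tensile-controlled instantaneous response
d(0⁺) = d_eq·(E_c/E_t)^{2/3}, the compressive-controlled Hertz equilibrium
d(∞) = (3P(1−ν²)/(4E_c√R))^{2/3}, and the a²/(E·k) poroelastic timescale; any
closed-form biphasic contact solution with the same parameterization can be
swapped behind the same interface. ν is fixed at 0 by default (standard
biphasic solid-matrix assumption) and configurable.

`hbc_fit()` inverts a record by Levenberg–Marquardt on the log
parameterization (log E_c, log(E_t − E_c), log k) — positivity and the
ordering constraint are built in, and k spans decades so log-space is the
natural scale. Six starts combine E_t/E_c ∈ {2, 8, 25} with
k ∈ {3·10⁻⁴, 3·10⁻³}, each seeded with the Hertz-equilibrium estimate of E_c
from the final displacement; the winner has the lowest SSE, ties broken by
the lowest permeability, with early exit on an exact fit. Fits with r² below
0.95 (configurable) are flagged `excluded`, implementing the fit-quality
exclusion rule; a record corrupted by a step artifact fails this rule.
`aggregate_facet()` averages the non-excluded points of each joint (up to six:
three per articular surface) and normalizes within animal to the control
level (C3-C4 by default). Within-animal normalization is a declared decision;
a missing control joint skips normalization with a warning rather than
failing the cohort.

## 6. Cohort statistics

`stratify_by_t2()` bins NP T2 at 60 and 40 ms into healthy, mild-moderate and
severe. The published bin definitions leave the boundary values open; the
declared rule assigns 60 ms to mild-moderate and 40 ms to severe — ties go to
the more degenerative bin, which is conservative for claims of health.

`diffusion_correlation()` correlates NP T2 with percent T1 reduction twice:
over all records and excluding discs with endplate resorption or severe
degeneration (T2 < 40 ms). In those discs transport is enhanced through
breached boundaries (marrow contact at resorptions, vascular ingrowth in
severe degeneration), which masks the positive T2-diffusion relationship of
intact discs; the exclusion recovers it. Excluded record ids and the
least-squares line of the retained subset are reported.

`correlation_matrix()` computes Pearson r over pairwise-complete observations
with the two-sided p from t = r·√((n−2)/(1−r²)) on n−2 df. No multiplicity
correction is applied by default, matching the single-matrix reporting
convention of this analysis; Benjamini–Hochberg is available via
`adjust = "BH"`. p-values below 1e-300 (e.g. exact collinearity) are reported
at that floor. Zero-variance columns yield rows flagged `undefined`.
Group-level ANOVA/Tukey/Dunn testing and mixed-effects DHI modeling are
standard procedures left to `stats`/`nlme`-tier tooling and are not part of
this package's tested surface.

## 7. The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
not anatomy: each animal contributes three cervical levels (two treated, the
middle one an untreated control), and a latent severity s ∈ [0, 1] per disc
drives every outcome through a linear effect map plus Gaussian noise.
Treated severities are Uniform(0.2, 1) — induced degeneration spans a broad
spectrum — and controls Uniform(0, 0.15), reflecting that nominally healthy
adjacent levels show mild degenerative change. Default effect magnitudes are
chosen to be realistic for a large-animal cervical model: NP T2 falling
75 → 30 ms across the severity range, normalized DHI falling to ~0.7, toe and
linear moduli stiffening several-fold, facet moduli softening by ~60 % and
facet permeability rising ~4-fold, histology score rising ~10 points, with
noise SDs of roughly 10–40 % of each effect span. Transition strain, maximum
strain and creep strain are severity-independent (their group differences are
not a robust feature of disc degeneration at this scale).

Endplate resorption occurs with logistic probability in s (intercept −4,
slope 5: rare in controls, common in severe discs). The diffusion metric
increases with the disc's noiseless NP T2 (slope 0.5 %/ms) among intact,
non-severe discs, and is elevated by +25 points when resorption is present or
observed T2 < 40 ms — encoding enhanced transport through breached
boundaries. The elevation coefficient is part of the effect map, so the
degenerate all-slopes-zero design produces exactly constant outcomes.

Raw-signal generators (`generate_t2_decay`, `generate_vfa_signals`,
`generate_compression_test`, `generate_indentation_creep`,
`generate_radiograph_landmarks`) produce the four raw input classes with the
same forward models the fitters assume; MRI noise is added on the two complex
channels, never to magnitudes, so the noise-floor correction is exercised
honestly. Every generator takes a seed, restores the caller's RNG state, and
is byte-reproducible under a fixed seed.

What passing tests do and do not show: the generators match the fitters'
model classes exactly, so round-trip recovery demonstrates correctness of the
estimation machinery, not robustness to model misspecification (multi-slice
partial volume, non-spherical indenter contact, viscoelastic rather than
poroelastic creep, non-triangular load profiles). Cohort-level results
demonstrate that the analysis recovers a correlation structure that is truly
present; they cannot validate the biological effect sizes themselves.

## 8. Problem sizes and verification

The test suite verifies, among others: exact recovery on noiseless data for
every fitter (T2, VFA T1, bilinear, biphasic — the latter over a 2×2×2
parameter grid); Monte-Carlo recovery under noise (200 Rician decays at study
conditions; 100 bilinear replicates at 1 % stress noise with median slope
errors ≈ 2.6 %/0.5 %; 100 biphasic replicates at 1 % displacement noise with
median errors ≈ 0.1 % (E_c), 4.6 % (E_t), 4 % (k) and r² > 0.95 throughout);
forward-model monotonicity and Hertz-equilibrium agreement over 100 random
parameter draws; Pearson r/p agreement with `stats::cor.test` to 1e-12 over
100 random tables; and reproduction of the six expected disc-facet
correlation signs in 20/20 synthetic 50-animal cohorts, with the
excluded-subset T2-diffusion correlation exceeding r = 0.6 in ≥ 80 % of
seeds. `scripts/acceptance.R` recomputes these quantities from scratch
against the installed package and writes them as JSON; all of its randomness
derives from the `--seed` argument.

## Known limitations

- No DICOM/image handling: ROIs, masks and landmarks are inputs.
- No B1 correction or multi-component T2; single-compartment relaxometry only.
- The biphasic kernel is a closed-form approximation, not a finite-element
  solution; no cartilage thickness correction is applied.
- Compression analysis covers axial loading only (no torsion or bending), and
  fits the loading limb only.
- The synthetic generator draws independent Gaussian noise per outcome;
  real within-animal correlation beyond the shared severity is not emulated.
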