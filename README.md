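# discfacet

Quantitative structure–function analysis of whole-motion-segment spinal
degeneration. Disc degeneration rarely stays confined to the disc: as the
nucleus pulposus (NP) loses water and proteoglycan, the disc stiffens, nutrient
diffusion across the endplates changes, and the posterior facet joints develop
early osteoarthritic changes. `discfacet` implements the full quantitative
pipeline used to characterize that cascade in large-animal degeneration
studies, for researchers analyzing paired imaging and biomechanical test data
from spinal motion segments:

- **MRI relaxometry** — NP T2 from multi-echo magnitude decays with Rician
  noise-floor correction, two-point variable-flip-angle (VFA) T1, and the
  pre/post-contrast percent-T1-reduction metric of trans-endplate diffusion;
- **radiographic morphometry** — disc height index (DHI: disc height over mean
  adjacent vertebral body length) from lateral-radiograph landmarks, normalized
  longitudinally to the pre-operative value;
- **disc compressive mechanics** — cycle segmentation of load–displacement
  records, stress–strain normalization by MRI-derived disc area and height, a
  continuous bilinear fit giving toe modulus, linear modulus and transition
  strain, and creep strain from the terminal hold;
- **facet cartilage indentation** — forward simulation and inversion of a
  Hertzian biphasic creep model for compressive modulus `E_c`, tensile modulus
  `E_t` and hydraulic permeability `k`, with an r² < 0.95 exclusion rule,
  six-point joint averaging and control-level normalization;
- **cohort statistics** — severity stratification by NP T2 (healthy > 60 ms,
  mild-moderate 40–60 ms, severe ≤ 40 ms), the diffusion-correlation exclusion
  rule, disc–facet Pearson correlation matrices and group summaries;
- **a synthetic-cohort generator** in which a latent per-disc degeneration
  severity jointly drives every outcome, so the whole pipeline is testable by
  parameter and sign recovery without any animal data.

## Core models

T2 is estimated by least squares on the magnitude-bias-corrected decay

    I(TE) = sqrt( (S0 · exp(−TE/T2))² + 2σ² ),

which absorbs the Rician noise floor that otherwise inflates T2. T1 uses the
two-point VFA linearization of the spoiled-gradient equation
`S(α) = M0 sin α (1−E1)/(1−E1 cos α)`, `E1 = exp(−TR/T1)`. The compressive
stress–strain curve is fit by a continuous two-segment piecewise-linear model
with exhaustive breakpoint search plus continuous refinement; the transition
strain is the intersection of the two fitted lines. Indentation creep follows
a Hertzian biphasic law in which the fluid phase initially carries the load
fraction `1 − E_c/E_t` and depressurizes on the poroelastic timescale
`a²/(E_t·k)` (contact radius `a = sqrt(R·d)`), so the early response is set by
the tensile modulus, the equilibrium by the compressive modulus, and the
transient rate by the permeability.

Units throughout: N, mm, MPa, seconds; relaxation times in ms; permeability in
mm⁴/(N·s).

## Worked example

```r
library(discfacet)

# A synthetic indentation test on degenerated facet cartilage, then inversion
truth <- biphasic_params(e_c_MPa = 0.5, e_t_MPa = 5, k_perm = 1e-3)
rec   <- generate_indentation_creep(truth, noise_sd = 0.003, seed = 42)
fit   <- hbc_fit(rec)
c(Ec = fit$params$e_c_MPa, Et = fit$params$e_t_MPa,
  k = fit$params$k_perm, r2 = fit$r2)
#>          Ec          Et           k          r2
#> 0.500409111 4.526879547 0.001098689 0.989881760

# A 50-animal synthetic cohort: stratify and correlate disc vs facet health
tab <- generate_cohort(cohort_design(n_animals = 50, seed = 7))
table(tab$degeneration_grade)
#>       healthy mild-moderate        severe
#>            62            55            33
correlation_matrix(tab, "np_t2_ms", c("facet_Et", "facet_k"))
#>   disc_var facet_var          r            p   n undefined
#> 1 np_t2_ms  facet_Et  0.7404956 2.515955e-27 150     FALSE
#> 2 np_t2_ms   facet_k -0.8281573 4.845615e-39 150     FALSE
```

The inversion recovers the compressive modulus to 0.1 % and the tensile
modulus and permeability to about 10 % at this noise level (the transient
carries less information than the equilibrium), with r² ≈ 0.99. The cohort
reproduces the expected degeneration structure: NP T2 correlates positively
with facet tensile modulus and negatively with facet permeability.

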