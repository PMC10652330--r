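# mtmrs

Simulation and analysis of **³¹P magnetisation-transfer MRS** experiments
that quantify the forward rate of ATP synthase flux in the living brain,
together with a layered **Monte-Carlo photon-transport** model of
transcranial red/near-infrared light delivery (photobiomodulation
dosimetry).

## Who this is for

Researchers running (or planning) saturation-transfer ³¹P spectroscopy
studies of cerebral energy metabolism — for example pre/post comparisons
of a light, drug or exercise intervention — who need a tested, end-to-end
pipeline from raw free induction decays to cohort statistics, with a
synthetic-data generator providing known ground truth for validation; and
anyone needing first-order dosimetry of how much red light actually
reaches cortical tissue through scalp, skull and CSF as a function of
wavelength and skin melanin content.

## The model

Saturating the γ-ATP resonance (−2.5 ppm) drains signal from its chemical
exchange partners Pi (ATP synthase pathway) and PCr (creatine kinase
pathway). With the saturated pool clamped, the observed signal follows
the Forsén–Hoffman two-site solution

S(τ)/S₀ = k_f·T_app·exp(−τ/T_app) + T_app/T₁,  1/T_app = 1/T₁ + k_f,

and fitting normalised peak areas versus saturation time τ (with T₁
fixed: 3.1 s for intracellular Pi, 5.1 s for PCr) yields the forward rate
k_f in s⁻¹. Cohort inference uses exact small-sample nonparametric tests:
the paired Wilcoxon signed-rank test (exact p by full enumeration, plus
the tie-corrected asymptotic Z without continuity correction), Kendall's
τ-b, and a Monte-Carlo-calibrated Lilliefors normality screen.

The dosimetry module is an MCML-style photon transport through an
epidermis/dermis/skull/CSF/grey-matter stack with chromophore-composed
absorption (melanin, haemoglobin, water, cytochrome-c oxidase) and
Henyey–Greenstein scattering.

## Worked example

Simulate a 7-subject paired phantom cohort (pre mean k_f = 0.2 s⁻¹, post
0.3 s⁻¹) and run the full pipeline — apodisation, FT, automatic phasing,
baseline correction, two-Lorentzian Pi-window fits, saturation-curve
normalisation, kinetic fits and cohort statistics:

```r
library(mtmrs)
cohort <- make_phantom_cohort(n_subjects = 7, seed = 1)
result <- run_cohort(cohort$subjects)
result
#> <cohort_result> 7 subjects
#>   group-mean-curve kf: pre 0.202, post 0.308
#>   mean of individual kf: pre 0.204, post 0.311
#> <cohort_report> 7 pairs; rate increased in 7
#>   kf_pi : W+ = 28, Z = -2.366, two-tailed p = 0.016 (exact, n = 7)
#>   kf_pcr : W+ = 24, Z = -1.690, two-tailed p = 0.109 (exact, n = 7)
```

The recovered rates match the generating truth (0.2/0.3 s⁻¹) to a few
percent; with all seven subjects increasing, the exact Wilcoxon p is
2/128 = 0.016 and the asymptotic statistic is Z = −2.366. Here the PCr
(creatine kinase) rate was generated unchanged between sessions, and the
test on it is correspondingly non-significant.

Dosimetry — how much 670 nm light is absorbed by cytochrome-c oxidase in
grey matter as scalp melanin rises from pale (0.04) to dark (0.43) skin
tones:

```r
ms <- melanin_sweep(n_photons = 3e4, seed = 1)
round(ms$table, 5)
#>   melanin_fraction gm_reach gm_absorbed cco_absorbed
#> 1             0.04  0.02817     0.02062      0.00114
#> 2             0.10  0.02058     0.01518      0.00084
#> 3             0.20  0.01383     0.01017      0.00056
#> 4             0.30  0.00987     0.00727      0.00040
#> 5             0.43  0.00685     0.00507      0.00028
ms$cco_drop
#> [1] 0.754
```

About 2% of the 670 nm light entering a pale-skinned head is absorbed in
grey matter and ~0.1% by CCO there; darkening the epidermis removes
roughly two thirds to three quarters of that dose.

## Layout

- `R/` — synthetic generator, spectral processing, peak fitting,
  exchange kinetics, cohort statistics, photon transport, pipeline.
- `src/mcml.cpp` — the Monte-Carlo transport core (Rcpp).
- `inst/extdata/` — editable chromophore and tissue-layer tables (CSV).
- `vignettes/mtmrs-methods.Rmd` — models, assumptions, parameter
  choices, numerical details and limitations.
- `tests/testthat/` — unit, property and end-to-end tests.
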