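---
title: "Saturation-transfer kinetics and red-light dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation-transfer kinetics and red-light dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmrs)
```

# The measurement

Phosphorus-31 magnetisation-transfer MRS measures the forward rate of the
ATP synthase reaction in vivo. A train of narrowband RF pulses saturates
the gamma-ATP resonance (-2.5 ppm relative to phosphocreatine at 0 ppm);
chemical exchange then carries the saturated magnetisation into the two
exchange partners, inorganic phosphate Pi (ATP synthase pathway) and PCr
(creatine kinase pathway), whose signals decay toward a reduced steady
state. With the partner pool held at zero, the observed pool follows the
Forsén–Hoffman solution of the two-pool longitudinal Bloch–McConnell
equations:

$$\frac{S(\tau)}{S_0} = k_f\,T_{app}\,e^{-\tau/T_{app}} +
  \frac{T_{app}}{T_1},\qquad
  \frac{1}{T_{app}} = \frac{1}{T_1} + k_f ,$$

where $\tau$ is the cumulative saturation time, $k_f$ the
pseudo-first-order forward exchange rate and $T_1$ the intrinsic
longitudinal relaxation time of the observed pool. `decay_fraction()`
implements the closed form; `bloch_mcconnell_decay()` integrates the ODE
system numerically (with a tunable saturation efficiency) and serves as an
independent oracle — the two agree to better than one part in $10^6$ over
the physiological parameter range, which the test suite asserts.

Intracellular pH is read off the Pi(i) chemical shift $\delta$ (ppm from
PCr) through the phosphate titration curve
$\mathrm{pH} = 6.66 + \log_{10}\!\big((\delta - 3.08)/(5.57 -
\delta)\big)$ (`estimate_ph()`). Note that evaluating this curve at the
usual in-vivo Pi(i) shift of ~4.9 ppm gives pH ≈ 7.09; studies that quote
cohort pH values around 7.5 from similar shifts are using a different
reference convention, so pH here should be compared only within a
consistent pipeline.

# The synthetic-data generator

Every downstream stage is tested against simulated acquisitions with
known ground truth. `simulate_fid()` builds the complex time-domain
signal as a sum of damped complex exponentials — one per resonance
(PME, Pi(e), Pi(i), PDE, PCr, and the three ATP peaks), plus a broad
(600 Hz) short-$T_2^*$ component standing in for the phospholipid
baseline. Under on-resonance saturation the Pi(i) and PCr amplitudes are
scaled by `decay_fraction()` at the condition's $\tau$, and gamma-ATP is
suppressed as $e^{-\tau/\tau_{sat}}$ with $\tau_{sat}=50$ ms
(near-instant complete saturation). Pi(e) is held constant under
saturation: there is no documented exchange pathway between gamma-ATP and
extracellular phosphate, and holding it fixed makes the Pi(i)/Pi(e)
separation a pure deconvolution problem for the fitter.

Timing defaults mirror a 3 T protocol: 3000 Hz bandwidth, 2048 complex
points, saturation conditions of 0, 3, 6, 12, 18, 30 and 44 pulses with a
169.29 ms pulse unit (114.29 ms pulse + 5 ms spoiler + 50 ms delay),
giving $\tau \approx$ 0, 0.5, 1.0, 2.0, 3.0, 5.1 and 7.4 s, plus an
off-resonance control at +15 ppm that serves as the normalisation
reference. The acquisition duration is derived as
`n_points/bandwidth` (683 ms) rather than taken from any rounded label.
The spectrometer frequency defaults to 49.9 MHz (nominal 3 T); it only
sets the Hz-per-ppm conversion.

Noise is i.i.d. complex Gaussian per time-domain point. The default
`noise_sd = 0.02` was calibrated once so that the *fitted* Pi(i) peak
area carries a 3–4% residual-RMS uncertainty through the full processing
chain — the scale of per-point error bars typical of in-vivo saturation
curves — while the exchange-driven drop at long $\tau$ remains obvious by
eye. Phantom cohorts (`make_phantom_cohort()`) sample subject rates with
a shared subject effect, so the pre/post difference has mean
$\mu_{post}-\mu_{pre}$ and a small paired SD (default 0.02 s$^{-1}$),
reflecting the strongly paired design the cohort statistics assume.
Defaults (7 subjects, pre mean 0.2 s$^{-1}$, post mean 0.3 s$^{-1}$)
emulate a small photobiomodulation study cohort.

What the generator deliberately does **not** model: $B_1$ inhomogeneity,
motion, eddy currents, RF bleed of the saturation pulse (adiabatic pulses
make it negligible), lineshape distortions beyond Lorentzian, or
J-coupling. Passing tests therefore demonstrate correctness of the
analysis pipeline under a faithful but idealised forward model, not
robustness to every artefact of real scanner data.

# Spectral processing

`apodize()` applies Gaussian (default, 5 Hz) or exponential line
broadening; the exponential window adds exactly its width to Lorentzian
linewidths, which the tests exploit. Both dialects exist because both are
defensible; the choice is recorded in the processing provenance. The
Fourier transform (`to_spectrum()`) halves the first FID point to
suppress the constant baseline offset of the one-sided DFT, and maps
frequency to a PCr-referenced ppm axis, decreasing left-to-right per NMR
convention.

Automatic phasing (`auto_phase()`) replaces interactive phasing: isolated
magnitude-spectrum peaks are fitted with a phase-sensitive complex
Lorentzian (absorption/dispersion mixing angle plus a complex linear
local baseline), and the per-peak angles are regressed on chemical shift
by weighted least squares with one outlier-trim pass. On synthetic data
it recovers imposed zeroth/first-order errors to well under 0.05 rad.
Pure-noise input is flagged and left unphased. In the pipeline the phases
are estimated once on the control spectrum and applied to all conditions
of a session, so any residual phase error is common mode and cancels in
the normalised curves.

Baseline correction fits a polynomial (default quartic) to the real
channel by least squares outside exclusion windows of ±0.5 ppm around
each assigned resonance, then subtracts it everywhere. The pipeline order
is fixed as filter → FT → phase → baseline, configurable via
`run_config()`. Every step appends to a provenance record;
`replay_provenance()` reproduces a processed spectrum bit-identically
from the raw FID.

# Peak fitting and curve building

The 4–6 ppm window is fitted (`fit_pi_window()`) with two Lorentzians —
chemical shift, amplitude and FWHM all floating — plus a quartic
in-window baseline, by Levenberg–Marquardt (`minpack.lm`). Pi(i) is
identified as the lower-shift peak (initialised at 4.9 vs 5.2 ppm).
Parameter bounds: centres inside the window, FWHM in (0.01, 1) ppm,
amplitudes nonnegative; fits that land on a bound, fail to converge, or
find no peak above the noise (5 point-noise SDs, estimated from median
absolute successive differences) are flagged rather than silently
returned. If the second component collapses, a flagged single-peak
fallback is used. PCr and gamma-ATP reuse the same engine with one
component (`fit_single_peak()`), where the starting centre additionally
snaps to the local data maximum within 0.35 ppm.

Areas are analytic ($A\pi w/2$ for a Lorentzian). Normalised saturation
curves divide each condition's area by the control area; per-point error
bars propagate the fit-residual RMS of condition and control in
quadrature (`build_saturation_curve()`).

# Kinetic fitting

`fit_kf()` estimates $(k_f, S_0)$ by unweighted least squares with $T_1$
clamped — 3.1 s for Pi(i) and 5.1 s for PCr by default. 3.1 s is used
(rather than the also-circulating 3.0 s) because it is the value the
reference analyses pair with their reported rates; 3.0 s is one config
switch away. Unweighted is the default because error-bar weighting is an
open choice in this literature; `weights = "error"` enables it.
$k_f$ is bounded to [0, 2] s$^{-1}$ — physiologically generous — and a
solution at a bound is flagged, not hidden.

Floating $T_1$ jointly (`fit_kf_float_t1()`, bounds [1, 7] s) is
supported but, with seven noisy points, the $T_1$ profile is extremely
shallow: across noise realisations at the calibrated noise the fitted
$T_1$ scatters over several seconds (and lands on a bound when the truth
lies outside the box). This is the identifiability failure that motivates
fixing $T_1$, and it is asserted in the tests as scatter rather than as a
guaranteed bound hit — profiling the RSS over a dense $T_1$ grid shows
the optimiser is finding the true (if nearly meaningless) minimum.

Group analysis fits the pointwise mean curve across subjects
(mean-then-fit, `fit_group_mean()`), and separately averages the
individual fits; both are reported by `run_cohort()` because they differ
for a nonlinear model.

# Cohort statistics

The paired Wilcoxon signed-rank test (`wilcoxon_signed_rank()`) uses
midranks for tied absolute differences, drops zero differences (|d| <
1e-12), and reports both the asymptotic statistic
$Z = (\min(W^+,W^-) - n(n+1)/4)/\sigma$ with tie-corrected $\sigma$ and
**no continuity correction** — with $n=7$ unanimous increases this gives
$Z=-2.366$; a 0.5 correction would give $-2.28$ — and the exact
two-tailed p from the full null distribution of $W^+$ over all $2^n$
sign assignments (computed by convolution, verified against literal
enumeration and `wilcox.test`), $2/128 = 0.0156 \to 0.016$ at $n=7$.
Kendall's $\tau_b$ (`kendall_tau_b()`) uses direct pair counts with tie
corrections; the exact p enumerates all permutations of one margin for
$n \le 8$. Normality screening (`ks_normality()`) is a Lilliefors-type
KS test whose null distribution is simulated (parameters are estimated,
so standard KS tables would be anticonservative). No multiple-testing
correction is applied anywhere, matching common practice for a
two-comparison confirmatory analysis.

# Photon transport

`run_mc()` is a layered MCML-style Monte-Carlo: photon packets launched
as a pencil beam at normal incidence, step lengths $-\ln\xi/(\mu_a+\mu_s)$,
albedo-weighted absorption, Henyey–Greenstein deflection, and Fresnel
reflection/refraction at refractive-index boundaries. Lateral coordinates
are tracked but tallies are layer-resolved, which suffices for every
reported fraction. Termination is weight-conserving: when a packet's
weight falls below $10^{-4}$ the residual is deposited in the current
layer. The alternative — Russian roulette — conserves energy only in
expectation, and we require reflectance + transmittance + absorption to
close to $10^{-9}$ on *every* run as a structural invariant; the bias of
residual deposition is bounded by the $10^{-4}$ threshold, far below
Monte-Carlo error at the photon counts used. Randomness comes from R's
RNG, so runs are bit-reproducible under `set.seed()`. Physics validation:
Beer–Lambert in the no-scattering limit, and the classic benchmark slab
(albedo 0.9, optical depth 2, $g=0.75$, matched boundaries) against the
van de Hulst table values $R_d = 0.09739$, $T_t = 0.66096$.

The default head model is a 1-D stack: epidermis (0.01 cm, the
melanin-bearing layer), dermis (0.39 cm), skull (0.7 cm), CSF (0.2 cm)
and semi-infinite grey matter. Housing melanin in a thin epidermis is the
standard skin-optics convention; applying a 0.04–0.43 melanin volume
fraction to the whole 0.4 cm scalp would extinguish essentially all red
light at any skin tone and is not physically meaningful. Absorption
composes linearly from shipped chromophore spectra
(`inst/extdata/chromophores.csv`): a melanosome power law
($1.70\times10^{12}\,\lambda^{-3.48}$ cm$^{-1}$), whole-blood
haemoglobin at 150 g/L, pure water, and an effective cytochrome-c/CCO
spectrum with the haem band near 695 nm and the broad copper band near
830 nm. These tables are compiled approximations with literature-shaped
spectra — adequate for bounds and ratios, not radiometric prediction —
and are plain CSV precisely so users can substitute their own. Scattering
follows reduced-scattering power laws $\mu_s'(\lambda) = a(\lambda/500)^{-b}$
per layer with $g = 0.9$.

Dosimetry quantities are normalised to the light transmitted into the
head (incident minus specular reflection). CCO attribution multiplies the
grey-matter absorbed fraction by CCO's share of the grey-matter
absorption coefficient at that wavelength — a post-hoc fraction, not
separate chromophore tracking. With the default model, the grey-matter
reaching fraction stays below 8% across 450–1100 nm (maximum ≈ 4.5% near
800 nm at $10^5$ photons per wavelength), about 2% of entering 670 nm
light is absorbed in grey matter, ~0.1% is absorbed by CCO there, and
darkening the epidermis from melanin fraction 0.04 to 0.43 removes
roughly two thirds of the CCO dose — all recomputed, not asserted, by
the test suite and the acceptance script.

# Problem sizes and numerical choices

Tests run the spectral pipeline at the full 2048-point, 8-condition
session size (a session analyses in ~0.1 s); cohort power checks use 10
phantom seeds of 7 subjects; transport tests use $2\times10^4$–$10^5$
photons per configuration with batch-based (20 batches) standard errors;
the acceptance script uses $10^5$ photons per wavelength on a 25 nm
grid. ODE integration uses `deSolve::lsoda` at rtol $10^{-10}$.
Nonlinear fits use `minpack.lm` with box constraints; standard errors
come from the Gauss–Newton covariance $s^2 (J^\top J)^{-1}$.

# Known limitations

- The generator's idealisations listed above; in particular, real
  phospholipid baselines are not single broad Lorentzians.
- The noiseless end-to-end round trip recovers $k_f$ to ~0.1% (not
  machine precision): the forward model intentionally places
  non-polynomial baseline structure and neighbouring-peak tails inside
  the fit window.
- Chromophore/tissue coefficient tables are approximate; all transport
  comparisons are bounds or ratios with tolerances, and absolute
  absorbed fractions should not be quoted beyond one significant figure.
- pH values inherit the reference-convention caveat above.
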