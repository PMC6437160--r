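---
title: "Models and methods behind globinchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind globinchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globinchar)
```

`globinchar` reproduces, on synthetic data with known ground truth, the
quantitative workflow used to characterize a pathogenic myoglobin variant:
ligand-binding kinetics, heme retention, redox thermodynamics,
autoxidation, infrared band ratios of tissue inclusions, expression-based
gene ranking, and parametric linkage. This vignette records the models, the
parameter choices that matter, and the design decisions taken where the
published methodology leaves room.

## The three-state spectral model

Myoglobin's visible spectrum is dominated by the heme Soret band, whose
position reports the iron's oxidation/ligation state. The package models
each of the three relevant states as a sum of Gaussians:

* **oxy** (Fe²⁺·O₂): Soret 418 nm, Q bands 545 and 580 nm — these centers
  are the classic oxymyoglobin signature and are treated as fixed;
* **deoxy** (Fe²⁺): Soret 434 nm, broad Q band near 556 nm;
* **met** (Fe³⁺): Soret 409 nm, charge-transfer bands near 505 and 635 nm.

Deoxy and met centers are standard literature positions exposed as
configurable defaults. Amplitudes are *relative* molar absorptivities:
nothing downstream depends on absolute extinction, because every estimator
either works on ratios/fractions or normalizes per trace.

`decompose()` projects an observed spectrum onto the three basis spectra by
non-negative least squares (Lawson–Hanson active set) and renormalizes the
fractions to sum to one. Non-negativity is physical (fractions cannot be
negative); renormalization makes the result invariant to concentration and
path length. The compose→decompose round trip is exact to ≤1e-6 on
noiseless mixtures.

## Kinetics

**Single exponential.** All time courses — O₂ binding at 418 nm, hemin
transfer at 410 nm — are fitted to `A(t) = offset + amplitude·e^(−kt)`.
Initialization comes from the tail mean and a log-linear regression of
|A − tail|; refinement is damped Gauss–Newton (Levenberg–Marquardt) with
the analytic Jacobian. Standard errors come from the Gauss–Newton
covariance `σ̂²(JᵀJ)⁻¹`. Traces whose total span is below 3× the noise
level are reported `converged = FALSE` with reason "degenerate amplitude"
rather than fitted; fits whose RMSE exceeds 5× the noise estimate carry a
flag but are still returned.

**O₂ binding.** Under pseudo-first-order conditions (O₂ in large excess
over ~1 µM protein), `k_obs = k_on[O₂] + k_off`. `fit_kobs_vs_conc()` runs
a weighted (1/SE²) linear regression of `k_obs` on concentration: slope =
k_on, intercept = k_off, `K_D = k_off/k_on`. The K_D standard error is
propagated from slope *and* intercept by the delta method including their
covariance — intercepts of steep lines are poorly determined, which is why
equilibrium constants from this design carry large uncertainties (a ~±1 µM
error on ~1 µM is normal). A negative fitted intercept is reported raw
with a flag and K_D marked not-determined; it is never silently clamped.

**Units.** Rates carry the unit of their trace (`s`, `min`, `h`). Passing
a seconds trace to the hemin-loss fitter (which contracts for hours) is an
error, never a silent conversion.

**Autoxidation.** Each spectrum in the time series is decomposed into
state fractions; `f_met(t) = 1 − e^(−k_ox t)` is then fitted by the same
damped least-squares machinery with offset and amplitude free (absorbing
small decomposition bias).

## Electrochemistry

**Reference electrodes.** Potentials convert additively using standard
25 °C offsets vs SHE: SCE +0.2412 V, Ag/AgCl/3M KCl +0.210 V. These
constants are tabulated values, not fitted.

**OTTLE Nernst analysis.** The titration records spectra at a series of
applied potentials. Two analysis wavelengths are used: one where the
reduced species absorbs more (deoxy Soret, 434 nm) and one where the
oxidized species absorbs more (met Soret, 409 nm). With `A^max`/`A^min`
the extreme absorbances observed at each wavelength across the titration,

* `x_red(E) = (A₄₃₄(E) − A^min₄₃₄) + (A^max₄₀₉ − A₄₀₉(E))`
* `x_ox(E)  = (A^max₄₃₄ − A₄₃₄(E)) + (A₄₀₉(E) − A^min₄₀₉)`

Every term above is proportional to the concentration of one species, and
the two sums share a single proportionality constant, so
`log₁₀(x_ox/x_red) = log₁₀([ox]/[red])` exactly — even though the deoxy
and met Soret bands overlap at both analysis wavelengths. This is the
design decision worth recording: the naive two-wavelength version that
subtracts only each wavelength's own minimum leaves a constant offset in
the log-ratio wherever the two analysis bands are unequally selective,
which shifts the apparent midpoint by that offset times the Nernst slope.
The published caption formula for this analysis is typographically
truncated; the four-term form implemented here is the standard
self-normalizing reading and satisfies all of its checkable consequences
(log-ratio −∞ at the most reducing point, zero at E = E°′, 59.16 mV/decade
slope for one electron at 25 °C).

`fit_nernst()` regresses E on the log-ratio: E°′ is the potential at zero
log-ratio, and `n = round(0.05916 V / |slope|)`. Points where either
progress signal is below 5% of its range are excluded: because the extreme
absorbances are estimated from the titration itself, the endpoint logs are
unstable. Two practical consequences, verified in the tests: E°′ is
unbiased for titrations placed symmetrically around the midpoint even with
a modest ±0.12 V span, but the *slope* is compressed unless the titration
includes near-complete endpoints. The noiseless-slope check therefore uses
an "anchored" design with points at E°′ ± 0.3 V — the in-silico analog of
recording the fully reduced and fully oxidized spectra, which is standard
practice in real spectroelectrochemistry.

**Square-wave voltammetry.** The net-current peak is located after
subtracting a linear baseline fitted on flanking windows (default 60 mV at
each scan end), then refined by a parabola through the 5 points around the
maximum; plateau ties break toward the lower potential. E°′ is taken as
the peak potential, the convention for surface-confined couples. A peak
whose maximum sits against a scan edge, or whose baseline-corrected
current remains above half the peak at either end, is flagged
"truncated peak".

## FTIR microspectroscopy

Spectra span 900–4000 cm⁻¹. Mie-scattering QC fits a line over
2000–3800 cm⁻¹ (nearly band-free except the CH stretches) and rejects
spectra whose baseline slope magnitude exceeds 5e-5 AU/cm⁻¹.

Band work happens on the Savitzky–Golay **second derivative** (15-point
window, polynomial order 2), which removes baseline and sharpens
overlapping bands. The filter is exact for polynomials up to order 2; the
half-window at each edge is reported `NA` rather than extrapolated, to
avoid fabricated curvature at the range ends. A band amplitude is the
absolute value of a *negative local minimum* of the second derivative
within ±4 cm⁻¹ of the nominal center — requiring a genuine local minimum
(deeper than both spectral neighbours) is what distinguishes a real
1627 cm⁻¹ β-sheet component from the flank of the 1654 cm⁻¹ amide I band.

Ratios follow the field's conventions: lipid/protein = 2925/1654 and
lipid-oxidation (carbonyl/CH₂) = 1740/2925. The carbonyl center is quoted
as 1739 or 1741 cm⁻¹ in different places; the default 1740 with the
±4 cm⁻¹ window covers both. Region comparison (inclusion vs surrounding
tissue, ≥10 pixels each) uses Welch's unequal-variance t-test, two-sided,
with the significance flag at p < 0.005, and reports medians and IQRs per
region.

The synthetic map generator samples at 1 cm⁻¹ (instruments sample finer
than their 4 cm⁻¹ optical resolution; a 15-point filter then spans
15 cm⁻¹). At 4 cm⁻¹ sampling the same filter would span 60 cm⁻¹ and merge
the amide I / β-sheet pair — a useful reminder that "15-point filter" is
only meaningful relative to the sampling interval.

## Genetics

**Enrichment.** For each promoter,
`score = log₁₀(max over target-tissue samples + 1) − log₁₀(median over all samples + 1)`.
The median is taken over the entire collection including the target group
(the documented switch `include_target_in_median = FALSE` excludes it);
with ~10% target samples the choice is numerically immaterial. The
">1000-fold" candidate rule is a *strict* score > 3.0. The planted 82/31/51
partition test shows the bookkeeping (enriched / previously known / novel)
reproduces count structure by construction — real-atlas counts cannot be
reproduced without the original sample set.

**Parametric linkage.** The disease model is autosomal dominant: disease
allele frequency 0.001, penetrance 0.999 for carriers, phenocopy rate
0.001 (all configurable). The likelihood is computed exactly for loop-free
pedigrees by variable elimination over *phased* two-locus states: each
person's latent state is an ordered pair of (disease-allele, marker-allele)
haplotypes, founders draw from Hardy–Weinberg at linkage equilibrium,
and each meiosis transmits a parental haplotype intact with probability
(1−θ)/2 per haplotype or recombined with probability θ/2. Phase must be
latent — unphased genotypes are not Markov across generations. Children
are eliminated before parents, with per-step rescaling to avoid underflow.
`LOD(θ) = [log L(θ) − log L(0.5)]/log 10`, and LOD(0.5) ≡ 0 by
construction. The test suite proves the peeling against an independent
brute-force enumeration of all joint states on pedigrees up to 6 members,
and against the closed form `m·log₁₀2` for m phase-known non-recombinant
meioses. Looped pedigrees and Mendelian inconsistencies are rejected with
the offending members named. Multipoint linkage is out of scope.

## Structure

`sasa()` implements Shrake–Rupley with a deterministic Fibonacci-lattice
point set (960 points by default; the isolated-sphere error is <1% and
falls with more points). Radii: C 1.70, N 1.55, O 1.52, S 1.80, Fe 2.00 Å;
probe 1.4 Å. `heme_sasa()` sums over HEM/HEC residues — including
propionates, since published values do not state their exclusion — and
converts Å² to nm². Published heme-exposure numbers for folded globins are
MD-ensemble averages; the static single-structure value is suitable for
qualitative comparisons (more/less exposed) only, which is how the tests
use it.

## The synthetic world, and what a green test establishes

All generators add iid Gaussian noise with σ = 0.002 AU (typical
stopped-flow/diode-array noise) on the absorbance or current scale;
expression uses log-normal background (meanlog 1, sdlog 0.5) with planted
multiplicative enrichment. Stopped-flow grids start at the instrument dead
time (0.68 ms). The default O₂ panel is 2.5–40 µM; because k_obs spans
~40–480 s⁻¹ across that panel, each trace gets its own grid reaching ~7
relaxation times unless the caller supplies one.

What the generators deliberately do **not** emulate: baseline drift,
shot/flicker noise, photobleaching, mixing artifacts, Mie scattering
(except as an additive QC test case), preparation-to-preparation
variability, genotyping error, and population stratification. A green
recovery test therefore establishes that the estimator inverts its own
forward model at realistic instrument noise — not that it is robust to
every pathology of real instruments.

One consequence is documented as a known red result: at σ = 0.002 AU the
autoxidation fit's replicate scatter is far smaller than the 0.5%
separation between the true rates 1.96 and 1.97 min⁻¹, so the acceptance
suite's t-test over 50 seeds *distinguishes* them — whereas the published
comparison calls them nearly identical on the strength of ±0.4 min⁻¹
experimental uncertainties dominated by biological replication. The
package keeps the honest behavior rather than inflating the noise model to
force agreement.

## Numerical choices

* Exponential fits: LM damping ×10 on failure, /3 on success; convergence
  when the SSR improvement falls below 1e-12 relative.
* NNLS: active-set tolerance 1e-10, iteration cap 30 per variable.
* Nernst flooring: 5% of the combined signal range.
* SWV parabola refinement restricted to the 5 points around the maximum;
  vertices outside that bracket fall back to the grid maximum.
* LOD grid: θ from 0 to 0.5 in steps of 0.01, ties toward smaller θ.
* Seeds: every generator takes an explicit seed (via `noise_spec()` or a
  `seed` argument) and restores the caller's RNG state afterwards; the
  pipeline derives per-stage seeds from a single master seed.

## Limitations

* Single-step binding and first-order conversions only; no CO/NO ligands,
  no bimolecular rebinding, no global multi-trace fits.
* Relative spectral units; no absolute extinction calibration, no
  pH-dependent band shifts.
* No full Mie-scatter correction (RMieS-EMSC) and no amide I curve
  deconvolution beyond the 1627 cm⁻¹ marker band.
* Single-marker parametric linkage only; biallelic or multi-allelic
  markers supported, but state space grows as (2·alleles)², so dense
  microsatellite panels are slow.
* Static-structure SASA; no trajectory analysis.
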