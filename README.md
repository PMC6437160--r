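# globinchar

Characterization toolkit for myoglobin (and other monomeric hemoprotein)
variants. When a missense variant like myoglobin p.His98Tyr is implicated in
disease, the case rests on a battery of quantitative assays: O₂-binding
kinetics, heme retention, redox thermodynamics, autoxidation, infrared
microspectroscopy of tissue inclusions, tissue-restricted expression
ranking, and pedigree linkage. `globinchar` implements the analysis side of
that battery as tested, reusable R functions, together with seeded
synthetic-data generators with known ground truth so every estimator is
validated by parameter recovery.

## What it computes

| Assay | Model | Estimator |
|---|---|---|
| Stopped-flow O₂ binding | `A(t) = A∞ − (A∞−A₀)e^(−k_obs t)`, `k_obs = k_on[O₂] + k_off` | `fit_single_exponential()`, `fit_kobs_vs_conc()` → k_on (slope), k_off (intercept), `K_D = k_off/k_on` |
| Hemin loss (410 nm) | `A(t) = c + a·e^(−k₋H t)` | `fit_hemin_loss()` (h⁻¹) |
| Autoxidation | spectra → deoxy/oxy/met fractions (NNLS), `f_met(t) = 1 − e^(−k_ox t)` | `decompose()`, `fit_autoxidation()` (min⁻¹) |
| OTTLE spectroelectrochemistry | Nernst: `E = E°′ + (RT ln10 / nF)·log₁₀([ox]/[red])`, 59.16 mV/decade per electron at 25 °C | `nernst_variable()`, `fit_nernst()`, `fit_ottle()` → E°′ vs SHE, n |
| Square-wave voltammetry | Gaussian net-current peak on linear baseline | `swv_peak()` + `convert_reference()` (SCE/Ag-AgCl → SHE) |
| FTIR microspectroscopy | Savitzky–Golay 2nd derivative (15 pt, order 2); band amplitudes at 2925/1739/1654/1627 cm⁻¹ | `second_derivative()`, `band_ratio()`, `compare_regions()` (Welch t, p < 0.005) |
| Expression enrichment | `score = log₁₀(max target + 1) − log₁₀(median all + 1)` | `enrichment_score()`, `select_candidates()` (strict > 3.0 = >1000-fold) |
| Parametric linkage | LOD(θ) = log₁₀ L(θ)/L(0.5); exact peeling over phased disease×marker genotypes | `lod_single_marker()`, `max_lod()` |
| Heme exposure | Shrake–Rupley SASA, probe 1.4 Å | `parse_structure()`, `sasa()`, `heme_sasa()` (nm²) |

Every assay has a matching generator (`gen_binding_traces()`,
`gen_hemin_loss_trace()`, `gen_autoxidation_series()`,
`gen_redox_titration()`, `gen_swv()`, `gen_ftir_map()`,
`gen_expression_matrix()`, `gen_pedigree_genotypes()`), all pure functions
of (parameters, seed).

## Worked example

Simulate the full two-variant characterization at the published ground
truths and fit everything back:

```r
library(globinchar)
rep <- run_characterization(default_characterization_config(seed = 1))
print(rep)
```

```
| variant | K_D (uM) | k_-H pH7 (1/h) | k_-H pH5 (1/h) | E0' spectro (V vs SHE) | E0' SWV (V vs SHE) | k_ox (1/min) |
|---|---|---|---|---|---|---|
| WT | 1.19 ± 0.028 | 0.223 ± 0.0025 | 1.44 ± 0.0052 | 0.0401 | -0.0563 | 1.96 ± 0.0029 |
| His98Tyr | 8.47 ± 0.061 | 1.2 ± 0.0042 | 1.86 ± 0.0075 | 0.0208 | -0.105 | 1.97 ± 0.0021 |

seed: 1; sigma_abs: 0.002 AU; globinchar 0.1.0
```

Each cell is an estimate recovered from noisy synthetic data generated at
that variant's true parameter (σ = 0.002 AU Gaussian absorbance noise).
Reading the table: the variant binds O₂ ~7× more weakly (K_D 8.5 vs
1.2 µM), loses its hemin ~5× faster at pH 7, sits ~19 mV lower in reduction
potential, and autoxidizes at an essentially identical rate — the pattern
that distinguishes a destabilized heme pocket from an oxidation-prone one.

Single assays work the same way:

```r
traces <- gen_binding_traces(k_on = 1.16e7, k_off = 13.9,
                             noise = noise_spec(0.002, seed = 42))
fits <- lapply(traces, fit_single_exponential)
fit_kobs_vs_conc(sapply(traces, `[[`, "ligand_conc"),
                 sapply(fits, `[[`, "rate"),
                 sapply(fits, `[[`, "rate_se"))
```

## Command line

`inst/cli/globinchar` dispatches subcommands
(`simulate`, `fit`, `nernst`, `swv`, `ftir`, `enrich`, `lod`, `sasa`,
`report`), e.g.:

```sh
globinchar simulate heminloss --k 1.19 --sigma 0.002 --seed 21 --out trace.csv
globinchar fit heminloss --in trace.csv          # JSON result on stdout
globinchar report --seed 1 --out-dir results/
```

## Notes

- The methods vignette (`vignettes/methods.Rmd`) documents the models,
  parameter choices, what the generators do and do not emulate, and known
  limitations.
- Design notes for maintainers live alongside the code; the static SASA
  calculator is for qualitative comparisons only (published heme-exposure
  numbers typically come from MD ensembles).
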