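# phytophys

Analysis of laboratory photophysiology measurements on microalgal
cultures — the kind of measurement chain used to characterise
photoacclimation of phytoplankton (including coral-associated algae) to
low, high, and diurnally varying light.

The package covers, as composable R functions plus a small CLI:

- **Fluorescence induction (FRR).** Forward model and Levenberg–Marquardt
  fitting of single-turnover induction curves with PSII connectivity:
  closed-center fraction `dC/dX = σ(1−C)(1−p)/(1−pC)` and yield
  `F = Fo + (Fm−Fo)·C(1−p)/(1−pC)`, giving `Fo`, `Fm`, the effective
  cross-section `σ_PSII` (Å²) and connectivity `p`. Derived optics:
  `ETR_PSII = σ_PSII (Fq′/Fv′)/(Fv/Fm) E` (per-RC and per-chl) and
  `a*_PSII = σ_PSII (RC_PSII/chl a)/(Fv′/Fm′)`.
- **Quenching analysis.** `Fv/Fm`, `Φ_PSII`, `qP`, `1−qP`, `NPQ` from PAM
  protocol landmarks (with the Oxborough–Baker `Fo′` estimate when `Fo′`
  is unmeasured), NPQ dark-relaxation fractions, and 77 K / room
  temperature emission-spectrum normalisation and peak/shoulder location.
- **Gas fluxes.** Clark-electrode trace slopes (OLS and Theil–Sen), gross
  photosynthesis `Ag = (light slope + |dark slope|)·3600/chl`, transient
  post-illumination O₂ uptake detection, ¹⁴C fixation rates
  (Lewis–Smith form with the 1.05 discrimination factor), Jassby–Platt
  `P = Pmax·tanh(αE/Pmax)` fitting with `Ek = Pmax/α`, and the
  photosynthetic quotient.
- **Physiology.** Growth rates through dilution events, spherical cell
  volumes, intracellular densities, molar C:N, percent changes, carbon
  unit conversions, daily photon dose of constant and half-sine light
  schedules.
- **Diel analysis.** Morning/afternoon hysteresis (irradiance-binned
  asymmetry index and `∮ v dE` loop area) and midday depression, plus a
  pipeline (`run_pipeline()`) that analyses a directory of input files
  and emits summary tables with a hash-recording manifest.
- **Synthetic data.** Seeded generators for all six input kinds with
  known ground truth, so the entire chain is validated by round trips.

## Worked example

```r
library(phytophys)

# a noisy single-turnover transient with known truth, then the fit
tr  <- simulate_frr_transient(0.4, 1.0, sigma = 380, p = 0.22,
                              noise_sd = 0.01, seed = 42)
fit_frr(tr)
#> <frr_fit>
#>   Fo = 0.4112, Fm = 0.9971 (Fv/Fm = 0.588)
#>   sigma_PSII = 408.5 A2, p = 0.2755
#>   rss = 0.0102 over 100 flashlets; converged: TRUE

# photosynthesis-irradiance fit at 5 % lognormal noise
pe <- simulate_pe_experiment(2.97, 0.09, noise_cv = 0.05, seed = 42)
fit_pe_curve(pe$e, pe$p)
#> <pe_fit>
#>   Pmax = 3.084 mg C mg chl-1 h-1 (256.8 umol C)
#>   alpha = 0.09028, Ek = 34.16 umol photons m-2 s-1
#>   rss = 0.092 over 9 points; converged: TRUE

# quenching coefficients from protocol landmarks
quench_params(quench_markers(fo = 0.39, fm = 1.0, ft = 0.45,
                             fm_prime = 0.62))
#>   fv_fm phi_psii    qp one_minus_qp   npq fo_prime ...
#> 1  0.61    0.274 0.557        0.443 0.613    0.315

# molar ratio of O2 evolved to C fixed
photosynthetic_quotient(338, 248)
#> [1] 1.362903
```

A single noisy transient lands a few percent off truth (σ̂ = 408.5 vs
380 here); across 50 seeds at this noise level the median estimates stay
within 5 % — that distinction is exactly what the synthetic generators
are for.

The same operations are scriptable from a shell via the thin wrapper in
`inst/cli/phytophys` (subcommands `simulate`, `fit-frr`, `quench`, `gas`,
`pe-fit`, `physiology`, `diel-report`).

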