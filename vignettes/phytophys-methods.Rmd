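---
title: "Models and methods in phytophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phytophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytophys)
```

phytophys implements the complete measurement chain of a laboratory
photophysiology study of a microalga acclimating to low, high, and
sinusoidally varying light: single-turnover fluorescence induction,
PAM quenching analysis, emission spectra, oxygen-electrode and
14C gas-flux analysis, photosynthesis–irradiance fitting, derived
physiology, and diel hysteresis. This vignette documents the models, the
defaults, the numerical choices, and the places where the design was
genuinely open.

## Fluorescence induction with PSII connectivity

A train of sub-saturating single-turnover flashlets progressively closes
PSII reaction centers. Writing $C$ for the closed fraction and $X$ for the
cumulative excitation dose (photons Å$^{-2}$), the connectivity-aware
induction model (Kolber–Prášil–Falkowski form) is

$$\frac{dC}{dX} = \sigma_{PSII}\,\frac{(1-C)(1-p)}{1-pC}, \qquad
F(C) = F_o + (F_m - F_o)\,\frac{C(1-p)}{1-pC},$$

with $\sigma_{PSII}$ the effective absorption cross-section (Å$^2$) and
$p \in [0,1)$ the probability that an exciton landing on a closed center
hops to an open neighbour. At $p = 0$ the model collapses to the Poisson
limit $C = 1 - e^{-\sigma X}$.

**Integration.** `frr_forward()` advances $C$ by classical 4th-order
Runge–Kutta, sub-stepping each flashlet so no step moves $C$ by more than
about 0.01. The ODE also has an implicit closed form
($pC - (1-p)\ln(1-C) = \sigma(1-p)X$, by separation of variables); the test
suite solves it by bisection and uses it as an independent oracle — the
integrator agrees with it to better than $10^{-8}$ and with the $p=0$
exponential to better than $10^{-4}$.

**Fitting.** `fit_frr()` estimates $(F_o, F_m, \sigma_{PSII}, p)$ by
Levenberg–Marquardt. Starting values: $F_o$ = mean of the first 3 yields,
$F_m$ = mean of the last 5, $\sigma$ from the early log-linear slope
assuming $p = 0$, and $p = 0.3$; $p$ is bounded in $[0, 0.99]$. Noiseless
transients are recovered to $10^{-6}$ relative error; at 1 % additive
noise the median $\hat\sigma$ and $\hat p$ over 50 seeds stay within 5 %
of truth. A transient with less than 5 % relative fluorescence rise is
rejected ("no variable fluorescence"); a fitted $F_v/F_m < 0.05$ is
flagged rather than silently returned, and non-convergence is always
reported in the `converged` field.

**Derived optics.** $\sigma_{PSII}$ is carried in Å$^2$ throughout and
converted ($1\,\text{Å}^2 = 10^{-20}\,\text{m}^2$) only inside
`compute_etr()` and `compute_apsii()`. The electron transport rate is
$ETR_{PSII} = \sigma_{PSII}\,(F_q'/F_v')/(F_v/F_m)\,E$; with $E$ converted
to photons m$^{-2}$ s$^{-1}$ this gives electrons RC$^{-1}$ s$^{-1}$
directly. The chlorophyll-normalised twin multiplies by the
photosynthetic unit size (default 0.002 mol RC per mol chl a) over the
chl a molar mass (893.5 g mol$^{-1}$; Avogadro $6.022\times10^{23}$).
Both values are exposed because the published per-chl scale for such
measurements is not always reconstructable from the stated constants —
users comparing with literature values should check which unit path the
source used. The chl-specific PSII absorption is
$a^*_{PSII} = \sigma_{PSII} (RC_{PSII}/\text{chl }a)/(F_v'/F_m')$ with the
unit size expressed per mg chl a.

## Quenching analysis

`quench_params()` computes the standard coefficients from protocol
landmarks: $F_v/F_m = (F_m-F_o)/F_m$, $\Phi_{PSII} = (F_m'-F_t)/F_m'$,
$qP = (F_m'-F_t)/(F_m'-F_o')$, $NPQ = (F_m-F_m')/F_m'$, and $1-qP$ (the
PSII excitation pressure). The identity
$\Phi_{PSII} = qP \cdot F_v'/F_m'$ holds algebraically for any $F_o'$ and
is enforced to $10^{-12}$ in the tests. When $F_o'$ is not measured it is
estimated with the Oxborough–Baker relation
$F_o' = F_o/(F_v/F_m + F_o/F_m')$, which reduces to $F_o$ at $F_m' = F_m$;
a measured $F_o'$ always takes precedence. $F_m' > F_m$ is physically
unexpected but occurs in real data — it is flagged, not fatal.

Raw-trace landmark extraction (`extract_quench_markers()`) uses the median
of the dark window for $F_o$ and the maximum over each saturating-pulse
window for $F_m$ and $F_m'$ — robust to noise, though the pulse-apex
maximum is positively biased under noise, which slightly inflates small
quantum yields (documented in the tests).

Emission spectra are normalised at a reference wavelength (690 nm by
convention for 77 K chlorophyll spectra) or at the maximum; the operation
is idempotent and scale-preserving. `locate_emission_peaks()` reports
strict local maxima above a prominence threshold with sub-sample
positions by parabolic interpolation, and detects shoulders (bands that
modulate a flank without forming a maximum, e.g. red-shifted antenna
emission near 710–712 nm) as interior local minima of the second
derivative away from reported peaks.

## Gas exchange and photosynthesis–irradiance

Oxygen slopes are ordinary least squares per labelled segment, with 5 s
trimmed at segment edges to avoid light/dark transition artifacts and a
Theil–Sen (median of pairwise slopes) variant for outlier-contaminated
traces. Gross photosynthesis adds the dark respiratory slope magnitude
back onto the net light slope,
$A_g = (s_{light} + |s_{dark}|)\cdot 3600/\text{chl}$, and is therefore
invariant to the electrode's absolute offset. Steady respiration is
estimated from the second half of the post-light dark segment so that a
transient post-illumination burst cannot contaminate it.

`detect_post_illumination_uptake()` fits a continuous two-segment
piecewise-linear model over the dark segment after the first
light-to-dark transition, scanning breakpoints up to 180 s; a burst is
reported when the early uptake exceeds steady uptake by the configurable
factor (default 1.5x). On noiseless synthetic bursts the rate is exact
and the breakpoint is recovered within the sampling step.

14C fixation rates follow the standard small-volume incubation form,
$P = \frac{DPM_{s}-DPM_{b}}{DPM_{tot}}\cdot\frac{DIC \cdot 1.05}{\text{chl}\cdot t}$,
with the 1.05 isotope-discrimination factor a documented, configurable
constant and DIC an input (carbonate chemistry is out of scope). Rates
are carried in µmol C with a mg C twin via the carbon molar mass
(12.011 g mol$^{-1}$).

P–E curves use the Jassby–Platt saturating form
$P = P_{max}\tanh(\alpha E/P_{max})$, fitted by Levenberg–Marquardt with
$E_k = P_{max}/\alpha$ attached. No photoinhibition term is modelled.
When all measured irradiances fall below about $1.5\,E_k$ the fitted
$P_{max}$ is extrapolation and the result is flagged
`"Pmax unconstrained"` — the 1.5 threshold is a deliberate, conservative
choice (at $1.5\,E_k$ the curve has reached only $\tanh(1.5)\approx 0.91$
of saturation).

## Physiology bookkeeping

Cells are modelled as spheres of the Coulter diameter — a convention
validated in the tests by reproducing both printed chlorophyll packaging
densities (3.5 and 2.2 fg chl a µm$^{-3}$) from the corresponding quotas
and diameters. Growth rates are $\mu = (\ln c - \ln c_0)/(t - t_0)$; for
semi-continuous series the pooled estimator sums log-growth over all
intervals that do not span a dilution reset, which recovers the
underlying exponential rate exactly. Atomic masses: C 12.011,
N 14.007 g mol$^{-1}$. Rounding to a table's printed precision is a
formatting decision only and is never applied to stored values.

A note on internal consistency of summary tables: when a published table
reports the mean of per-replicate ratios (e.g. molar C:N), recomputing
the ratio from the mean quotas need not match it. Of the table rows the
package recomputes, only combinations that are internally consistent are
asserted exactly in the tests.

## Light schedules and the diel module

Schedules are constant (continuous light) or half-sine,
$E(t) = E_{peak}\sin(\pi t/\text{photoperiod})$ — the simplest shape
matching a computer-controlled "sinusoidal" lamp program. The daily dose
is the 24 h integral in mol photons m$^{-2}$ d$^{-1}$ (analytic for
constant light, numeric with $10^{-10}$ relative tolerance otherwise).
A half-sine with a 500 µmol photons m$^{-2}$ s$^{-1}$ peak over 12 h
integrates to 13.75 mol photons m$^{-2}$ d$^{-1}$; published dose figures
for nominally sinusoidal programs can differ by a few percent because the
true lamp program shape is rarely stated. The package documents this
rather than tuning the shape.

The diel generator is phenomenological, not mechanistic: each parameter
follows a linear morning ramp from baseline to a mid-morning plateau
(`peak_mult` times baseline), a falling phase that is the time-mirror of
the rising phase scaled by the afternoon `depression` factor, and
baseline at night. No xanthophyll-cycle kinetics, state transitions, or
chlororespiration are simulated — the shapes encode the observed
qualitative pattern (mid-morning maximum, midday depression, hysteresis)
so that the analysis operations can be validated by exact round trips:
`midday_depression()` returns the configured depression factor and
`hysteresis_index()` returns one minus it, both to $10^{-12}$ in the
noiseless, lag-free case.

`hysteresis_index()` splits the photoperiod at the irradiance maximum
(boundary sample assigned to the morning), bins samples by irradiance in
bins of 10 % of the peak (the matching tolerance is a design choice — no
standard exists), and compares bin **medians** between phases:
$\Delta = (v_{am} - v_{pm})/v_{am}$, index = mean $\Delta$ over matched
bins. Medians make the index insensitive to the single boundary sample,
which carries the depressed midday value so that `midday_depression()`
(nearest sample to the irradiance peak over the pre-midday maximum)
round-trips exactly. Night samples (zero irradiance) carry no
morning/afternoon meaning and are excluded. The loop area is the signed
integral $\oint v\,dE$ around the closed daily trajectory — zero for a
time-symmetric series, and equal to minus the signed shoelace area of the
$(E, v)$ polygon, which the tests verify.

## Synthetic data: what it does and does not emulate

Every input kind has a seeded generator whose noiseless output is the
exact forward model, so each analysis can be validated by round-tripping.
Noise models are the standard instrument behaviours: additive Gaussian on
fluorescence (SD as a fraction of $F_m$), additive Gaussian on O$_2$
concentration, multiplicative unit-mean lognormal on P–E rates
(multiplicative because scintillation-derived rates have roughly constant
CV). All randomness flows through one explicit seed per call via an
RNG-state-preserving wrapper; no generator mutates the global stream when
seeded. The PAM generator holds the final 10 s of the actinic phase
exactly at the steady-state $F_t$ so that noiseless marker extraction
recovers the configured NPQ and $\Phi_{PSII}$ without relaxation
residue.

Passing round-trip tests therefore demonstrates correctness of the
estimators under the stated noise models — they do not demonstrate
robustness to instrument drift, baseline wander, photobleaching during
the protocol, or model misspecification (e.g. heterogeneous PSII
populations), none of which the generators emulate.

## Problem sizes and determinism

The test suite and the acceptance script use: 100-flashlet transients
(cumulative dose $10^{-2}$ photons Å$^{-2}$), 50 seeds for the 1 %-noise
FRR and 5 %-CV P–E recovery studies, 100 seeds for the 0.5 %-noise bias
check, 720 s oxygen traces at 1 Hz, 9-point P–E curves spanning
5–1500 µmol photons m$^{-2}$ s$^{-1}$, 15-min diel sampling, and 20-day
growth series. These sizes mirror realistic instrument sessions while
keeping a full pipeline run to seconds. Pipeline outputs are a pure
function of (inputs, configuration): reruns are byte-identical, and the
manifest records input MD5 hashes and the seed.
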