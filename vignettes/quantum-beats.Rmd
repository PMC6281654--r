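---
title: "Modelling and extracting vibrational quantum beats in TR-PES"
author: "beatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and extracting vibrational quantum beats in TR-PES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatmap)
```

## The physical picture

A spectrally broad ultrafast pump pulse does not excite a single vibronic
eigenstate of a jet-cooled molecule: it prepares a coherent superposition
— a wavepacket —

$$|\Psi(\Delta t)\rangle \;=\; \sum_n \tilde a_n\,|\psi_n\rangle\,
  e^{-i\,2\pi c E_n \Delta t},$$

with level energies $E_n$ in cm$^{-1}$, $c$ the speed of light in cm/ps,
and complex coefficients $\tilde a_n = a_n e^{-i\phi_n}$ collecting the
populations and initial phases. A delayed probe pulse ionizes the
molecule; whenever two eigenstates $n$ and $m$ ionize into the *same*
final cation state, their transition amplitudes interfere and the
photoelectron signal oscillates at the gap frequency
$\omega = (E_n - E_m)/\hbar$, i.e. at $|E_n - E_m|$ in wavenumbers —
quantum beats. The package was built around this physics as it plays
out in methyl anthranilate (MA), the precursor of the sunscreen filter
meradimate: the S$_1$ state of MA carries two Franck–Condon-active
modes near 179 and 421 cm$^{-1}$, and the beat pattern of its
time-resolved photoelectron spectra encodes both the level structure
and — through beat dampening — intramolecular vibrational energy
redistribution (IVR).

The package covers five stages, each usable on its own:

1. **Wavepacket construction** (`stick_spectrum()`, `pump_pulse()`,
   `build_wavepacket()`): amplitudes $a_n \propto \sqrt{I_n}\,g(E_n)$
   from stick intensities $I_n$ and the unit-peak Gaussian pump field
   envelope $g$, normalized to $\sum a_n^2 = 1$.
2. **Free propagation** (`survival_probability()`,
   `apply_mode_phase()`, `smooth_with_irf()`): the phase-augmented
   survival probability (below), optional mode-dependent phases, and
   Gaussian instrument-response smoothing.
3. **Beat extraction** (`fft_spectrum()`, `find_beat_peaks()`,
   `isolate_beats()`, `fft_vs_eke()`, `fft_vs_time()`,
   `detect_revival()`): tapered FFT spectra of decay-normalized
   transients, per-eKE beat maps, sliding-window spectrograms, revival
   detection.
4. **Kinetic fitting** (`beat_fit_model()`, `init_from_fft()`,
   `fit_transient()`): IRF-convolved exponential decays modulated by
   damped cosines, fitted by Levenberg–Marquardt least squares with
   multistart.
5. **State counting** (`beyer_swinehart_counts()`,
   `density_of_states()`): exact harmonic state counts by the
   Beyer–Swinehart fold.

A sixth module, the synthetic generator (`generate_trpes()`,
`ma_scenario()`, `make_fixture_suite()`), produces 2-D delay × eKE maps
with the statistical structure the analysis assumes, so the entire
pipeline is testable without any measured data.

## The phase-augmented correlator

The textbook survival probability
$|\langle\Psi(\Delta t)|\Psi(0)\rangle|^2$ is independent of the
per-level phases $\phi_n$ (they cancel in
$\sum_n |a_n|^2 e^{-i\omega_n t}$), yet the observed beat pattern of MA
requires a phase on the $\nu_{179}$ levels: beats appearing at lower
eKE are shifted in delay, which a mode-dependent ionization phase
expresses. This package therefore computes

$$P(\Delta t) \;=\; \Bigl|\sum_n a_n^2\,
  e^{-i\,(2\pi c E_n \Delta t + \phi_n)}\Bigr|^2 ,$$

in which a phase added to a subset of levels shifts exactly the beat
components between that subset and the rest by the phase difference,
and a global phase is inert. With all $\phi_n = 0$ this reduces to the
standard correlator with $P(0) = 1$. This is an *interpretation* — a
deliberately minimal way to let vibrational phase information enter a
correlator that would otherwise be blind to it — not a derivation from
an ionization matrix element; its empirical adequacy is judged by the
spectrogram structure it reproduces (see the acceptance tests).

Applying $\pi/2$ to the $\nu_{179}$ progression of the shipped MA level
list (`ma_lif_spectrum()`, see below) delays the alignment of the 55
and 63 cm$^{-1}$ components of the 60 cm$^{-1}$ band by a quarter of
their 4.2 ps rephasing period, which is what pushes the first 60
cm$^{-1}$ revival out to $\sim$5 ps.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| pump FWHM | 500 | cm$^{-1}$ | bandwidth of the $\sim$40 fs pump pulses |
| amplitude weighting | `sqrt` | — | $I_n \propto$ \|transition moment\|$^2$, so the field-level amplitude is $\sqrt{I_n}$; `linear` available for sensitivity checks |
| population floor | $10^{-6}$ | — | drop levels the pump barely touches |
| stick merge tolerance | 0.5 | cm$^{-1}$ | hygiene for digitized spectra |
| time grid | 0–12.5, step 0.005 | ps | Nyquist $\approx$ 3300 cm$^{-1}$, ample for gaps $\le$ 600 cm$^{-1}$ |
| IRF FWHM | 0.1 | ps | of the order of the pump–probe cross-correlation; attenuates a beat at $\tilde\nu$ by $e^{-(\pi c\tilde\nu w)^2/4\ln 2}$, explaining the absence of beats $\gtrsim$250 cm$^{-1}$ |
| FFT taper / padding | Hann / 8 | — | sidelobe suppression / peak interpolation |
| spectrogram window / step | 2.5 / 0.1 | ps | resolves 60 cm$^{-1}$ while localizing few-ps dampening |
| eKE bin width | $\ge$50 | cm$^{-1}$ | stabilizes per-column noise in FFT(eKE) |
| DOS bin / smoothing window | 1 / 100 | cm$^{-1}$ | exact fold for integer frequencies / smooth density |

All energies are in cm$^{-1}$, delays in ps, wavelengths in vacuum nm;
`wavelength_to_relative_energy()` is the single conversion point.

## Decay isolation and kinetic fitting

Beats ride on an overall population decay. `isolate_beats()` fits a
slowly varying baseline — constant, IRF-convolved single exponential,
or bi-exponential, chosen by corrected AIC in `"auto"` mode — and
returns $y/\text{baseline} - 1$ (ratio mode, the default) so that FFT
magnitudes read directly as modulation depths.

`fit_transient()` fits

$$S(t) = G_{\mathrm{irf}} \ast \Bigl[H(t)\sum_j A_j e^{-t/\tau_j}
 \Bigl(1 + \sum_k B_k e^{-t/\tau^d_k}
 \cos(2\pi c\tilde\nu_k t + \phi_k)\Bigr)\Bigr] + y_0 .$$

Beats are multiplicative on the decay by default (the physical picture
of a modulated S$_1$ ionization signal; an additive mode is a flag
away), and all beats share one dampening lifetime $\tau^d$ by default —
the "overall beat decay lifetime" that IVR semantics suggest —
with per-beat lifetimes available through the `group` column.
Numerical choices worth knowing:

* the model is evaluated on an oversampled grid (automatically chosen
  so the convolution step is below $\sigma_{\mathrm{irf}}/3$) and
  interpolated back;
* the optimizer is `minpack.lm` Levenberg–Marquardt with numerical
  Jacobian, box constraints (lifetimes $> 10^{-3}$ ps, frequencies
  $> 1$ cm$^{-1}$), and a recorded-seed multistart (default 8 jittered
  restarts) to escape local minima — a beat frequency wrong by one
  period over the record is a local minimum, so good seeds matter;
* $\tau^d$ is bounded above at ten record lengths: slower dampening is
  indistinguishable from none and would otherwise drift unbounded;
* `init_from_fft()` seeds frequencies from an *untapered* FFT of the
  isolated transient restricted to $t \ge 2\,\mathrm{FWHM}_{\rm irf}$
  (damped beats live at early delays, which a centered taper would
  suppress, and the rise region would otherwise leak broadly), ignores
  candidates below three resolution elements (slow baseline-misfit
  residuals) or above 250 cm$^{-1}$ (IRF-suppressed), and skips peaks
  within three resolution elements of a stronger accepted peak (taper
  sidelobes);
* standard errors come from the scaled covariance at the optimum, and
  the convergence flag reports the optimizer verdict honestly —
  non-convergence is never silently returned as success.

## The synthetic generator

`generate_trpes()` realizes the common-final-state mechanism term by
term. For each cation level $v^+$ with Franck–Condon row
$\mathrm{FC}[n, v^+]$ (row-stochastic), each S$_1$ level contributes a
Gaussian photoelectron feature of weight $a_n^2\,\mathrm{FC}[n,v^+]$ at
its energy-conserving eKE
$(\mathrm{offset} - E_{v^+} + E_n)$, and each pair $(n, m)$ with
$\mathrm{FC}[n,v^+]\mathrm{FC}[m,v^+] > 0$ contributes

$$2\,a_n a_m \sqrt{\mathrm{FC}[n,v^+]\,\mathrm{FC}[m,v^+]}\;
  \sqrt{g_n(\mathrm{eKE})\,g_m(\mathrm{eKE})}\;
  \cos(\Delta\omega\,t + \Delta\phi)\; e^{-t/\tau^d_{nm}},$$

after which the map is gated at $t = 0$, multiplied by the population
decay, convolved with the IRF along the delay axis (zero-padded on the
left — the signal is physically zero before pump–probe overlap) and
degraded with seeded Gaussian (or optionally Poisson-like) noise.
Consequences that the tests exploit: a diagonal FC matrix produces no
beats at all; with a single shared final state every pairwise gap
beats, localized on the highest-eKE feature; and beat dampening is a
per-interference-term property (IVR removes population from the
*initially prepared* levels), with a global default and per-pair
overrides.

Two deliberate simplifications are documented rather than hidden.
First, the generator works with field-level amplitudes
$a_n\sqrt{\mathrm{FC}}$ (physical for ionization amplitudes), while the
1-D correlator uses populations $a_n^2$; the two coincide in shape for
equal populations, which is the configuration in which the
eKE-integrated map is required to reproduce the 1-D correlator exactly
(`eke_reference = "final_state"`, the bandwidth $\gg$ level-spread
limit). Second, photoelectron features are Gaussian with a default 250
cm$^{-1}$ FWHM; the true spectrometer lineshape is not modelled.

`ma_scenario()` packages the study conditions: `"348"` (the approximate
LIF list pumped on its red flank — persistent 180 cm$^{-1}$ beats),
`"344"` ($\pi/2$ on $\nu_{179}$ — dephasing and revivals), `"330"` and
`"menA330"` (a synthetic high-lying cluster at 1300/1360/1480
cm$^{-1}$, all ionizing to a common final state, with shared beat
dampening of 1.4 and 1.0 ps respectively), and `"beat_free"`
(single-level control). The cluster is a *structural stand-in*: the
real level structure 1400 cm$^{-1}$ above the origin is dense and
unresolved; three levels giving beats at exactly 60/120/180 cm$^{-1}$
make the shared-dampening truth well-posed for recovery tests while
matching the observed band positions to within a few cm$^{-1}$.

## The shipped level and mode lists

`ma_lif_spectrum()` is a *best-effort, approximate* list of the
dominant S$_1$ levels of MA — 0, 179, 358, 366, 421, 537 and a
satellite near 600 cm$^{-1}$ with plausible relative intensities. The
complete line list with exact weights exists only in the original
study's data deposition. The approximate list reproduces the assigned
beat gaps (55, 63, 116, 179 cm$^{-1}$), the dampening of all bands in
the phase-augmented calculation, and the $\sim$5 ps revival of the 60
cm$^{-1}$ band (at 5.2 ps, including the model's characteristic
spurious second recurrence near 9.5 ps); it does *not* reproduce the
published 7 ps (180 cm$^{-1}$) and 9.5 ps (115 cm$^{-1}$) revival
times, which are set by satellite spacings of $\sim$4.8 and $\sim$3.5
cm$^{-1}$ within those bands that the main-text list cannot contain.
The corresponding acceptance-test expectations are left failing rather
than widened.

`ma_s1_modes_synthetic()` is likewise a synthetic stand-in: 54
plausible harmonic frequencies for the S$_1$ state of the 20-atom
molecule, anchored by the two experimentally known modes (179, 421
cm$^{-1}$) and with five ring modes in the 1400–1500 cm$^{-1}$ window.
With it, the Beyer–Swinehart density of states is $\sim$470 states
cm$^{-1}$ near 1400 cm$^{-1}$ and $\sim$0.2 states/cm$^{-1}$ near 200
cm$^{-1}$ (100 cm$^{-1}$ smoothing window) — the right orders of
magnitude for the IVR-threshold argument, but not a substitute for the
computed frequency list.

## What passing tests do and do not show

The synthetic maps have uniform grids, Gaussian features, homoscedastic
noise and exactly exponential dampening. Real TR-PES data additionally
carry velocity-map-imaging reconstruction noise correlated across eKE,
non-Gaussian lineshapes, pump–probe scatter around $t = 0$ and
slow drifts. Passing the suite therefore demonstrates the correctness
of the algorithms and the identifiability of the model parameters
under the stated conditions — not instrument-grade robustness. The
problem sizes used throughout (grids of 750–2500 delay points, 50–65
eKE bins, 20–50 fit replicates, state counts to a few thousand
cm$^{-1}$) were chosen as the smallest at which every quantity of
interest is comfortably resolved.

Known limitations, shared with the underlying model: no explicit
projection onto the cation surface inside the correlator (eKE structure
lives entirely in the generator), no Franck–Condon factors computed
from displacements, no anharmonicity in the state counts, no
photoelectron angular distributions, and single-transient fitting only
(no global analysis across eKE bands).

## A worked example

```{r example, eval = FALSE}
# the 348 nm-like conditions: v = 0..2 of the 179 cm^-1 progression
sp <- stick_spectrum(c(0, 179, 358), c(1, 1, 1))
wp <- build_wavepacket(sp, pump_pulse(500, center_cm1 = 100))
tr <- smooth_with_irf(survival_probability(wp, seq(0, 7.5, by = 0.005)), 0.1)
find_beat_peaks(fft_spectrum(tr))   # one dominant peak at ~179 cm^-1

# fit a damped two-beat transient end to end
map <- generate_trpes(ma_scenario("330", rng_seed = 4))
tr1 <- integrate_eke(map, c(150, 2500))
fit <- fit_transient(tr1, init_from_fft(tr1, max_beats = 3), seed = 4)
fit_parameter(fit, "taud1")         # shared beat dampening lifetime, ps
```
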