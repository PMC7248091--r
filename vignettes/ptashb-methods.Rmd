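---
title: "Photothermal angular-scattering hemoglobinometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal angular-scattering hemoglobinometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptashb)
```

## The measurement principle

Photothermal angular scattering (PTAS) senses hemoglobin without
reagents. A capillary filled with whole blood is illuminated by a probe
beam whose wavelength lies outside the hemoglobin absorption band; the
tube and its contents scatter the light into a semi-periodic angular
fringe pattern on a camera. A second, modulated beam inside the
absorption band (around 532 nm) is absorbed by hemoglobin, heats the
blood, and lowers its refractive index, which shifts the fringe pattern.
The fringe-phase excursion at the modulation frequency therefore encodes
the hemoglobin concentration [Hb].

`ptashb` implements the full computational chain for such a sensor:

1. a physics-based **instrument simulator** (`simulate_stack()`) standing
   in for the optical hardware,
2. **demodulation** of an image stack into a scalar sensor signal
   (`measure_stack()`),
3. **Hill-equation calibration** between signal and [Hb]
   (`fit_hill()`, `invert_hill()`),
4. the **analytical and clinical evaluation statistics** used to qualify
   such a device: detection limits, precision, Passing-Bablok and
   Bland-Altman method comparison, and WHO-cutoff anemia screening.

## The instrument simulator

Each frame is rendered as row-constant cosine fringes

$$ I(x, t) = \bar I \, \bigl(1 + V \cos(2\pi f x / W + \phi_0 +
   a(\mathrm{Hb})\, w(t))\bigr), $$

with mean level $\bar I$ (counts), visibility $V$, spatial frequency $f$
(cycles per image width $W$), static offset $\phi_0$, and a
time-dependent phase excursion. Two model components carry the physics:

* **Hill-type amplitude.** The excursion amplitude saturates with
  concentration, $a(\mathrm{Hb}) = \phi_{\max}\,
  \mathrm{Hb}^h / (K^h + \mathrm{Hb}^h)$, matching the saturating
  response of photothermal sensors at high absorber concentration.
  Defaults $\phi_{\max} = 1.5$ rad, $K = 9$ g/dL, $h = 1.2$ place the
  half-saturation point mid-range of whole blood (≈ 0–18 g/dL) and keep
  the excursion below $\pi$, which makes temporal phase unwrapping
  unambiguous. The real instrument's fitted constants are not public;
  these are conventional, physically plausible choices.
* **Thermally low-passed PWM drive.** The photothermal laser is switched
  on/off (0/1, not ±1) at 1 Hz by pulse-width modulation; the thermal
  response of a ~200 µm capillary is modelled as a first-order lag with
  time constant `thermal_tau` (default 0.05 s). `modulation_waveform()`
  returns the *steady-state periodic* response, so acquisitions are
  exactly periodic over the integer number of modulation cycles that the
  default timing (30 Hz for 5 s, 1 Hz modulation) guarantees. The
  heating actually *decreases* the refractive index; only the magnitude
  of the excursion matters downstream, so the simulator adds the phase
  term and documents the sign as conventional.

Noise is additive Gaussian read noise (default SD 30 counts on a
1000-count mean) with optional Poisson shot noise, clipped at zero.
Frames default to 512 × 64 px with fringe frequency 24 — full-HD frames
carry no extra information for the vertically averaged analysis and
would only slow simulation studies; `optical_config()` accepts the full
sensor geometry when wanted.

### What the generator does and does not emulate

The simulator reproduces the *structure* of real acquisitions —
saturating concentration response, modulated fringe phase, thermal lag,
detector noise — so that every stage of the analysis chain can be
exercised end to end with known ground truth. It deliberately omits
wave-optics scattering theory for the capillary, heat diffusion,
mechanical vibration, capillary repositioning and camera artifacts.
Consequently its detector-noise-only measurement floor is far lower than
a bench instrument's: passing tests demonstrate correctness of the
computations, not the analytical performance of any physical device. To
keep *replicate* statistics realistic, the study-level generators
(`simulate_calibration_study()` and friends) add a per-measurement
multiplicative jitter on the photothermal amplitude (default 1% SD, plus
0.5% day-to-day in multi-day series), emulating repositioning and
thermal variability; with those defaults the simulated intra-assay CV at
11.2 g/dL lands near 2%, the order of magnitude reported for portable
hemoglobinometers. The jitter lives in the study generators only — the
`simulate_stack()` contract itself stays exact.

## Demodulation

For each frame the image is averaged along the vertical axis
(`average_profile()`); fringes are row-constant, so averaging trades
nothing for a $\sqrt{H}$ noise reduction. The fringe bin is located
**once**, on the temporal-mean profile, as the band-restricted argmax of
the DFT magnitude (`locate_fringe_bin()`): a per-frame search could hop
bins under noise and destroy phase continuity. The phase at that bin
(`extract_phase()`) follows the convention that
$c + a\cos(2\pi f x/W + \varphi)$ returns $\varphi$; it is exact (≤ 1e-9
rad) for single tones at integer bins. The per-frame phases are
temporally unwrapped to $|\Delta| \le \pi$ and detrended, and the sensor
signal is $2/N$ times the DFT magnitude of the trace at the modulation
bin (`lockin_magnitude()`), so a pure sinusoid of amplitude $a$ reads
back exactly $a$ radians. The $2/N$ convention is arbitrary up to
calibration; it is frozen and documented so signals are comparable
across runs.

### Detrending

Slow thermal drift and the arbitrary phase origin must be removed
without touching the modulation component. An ordinary least-squares
line over all samples is *not* orthogonal to a sampled sinusoid
($\sum_n n e^{i\omega n} = N/(e^{i\omega}-1) \ne 0$), and subtracting it
leaks a percent-level error into the modulation bin at $N = 150$.
`phase_trace()` therefore fits the line through **per-modulation-cycle
means**: for any trace periodic at the modulation frequency over integer
cycles the cycle means are constant, so the fitted slope is exactly
zero, while a constant plus linear ramp is still removed exactly. When
the samples-per-cycle count is not an integer the code falls back to the
full-sample least-squares line. With the default timing (150 frames at
30 Hz; 0.2 Hz resolution) the 1 Hz modulation falls exactly on DFT
bin 5, and the noiseless round trip

```
measure_stack(simulate_stack(hb))  ==  phase_amplitude(hb) * waveform_fundamental()
```

holds to machine precision. `waveform_fundamental()` is the fundamental
of the modulation waveform *as sampled by the acquisition*; for the
ideal square drive it differs from the continuous-time $2/\pi$ by the
discrete edge correction ($1/(15 \sin(\pi/30)) \approx 0.6379$ vs
$0.6366$ at 30 Hz), which is why tests compare against the realized
fundamental and treat $2/\pi$ as approximate.

## Calibration

`fit_hill()` fits the four-parameter Hill law
$s(\mathrm{Hb}) = s_0 + s_{\max} \mathrm{Hb}^h/(k^h + \mathrm{Hb}^h)$ to
per-specimen replicate means, weighted by replicate count — matching how
calibration data are reported (per-specimen means with confidence
intervals). The baseline $s_0$ is included because real blanks read
nonzero. Optimisation is bounded Levenberg–Marquardt (all parameters
positive, `ftol = ptol = 1e-10`, up to 10⁴ evaluations) from a
deterministic, scale-free start ($s_0$ = min mean, $s_{\max}$ = range,
$k$ = concentration at half-range by interpolation, $h = 1$), so
identical tables give identical fits. $R^2$ is computed against the
replicate means with the same weights. After every fit the predicted
curve is checked numerically for monotonicity (analytic for positive
parameters, asserted anyway), and a vanishing fitted span is flagged as
degenerate rather than silently inverted.

`invert_hill()` uses the closed form
$\mathrm{Hb} = k\,((s - s_0)/(s_0 + s_{\max} - s))^{1/h}$. Signals at or
below baseline clamp to 0 g/dL and signals beyond 99.9% of the span
clamp to the corresponding ceiling concentration; both cases are
reported in a `censored` column, never silently.

## Analytical performance

* **LoB** is the plain arithmetic mean of blank replicate measurements —
  the rule used by the evaluation this package models, which differs
  from the standard CLSI `mean + 1.645 SD`; the standard rule is
  available via `limit_of_blank(..., method = "mean_plus_1.645sd")`.
* **LoD** is `LoB + 1.645 * SD` of a low-concentration sample's
  replicates (sample SD, $n-1$).
* **LoQ** scans *adjacent* level pairs of a dilution ladder for the pair
  whose mean CV is closest to the 20% target (ties resolve to the lower
  pair) and averages the pair's **nominal** (reference-analyzer)
  concentrations. Nominal rather than measured means reproduce the
  published worked example exactly ((0.0950 + 0.1188)/2 = 0.1069 g/dL);
  measured means would give 0.1053.
* **Precision** follows the usual intra/inter design: single-run
  mean/SD/CV for intra-assay; for inter-assay (equal replicates across
  ≥ 2 days) the SD is the total $n-1$ SD over all values, capturing
  within-day and between-day variability in one number. Published
  precision tables round means, SDs and CVs independently and are
  internally inconsistent at the printed precision, so tests assert the
  formula identities on computed values, not printed ones.

## Method comparison

`passing_bablok()` implements the classical nonparametric estimator:
all $\binom{n}{2}$ pairwise slopes excluding undefined ones
($x_i = x_j$) and slopes exactly $-1$; the estimate is the median
shifted by $K$ = #(slopes < $-1$) ranks, which makes the estimator
symmetric in the two methods. CIs use the rank offsets
$M_1 = \lceil (N - C)/2 \rceil$, $M_2 = N - M_1 + 1$ with
$C = z\sqrt{n(n-1)(2n+5)/18}$; the intercept is
$\mathrm{median}(y - bx)$ with CI bounds evaluated at the slope CI
bounds. Exact scale equivariance and slope reciprocity under swapping
hold on all-positive-slope data (the rank offset is tied to the $-1$
boundary) and are tested there; the estimator is verified against an
independently written brute-force enumerator on 100 random instances.

`bland_altman()` fixes the difference orientation as device − reference
and the LOA multiplier at 1.96; the bias CI is
$\pm 1.96\,\mathrm{SD}/\sqrt{n}$ and each LOA CI uses the large-sample
$\pm 1.96\,\mathrm{SD}\sqrt{3/n}$ approximation. Published LOA figures
from the modelled evaluation differ in the fourth decimal from
bias ± 1.96 × printed SD (rounding), so they are not used as exact
oracles. `within_threshold_fraction()` reports the percentage of pairs
within a clinical threshold (default 1.0 g/dL), boundary inclusive, to
one decimal.

## Anemia screening

`classify_anemia()` applies the WHO adult cutoffs with a *strict*
inequality — [Hb] below 13.0 g/dL (males) or 12.0 g/dL (females) is
anemic; values exactly at the cutoff are not. Cutoffs are overridable
for other populations, but age-/race-specific tables are out of scope.
`evaluate_anemia()` treats the reference classification as ground truth
and reports confusion counts with sensitivity, specificity and accuracy
per sex stratum and pooled (2 d.p.). Zero-denominator ratios are
reported as `NA`, never as 0 or 100.

## Numerical choices and degenerate inputs

* Fringe search band defaults to bins 2 … W/4; DC is always excluded,
  and profiles are mean-subtracted before the spatial DFT to suppress DC
  leakage. Argmax ties resolve to the lowest bin.
* A fringe coefficient below `1e-12 * W * max(|profile|)` raises a
  degenerate-signal error (pure-DC or all-zero frames cannot yield a
  phase).
* A modulation frequency off the DFT grid warns and uses the nearest
  bin; at or above Nyquist it is an error.
* Stacks are validated on construction: consistent dimensions,
  non-negative intensities, frame count = `round(frame_rate * duration)`.
* Seeded simulation never perturbs the caller's RNG stream, and derived
  sub-seeds stay below $2^{31}$.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run deliberately compact
studies chosen to exercise every code path with stable statistics: a
16-level × 10-replicate calibration (the published design), 60-replicate
blank and low-concentration arms, a 5-level × 10-replicate LoQ ladder,
5 × 5 precision runs, and clinical comparison cohorts of 100–250
simulated specimens at 512 × 64 px. These sizes give sub-percent Monte
Carlo noise on the reported statistics while keeping a full run in the
minutes range on a single core.

## Known limitations

* The simulator's noise floor reflects detector noise only; absolute
  LoB/LoD/LoQ values from simulation are optimistic relative to any
  physical instrument.
* Single-bin phase tracking assumes a dominant fringe frequency; no
  sub-bin interpolation or 2-D fringe analysis is attempted.
* Phase excursions above $\pi$ between consecutive frames would defeat
  temporal unwrapping; defaults keep well clear of this.
* The Hill parameterisation (4-parameter, replicate-mean weighting) is a
  documented choice; other parameterisations fit the same data
  comparably and invert differently near saturation.
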