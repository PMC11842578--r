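---
title: "Models and methods behind embryoject"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryoject}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoject)
```

`embryoject` simulates the computational core of a robot-assisted
zebrafish-embryo microinjection rig: a four-fibre FBG force sensor on the
injection needle, its least-squares calibration, the micromechanics of
holding an embryo at a suction port, PD-controlled transport and puncture
with force-jump detection, and batch performance accounting. This
vignette records the models, the parameter choices and their rationale,
the numerical conventions, and the limits of what the simulator can show.

## Sensor model and units

The sensor abstraction is deliberately linear: Bragg wavelength
$\lambda = 2N\Lambda$, shift
$\Delta\lambda = k_\varepsilon \varepsilon + k_{\Delta T}\Delta T$, and
cantilever bending strain $\varepsilon = F d \gamma / (EI)$ at the
grating. No reflection-spectrum or apodisation physics is modelled; the
package works entirely at the level of per-fibre wavelength shifts.

Wavelength shifts are in nm and forces in mN throughout. The decoding
matrices therefore carry mN/nm; this convention matches a sensor
calibrated over a 0–10 mN range, where the largest decoding coefficients
are a few tenths of a mN per nm.

Fibres are indexed 1–4 at 90° increments counter-clockwise viewed from
the needle tip, with fibre 1 on +X. Nothing in the decoding depends on
this convention, but the physics-based forward model
(`physical_forward_matrix()`) uses it to project a transverse force onto
each fibre's bending plane with cosine weights — the natural choice for
an orthogonal four-fibre layout, though any fixed rotation of it would
serve equally.

Common-mode rejection is defined on exactly three fibres (the mean of
three shifts is subtracted), while the axial decoder uses all four raw
shifts. Which three fibres feed the transverse path is a free choice; the
package defaults to fibres 1–3 and records the subset in the calibration
model so a refit with another subset is self-describing.

A consequence worth noting: the reference transverse matrix has rows that
sum to zero, so the transverse output is exactly invariant to any common
shift (temperature, axial strain). The reference axial row sums to 0.230,
so axial decoding is *not* temperature-free — a real property of
four-fibre axial sensing that the simulator preserves.

## Calibration: sweep design and fitting route

The synthetic calibration sweep applies loads at pitch
$\alpha \in \pm\{30°,45°,\ldots,90°\}$ and roll
$\beta \in \{0°,15°,\ldots,90°\}$, decomposed as
$(F_X,F_Y,F_Z) = F_P(\sin\alpha\cos\beta,\ \sin\alpha\sin\beta,\ \cos\alpha)$.
The third component is read as $F_P\cos\alpha$, the only reading that
preserves $\|F\| = F_P$ for all angles (an exact identity the tests
check). Five load magnitudes $\{2,4,6,8,10\}$ mN complete the default
grid: $10 \times 7 \times 5 = 350$ samples. The five-level split of the
0–10 mN range is a design choice — the angle grids and total are fixed by
the rig protocol being emulated, and five evenly spaced levels is the
natural way to reach that total; it is configurable in
`calibration_grid()`.

Fitting proceeds forward-first: the $4\times3$ sensitivity matrix $G$
(shifts per unit force) is estimated by ordinary least squares of the
recorded shifts on the *known* applied forces, and the decoders are then
Moore–Penrose pseudoinverses — the axial row is row 3 of $G^+$, and the
transverse block solves $C\,(M G) = [I_2\ 0]$ in minimum norm, where $M$
is the centring/selection operator. The reason is identifiability: pure
force loading excites only a 3-dimensional subspace of the 4-dimensional
shift space, so a direct regression of $F_Z$ on the four noisy shifts has
one direction constrained only by noise and its coefficients are
unstable. The forward regression has exact regressors (the designed
loads), is full rank by construction, and collapses to the same exact
answer on noiseless data; with 0.01 nm read noise over 350 samples it
recovers every reference coefficient to well under 1 %. Both decoders'
no-intercept structure reflects the homogeneous linear maps; no
regularisation is applied.

Fit quality is reported as through-origin slopes of decoded versus true
force per axis (slope 1 = perfect), mean absolute error per axis, and
residuals binned by $|F_\text{true}|$ in ten 1 mN bins over 0–10 mN.
Binning on the magnitude keeps ten bins at 1 mN intervals over the
calibrated range; the report is invariant to sample order.

## Holding micromechanics

All closed forms take geometry in µm and densities in g/cm³ and convert
to SI internally; outputs are N, Pa and N·m. For the default embryo
(R = 500 µm, ρc = 2.18 g/cm³) in water (ρf = 1.0 g/cm³, g = 10 m/s²)
with a 375 µm port:

* net weight $(4/3)\pi R^3 \Delta\rho g = 6.178\times10^{-6}$ N;
* contact offset $L = \sqrt{R^2 - R_H^2} = 330.72$ µm;
* seating angle $\theta = \arccos(R_H/R) = 41.41°$ — this convention is
  chosen because it is the one consistent with the offset formula
  ($L = R\sin\theta$) and reproduces the worked 41.41°;
* minimum drag $F_N\tan\theta = 5.45\times10^{-6}$ N;
* critical pressure: gravity term
  $(4/3)\Delta\rho (R/R_H)^3 g L = 12.33$ Pa, plus the wetting term
  $4\sigma\cos\beta/(2R_H)$.

Figures sometimes quoted for this rig configuration
($F_D \approx 3.68\times10^{-6}$ N, $P_C \approx 549.93$ Pa) are **not**
reproducible from these closed forms with the parameters above: the drag
value is inconsistent with $F_N\tan\theta$ at 41.41°, and the pressure
total requires wetting parameters that are not stated. The package
implements the equations literally, reports its own values, and leaves
$\sigma$ and the contact angle explicit rather than back-solving for
whatever values would force agreement. Defaults $\sigma = 0.072$ N/m and
contact angle 0° describe clean water against air and are clearly
defaults, not measurements. The moment balance
$M_{F_B} + M_{F_N} + M_G + M_{F_H} = 0$ closes to machine precision at
the gravity-term critical pressure with $M_{F_N}=0$ (detachment), which
the tests assert at 1e-12 relative tolerance.

The embryo density of 2.18 g/cm³ is taken as given even though it is
high for embryos generally; it only scales the (tiny) gravity terms.

## Control, puncture schedule and detection

The PD law $u = K_p e + K_d \dot e$ uses a backward difference on the
sampled error and saturates at a configurable output limit (default
2×10⁴ pulse units) because real pump drivers do. The transport plant is
the simplest dynamics that make a PD loop meaningful: commanded velocity
$g\,u$ reached with a first-order lag (τ = 0.1 s), position integrating
velocity. Default gains $K_p = 2$, $K_d = 0.05$ put the continuous-time
closed loop firmly overdamped (poles ≈ −2.5 and −8 s⁻¹), settling a 1 mm
step below 5 µm in ≈ 2.1 s with no overshoot, and remain stable at the
15 Hz vision update rate. The loop runs measurement-synchronous: control
updates at the vision rate with zero-order hold, the plant integrates at
10 ms substeps.

The two-speed schedule advances at `v_fast` (200 µm/s) until the rupture
position and `v_slow` (60 µm/s) toward the yolk centre. The two intervals
share the rupture position; the fast interval is closed there and the
slow one open — the speed drops only strictly after rupture, matching a
controller that switches on the detected event.

The rupture detector tracks the running maximum of the total force and
fires when (a) that maximum has exceeded `min_peak` and (b) the current
sample has fallen at least `min_drop_frac` of it within `window` samples
of the peak. Defaults 1 mN / 50 % / 50 samples are chosen from the
morphology of measured punctures — a ≈ 3.9 mN peak collapsing almost
instantly — and sit far from both failure modes: at 0.05 mN trace noise
the armed threshold is 20 noise SDs (no false positives over thousands of
noise-only traces) while the collapse spans ≥ 95 % of the peak (recall
≥ 99 % within ±25 samples of ground truth). The event's rupture index is
the running-peak sample (the rupture instant); the detection index, a few
samples later, is where the drop criterion was met. Baselines are medians
of the pre-rise and post-drop segments.

## The synthetic-data generators

The generators define the simulated study conditions; their defaults are
fixed, not tuning knobs.

* **Calibration sweeps** use the consistent forward matrix of the
  reference calibration (minimum-norm right inverse of the stacked
  decoders) plus i.i.d. Gaussian read noise (default 0.01 nm). They
  emulate load application exactly; they do not emulate hysteresis,
  creep, temperature drift during the sweep, or fibre misalignment.
* **Puncture traces** follow the canonical morphology at the 1000 Hz
  decoder rate: baseline, linear force rise with indentation
  (stiffness 0.02 mN/µm, so the default 3.9 mN rupture force implies
  ≈ 195 µm of indentation), collapse within ≤ 5 samples, residual
  post-rupture baseline (0.1 mN) during the slow advance. The peak is
  split 3.1 : 2.4 between transverse and axial channels (the prototype's
  measured decomposition) so component norms equal the total. Real
  traces show viscoelastic relaxation, partial punctures and chorion
  slippage; the generator does not.
* **Perception** is truth plus isotropic Gaussian noise — a parametric
  stand-in for the object-detection and keypoint networks of a real rig,
  with none of their failure modes (occlusion, misdetection, lighting).
  The tip placement error is the magnitude of a 2-D Gaussian, i.e.
  Rayleigh: with per-axis SD $4.95/\sqrt{\pi/2} = 3.95$ µm its mean is
  4.95 µm and its 99.9th percentile ≈ 14.7 µm, jointly matching the
  observed mean error and the ≈ 0–15 µm observed range. (A 1-D
  half-normal with the same mean would put the 99.9th percentile at
  20.4 µm, outside that range — one reason to prefer the 2-D model, the
  other being that tip position genuinely lives in the image plane.)
* **Survival** is Bernoulli with a logistic link on tip placement error,
  $p = \mathrm{logit}^{-1}(2.4523 - 0.15\,e)$; the slope is a plausible
  sensitivity (≈ 3 pp per µm near the mean) and the intercept is
  calibrated once so the error-averaged survival is 84 %, the prototype's
  observed batch rate. A fixed-probability mode exists for controlled
  experiments. Survival here is an outcome model, not a mechanism.
* **Phase timings.** Fixed overheads (feed 3 s, hold 2 s, inject 2.5 s,
  recycle 2.5 s) plus the simulated transport (≈ 2.1 s) and puncture
  (≈ 7.7 s) phases sum to ≈ 19.9 s per cell, calibrated once to the
  prototype's ≈ 20 s/cell operating point. Per-phase durations are a
  modelling choice; only the total is anchored.

Randomness is scoped: every generator takes a `seed` and restores the
global RNG state. Batches derive per-cell seeds as
`root + 1000003·i (mod 2³¹−1)` and each cycle derives its four phase
streams with stride 104729, so streams never collide across cells and
batches are order-independent and byte-reproducible
(`batch_json()` serialises at full precision).

## Batch metrics and conventions

Efficiency is $T_{tim}/N_{tot}$ s/cell and puncture rate
$N_{puc}/N_{tot}\times100\%$. The survival rate divides by the number
*punctured* by default — the stated definition — but comparative tables
for manual injection are often computed against the number *attempted*;
`survival_rate(..., denominator = "total")` reproduces that convention
(e.g. 33/50 = 66 % versus 33/46 = 71.7 %). Neither is silently
corrected; the caller chooses.

Positioning-error summaries group samples consecutively (default groups
of 10) and report type-7 (linear-interpolation) quartiles, the R default,
with outliers by the 1.5×IQR fence; no quartile convention is canonical
for such summaries, so the report states one.

Reported rates are kept at full precision in code and JSON; rounding to
one decimal happens only in printed displays.

## Problem sizes and test design

The test suite exercises the full 350-sample calibration, 1,000
signal and 1,000 noise-only traces for the detector, a deterministic
1 mm transport step, and 100-cell reproducibility batches, plus smaller
property loops (randomised linearity, conservation and invariance
checks); it completes in under a minute. The acceptance script re-runs
the same pipelines from scratch and additionally estimates the survival
rate over five independent 100-cell batches (500 cycles), since a single
100-cell batch has a binomial SD of ≈ 4 percentage points.

## Known limitations

* No fluid dynamics: channel flow, drag on a moving embryo and the
  spatial geometry of the chip are not simulated; "drag" is only the
  static mobilisation threshold.
* No optical detail: the FBG model is linear in strain and temperature.
* The transport plant is first-order by construction, so controller
  conclusions transfer only qualitatively to rigs with richer dynamics.
* Perception and survival are parametric stubs; passing their tests
  shows the pipeline logic is sound, not that real detection networks or
  real embryos behave this way.
* The quoted-but-underivable drag and holding-pressure figures discussed
  above remain documented discrepancies, not reproduced numbers.
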