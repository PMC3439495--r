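---
title: "Temporal characterization of LCD luminance signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal characterization of LCD luminance signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdtempo)
```

## The signal model

A photometer pointed at an LCD test patch records

$$L(t) = L_{\max}\, T(t)\, B(t)\, \bigl(1 + d\, r(t)\bigr) + \varepsilon(t),$$

where $T(t) \in [0,1]$ is the voltage-driven transparency of the liquid
crystal, $B(t)$ the backlight modulation (mean 1), $r(t)$ a small
refresh-locked component ("frame response") of relative depth $d$, and
$\varepsilon$ sensor noise.  The package's estimators all operate on this
multiplicative structure; its simulator (`display_model()`,
`simulate_transition()`, `simulate_static()`) generates it with known
ground truth.

Key modeling choices in the simulator:

* **LC kinetics** are first-order exponentials with separate rise and
  fall time constants (`tau_rise_ms`, `tau_fall_ms`, defaults 8 and
  4 ms).  Field-induced alignment is voltage-accelerated while
  relaxation is elastic, so asymmetry is the rule; first-order capture
  is sufficient to exercise every downstream estimator, though real
  panels can deviate from single-exponential shapes.
* **Backlight** PWM is a duty-cycled square wave with raised-cosine edge
  smoothing (0.2 ms, so edges span a couple of samples at 10 kHz) that
  is *area-sampled* over each sample interval: a photometer integrates
  over its aperture, and point sampling would quantize pulse edges to
  whole samples and alias pulse area into spurious low-frequency ripple.
* **Blinking (motion-picture) backlights** default to flashing during
  the *last* `duty_cycle` fraction of each frame.  Implementations do
  this so the liquid crystal has settled before it is illuminated;
  flashing at frame start would illuminate the mid-transition state and
  worsen, not improve, motion rendition (see the blur section).
* **Frame response** is modeled as a sawtooth at the refresh rate.  Only
  its spectral signature matters to the pipeline, and measurements
  constrain its amplitude (about 2% of the mean on the worst panels) but
  not its shape.
* **Overdrive (DCC) overshoot** is an additive excess pulse
  $(1-e^{-u/\tau})\,e^{-u/\delta}$ scaled (numerically) so the realized
  waveform peak exceeds the target by exactly `overshoot_fraction` of
  the amplitude; the decay default $\delta$ spans about three frames,
  matching overshoot transients observed on badly tuned monitors.
  Luminance stepping clamps each frame at configured plateau fractions;
  pre-tilt (DCC II) advances the effective rising onset by one frame.
* **Noise** is zero-mean Gaussian and seeded; instrument spec sheets
  quote a noise-equivalent power but not a distribution.

Default acquisition is 10,000 samples over 1 s at a 60 Hz refresh — a
standard optical-transient-recorder configuration — and all simulations
in the tests and the acceptance script use these values unless the
check itself concerns another refresh rate (e.g. the 75 Hz
frame-response control).

## Decomposition: the division method with dynamical filtering

Filtering the backlight out of a transition recording with a fixed
low-pass, as display-metrology standards suggest, biases response times
whenever the ripple and the transition share bandwidth.  The division
method instead measures the backlight separately and removes it
multiplicatively:

1. **Template estimation** (`estimate_backlight_template()`): from a
   static recording, the dominant frequency is found on the periodogram
   and refined by maximizing the Gaussian-tapered projection onto a
   complex exponential (sub-bin accuracy is essential: folding a
   hundred periods with a half-bin frequency error smears the template
   edges).  All samples are folded by phase into bins of roughly a
   quarter sample and averaged; empty bins are filled by periodic
   interpolation.
2. **Phase alignment** (`align_phase()`): the lag follows in closed form
   from the argument difference between the template fundamental and the
   trace ripple fundamental (the ripple is isolated by dividing out a
   one-period moving average, which cancels the transition trend).  PWM
   harmonics are phase-locked to the fundamental, so the fundamental
   determines the alignment; the estimator is unbiased and invariant to
   slow trends.
3. **Division with dynamical filtering** (`divide_out_backlight()`):
   the trace is divided by the phase-shifted tiled template.  Samples
   whose template value is below 5% of the mean (deep-PWM off phases) or
   which straddle a steep template edge (where a sub-sample phase error
   costs a full step height) are masked and bridged with a cubic
   Hermite whose endpoint slopes come from the flanking samples only — a
   straight line across a gap containing a transition corner would
   leave the plateau early.  Residual ripple is then suppressed by a
   one-period moving average blended in proportion to the local slope:
   a boxcar of exactly one period nulls the fundamental and every
   harmonic at once, so plateaus come out clean, while fast transitions
   pass through unfiltered and unbiased.

On synthetic product signals (PWM 80–250 Hz, modulation depth up to
0.8, random duty cycles and phases, noise off) the recovered transition
stays within 2% of the transition amplitude of the generator's
$T(t)$, and response times measured on it match $\tau \ln 9$ within a
fraction of a sample interval; the acceptance script recomputes both
bounds at every run.

## Levels and response times

**Steady levels** are estimated as the mode of a Gaussian kernel density
over the plateau portion (last 50% of each half-period; the first half
is excluded to keep transition tails out) with Terrell's oversmoothed
bandwidth $h = 1.144\,\hat\sigma\,n^{-1/5}$.  The mode is the right
location summary here: residual duty-cycled ripple dwells
asymmetrically, so a mean would be biased toward the longer dwell.

**ISO-style response time** is the time between the last crossing of the
10% amplitude level before the sustained rise and the first sustained
crossing of the 90% level, linearly interpolated between samples.
"Sustained" means remaining beyond threshold for at least 0.5 ms, which
makes the crossing robust to residual ripple.  A second pass re-measures
on a signal smoothed over 5% of the first-pass RT: crossing jitter
scales as noise divided by slope and the slope at the 90% level of a
slow exponential is shallow, while the smoothing bias is
$O((0.05\,\mathrm{RT})^2)$ and the window degenerates to nothing for
fast transitions (a step still measures below one sample interval).

**Overshoot-extended RT** measures from the 10% crossing to the *final*
crossing of the 110% level on the post-peak decay.  Falling
undershoots are mirrored symmetrically (the extended metric is defined
for overshoot; the mirror is this package's convention).  The detectors
for stepping (per-frame medians over the steady 30–95% of each frame;
a plateau must be flat both absolutely and relative to the jump that
ends it, since a smooth exponential changes within a frame about as
much as between frames), pre-tilt advance (first sustained departure
from baseline + 5% amplitude, rounded to whole frames) and repetition
instability (max/min RT ratio above 1.5 — halfway between stable
repetitions and the doubling seen in the field) each recover their
generator ground truth in the test suite.

## Spectral diagnostics

PSDs are periodograms of the mean-normalized signal with a Gaussian
taper (taper SD of n/8; the family is standard for this purpose, the
width is this package's choice).  The density normalization satisfies
$\sum P_k \Delta f = $ taper-weighted variance, asserted as a Parseval
check in the tests.

*Dominant frequency* is the frequency of maximal power in a band
(default 20–500 Hz, excluding DC/drift and covering all plausible
backlight fundamentals), with two pragmatic refinements over the
literal single-bin argmax:

* line power is compared over a 5-bin neighborhood before the raw
  argmax within the winning neighborhood is returned — a fundamental
  falling mid-bin splits its power across bins (scalloping) and could
  otherwise lose to a better-centered harmonic;
* signals whose mean-normalized variance falls below $10^{-6}$
  (modulation SD of 0.1% of the mean, the instrument noise-floor scale)
  report no dominant frequency at all.

*Frame response* is declared when the bin nearest the refresh rate is a
local maximum (±3 bins) of the lightly smoothed PSD and exceeds five
times the local median, with an absolute floor of $10^{-8}$ on the
density.  The smoothing and the floor exist because implementation
proved the bare rule wrong: single periodogram bins of noise are
exponentially distributed and false-alarm at a few times the median,
and sampling beats between a strong PWM line and the sample grid can
place genuine but minuscule lines exactly at the refresh bin, four
orders of magnitude below a real 2% frame response.

*Phase locking* classifies a backlight as locked when its fundamental is
within 0.5 Hz (half a periodogram bin at the 1 s reference recording) of
an integer multiple of the refresh rate.

## Visible motion blur

For an observer tracking an edge moving at $v$ pixels/frame, the
sample-and-hold luminance course paints itself across the retina.  The
chain in `vmb_jnd()`:

1. **METP** — the transition convolved with a rectangular window exactly
   one frame wide (fractional-sample width; an integer window would
   leave spurious ripple when averaging frame-periodic blinking
   backlights).  An ideal step becomes a one-frame linear ramp — the
   hold-blur floor.
2. **Time to space** — $\Delta x = v f_r / (R f_s)$ degrees per sample
   ($R$ pixels/degree, $f_r$ refresh, $f_s$ sampling rate): at
   16 px/frame, 60 Hz, 10 kHz and 40 px/deg one frame maps to 0.4°.
3. **Centering** — a cumulative Gaussian is least-squares fitted and the
   profile re-windowed symmetrically about the fitted midpoint (50%
   crossing as a flagged fallback).
4. **Contrast and masking** — the profile (normalized by its upper
   level, floored at $10^{-3}$: panels leak, black is never zero) is
   convolved with truncated Gaussian center and surround kernels whose
   normalization factors solve the erf-based constraint that each
   kernel integrate to its scaling constant over its ±4σ support; local
   contrast is (center − surround)/surround, a ratio invariant to
   absolute luminance; contrast energy is the squared contrast pooled
   by the masking kernel; masked contrast divides by
   $\sqrt{c_t^2 + E}$.
5. **JND** — $\mathrm{JND} = s\,\bigl(\int |\Delta C_m|^p\,dx\bigr)^{1/p}$
   between the signal's masked contrast and that of an ideal step edge,
   minimized over every candidate edge location (every inter-sample
   position, evaluated exhaustively; a fast shifted-base scan is
   re-checked from scratch at the best candidates so the reported
   minimum is exact).  A profile identical to an ideal edge scores 0;
   values above 1 predict visible blur.

The kernel widths (0.03° center, 0.18° surround, 0.10° masking pool),
scaling constants, masking threshold (0.02) and the two JND parameters
($s = 50$, $p = 2$) are free model constants shipped in
`inst/extdata/blur-model-default.json`.  They are package-chosen,
physiologically plausible values — a foveal midget-scale center, a
surround about six times wider — not a calibrated fit to any
psychophysical dataset; absolute JND levels should be read as relative
comparisons between conditions unless the user substitutes calibrated
constants via `blur_params_from_json()`.  The model's *ordinal*
behavior is what the tests pin down: zero for an ideal edge,
monotonicity in the LC time constant and in speed, and the
motion-picture-mode comparison below.

**Blinking backlights** concentrate light emission into a short flash
per frame, shortening the effective hold time.  With the flash late in
the frame (the simulator default) and an LC that settles within about
half a frame, the model predicts substantially less blur than a
constant backlight (ratio ≈ 0.3 at τ = 4 ms in the acceptance run).
For τ approaching a full frame the flash illuminates a mid-transition
state and the advantage disappears — a physically expected limitation
worth keeping in mind when evaluating motion-picture modes on slow
panels.

## What the synthetic conditions do and do not show

The simulator reproduces the *structure* of LCD photometric output —
multiplicative backlight, first-order asymmetric LC kinetics, DCC
artifacts, refresh-locked components, sensor noise — under the reference
acquisition (1 s at 10 kHz, 60 Hz refresh, ISO five-level gray grid,
10 frames per level).  Passing tests therefore demonstrate estimator
correctness on signals with that structure and known ground truth.  They
do not certify behavior on phenomena the generator does not model:
non-exponential LC shapes, temperature drift of the backlight during
warm-up, spatially inhomogeneous backlights, local dimming, subpixel
inversion, or viewing-angle effects.  Real monitors should be
characterized individually; this package is the instrument for doing so,
and its report (`run_characterization()`) is deterministic under a fixed
seed so such characterizations are reproducible.

## Numerical choices and degenerate inputs

* Periodogram bin width at the reference recording is 1 Hz; frequency
  refinement works within ±1 bin of the coarse peak.
* Division masks template values below 5% of the template mean and
  template-edge zones (gradient above 4% of the template range, widened
  by two bins); masked runs touching the trace ends are extrapolated
  linearly from the nearest twelve clean samples.
* KDE level estimation falls back to the median when the plateau is
  numerically constant (zero bandwidth is not meaningful).
* `response_time()` refuses signals that never cross both thresholds;
  `overshoot_response_time()` reports the peak fraction but no extended
  RT when the peak stays below 110%; `vmb_jnd()` warns and returns 0 on
  zero-amplitude transitions.
* Tie-breaks: equal spectral peaks resolve to the lower frequency;
  `which.min`/`which.max` conventions make every reported location
  deterministic.

## Interfaces

All functionality is exposed as plain R functions over
`luminance_trace` objects; `read_trace()`/`write_trace()` provide a
plain-text exchange format (commented `key=value` header, one sample per
line, full double precision round-trip), and `report_to_json()`
serializes characterization reports.  Scripted use is a matter of
calling these functions from `Rscript`, as `scripts/acceptance.R` does.
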