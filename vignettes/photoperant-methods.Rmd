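---
title: "Methods: simulating and analyzing cued-operant photometry sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing cued-operant photometry sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoperant)
```

## The task and what the pipeline measures

`photoperant` analyzes sessions of a three-phase appetitive conditioning
task run in an operant box with a lick spout, a lever, and a tone
generator, recorded together with two-channel fiber photometry of a
genetically encoded calcium indicator:

* **Phase I (classical conditioning).** A 5 s tone plays, followed by a
  15 s intertrial interval. Licks during the tone are rewarded; licks
  outside it are not. One trial per tone, 5–10 trials per test, two tests
  per day, 8 days.
* **Phase II (operant conditioning).** No tone. A lever press opens the
  spout for 5 s; the press itself starts a 10 s trial, and presses during
  an open trial belong to that trial rather than starting a new one. Tests
  are 5 min of free operant responding, 6 days.
* **Phase III (cued operant conditioning).** Only a press *during* the
  tone opens the spout (again for 5 s). One trial per tone, 5 days.

From the behavioral event log the pipeline computes per-trial outcome
classes (**rewarded** — at least one lick coinciding with a reward
delivery; **non-rewarded** — licks but none rewarded; **no-licks** /
**no-presses** — the qualifying action never happened), latencies (first
lick from trial start, first press, press-to-first-lick) and counts, and
aggregates them per test, per day, and across animals (SEM over animals).
From the photometry it computes a normalized, artifact-corrected calcium
trace, detects discrete transients, attributes them to lever presses and
lick-bout onsets, and quantifies event-aligned activity in peri-event
matrices.

All timestamps live on one master clock in seconds with $t = 0$ at session
start; the rig's sync pulse is represented as an explicit offset applied
once when a recording is loaded.

## Signal model

### Normalization

Each raw channel is normalized as

$$ \frac{\Delta F}{F}(t) \;=\; \frac{F(t) - F_0(t)}{F_0(t)}, $$

where $F_0(t)$ is a **centered rolling mean** of the raw trace over a
window of 30 s by default, shrinking symmetrically at the recording edges.
The window length is the one genuinely free parameter of the
normalization: it must be long relative to indicator transients (about
1 s) so they are not absorbed into the baseline, and short relative to
photobleaching so slow decay divides out. 30 s satisfies both by more
than an order of magnitude and the results are insensitive to factor-of-two
changes; it is configurable everywhere (`window_s`).

The ratio form makes the output invariant to rescaling the raw trace by
any positive constant (LED power, detector gain), which is tested as a
property.

### Isosbestic correction

The 405 nm excitation channel is calcium-independent, so motion artifacts
and shared background appear in it with the same relative amplitude as in
the 465 nm channel while calcium transients do not. Subtraction is
performed **after** normalization, at unit gain:
$\mathrm{d}F(t) = \Delta F/F_{465}(t) - \Delta F/F_{405}(t)$. With matched
channel gains this cancels a shared artifact exactly in the noise-free
case; for rigs with unequal artifact gains a least-squares-scaled
subtraction is available (`fit_405 = TRUE`).

### Peak events

A *peak event* is one contiguous excursion of the corrected trace above a
threshold, reported at the excursion maximum. The threshold is
`threshold_sd` (default 2) times a session-wide scale estimate. Two
deliberate choices here:

* **The scale estimate defaults to the robust $1.4826 \times
  \mathrm{MAD}$** of the corrected trace rather than its plain standard
  deviation (`sd_method = "sd"` restores the latter). A threshold meant to
  reference the noise floor must not be inflated by the very transients
  being detected; in transient-dense sessions the plain session SD is
  dominated by signal, and a "2 SD" cut then silently rises above the
  smaller transient class. The MAD is essentially unaffected because
  transients occupy a small fraction of samples.
* **A 0.1 s boxcar low-pass is applied before thresholding** (`smooth_s`),
  and excursions shorter than 0.1 s (`min_width_s`) are rejected.
  Bandpass-limited sensor noise rarely stays above 2 robust SD for 10
  consecutive samples at 100 Hz, whereas indicator transients (decay time
  constants of hundreds of milliseconds) always do. Without the low-pass,
  noise riding on a transient's decay occasionally splits one excursion
  into several, creating spurious "shoulder" events. These two guards are
  what make a transient-free recording yield exactly zero peak events
  rather than the threshold crossings any Gaussian trace produces.

One caveat the excursion rule implies: raising the threshold removes peaks
monotonically only while excursions are unimodal. When two transients
overlap, a higher threshold can split their merged excursion at the saddle
and the event count briefly rises. The monotonicity property is therefore
only guaranteed (and only tested) for isolated transients.

### Linking peaks to behavior

Detected peaks are attributed to the behavioral instants the task model
cares about: the trial's opening lever press and each lick-bout onset (a
lick preceded by at least 1 s without licking — the bout threshold is
configurable; the source protocol speaks of "licking bouts" without
defining them). Events are visited chronologically and each claims the
nearest unclaimed peak within a 2 s window after it, matching the 2 s
quantification window used for cue-aligned amplitudes. Unlinked peaks are
kept with null links.

### Peri-event matrices

Rows are trials, columns a common grid over `[-pre_s, post_s)` around the
alignment event (tone onset, opening press, or first bout onset), filled
by nearest-sample lookup at the recording's own rate — no interpolation.
Rows whose window leaves the recording are flagged incomplete and padded
with `NA`, never extrapolated. Windowed amplitudes (e.g. "max peak within
the first 2 s of the tone") are per-row maxima over a half-open window;
all windows in the package are half-open `[start, end)`, so an event at
exactly the tone offset is outside the cue.

## The synthetic-session simulator

The simulator exists so that every stage of the analysis can be validated
against known ground truth; it is first-class, tested code.

**Virtual mouse.** The agent's expected action latency relaxes
exponentially over training days,
$\ell(d) = \ell_\infty + (\ell_1 - \ell_\infty)\, e^{-(d-1)/\tau}$
(defaults $\ell_1 = 6$ s, $\ell_\infty = 1$ s, $\tau = 1.5$ days), and its
probability of attempting the correct action rises on the same schedule
(0.3 → 0.9). Individual latencies are drawn log-normally around the
schedule with CV 0.3 — the protocol's published learning curves constrain
trends, not distributions, so a right-skewed positive law is the natural
choice. Licking is a regular 8 Hz train lasting 2 s; the press-to-lick
delay averages 3 s, comfortably inside the 5 s reward window while keeping
press- and lick-locked calcium events resolvable as separate excursions.
Disengaged cued trials may still contain an off-cue lick bout (probability
0.5), which is what produces non-rewarded trials. Because the behavioral
rules, not the agent's intent, decide rewards, ground-truth outcomes are
derived from the generated event stream itself.

**Generative photometry.** On a uniform grid (default 100 Hz; the source
acquisition rate is not stated, so it is configurable),

$$ F_{465}(t) = B_{465}\, e^{-t/\tau_b}\,\bigl(1 + s(t) + a(t)\bigr) +
   \varepsilon(t), \qquad
   F_{405}(t) = B_{405}\, e^{-t/\tau_b}\,\bigl(1 + g\,a(t)\bigr) +
   \varepsilon'(t), $$

where $s(t)$ sums double-exponential transient kernels
$(1-e^{-t/\tau_r})e^{-t/\tau_d}$ (rise 0.1 s, decay 0.8 s, fast-GCaMP
kinetics), **normalized to unit peak** so configured amplitudes are true
ΔF/F peak heights, placed at each ground-truth transient time — every
opening press and every lick-bout onset — with amplitude 0.06 on rewarded
and 0.02 on non-rewarded trials (a 3:1 contrast); a smooth negative dip of
0.02 during rewarded consumption reproduces the signal depression seen
while animals lick. $a(t)$ is a sparse train of sharp random-sign
deflections shared by both channels. Injecting the artifact
multiplicatively (in ΔF/F units on each channel's bleached baseline) is
what makes unit-gain subtraction cancel it exactly after ratio
normalization; an additive raw artifact with unequal channel baselines
could not cancel exactly, which would contradict the correction's own
design goal. Noise is additive white Gaussian at 0.2 % of baseline per
channel. Bleaching uses a 3000 s time constant.

**What the simulator does not emulate.** Hemodynamic or pH confounds,
indicator nonlinearity and saturation, spike-to-calcium convolution
structure, correlated (1/f) noise, lick-by-lick microstructure, posture-
dependent artifact coupling, and individual-animal parameter spread beyond
seed-to-seed sampling. Passing recovery tests on these synthetics
therefore demonstrates that the *pipeline's* transformations are correct
and calibrated — not that real recordings satisfy the generative
assumptions.

**Study-condition regimes.** Three canned regimes recur in the tests: the
default *learning* agent; an *inactive* agent (no actions — the
anesthesia-like flat-trace regime, in which the pipeline must find zero
peak events); and a *proficient* agent with latency and engagement at
asymptote from day 1, matching the cued-operant phase in which animals
arrive already trained and show flat behavioral curves. The proficient
regime matters for day-trend analyses: under a learning agent the
rewarded/non-rewarded mix shifts across days, so pooled linked-peak
amplitudes acquire a real upward trend even with constant per-class
generative amplitudes — a property of the mixture, not a detection bias.

## Numerical and edge-case choices

* Rolling means use an exact cumulative-sum formulation (verified against
  a nested-loop reference to $10^{-10}$ relative error) with shrinking
  windows at the edges; window widths are forced odd for symmetry.
* A non-positive rolling baseline (raw fluorescence must stay positive) is
  an error, as is a recording of fewer than two samples.
* "Rewarded lick" means a lick whose timestamp matches a reward delivery
  within 1 ms — the rig logs the two jointly — rather than re-deriving
  spout state, which is robust to truncated logs.
* Phase II's "latency to first press" is measured from the previous
  trial's end (or session start), since the press itself defines the trial
  start. Trials without a qualifying event carry `NA` latencies and are
  excluded from means, never zero-filled.
* Event timestamps are written at 0.1 ms resolution, making the
  text round trip lossless; identical seeds reproduce byte-identical
  files.
* Tone markers must alternate; an unmatched `tone_on` at end of file is
  auto-closed at the session end with a warning.
* Pose files use image-style coordinates (origin top-left, y downward);
  the distance-to-target and occupancy analyses are translation-invariant
  so the convention only matters for plotting. The calcium–distance
  correlation uses a circular-time-shift null rather than i.i.d.
  shuffling, preserving the autocorrelation of both series.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script validate on cohorts of 8
simulated mice (the published cohort size), 50 replayed sessions per phase
for contingency checking, 20 seeded sessions for transient recovery and
artifact-correlation statistics, and 1000 random arrays for the
normalization oracle. These sizes give stable statistics (hundreds of
trials and transients per estimate) while keeping the whole suite at a few
minutes on one core.

## Known limitations

* Unit-gain subtraction assumes matched channel artifact gains; the fitted
  mode is provided but not the default, mirroring the ambiguity in
  published practice.
* The excursion-based peak definition merges transients closer than the
  threshold-crossing width; closely spaced press/lick events can be
  reported as one event (the simulator's default 3 s separation avoids
  this regime).
* The behavioral agent has no satiation, motivation drift, or
  within-session learning; per-day schedules are the only nonstationarity.
* `aggregate_by_day` treats animals as the experimental unit (SEM over
  mice); it does not fit mixed models — its tidy outputs are intended as
  input for any downstream statistics package.
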