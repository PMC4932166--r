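---
title: "Methods: simulating and recognizing a dual-modality EOG/sEMG interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recognizing a dual-modality EOG/sEMG interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoemg)
```

## The problem and the signal model

People who have lost speech and limb control (late-stage ALS, muscular
dystrophy) often retain control of their eyes and of the muscles around
them. An electrode montage worn like goggles can pick up two kinds of
usable signal at once:

* the **electrooculogram (EOG)** — the corneo-retinal dipole potential,
  whose DC level tracks gaze angle and whose transients mark saccades; and
* the **facial surface EMG (sEMG)** — bursts produced by deliberate
  one-sided hard blinks or a jaw clench (bite).

With a *cross-channel* montage, each of the two EOG channels records a
mixture of the horizontal and vertical gaze components, with opposite
horizontal polarity. Writing the channel traces as

$$\mathrm{CH1}(t) = +h(t) + v(t) + d_1(t) + \varepsilon_1(t), \qquad
  \mathrm{CH2}(t) = -h(t) + v(t) + d_2(t) + \varepsilon_2(t),$$

the sum $\mathrm{CH1}+\mathrm{CH2}$ isolates the vertical component and
the difference $\mathrm{CH1}-\mathrm{CH2}$ the horizontal component
(`derive_vh()`, with `recover_channels()` its exact inverse). $d_i$ are
slow baseline drifts, the central nuisance of DC electrooculography, and
$\varepsilon_i$ measurement noise. The device streams six channels at
1 kHz: CH1/CH2 (DC EOG), CH3/CH4 (AC EOG: band-passed copies showing
onset/offset transients), CH5/CH6 (right- and left-side sEMG).

Five command classes are recognized: *right* and *left* eye movements
(EOG) and *right blink*, *left blink*, *bite* (sEMG). Involuntary
(normal) blinks must produce **no** output, and vertical eye movements
are detected but deliberately never emitted as commands, because vertical
EOG deflections resemble blink artifacts and most users cannot reliably
control upward saccades.

## The recognition procedure

### sEMG chain

Each sEMG channel is high-pass filtered at 66.7 Hz (removing electrode DC
and 60 Hz line interference), rectified, and averaged over a causal
window of $n = 50$ samples (`rectified_moving_average()`; during the
first $n-1$ samples the mean is taken over the available prefix so the
envelope does not start with a spurious ramp). Supra-threshold runs of at
least 50 ms become activity intervals; per-channel intervals closer than
the 50 ms `overlap_window` merge into episodes. The channel pattern
classifies the episode: CH5 only is a right blink, CH6 only a left blink,
both a bite. A bite or strong bilateral blink is collapsed into the
single `bite` class — nothing downstream distinguishes them.

### EOG chain with baseline renewal

The DC paths are low-pass filtered at 10 Hz; derived DC and AC traces
feed a per-sample state machine (`detect_saccades()`, compiled code since
it is inherently sequential):

1. DC and AC simultaneously exceed the direction threshold with
   consistent sign — the direction is decided and the event is emitted;
2. DC stays beyond threshold while AC settles back — the gaze is being
   held off-center;
3. an AC excursion of opposite sign marks the return to center;
4. both elements re-enter their baseline bands — the DC reference is
   updated and a 0.3 s refractory period begins.

Baseline drift is controlled by **renewal**: whenever the AC element has
been quiet and the sEMG inactive for `quiet_window` (0.5 s), the current
DC values are taken as the new front-gaze reference. With linear drift
rate $r$ and renewal guaranteed at least every $T$ seconds of quiet, the
DC offset error at any onset is at most $rT$; no false saccade can occur
while $rT$ stays below the DC threshold (verified empirically on
drift-only recordings in the test suite).

A **vertical gate** compares the changing ranges of the two derived
components at trigger time: only when the horizontal range strictly
exceeds the vertical one is a horizontal command emitted; ties and
vertical-dominant deflections are labeled `vertical` and suppressed.

### Integration and arbitration

`run_recognition()` gives sEMG priority: samples inside an episode (plus
a 0.1 s margin) are masked from EOG processing, and after each episode
the references are re-initialized — EOG decisions resume only after a
fresh renewal. This is what prevents a bite's large bilateral artifact
from doubling as a gaze command: on a constructed recording with a DC
excursion exactly concurrent with a bite burst, exactly one event (the
bite) is emitted.

## Calibration

Thresholds are per-user (`calibrate_thresholds()`). From a labeled
calibration session containing all five voluntary classes and normal
blinks, each sEMG channel gets

$$\theta = \max\left(\mu_\text{rest} + k\sigma_\text{rest},\;
  \tfrac{1}{2}(\max p_\text{normal} + \min p_\text{voluntary})\right),$$

with $k = 5$: clear of the noise floor, above every calibration normal
blink, below every voluntary burst. If the weakest voluntary peak does
not exceed the strongest normal-blink peak the calibration is infeasible
and says so. EOG DC/AC thresholds are set to 40% of the median per-event
excursion/transient peak of the labeled left/right saccades — the
fraction is a design choice (the thresholds are described only as
empirically set per user); 40% leaves headroom both against noise from
below and against weak saccades from above, and is exposed in the
calibration object rather than hard-coded downstream.

## What the generator emulates

`synthesize()` renders an action schedule into the six channels:

* saccades are plateau (step–hold–return) traces — linear 40 ms rise for
  horizontal, 60 ms for vertical (vertical saccades are slower and
  weaker: default amplitudes 1.0 vs 0.6 units);
* sEMG bursts are white noise band-limited above 66.7 Hz under a
  raised-cosine envelope with 50 ms tapers (0.3 s duration);
* normal blinks are weak bilateral bursts at 40% of the voluntary
  amplitude plus a small vertical EOG bump (half the vertical saccade
  amplitude) — visible to the vertical gate, below the sEMG thresholds;
* drift is a linear slope (0.02 units/s) plus an independent Gaussian
  random walk (0.01 units/√s) per DC channel; 60 Hz line interference
  (amplitude 0.05) is common-mode across channels; white noise
  (σ = 0.03) is independent per channel;
* the AC channels are produced by the modeled analog path: low-pass
  (10 Hz) then high-pass (0.5 Hz) of the raw channel signal.

Signal units are arbitrary normalized units — the recording chain
amplifies by roughly 1000× and no absolute calibration exists — so
thresholds and amplitudes live on one common scale. Per-user amplitude
idiosyncrasy is modeled as a ±15% jitter (`gen_config_user()`).

The generator reproduces the statistical structure the recognizer
assumes: cross-channel mixing, drift, channel-localized bursts, and the
amplitude ordering normal blink < threshold < voluntary burst. It does
**not** model electrode lift-off, occlusal irregularity (a documented
cause of real bite failures), muscle fatigue, head movement artifacts, or
inter-trial amplitude drift within a user. Passing the synthetic
protocol therefore demonstrates the correctness and calibration logic of
the pipeline under its assumed signal model, not clinical performance;
on real recordings the bite class in particular is expected to fall off
(the published bite rate is 67%, dominated by threshold rejections).

## Numerical choices

* **Filters.** Butterworth order 2, applied forward–backward so the DC
  and AC paths stay phase-aligned. The implementation uses odd
  (reflection) extension with steady-state initial conditions at both
  ends — naive forward–backward filtering leaves edge transients large
  enough to corrupt rest-noise statistics. The published chain names
  only the 66.7 Hz sEMG cutoff; the 10 Hz DC and 0.5 Hz AC cutoffs are
  declared defaults in `preprocess_config()`.
* **Baseline bands.** "Returned to baseline" is operationalized as
  |signal| below 20% of the corresponding threshold; the source gives no
  band. Both fractions are options (`saccade_options()`).
* **Tie-breaks.** The vertical gate sends exact ties to `vertical`
  (fail-safe: no command). Event matching in `evaluate_events()` is
  greedy one-to-one, earliest truth first, nearest prediction, earlier
  prediction on distance ties.
* **Degenerate inputs.** Empty schedules synthesize valid silent
  recordings; recordings shorter than the renewal quiet window raise an
  insufficient-data error; an sEMG episode with neither channel active
  is rejected as invalid; zero-activity envelopes yield empty interval
  lists rather than errors.
* **Rounding.** Percentages are compared to published precision using
  round-half-up (`round_half_up()`), since banker's rounding would
  misreport e.g. 95.14 → 95.1 boundary cases.

## Evaluation and the published-table checks

`evaluate_events()` scores each presented action as *correct*, *reject*
(no reaction) or *miss* (wrong response); `pe_score()` implements the
5-point rule (5/2/0). Pooled rates are computed over trials, not as
means of per-pattern percentages — that is what reproduces the published
pooled values (274/288 = 95.1% correct, 4/288 = 1.4% reject,
10/288 = 3.5% miss) exactly. Normal-blink presentations invert the
logic: no reaction is the correct outcome.

`table_report()` recomputes every derivable printed summary from the
transcribed per-subject tables and flags agreement to within one unit in
the last printed digit. Three groups of printed values are known not to
recompute from their own tables and are reported as failing by design:
the per-class 5-point scores (e.g. the right column's counts give 4.81,
not the printed 4.78), the left-blink class average (the cells give 93%,
printed 94%), and the two-division per-operation times (77.0 s / 56
operations is 1.375 s, not the printed 1.93 s). The printed mean miss
rate 1.45% recomputes to 1.444%, a last-digit slip covered by the
one-digit rule. None of these are used as targets anywhere.

## The speller simulations

`build_tree()` lays the alphabet at the leaves of a balanced k-ary tree
(k = 4: quadrant selection with right → lower-right, left → lower-left,
right blink → upper-right, left blink → upper-left; k = 2: the
single-modality variants). The default 65-symbol alphabet is the
smallest round set giving depth 4 at k = 4 and depth 7 at k = 2; the
original software's symbol count is not published. `simulate_spelling()`
walks the tree at a configured pace — `per_operation_time` is an input
(default 1.5625 s = 50.0 s / 32 operations, the observed four-division
pace), deliberately not derived from signal simulation, so throughput
arithmetic is reproducible independently of recognizer accuracy. After a
missed (wrong-branch) command the walker restarts the current
character's descent; the recovery protocol is not published, and restart
is the simplest policy that makes every miss cost exactly the wasted
partial path. `simulate_scanner()` models the single-click mode used
with severely handicapped users: linear auto-scan, one recognized
pattern selects the highlighted symbol, a failed click waits a full
cycle, and a max-cycle cap turns pathological error rates into an
explicit timeout.

## Problem sizes used in the bundled checks

The end-to-end protocol experiment runs 8 simulated users × 9 trials ×
4 command classes × 20 replicate seeds (5760 trials) for accuracy, and
8 users × 3 normal blinks × 10 seeds (240 blinks) for rejection —
matching the published protocol's cell counts while keeping a full run
in the minutes range. Property checks (noise monotonicity, drift
robustness) use shorter recordings with 2 presentations per class, 20
seeds. All randomness flows from a single master seed through a
deterministic mixing function, so every reported number is exactly
reproducible.

## Known limitations

* Threshold-based recognition only: no feature learning, no
  frequency-domain sEMG classification, no continuous gaze-angle
  estimation or cursor control.
* Batch processing: zero-phase filtering is acausal, so the pipeline
  makes no online-latency claims.
* One decision per fixation: a long held gaze emits a single command
  (whether held gaze should auto-repeat is an open interface question).
* The generator's amplitude scale and SNR are declared, not fitted to
  device data; absolute figure axes for the original device are not
  available.
* Up/down saccades and the 3-electrode montage variant are out of scope;
  vertical movements exist only as a gated-out internal label.
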