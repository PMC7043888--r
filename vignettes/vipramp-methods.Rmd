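---
title: "Methods: task simulation and VIP-cell dynamics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task simulation and VIP-cell dynamics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipramp)
```

## The task and what the package models

`vipramp` models a go/no-go visual change-detection task as used with
head-fixed mice on a running disc: natural-scene images are flashed for
250 ms, separated by 500 ms of gray screen (a 750 ms stimulus period). On
*go* trials the image identity changes and the animal reports the change by
licking within a 750 ms response window to earn a water reward; on *catch*
trials no change occurs and licks in the sham window are false alarms. To
probe temporal-expectation signals, about 5% of non-change flashes are
randomly *omitted* — the screen simply stays gray for an extra period,
leaving a gap in an otherwise predictable rhythm.

The package contains (i) a generative simulator of complete behavior
sessions, (ii) a synthetic calcium event-trace generator for excitatory and
VIP inhibitory populations whose temporal structure switches between a
*novel* (stimulus-driven) and a *familiar* (pre-stimulus ramping,
stimulus-suppressed, omission-ramping) regime, (iii) the trace-processing
steps used with two-photon data (neuropil subtraction, rolling-mode dF/F,
causal half-Gaussian smoothing, frame/stimulus alignment, pupillometry
cleaning), and (iv) the behavioral and neural response metrics and
group-level statistics that quantify those regimes.

## Session generation

**Change times.** Trial change (and sham-change) times are drawn as
`change_time_min + X`, where `X` is exponential with upper truncation at
`change_time_max - change_time_min`. The exponential scale is calibrated
numerically (`change_time_scale()`) so that the *truncated* mean equals the
configured mean: solving
$E[X \mid X \le L] = s - L e^{-L/s}/(1-e^{-L/s}) = 2.0$ with $L = 6$ gives
$s \approx 2.80$ s, so draws have mean 4.25 s within [2.25, 8.25] s.
Sampling is by inverse CDF of the truncated law, so the bounds hold by
construction and each draw consumes exactly one uniform (which keeps the
simulation's random stream stable). A configured mean outside the
attainable range $(\text{min}, (\text{min}+\text{max})/2)$ is rejected as a
configuration error.

**Transition paths.** The image sequence follows Eulerian circuits over the
complete directed graph on the 8 images *including self-loops*: each path
traverses all 64 ordered transitions exactly once (randomized Hierholzer
construction), and the 8 same-to-same transitions are the catch trials, so
the 12.5% catch frequency is a structural property of the path rather than
an independent coin flip. A session pre-generates 1000 paths, draws one at
random, advances one transition per trial, and on exhaustion draws a fresh
path rotated (circuits are closed) to start at the currently displayed
image, keeping the displayed sequence coherent.

**Trials, aborts and rewards.** Scheduled change times are drawn
continuously and snapped to the next flash onset, so changes always occur
on flash boundaries. Any lick before the (sham) change aborts the trial,
which restarts at the next flash with the *same* scheduled change time; the
repeat count is capped at 5, after which the trial is recorded `ABORTED`
and the session moves to the next transition. The response window is
half-open on the left and closed on the right, `(change, change + 0.75]`,
so the printed 750 ms latency is attainable. Sessions open with five
free-reward trials (non-contingent reward at the scheduled change time;
these consume path transitions like any trial), and a further
non-contingent reward is delivered at the end of every 10th consecutive
MISS trial. Implementing the streak reward as a *reward event* rather than
as a converted trial keeps the go/catch composition of the path intact and
makes "exactly 10 MISS trials between automatic rewards" an exact property
of the simulator.

**Omissions.** After the trial structure is resolved, eligible flashes
(neither a change nor the flash immediately preceding a change) are flagged
omitted with independent probability 0.05. Consecutive omissions are
allowed, and the flash immediately *after* a change is eligible (only the
change and pre-change exclusions are specified by the task). Omitted
flashes keep their slot: their onset remains defined (it anchors the
omission analyses) but nothing is displayed.

**The agent.** The simulated mouse is a probabilistic responder: it licks
in the response window with probability `p_hit` on go trials (reaction
times normal, mean 0.35 s, SD 0.08 s, truncated to the window), guesses on
catch trials with probability 0.15, and emits spontaneous trial-aborting
licks at 2% per pre-change flash. Running alternates exponential bouts
(mean 20 s running) tuned to a 40% running fraction at ~12 cm/s, sampled
at the 60 Hz stimulus clock; pupil area is a positive AR(1)-fluctuating
baseline at 30 Hz. These values are plausible for a trained, engaged
mouse; none of the analyses depend on them beyond the properties asserted
in the tests (e.g. hit-rate recovery, engagement filtering).

## Synthetic population activity

Event traces are generated directly at the event level (the quantity the
analyses consume): per imaging frame (30 Hz) an event count is Poisson with
the cell's instantaneous rate, and the frame magnitude is the sum of that
many exponential marks (mean 0.01 a.u., matching the scale of typical
deconvolved event magnitudes). The event-magnitude distribution of real
deconvolved traces is not well characterized; the exponential mark is a
modeling convenience and is labelled as such.

Rates are driven by the time elapsed since the last *displayed* flash:

* **Transient profile** (excitatory cells; driven-mode VIP): a Gaussian
  bump peaking 150 ms after onset (SD 50 ms), scaled by per-image tuning
  weights (preferred image weight 1; others uniform below
  `exp(-tuning_sharpness)`). Silent during omission gaps. Under the
  familiar condition excitatory amplitudes are scaled by 0.65 and tuning is
  sharpened (sharpness 1.4 vs 0.7) — the direction of the
  experience-dependent reduction and selectivity increase; the exact effect
  sizes are free parameters, not claims.
* **Suppressed/ramping profile** (familiar-mode VIP): the rate decays from
  its peak during the 150 ms after stimulus onset, then ramps linearly back
  up across the inter-stimulus interval to peak at the next onset. When a
  flash is omitted the ramp *continues to grow* through the gap
  (`omission_rule = "continue_ramp"`, gain 1.5 per omitted period) until
  the next displayed stimulus, so omission-window activity exceeds
  stimulus-window activity — the defining phenomenology of the familiar
  regime.

VIP mode composition is a study condition, not a per-cell coin flip:
`round(n_vip * fraction)` cells are assigned to each mode, with defaults
60% suppressed/ramping under familiar and 85% driven under novel images
(matching the reported majority fractions). This makes the planted
composition of every generated population exact, so directional tests
measure classification accuracy rather than binomial noise in the ground
truth.

A fluorescence forward model (`render_fluorescence()`) is provided for
testing the processing chain: the true somatic trace is baseline plus
events convolved with a causal single-exponential kernel (τ = 0.7 s,
GCaMP6f-like; unit peak so a lone event of magnitude m rises m·gain above
baseline), the neuropil trace is independent smooth noise, and the measured
trace is composed exactly as `FM = FC + r·FN` (default r = 0.7, here a
known simulation input rather than an estimated quantity).

### What the generator does and does not emulate

The synthetic layer reproduces the *statistical structure the analyses
assume*: image tuning, condition-dependent temporal profiles, omission
continuation, Poisson event noise. It does not model correlated population
noise beyond shared rate profiles, imaging noise, neuropil structure,
slow drift, or behavioral modulation of neural gain. Passing tests
therefore demonstrate that the analysis code recovers planted structure
correctly at realistic signal-to-noise — not that the biological effects
would be detected in any particular real dataset.

## Trace processing

* **Neuropil subtraction** is the exact algebraic inverse `FC = FM - r·FN`.
* **dF/F** uses a *trailing* 180 s rolling-mode baseline (a baseline must
  not peek forward). The mode of a continuous-valued trace is estimated by
  histogram binning at 0.1% of the trace range, with counts updated
  incrementally as the window slides and the baseline taken as the fullest
  bin's center — accurate to half a bin width (~0.05% of range).
* **Event smoothing** convolves with the non-negative-lag half of a
  Gaussian (SD 65 ms) sampled at the frame rate, truncated at 4 SD and
  renormalized to unit sum, conserving total event mass and strict
  causality.
* **Alignment** maps each imaging frame to the latest stimulus clock time
  *strictly before* it (ties map to the preceding time), so responses are
  never attributed to later events.
* **Pupillometry** fits an algebraic least-squares conic to tracked points
  with confidence ≥ 0.8, requires ≥ 6 such points (blinks yield missing
  frames), and reports area as that of a circle with radius equal to the
  fitted *semi-major* axis — the reading under which a circular pupil of
  radius R has area πR². Trace cleaning removes > 3 SD outliers, widens
  missing runs by 2 frames each side, and interpolates linearly with flat
  edge extrapolation.

## Response metrics

**Windows.** Flash responses are means of the event trace over
`[onset, onset + 500 ms)` (the 250 ms flash plus 250 ms for delayed and
off responses); omission responses use `[onset, onset + 750 ms)` anchored
at the scheduled-but-not-shown onset. Window membership is half-open and
frame counts are rounded to the nearest frame at 30 Hz.

**Responsiveness classification.** For each cell, every
preferred-image presentation response is compared with 10,000 resamples
(with replacement) of that cell's omission responses; the presentation's
p-value is the fraction of resampled values greater than *or equal to* the
response — ties count against significance, so an all-zero cell can never
be classified responsive. A cell is *image responsive* when ≥ 25% of
preferred-image presentations have p < 0.05, and *omission responsive*
when ≥ 10% of omission responses (tested against resampled displayed-flash
responses) do. The null pool for each test is the complementary pool of
the same cell. Under exchangeable target/null pools the per-presentation
p-values are approximately uniform and the 25% fraction rule makes the
cell-level false-positive rate far below 5% (the calibration test verifies
< 5% over 1000 replicate cells).

**Ramp indices.** The dynamics of a cell's event-triggered average are
quantified as `log2((R_late + ε)/(R_early + ε))` with ε = 1e−6 a.u.,
where `R_early`/`R_late` are the means of the first/last sub-window:
positive when activity increases across the window, negative when it
decreases, 0 for a flat (or all-zero) trace, and antisymmetric under time
reversal. Three windows are used: pre-stimulus (400 ms before onset,
120 ms sub-windows), stimulus (125 ms from stimulus *onset*, 65 ms
sub-windows — which overlap by one frame in the middle, as specified), and
omission (the 750 ms omission window split into 375 ms halves; the split
is a package convention, as no sub-window lengths are conventional for
this window). The stimulus window is anchored at onset — the anchoring
consistent with the reported marginal distributions — with
`anchor = "offset"` available as a config option. Cells with a positive
stimulus ramp index are classed *stimulus-driven*, otherwise
*stimulus-suppressed*.

**Other metrics.** The preferred image is the argmax of per-image mean
responses (ties to the lowest index); lifetime sparseness uses
$S = (1 - (\sum r_i/N)^2/(\sum r_i^2/N))/(1 - 1/N)$ and is reported only
for image-responsive cells; population tuning curves rank-sort each
responsive cell's tuning and average position-wise (suppressed below 10
cells); time-to-peak is the argmax of the triggered average within 500 ms
of onset.

**Behavior.** Hit and false-alarm rates are computed over engaged trials,
where engagement is a reward rate ≥ 2/min in a centered 5-minute rolling
window (the window length is a package choice; the criterion names only
the rate). d′ applies a `[1/(2n), 1 − 1/(2n)]` clip to each rate before
the inverse-normal transform so perfect rates stay finite. Stimulus
presentations are classed running/stationary by mean speed > 5 cm/s in
[−0.5, 0.75] s around onset (± 2 s around omissions).

## Group statistics

Across image-set conditions (A familiar; B, C, D novel) the pipeline tests
each per-cell metric with a one-way ANOVA for an overall image-set effect
followed by pairwise Welch (unequal-variance) t-tests at a
Bonferroni-corrected level of 0.05/6 ≈ 0.0083 for four sets; pairwise
tests are always computed and the ANOVA gates nothing. Confidence
intervals on summary fractions use a percentile bootstrap of the mean
(1000 replicates, dedicated seed); a parametric alternative can be
selected in the config, as the bootstrap choice is a package convention.

## Determinism and problem sizes

Every stochastic stage takes an explicit integer seed and refuses to run
without one; identical inputs and seeds give byte-identical tables. Seeded
functions restore the caller's RNG state on exit. The test suite and the
worked examples use desk-scale problem sizes chosen to exercise every code
path with comfortable statistical margins — 5–15 minute sessions,
populations of tens of cells, 500–10,000 resamples — and the full suite
runs in well under a minute; session-scale defaults (60 min, 180
excitatory / 15 VIP cells, 10,000 resamples) remain the package defaults.

## Known limitations

* The simulator does not model training-stage progression, water
  restriction, hardware timing jitter, or inter-trial gray timeouts beyond
  the flash grid.
* Reported per-session presentation counts in the source literature are
  mutually inconsistent (4699 total vs 487 × 8 images); the simulator
  follows the generative rules (4800 slots/hour) and does not target those
  counts.
* Omission scheduling is independent Bernoulli per eligible flash; the
  real experiment's scheduler may have additional unstated constraints
  (e.g. spacing).
* The event-magnitude mark distribution and the VIP ramp shapes are
  parametric conveniences; analyses that depend on fine trace shape beyond
  the tested window statistics should not be read into them.
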