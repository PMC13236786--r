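---
title: "Classifying search-array locations from raw gaze traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying search-array locations from raw gaze traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a six-location visual search task, a participant fixates the screen
center, a circular array of six stimuli appears (one target, five
distractors, all equidistant from fixation), and the participant reports a
feature of the target within a 1,200-ms response window while an eye
tracker samples gaze position at 500 Hz. On half of the trials one
distractor carries a learned attentional history (it was the search target
in an earlier phase); such a stimulus is neither task-relevant nor salient
but still attracts the eyes on a fraction of trials ("experience-driven
attentional capture"), usually followed by a corrective saccade to the
target.

Traditional analyses reduce each trial's trace to one number, typically
whether the first saccade landed in a 60-degree wedge ("chunk") around the
distractor. This package instead trains a small one-dimensional
convolutional network to classify, from the full raw (x, y) time course,
either the target location or the distractor location (labels 0-5), and
then asks three questions:

1. Is the location decodable above the 1/6 chance level (frequentist tests
   and a hierarchical Bayesian model)?
2. Does the network beat the first-saccade heuristic on the same trials?
3. Which samples of the trace carry the signal (additive feature
   attribution, rotation-aligned density maps, polar/temporal histograms)?

## Data representation and preprocessing

A trial's trace holds the samples recorded while the array was on screen;
the array disappears at the response, so traces are shorter than the
600-sample window on almost every trial. Preprocessing follows three fixed
rules:

* missing samples (tracker dropouts) are replaced by the central fixation
  coordinate — `(1279.5, 719.5)` px on the default 2560 x 1440 display;
* traces are padded at the end with the fixation coordinate to exactly 600
  samples, or truncated if a tracker/response misalignment left a few
  excess samples;
* the trials are stacked into a `(n_trials, 2, 600)` array (feature 1 =
  x, feature 2 = y), with one integer label per trial.

Gaze is fed to the network in raw pixel units: the fixation fill value is
itself a pixel coordinate, and no scaling is applied by default (an
optional standardization switch exists for experimentation but is off
everywhere in this package's analyses).

Participants whose average proportion of missing samples (over trials,
each trial weighted equally) lies more than two sample standard deviations
above the group mean are excluded. Ties at exactly the threshold are
retained; trials with no recorded samples are skipped in the average since
they say nothing about tracking quality.

## The classifier

The network is deliberately small and fixed:

```
conv1d(2 -> 64 features, kernel 3, stride 1, no padding)
  -> ReLU -> dropout(p = 0.25) -> maxpool(size 5, stride 5)
  -> flatten (7,616 units)
  -> linear 7,616 -> 64 -> 32 -> 6 (no intermediate activation)
```

The flatten width is forced by the arithmetic: 600 samples through an
unpadded kernel-3 convolution give 598 positions, pooling by 5 gives 119,
and 119 x 64 = 7,616 (padded convolution would give 7,680, so the
no-padding choice is derived, not assumed). The three weight-bearing
linear transforms read the published stack as input 7,616 -> 64 -> 32 ->
output 6; the alternative reading with an extra 7,616-unit transform is
noted but not adopted. The largest logit is the predicted location, ties
to the lowest index (ties have measure zero after training).

Weights are initialized from the fan-in-scaled uniform distribution
U(-1/sqrt(fan_in), +1/sqrt(fan_in)) under a recorded seed. The forward and
backward passes are implemented directly as BLAS matrix products over an
im2col layout, with small C++ kernels for the gather/scatter steps; a
direct-arithmetic re-evaluation of the same network and a numerical
gradient check serve as independent oracles in the test suite.

## Training

Training uses mini-batches of 64 (the last batch takes the remainder, so
an epoch makes exactly `ceiling(n/64)` Adam updates), categorical
cross-entropy, an initial learning rate of 1e-3 multiplied by gamma = 0.9
after every training/validation cycle, and early stopping with patience 10
on the validation loss: a strictly smaller loss snapshots the weights and
resets the counter, anything else increments it, and on stop the best
snapshot is restored. Adam uses the community-default moment constants
(0.9, 0.999) and epsilon 1e-8; the defaults live in `train_config()` for
auditability. Validation loss is the mean cross-entropy over all
validation trials (not a mean of batch means), evaluated with frozen
weights and dropout inactive. A `max_epochs` cap (default 200) guards
against the case where early stopping never triggers. Training batches are
reshuffled every epoch by default; everything is reproducible from the
single integer seed in `train_config()`.

The validation set is every third trial within each participant (1-based
ranks divisible by 3), which yields the exact two-thirds/one-third split
for the session lengths of interest; any fixed offset gives identical
counts when trial counts are divisible by 3. For distractor analyses,
distractor-absent trials are removed before splitting.

## Hierarchical model of accuracy

Participant-level classification counts are modeled as

```
C_i ~ Binomial(N_i, p_i)
p_i ~ Beta(alpha, beta)
alpha ~ Exponential(rate 0.1)
beta  ~ Exponential(rate 0.05)
```

The exponential parameters are read as rates (prior means 10 and 20),
which centers the prior group mean alpha/(alpha+beta) near 1/3 — closer to
the 1/6 chance level than a high-accuracy posterior, i.e. a mild shrinkage
toward chance. A configuration flag covers the scale-parameter reading for
sensitivity analyses. The posterior is sampled by MCMC through JAGS
(conjugate Gibbs steps for the latent p_i, slice sampling for the shape
parameters), four chains of 1,000 iterations with the first half treated
as warm-up, each chain seeded separately so runs are exactly reproducible.
This sampler targets the identical posterior as a gradient-based sampler
would; it was chosen because it is the standard, robust tool available to
an R workflow for this conjugate structure.

Two practical notes, both visible in the fit object:

* the shape parameters (alpha, beta) sit on a correlated ridge and mix
  slowly (split R-hat can exceed 1.05 at these chain lengths); the derived
  group mean `beta_mean = alpha/(alpha+beta)` — the quantity all
  inferences use — mixes cleanly (R-hat ~ 1.00, effective sample size in
  the hundreds to thousands). Any R-hat above 1.05 raises a warning and is
  recorded in `diagnostics`; it is never silent.
* the 95% interval is a highest-posterior-density interval: the narrowest
  contiguous window containing 95% of the sorted draws.

Split-R-hat and a rank-normalized effective sample size (combined-chain
autocorrelations with the initial-positive-sequence truncation) are
implemented in `mcmc_diagnostics()`.

## The first-saccade comparator

`detect_first_saccade()` finds the first run of at least 5 samples whose
central-difference speed exceeds a threshold; the landing is the gaze at
the run's end. The default threshold of 1 px/sample (250 px/s sustained
for 10 ms) suits video-oculography noise of a pixel or two RMS. The
synthetic generator below uses 12-px Gaussian noise, under which fixation
speeds average ~10 px/sample while synthetic saccades peak near 40-60, so
the analyses on synthetic data pass `velocity_threshold = 20`; the
threshold is an explicit argument precisely because it must track the
noise level of the data at hand. Pre-parsed vendor events can be
substituted for the detector wherever events are consumed.

Landings are assigned to one of six half-open 60-degree wedges centered on
the stimulus angles; the per-participant rate of first saccades landing in
the distractor's wedge, over distractor-present trials with eye data and a
detected saccade, is the comparator. It is compared against the
classifier's per-participant accuracy on the same qualifying trials with a
paired t-test and a participant-level bootstrap CI of the mean difference.
A landing at the exact screen center (possible when a fixation-filled
sample terminates a run) has no polar angle; such trials stay in the
denominator but cannot score a distractor landing.

The supplementary `min_mean_distance_baseline()` — return the location
with the smallest mean Euclidean distance to all samples — is the simple
fixed algorithm that suffices for *target* identification and motivates
why a learned classifier is interesting mainly for *distractor*
prediction.

## Additive feature attribution

`explain()` assigns each input cell (feature x sample) a signed
contribution to each class logit, relative to a background set
(conventionally the first 100 validation trials). Contributions are
computed per (query, background) pair by backpropagating multipliers:

* linear stages (convolution, linear transforms, flatten, inactive
  dropout) propagate multipliers exactly like gradients of the difference;
* the ReLU uses the rescale rule, multiplier x (delta-output /
  delta-input), with a zero multiplier where the input difference
  vanishes (the output difference vanishes there too);
* max pooling routes each pooled unit's multiplier to a single input
  position — the query's argmax if its difference from the background is
  nonzero, else the background's argmax — scaled by delta-output /
  delta-input at the routed position.

Every rule conserves the summed contribution, so per class the
contributions add up to `logit(query) - logit(background)` to machine
precision; averaged over the background set this is the
completeness/additivity property against the background-mean output, and
`explain()` verifies it on every explained trial (tolerance 1e-3 relative,
observed residuals ~1e-12). On a purely linear surrogate model the
procedure reproduces the closed-form Shapley values exactly, which the
test suite asserts.

The per-sample "global importance" is the mean absolute contribution over
the 12 feature-by-class cells at that sample. Downstream analyses use the
per-trial argmax sample (earliest on ties): its time in ms (sample x 2 ms,
0-based) against the response time; its gaze coordinates rotated rigidly
about the screen center so every trial's distractor sits at a common
angle; a Gaussian KDE of those rotated points on a 10-px grid with the
Silverman bandwidth `h = mean(sd_x, sd_y) * n^(-1/6)` (the two-dimensional
rule; the exponent is an argument), max-normalized so heatmaps are
comparable; and a polar histogram whose bins are centered on the six
stimulus angles, reporting per-bin counts and mean peak times.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analyses
assume, with every distribution parameterized in `synth_config()`:

* target uniform over six locations; a distractor on exactly half of the
  trials (exact counts per participant), uniform over the remaining five;
* fixation at the screen center, then a saccade after a lognormal latency
  (median 200 ms, a typical first-saccade latency in search), duration
  uniform 30-50 ms, with a logistic position profile — smooth enough for
  velocity-threshold detection without modeling the full main sequence;
* on captured trials (probability 0.3 among distractor-present trials)
  the first saccade goes to the distractor, dwells 150 ms, and a
  corrective saccade proceeds to the target;
* response time = target arrival + a 60-ms floor + an exponential
  decision lag (mean 200 ms), truncated at the 1,200-ms deadline; the
  trace ends at the response (the array disappears), and downstream
  padding restores the 600-sample window;
* isotropic Gaussian pixel noise (12 px) on every sample and 2% missing
  samples.

`null_dataset()` regenerates the labels uniformly after the traces are
made, so any classifier's expected accuracy is exactly 1/6 — the negative
control for the whole pipeline.

What the generator does *not* emulate: secondary saccades and
microsaccades, main-sequence velocity profiles, smooth pursuit or drift,
blink artifacts with their pre/post distortions, participant-specific
idiosyncrasies, and any pupil dynamics. Passing end-to-end tests on these
data therefore shows that the pipeline detects the kind of signal the
theory predicts — a brief, early visit toward the distractor followed by
correction — not that a particular accuracy level will be attained on
human data.

## Numerical choices and degenerate inputs

* Prediction ties break to the lowest class index; argmax-sample ties to
  the earliest sample.
* The min-mean-distance baseline treats distances within 1e-9 (relative)
  as tied, so the equidistant screen center resolves to location 0 rather
  than floating-point noise.
* HPDI requires at least 100 draws; bandwidths require at least 2 points
  with nonzero spread; chunk assignment is undefined exactly at the
  center (errors in the strict function, `NA` in `safe_chunk()`).
* Cross-entropy uses the log-sum-exp stabilization; non-finite losses or
  logits abort training with the epoch in the message rather than
  propagating NaNs.
* Desk-scale problem sizes used by the test suite and the acceptance
  script: 12 participants x 96 trials for target/null runs and 32 x 150
  for capture runs; 25-40 epoch caps. These keep full runs in the
  minutes range on one CPU while leaving all statistical checks
  well-powered.

## Known limitations

* The learning-rate decay is per epoch, so with small datasets (few
  updates per epoch) the effective training budget is far smaller than in
  a large study; accuracies on desk-scale synthetic data are therefore
  conservative rather than asymptotic. One visible consequence: on
  synthetic capture data the first-saccade heuristic, whose velocity
  threshold is matched to the generator's noise, can exceed the
  under-trained classifier's accuracy — the paired comparison machinery is
  the deliverable there, not a claim about which method wins at any scale.
* JAGS's samplers, not a gradient-based sampler, generate the posterior;
  the targeted distribution is identical but per-iteration autocorrelation
  of the shape parameters differs from what a Hamiltonian sampler would
  give.
* The saccade detector is a plain velocity-threshold rule; it is not
  claimed to match vendor event parsers sample for sample, and analyses of
  real exports should prefer the vendor events where available.
* EDF parsing, blink/drift correction, and calibration handling are out of
  scope; the package consumes the plain CSV interchange format.
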