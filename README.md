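# gazecnn

Convolutional classification of visual-search gaze traces, in R.

In a six-location visual search task, gaze is sampled at 500 Hz while a
participant finds a shape-defined target among five distractors arranged in
a ring around fixation and responds within 1,200 ms. On half of the trials
one distractor carries a learned attentional history and reflexively
attracts the eyes on a fraction of trials before a corrective saccade.
`gazecnn` asks whether the raw (x, y) gaze time course alone is enough to
classify where the target — and, more interestingly, where that
task-irrelevant distractor — was shown, and then characterizes *which*
samples of the trace carried the signal.

The pipeline:

* **Preprocessing** — missing samples become the central fixation
  coordinate (1279.5, 719.5 px on a 2560 × 1440 display), traces are
  fixation-padded/truncated to 600 samples, and trials are stacked into an
  `(n, 2, 600)` tensor with location labels 0–5. Participants with missing
  data more than 2 SD above the group mean are excluded.
* **Classifier** — a 1D CNN: conv(kernel 3, stride 1, 64 features) → ReLU →
  dropout(0.25) → maxpool(5, 5) → flatten(7,616) → linear 7,616 → 64 → 32 →
  6 logits; argmax = predicted location. Trained with mini-batches of 64,
  categorical cross-entropy, Adam at learning rate 10⁻³ decayed by γ = 0.9
  per epoch, early stopping with patience 10 and best-checkpoint restore.
  Validation is every third trial within each participant (a
  two-thirds/one-third split).
* **Inference** — participant-level accuracies with 10,000-replicate
  bootstrap CIs and t-tests against the 1/6 chance level, plus a
  hierarchical model `C_i ~ Binomial(N_i, p_i)`, `p_i ~ Beta(α, β)`,
  `α ~ Exp(0.1)`, `β ~ Exp(0.05)`, sampled by MCMC (4 × 1,000 iterations),
  summarized by the posterior of the group mean α/(α+β) with a 95% HPDI,
  split-R̂ and effective-sample-size diagnostics.
* **Comparator** — the traditional first-saccade heuristic: rate of first
  saccades landing in the distractor's 60° "chunk", compared to CNN
  accuracy on the same trials with a paired t-test.
* **Attribution** — DeepLIFT-style additive contributions with an exact
  completeness guarantee (per class, contributions sum to
  `logit(query) − mean logit(background)` to machine precision), reduced to
  a per-sample global importance (mean |contribution| over the 12
  feature × class cells), then peak-importance times vs RT,
  rotation-aligned Gaussian KDE maps (Silverman bandwidth, 10-px grid) and
  polar/temporal histograms.
* **Synthetic generator** — gaze datasets with known ground truth
  (target-directed saccades, optional distractor capture + correction,
  noise, missingness, response deadline), plus a label-shuffled null
  generator, so every stage can be validated end to end.

## Worked example

```r
library(gazecnn)
d <- generate_dataset(synth_config(n_participants = 12, trials_per_participant = 96,
                                   capture_prob = 0.3, seed = 7))
print(d)
excl <- exclude_participants(d)
cat("exclusion threshold:", round(excl$threshold, 4), "; excluded:",
    if (length(excl$excluded)) excl$excluded else "none", "\n")
tens <- preprocess_dataset(d, "target")
sp <- split_every_third(d$trials)
fit <- fit_cnn(tens, sp, network_config(), train_config(seed = 11, max_epochs = 10))
print(fit)

val <- sp$val                                   # validation trials of the split
vrows <- match(paste(val$participant_id, val$trial_index),
               paste(tens$trial_order$participant_id, tens$trial_order$trial_index))
logits <- forward(fit$model, tens$values[vrows, , , drop = FALSE])
report <- score(predict_classes(logits), tens$labels[vrows], tens$trial_order[vrows, ])
print(report)
ci <- bootstrap_ci(report$per_participant$accuracy, seed = 2)
tt <- t_vs_chance(report$per_participant$accuracy)
cat(sprintf("bootstrap 95%% CI [%.1f%%, %.1f%%]; t(%d) = %.2f, p = %.2g\n",
            100 * ci$lower, 100 * ci$upper, tt$df, tt$t, tt$p))
print(sample_posterior(report, bayes_model_spec(seed = 3)))
```

This prints:

```
<gaze_dataset> 1152 trials, 12 participants, horizontal-meridian array
exclusion threshold: 0.0218 ; excluded: none
tensor: 1152 x 2 x 600
split: 768 train / 384 validation
<gaze_cnn_fit> 10 epochs (best: 9), final val acc 0.891
<accuracy_report> overall 85.68% over 384 trials, 12 participants
bootstrap 95% CI [82.3%, 88.8%]; t(11) = 38.73, p = 4.1e-13
<bayes_fit> group-mean accuracy 0.846, 95% HPDI [0.798, 0.900] (NOT CONVERGED)
```

Reading the output: on clean synthetic data the target location is
decodable from the raw trace at ~86% against a 16.67% chance level, the
participant-level bootstrap interval and t-test agree, and the
hierarchical model places the group-level accuracy near the empirical
value. The `NOT CONVERGED` tag refers to the beta *shape* parameters,
whose ridge-shaped posterior mixes slowly at these chain lengths; the
group-mean draws the summary is built from mix cleanly (see the
diagnostics table in the fit and the methods vignette for why this is
surfaced rather than hidden).

A thin command-line wrapper over the same functions is installed as
`exec/gazecnn`, with `simulate`, `preprocess`, `split`, `train`,
`evaluate`, `bayes`, `heuristic` and `shap` subcommands; run any of them
without arguments for usage.

## Package layout

```
R/                 geometry, dataset I/O, preprocessing, splitting, the CNN
                   and its training loop, evaluation, the hierarchical
                   model, the saccade heuristic, attribution, the generator
src/               C++ kernels for the convolution/pooling gather-scatter
tests/testthat/    unit, property and end-to-end acceptance tests
vignettes/         methods vignette (models, assumptions, design choices)
scripts/           acceptance script (see above)
exec/              command-line entry point
```
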