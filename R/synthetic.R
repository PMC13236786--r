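# Synthetic visual-search gaze generator. Emulates the statistical
# structure the analyses assume: central fixation, a first saccade launched
# after a lognormal latency either to the target (direct trials) or to the
# color-singleton distractor (captured trials, distractor-present only),
# a dwell and a corrective saccade back to the target after capture,
# Gaussian pixel noise, per-sample missingness, and a trace that ends at
# the response (the array disappears at response; downstream preprocessing
# pads with fixation).

#' Synthetic-dataset configuration
#'
#' Defaults describe a plausible six-location search session at 500 Hz with
#' a 1,200-ms response window: first-saccade latency lognormal with a
#' 200-ms median, 30-50-ms saccade durations, a 150-ms dwell on a captured
#' distractor before correction, ~12-px gaze noise, 2% dropped samples, and
#' a distractor on half of the trials with 30% of those captured.
#'
#' @param n_participants,trials_per_participant Session size.
#' @param distractor_present_fraction Fraction of trials with a distractor
#'   (counts are exact per participant when the product is an integer).
#' @param capture_prob Probability that a distractor-present trial's first
#'   saccade goes to the distractor.
#' @param saccade_latency_meanlog,saccade_latency_sdlog Lognormal latency
#'   parameters, ms.
#' @param saccade_duration_range_ms Uniform saccade duration range, ms.
#' @param corrective_delay_ms Dwell on the captured distractor before the
#'   corrective saccade, ms.
#' @param decision_lag_ms Mean lag between target arrival and the button
#'   response, ms (exponential with this mean, plus a 60-ms floor).
#' @param gaze_noise_sd Gaussian noise on each recorded sample, px.
#' @param missing_rate Per-sample probability of a missing (NA) sample.
#' @param rt_max_ms Response deadline, ms; traces are capped here.
#' @param seed Integer seed; generation is bitwise reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 12L, trials_per_participant = 96L,
                         distractor_present_fraction = 0.5,
                         capture_prob = 0.3,
                         saccade_latency_meanlog = log(200),
                         saccade_latency_sdlog = 0.25,
                         saccade_duration_range_ms = c(30, 50),
                         corrective_delay_ms = 150,
                         decision_lag_ms = 200,
                         gaze_noise_sd = 12,
                         missing_rate = 0.02,
                         rt_max_ms = 1200,
                         seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_participant >= 1,
            distractor_present_fraction >= 0, distractor_present_fraction <= 1,
            capture_prob >= 0, capture_prob <= 1,
            missing_rate >= 0, missing_rate < 1, gaze_noise_sd >= 0,
            rt_max_ms > 0)
  structure(as.list(environment()), class = "synth_config")
}

# logistic displacement profile from `from` to `to` over [t0, t0 + dur]
sigmoid_profile <- function(t, t0, dur, from, to) {
  u <- (t - t0) / dur
  f <- 1 / (1 + exp(-12 * (u - 0.5)))
  f[u <= 0] <- 0
  f[u >= 1] <- 1
  from + (to - from) * f
}

#' Generate a synthetic visual-search gaze dataset
#'
#' @param cfg A [synth_config()].
#' @param g An [array_geometry()].
#' @return A [gaze_dataset()] with all ground truth recorded in the trial
#'   table.
#' @export
generate_dataset <- function(cfg = synth_config(), g = default_geometry()) {
  rng <- local_rng(cfg$seed)
  on.exit(restore_rng(rng))
  loc <- location_coords(g)
  period <- 2                          # ms per sample at 500 Hz
  max_samples <- as.integer(cfg$rt_max_ms / period)
  trials_list <- list()
  traces <- list()
  row <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%03d", p)
    n_tr <- cfg$trials_per_participant
    n_present <- round(cfg$distractor_present_fraction * n_tr)
    present <- logical(n_tr)
    present[sample.int(n_tr, n_present)] <- TRUE
    for (tr in seq_len(n_tr)) {
      target <- sample(0:5, 1L)
      distractor <- if (present[tr]) sample(setdiff(0:5, target), 1L) else NA_integer_
      captured <- present[tr] && stats::runif(1) < cfg$capture_prob
      latency <- stats::rlnorm(1, cfg$saccade_latency_meanlog,
                               cfg$saccade_latency_sdlog)
      dur1 <- stats::runif(1, cfg$saccade_duration_range_ms[1L],
                           cfg$saccade_duration_range_ms[2L])
      ctr <- c(g$center_x, g$center_y)
      tgt <- loc[target + 1L, ]
      if (captured) {
        dtr <- loc[distractor + 1L, ]
        dur2 <- stats::runif(1, cfg$saccade_duration_range_ms[1L],
                             cfg$saccade_duration_range_ms[2L])
        t_corr <- latency + dur1 + cfg$corrective_delay_ms
        arrival <- t_corr + dur2
      } else {
        arrival <- latency + dur1
      }
      rt <- arrival + 60 + stats::rexp(1, 1 / cfg$decision_lag_ms)
      rt <- min(rt, cfg$rt_max_ms)
      n_rec <- min(max_samples, max(1L, floor(rt / period)))
      tm <- (seq_len(n_rec) - 1) * period
      if (captured) {
        x <- sigmoid_profile(tm, latency, dur1, ctr[1L], dtr[1L])
        y <- sigmoid_profile(tm, latency, dur1, ctr[2L], dtr[2L])
        late <- tm >= t_corr
        x[late] <- sigmoid_profile(tm[late], t_corr, dur2, dtr[1L], tgt[1L])
        y[late] <- sigmoid_profile(tm[late], t_corr, dur2, dtr[2L], tgt[2L])
      } else {
        x <- sigmoid_profile(tm, latency, dur1, ctr[1L], tgt[1L])
        y <- sigmoid_profile(tm, latency, dur1, ctr[2L], tgt[2L])
      }
      x <- x + stats::rnorm(n_rec, 0, cfg$gaze_noise_sd)
      y <- y + stats::rnorm(n_rec, 0, cfg$gaze_noise_sd)
      if (cfg$missing_rate > 0) {
        gone <- stats::runif(n_rec) < cfg$missing_rate
        x[gone] <- NA_real_
        y[gone] <- NA_real_
      }
      row <- row + 1L
      trials_list[[row]] <- data.frame(
        participant_id = pid, trial_index = tr, target_location = target,
        distractor_location = distractor, rt_ms = rt,
        n_recorded_samples = n_rec,
        first_saccade_to_distractor = captured)
      traces[[row]] <- data.frame(x = x, y = y)
    }
  }
  trials <- do.call(rbind, trials_list)
  gaze_dataset(g, trials, traces)
}

#' Null dataset: traces carry no information about the labels
#'
#' Generates a capture-free dataset, then reassigns every trial's target
#' label uniformly over the six locations (and, on distractor-present
#' trials, the distractor label uniformly over the remaining five),
#' independently of the traces. Any classifier's expected accuracy on
#' either labeling is exactly 1/6.
#'
#' @param cfg A [synth_config()] (its `capture_prob` is ignored).
#' @param g An [array_geometry()].
#' @return A [gaze_dataset()].
#' @export
null_dataset <- function(cfg = synth_config(), g = default_geometry()) {
  cfg$capture_prob <- 0
  d <- generate_dataset(cfg, g)
  rng <- local_rng(cfg$seed + 1234567L)
  on.exit(restore_rng(rng))
  n <- nrow(d$trials)
  new_target <- sample(0:5, n, replace = TRUE)
  present <- !is.na(d$trials$distractor_location)
  new_distr <- rep(NA_integer_, n)
  new_distr[present] <- vapply(new_target[present], function(t)
    sample(setdiff(0:5, t), 1L), 0L)
  d$trials$target_location <- new_target
  d$trials$distractor_location <- new_distr
  d$trials$first_saccade_to_distractor <- FALSE
  gaze_dataset(d$geometry, d$trials, d$traces)
}
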