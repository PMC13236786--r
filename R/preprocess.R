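#' Replace missing gaze samples with central fixation
#'
#' Missing samples (eye not tracked, `NA` in the raw export) are replaced by
#' the screen-center fixation coordinate -- (1279.5, 719.5) on the default
#' 2560 x 1440 display. Observed values pass through unchanged.
#'
#' @param trace Data frame with columns `x`, `y`.
#' @param g An [array_geometry()].
#' @return The trace with no remaining `NA`.
#' @export
fill_missing <- function(trace, g) {
  trace$x[is.na(trace$x)] <- g$center_x
  trace$y[is.na(trace$y)] <- g$center_y
  trace
}

#' Pad or truncate a trace to a fixed length
#'
#' The search array disappears at the response, so short trials are padded
#' at the end with the fixation coordinate up to `L` samples (600 for the
#' 1,200-ms response window at 500 Hz); traces that overrun the window by a
#' few samples (tracker/response-signal misalignment) are truncated to `L`.
#'
#' @param trace Data frame with columns `x`, `y`, no missing values
#'   (run [fill_missing()] first).
#' @param L Target length in samples.
#' @param g An [array_geometry()] supplying the fixation coordinate.
#' @return A trace of exactly `L` samples.
#' @export
pad_or_truncate <- function(trace, L = 600L, g = default_geometry()) {
  if (L <= 0) stop("L must be a positive sample count")
  if (anyNA(trace$x) || anyNA(trace$y))
    stop("trace still contains missing samples; run fill_missing() first")
  n <- nrow(trace)
  if (n >= L) return(trace[seq_len(L), , drop = FALSE])
  pad <- data.frame(x = rep(g$center_x, L - n), y = rep(g$center_y, L - n))
  out <- rbind(trace, pad)
  rownames(out) <- NULL
  out
}

#' Assemble fixed-length traces into the trials x features x samples tensor
#'
#' Stacks the preprocessed traces into a numeric array of shape
#' `(n_trials, 2, L)` -- feature 1 is x-position, feature 2 is y-position --
#' and pairs it with the integer location labels (0-5) taken from the trial
#' table. With `semantics = "distractor"` every trial must have a distractor
#' (subset with [subset_distractor_present()] first).
#'
#' @param traces List of fixed-length, fully observed traces.
#' @param trials Trial table aligned with `traces`.
#' @param semantics `"target"` or `"distractor"`: which location to label.
#' @return A list of class `trace_tensor`: `values` (the array), `labels`
#'   (integer 0-5), `trial_order` (data frame `participant_id`,
#'   `trial_index`), `semantics`.
#' @export
assemble <- function(traces, trials, semantics = c("target", "distractor")) {
  semantics <- match.arg(semantics)
  stopifnot(length(traces) == nrow(trials))
  n <- length(traces)
  lens <- vapply(traces, nrow, 0L)
  if (n > 0L && length(unique(lens)) != 1L)
    stop("all traces must share the same fixed length")
  L <- if (n > 0L) lens[1] else 0L
  labels <- if (semantics == "target") trials$target_location else trials$distractor_location
  if (semantics == "distractor" && anyNA(labels))
    stop("distractor semantics requires distractor-present trials only; ",
         "subset with subset_distractor_present() first")
  values <- array(NA_real_, dim = c(n, 2L, L))
  for (i in seq_len(n)) {
    if (anyNA(traces[[i]])) stop("trace ", i, " contains missing samples")
    values[i, 1L, ] <- traces[[i]]$x
    values[i, 2L, ] <- traces[[i]]$y
  }
  structure(list(values = values, labels = as.integer(labels),
                 trial_order = data.frame(participant_id = trials$participant_id,
                                          trial_index = trials$trial_index),
                 semantics = semantics),
            class = "trace_tensor")
}

#' Full preprocessing: dataset to model-ready tensor
#'
#' Convenience wrapper chaining [fill_missing()], [pad_or_truncate()] and
#' [assemble()] over all trials of a dataset.
#'
#' @param d A [gaze_dataset()].
#' @param semantics `"target"` or `"distractor"`.
#' @param L Window length in samples (600 = 1,200 ms at 500 Hz).
#' @return A `trace_tensor`.
#' @export
preprocess_dataset <- function(d, semantics = c("target", "distractor"), L = 600L) {
  semantics <- match.arg(semantics)
  trials <- d$trials
  traces <- d$traces
  if (semantics == "distractor") {
    keep <- !is.na(trials$distractor_location)
    trials <- trials[keep, , drop = FALSE]
    traces <- traces[keep]
  }
  fixed <- lapply(traces, function(tr)
    pad_or_truncate(fill_missing(tr, d$geometry), L, d$geometry))
  assemble(fixed, trials, semantics)
}

#' Participant exclusion by missing-data proportion
#'
#' For each trial, the proportion of recorded samples (while the array was
#' on screen) with a missing gaze coordinate; per participant, the mean of
#' those trial proportions; excluded are participants whose mean lies
#' strictly above the group mean plus two (sample, n-1) standard deviations.
#' Trials with zero recorded samples carry no information about tracking
#' quality and are skipped in the per-participant mean.
#'
#' @param d A [gaze_dataset()] with at least two participants.
#' @return A list of class `exclusion_report`: `per_participant` (data frame
#'   `participant_id`, `missing_proportion`), `group_mean`, `group_sd`,
#'   `threshold`, `excluded` (character vector of participant ids).
#' @export
exclude_participants <- function(d) {
  prop_trial <- vapply(d$traces, function(tr) {
    if (nrow(tr) == 0L) return(NA_real_)
    mean(is.na(tr$x) | is.na(tr$y))
  }, 0)
  per <- tapply(prop_trial, d$trials$participant_id,
                function(p) mean(p, na.rm = TRUE))
  if (length(per) < 2L)
    stop("exclusion threshold needs at least two participants")
  props <- as.numeric(per)
  m <- mean(props)
  s <- stats::sd(props)
  thr <- m + 2 * s
  excluded <- names(per)[props > thr]
  structure(list(per_participant = data.frame(participant_id = names(per),
                                              missing_proportion = props,
                                              row.names = NULL),
                 group_mean = m, group_sd = s, threshold = thr,
                 excluded = excluded),
            class = "exclusion_report")
}

#' Drop excluded participants from a dataset
#'
#' @param d A [gaze_dataset()].
#' @param report An `exclusion_report` from [exclude_participants()].
#' @return The dataset without the excluded participants' trials.
#' @export
apply_exclusions <- function(d, report) {
  keep <- !(d$trials$participant_id %in% report$excluded)
  gaze_dataset(d$geometry, d$trials[keep, , drop = FALSE], d$traces[keep])
}
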