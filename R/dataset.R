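#' In-memory gaze dataset
#'
#' Bundles the array geometry, a per-trial metadata table and one raw gaze
#' trace per trial. Traces hold the samples recorded while the search array
#' was on screen (500 Hz, i.e. one sample per 2 ms); missing samples (eye
#' not tracked) are `NA`. Trials are kept sorted by
#' `(participant_id, trial_index)` and `traces[[i]]` belongs to `trials[i, ]`.
#'
#' @param geometry An [array_geometry()].
#' @param trials Data frame with columns `participant_id`, `trial_index`,
#'   `target_location` (0-5), `distractor_location` (0-5 or `NA` when no
#'   color-singleton distractor was shown), `rt_ms` (`NA` if no response),
#'   `n_recorded_samples`.
#' @param traces List of data frames with numeric columns `x`, `y`
#'   (pixels, `NA` = missing sample), one per trial row.
#' @return An object of class `gaze_dataset`.
#' @export
gaze_dataset <- function(geometry, trials, traces) {
  stopifnot(inherits(geometry, "array_geometry"), is.data.frame(trials),
            is.list(traces))
  req <- c("participant_id", "trial_index", "target_location",
           "distractor_location", "rt_ms", "n_recorded_samples")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table is missing required column(s): ", paste(miss, collapse = ", "))
  if (length(traces) != nrow(trials))
    stop("need exactly one trace per trial row (", nrow(trials), " trials, ",
         length(traces), " traces)")
  ord <- order(trials$participant_id, trials$trial_index)
  trials <- trials[ord, , drop = FALSE]
  traces <- traces[ord]
  rownames(trials) <- NULL
  if (anyDuplicated(trials[c("participant_id", "trial_index")]))
    stop("trial_index must be unique within participant")
  bad <- !is.na(trials$distractor_location) &
    trials$distractor_location == trials$target_location
  if (any(bad))
    stop("distractor_location equals target_location on ", sum(bad), " trial(s)")
  if (any(trials$target_location < 0 | trials$target_location > 5))
    stop("target_location must be in 0-5")
  structure(list(geometry = geometry, trials = trials, traces = traces),
            class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat("<gaze_dataset> ", nrow(x$trials), " trials, ",
      length(unique(x$trials$participant_id)), " participants, ",
      x$geometry$meridian, "-meridian array\n", sep = "")
  invisible(x)
}

trial_key <- function(participant_id, trial_index) {
  paste(participant_id, trial_index, sep = "\r")
}

#' Read a gaze dataset from the CSV interchange pair
#'
#' `meta_file` holds one row per trial
#' (`participant_id,trial_index,target_location,distractor_location,rt_ms,n_recorded_samples`;
#' an absent distractor is an empty cell). `trace_file` holds one row per
#' recorded sample (`participant_id,trial_index,sample_index,x,y`;
#' `sample_index` is 0-based and a missing gaze coordinate is an empty cell).
#'
#' @param trace_file,meta_file Paths to the two CSV files.
#' @param geometry Geometry to attach; defaults to [default_geometry()].
#' @return A [gaze_dataset()].
#' @export
read_dataset <- function(trace_file, meta_file, geometry = default_geometry()) {
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  req_meta <- c("participant_id", "trial_index", "target_location",
                "distractor_location", "rt_ms", "n_recorded_samples")
  miss <- setdiff(req_meta, names(meta))
  if (length(miss))
    stop("metadata file is missing required column(s): ", paste(miss, collapse = ", "))
  tr <- utils::read.csv(trace_file, stringsAsFactors = FALSE)
  req_tr <- c("participant_id", "trial_index", "sample_index", "x", "y")
  miss <- setdiff(req_tr, names(tr))
  if (length(miss))
    stop("trace file is missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in c("target_location", "distractor_location", "rt_ms", "n_recorded_samples"))
    meta[[cc]] <- as.numeric(meta[[cc]])
  meta <- meta[order(meta$participant_id, meta$trial_index), , drop = FALSE]
  keys <- trial_key(meta$participant_id, meta$trial_index)
  tkeys <- trial_key(tr$participant_id, tr$trial_index)
  unknown <- !(tkeys %in% keys)
  if (any(unknown))
    stop("trace file references trial(s) absent from the metadata: e.g. ",
         "participant ", tr$participant_id[which(unknown)[1]], ", trial ",
         tr$trial_index[which(unknown)[1]])
  grp <- split(tr[order(match(tkeys, keys), tr$sample_index),
                  c("x", "y", "sample_index")],
               factor(tkeys[order(match(tkeys, keys), tr$sample_index)], levels = keys))
  traces <- lapply(seq_along(keys), function(i) {
    gi <- grp[[i]]
    if (is.null(gi) || nrow(gi) == 0L)
      return(data.frame(x = numeric(0), y = numeric(0)))
    data.frame(x = as.numeric(gi$x), y = as.numeric(gi$y))
  })
  n_tr <- vapply(traces, nrow, 0L)
  if (any(n_tr != meta$n_recorded_samples))
    stop("trace length disagrees with n_recorded_samples for ",
         sum(n_tr != meta$n_recorded_samples), " trial(s)")
  gaze_dataset(geometry, meta, traces)
}

#' Write a gaze dataset to the CSV interchange pair
#'
#' Inverse of [read_dataset()]: finite values and `NA` markers round-trip
#' losslessly (`NA` is written as an empty cell, coordinates with enough
#' significant digits to reproduce the double exactly).
#'
#' @param d A [gaze_dataset()].
#' @param trace_file,meta_file Output paths.
#' @export
write_dataset <- function(d, trace_file, meta_file) {
  stopifnot(inherits(d, "gaze_dataset"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  meta <- d$trials[c("participant_id", "trial_index", "target_location",
                     "distractor_location", "rt_ms", "n_recorded_samples")]
  meta$rt_ms <- fmt(meta$rt_ms)
  utils::write.csv(meta, meta_file, row.names = FALSE, na = "", quote = FALSE)
  n <- vapply(d$traces, nrow, 0L)
  tr <- data.frame(
    participant_id = rep(d$trials$participant_id, n),
    trial_index = rep(d$trials$trial_index, n),
    sample_index = unlist(lapply(n, function(k) seq_len(k) - 1L), use.names = FALSE),
    x = fmt(unlist(lapply(d$traces, `[[`, "x"), use.names = FALSE)),
    y = fmt(unlist(lapply(d$traces, `[[`, "y"), use.names = FALSE)))
  utils::write.csv(tr, trace_file, row.names = FALSE, na = "", quote = FALSE)
  invisible(NULL)
}
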