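# First-saccade landing heuristic: the traditional comparator for the
# classifier. Velocity-based detection is provided for synthetic or
# re-exported data; vendor-parsed saccade events can be supplied verbatim
# instead (see first_saccade_events).

#' Detect the first saccade in a fixed-length trace
#'
#' A saccade is the first run of at least `min_duration` samples whose
#' gaze speed (central difference, pixels per sample) exceeds
#' `velocity_threshold`. The landing point is the gaze at the run's last
#' sample. At 500 Hz the defaults (speed > 1 px/sample sustained for 5
#' samples) correspond to 250 px/s for 10 ms.
#'
#' @param trace Data frame `x`, `y` with no missing samples.
#' @param velocity_threshold Speed threshold, pixels/sample.
#' @param min_duration Minimum run length, samples.
#' @return A list `(onset_sample, offset_sample, landing_x, landing_y,
#'   peak_velocity)` with 1-based sample indices, or `NULL` if no saccade is
#'   found.
#' @export
detect_first_saccade <- function(trace, velocity_threshold = 1.0,
                                 min_duration = 5L) {
  n <- nrow(trace)
  if (n < 3L) return(NULL)
  if (anyNA(trace$x) || anyNA(trace$y))
    stop("trace contains missing samples; run fill_missing() first")
  vx <- (trace$x[3:n] - trace$x[1:(n - 2)]) / 2
  vy <- (trace$y[3:n] - trace$y[1:(n - 2)]) / 2
  speed <- c(0, sqrt(vx^2 + vy^2), 0)   # speed undefined at the ends
  fast <- speed > velocity_threshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_duration)
  if (!length(hit)) return(NULL)
  onset <- starts[hit[1L]]
  offset <- ends[hit[1L]]
  list(onset_sample = onset, offset_sample = offset,
       landing_x = trace$x[offset], landing_y = trace$y[offset],
       peak_velocity = max(speed[onset:offset]))
}

#' First-saccade events for every trial of a dataset
#'
#' Runs [fill_missing()] and [detect_first_saccade()] over all trials.
#' Pre-parsed events (e.g. from a vendor parser) can be substituted for any
#' downstream use as a data frame
#' `participant_id,trial_index,onset_sample,landing_x,landing_y`.
#'
#' @param d A [gaze_dataset()].
#' @param ... Passed to [detect_first_saccade()].
#' @return A list of events (or `NULL`) aligned with `d$trials`.
#' @export
first_saccade_events <- function(d, ...) {
  lapply(d$traces, function(tr) {
    if (nrow(tr) == 0L) return(NULL)
    detect_first_saccade(fill_missing(tr, d$geometry), ...)
  })
}

#' Assign a screen point to one of six pie-shaped chunks
#'
#' The array is divided into six 60-degree wedges, each centered on a
#' candidate stimulus location; a point belongs to the wedge whose half-open
#' angular interval `[angle - 30, angle + 30)` contains its polar angle
#' around the screen center (radius is ignored).
#'
#' @param x,y Point in screen pixels (vectorized); must not be exactly the
#'   center.
#' @param g An [array_geometry()].
#' @return Integer location indices 0-5.
#' @export
assign_chunk <- function(x, y, g) {
  dx <- x - g$center_x
  dy <- -(y - g$center_y)              # y grows downward on screen
  if (any(dx == 0 & dy == 0))
    stop("point at the exact array center has no defined polar angle")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  th0 <- g$location_angles[1L]          # smallest angle; location index 0
  idx <- floor(((ang - th0 + 30) %% 360) / 60)
  as.integer(idx)
}

#' Per-participant first-saccade-to-distractor rate
#'
#' Over distractor-present trials that contain eye data and a detected
#' saccade, the fraction whose first saccade lands in the distractor's
#' chunk. Participants with no qualifying trials are omitted with a warning.
#'
#' @param d A [gaze_dataset()] (distractor-present trials are selected
#'   internally).
#' @param events Per-trial events aligned with `d$trials`, e.g. from
#'   [first_saccade_events()].
#' @return Data frame `participant_id, n_saccade_trials, n_distractor_landings,
#'   rate`, plus attribute `qualifying` (logical over `d$trials`) marking the
#'   trials that entered a denominator.
#' @export
first_saccade_distractor_rate <- function(d, events) {
  stopifnot(length(events) == nrow(d$trials))
  present <- !is.na(d$trials$distractor_location)
  has_ev <- !vapply(events, is.null, TRUE)
  qual <- present & has_ev
  landed <- rep(FALSE, nrow(d$trials))
  qi <- which(qual)
  if (length(qi)) {
    lx <- vapply(events[qi], `[[`, 0, "landing_x")
    ly <- vapply(events[qi], `[[`, 0, "landing_y")
    chunk <- safe_chunk(lx, ly, d$geometry)  # NA: landing at exact center
    landed[qi] <- !is.na(chunk) & chunk == d$trials$distractor_location[qi]
  }
  pids <- unique(d$trials$participant_id[present])
  rows <- lapply(pids, function(p) {
    sel <- qual & d$trials$participant_id == p
    if (!any(sel)) return(NULL)
    data.frame(participant_id = p, n_saccade_trials = sum(sel),
               n_distractor_landings = sum(landed[sel]),
               rate = sum(landed[sel]) / sum(sel))
  })
  dropped <- pids[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("no distractor-present trials with a detected saccade for: ",
            paste(dropped, collapse = ", "), "; participant(s) omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "qualifying") <- qual
  out
}

#' Chunk assignment tolerating exact-center points
#'
#' Like [assign_chunk()] but returns `NA` for points at the exact array
#' center (which can arise when a fixation-filled sample is a saccade's
#' landing) instead of raising an error.
#'
#' @inheritParams assign_chunk
#' @return Integer location indices 0-5, `NA` at the exact center.
#' @export
safe_chunk <- function(x, y, g) {
  central <- x == g$center_x & y == g$center_y
  out <- rep(NA_integer_, length(x))
  if (any(!central))
    out[!central] <- assign_chunk(x[!central], y[!central], g)
  out
}

#' Minimum-mean-distance location baseline
#'
#' The simple fixed algorithm for target identification: for each of the six
#' candidate locations, the mean Euclidean distance from every sample of the
#' trace to that location's center; the location with the smallest mean wins
#' (ties to the lowest index).
#'
#' @param trace Data frame `x`, `y`, fully observed.
#' @param g An [array_geometry()].
#' @return Integer location index 0-5.
#' @export
min_mean_distance_baseline <- function(trace, g) {
  if (anyNA(trace$x) || anyNA(trace$y))
    stop("trace contains missing samples; run fill_missing() first")
  loc <- location_coords(g)
  md <- vapply(seq_len(6L), function(i)
    mean(sqrt((trace$x - loc[i, 1L])^2 + (trace$y - loc[i, 2L])^2)), 0)
  # ties (e.g. a trace parked at the equidistant center) go to the lowest
  # index; tolerate floating-point jitter when deciding what ties
  as.integer(which(md - min(md) <= 1e-9 * max(md, 1))[1L] - 1L)
}
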