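#' Every-third-trial train/validation split
#'
#' Within each participant, trials are ranked in presentation order
#' (ascending `trial_index`); every third trial (1-based ranks divisible by
#' 3) forms the validation set and the rest the training set, giving the
#' two-thirds/one-third split exactly when trial counts are divisible by 3.
#'
#' @param trials Trial table (`participant_id`, `trial_index`, ...).
#' @return A list of class `split_index` with data frames `train` and `val`
#'   (`participant_id`, `trial_index`) and an `assignments` frame adding a
#'   `role` column.
#' @export
split_every_third <- function(trials) {
  stopifnot(all(c("participant_id", "trial_index") %in% names(trials)))
  ord <- order(trials$participant_id, trials$trial_index)
  t2 <- trials[ord, c("participant_id", "trial_index"), drop = FALSE]
  rank <- stats::ave(seq_len(nrow(t2)), t2$participant_id, FUN = seq_along)
  role <- ifelse(rank %% 3L == 0L, "val", "train")
  assignments <- data.frame(t2, role = role, row.names = NULL)
  structure(list(train = assignments[assignments$role == "train", 1:2],
                 val = assignments[assignments$role == "val", 1:2],
                 assignments = assignments),
            class = "split_index")
}

#' Keep only distractor-present trials
#'
#' @param trials Trial table.
#' @return The rows with a non-missing `distractor_location`, order preserved.
#' @export
subset_distractor_present <- function(trials) {
  trials[!is.na(trials$distractor_location), , drop = FALSE]
}

#' Mini-batch plan
#'
#' Partitions `n` trial positions into consecutive batches of `batch_size`
#' (the last batch takes the remainder), optionally after a seeded
#' permutation. The plan always covers every position exactly once.
#'
#' @param n Number of trials (>= 1).
#' @param batch_size Batch size; 64 matches the training defaults.
#' @param shuffle_seed `NULL` for presentation order, or an integer seeding a
#'   reproducible permutation (the global RNG stream is left untouched).
#' @return A list of integer vectors of positions; `ceiling(n / batch_size)`
#'   batches in total.
#' @export
make_minibatches <- function(n, batch_size = 64L, shuffle_seed = NULL) {
  if (n < 1L) stop("need at least one trial to batch")
  stopifnot(batch_size >= 1L)
  idx <- seq_len(n)
  if (!is.null(shuffle_seed)) {
    rng <- local_rng(shuffle_seed)
    on.exit(restore_rng(rng))
    idx <- sample(idx)
  }
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Save the global RNG state and reseed; restore_rng() puts it back.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Map a split_index onto a trace_tensor's trial order -> integer row indices.
split_rows <- function(split, tensor) {
  keys <- trial_key(tensor$trial_order$participant_id, tensor$trial_order$trial_index)
  tr <- match(trial_key(split$train$participant_id, split$train$trial_index), keys)
  va <- match(trial_key(split$val$participant_id, split$val$trial_index), keys)
  tr <- tr[!is.na(tr)]
  va <- va[!is.na(va)]
  if (length(tr) + length(va) == 0L)
    stop("split does not reference any trial present in the tensor")
  list(train = tr, val = va)
}
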