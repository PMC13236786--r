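#' Chance accuracy for a six-location array
#' @return 1/6.
#' @export
chance_level <- function() 1 / 6

#' Score predictions against labels
#'
#' @param preds Integer predicted locations (0-5).
#' @param labels Integer true locations (0-5).
#' @param trials Data frame aligned with `preds` carrying `participant_id`
#'   (a `trial_order` frame works).
#' @return A list of class `accuracy_report`: `overall_accuracy`,
#'   `per_participant` (data frame `participant_id,n_correct,n_trials,accuracy`),
#'   `trial_outcomes` (logical), `confusion` (6 x 6 counts, rows = true
#'   location, columns = predicted).
#' @export
score <- function(preds, labels, trials) {
  if (length(preds) != length(labels) || length(preds) != nrow(trials))
    stop("preds, labels and trials must have matching lengths")
  correct <- preds == labels
  per <- aggregate(correct, by = list(participant_id = trials$participant_id),
                   FUN = function(z) c(sum(z), length(z)))
  pp <- data.frame(participant_id = per$participant_id,
                   n_correct = per$x[, 1L], n_trials = per$x[, 2L])
  pp$accuracy <- pp$n_correct / pp$n_trials
  confusion <- table(factor(labels, levels = 0:5), factor(preds, levels = 0:5))
  structure(list(overall_accuracy = mean(correct), per_participant = pp,
                 trial_outcomes = correct,
                 confusion = unclass(confusion)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> overall ", sprintf("%.2f%%", 100 * x$overall_accuracy),
      " over ", length(x$trial_outcomes), " trials, ",
      nrow(x$per_participant), " participants\n", sep = "")
  invisible(x)
}

#' Participant-level percentile bootstrap confidence interval
#'
#' Resamples participants with replacement, takes the mean of their
#' accuracies per replicate, and reports percentile bounds.
#'
#' @param per_participant_acc Numeric vector of participant accuracies.
#' @param n_boot Bootstrap replicates (10,000 by default).
#' @param seed Integer seed (the global RNG stream is left untouched).
#' @param level Coverage level.
#' @return A list of class `interval_estimate`: `mean`, `lower`, `upper`,
#'   `level`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(per_participant_acc, n_boot = 10000L, seed = 1L,
                         level = 0.95) {
  if (length(per_participant_acc) < 1L)
    stop("need at least one participant accuracy")
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n <- length(per_participant_acc)
  reps <- vapply(seq_len(n_boot),
                 function(i) mean(per_participant_acc[sample.int(n, n, replace = TRUE)]),
                 0)
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(mean = mean(per_participant_acc), lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, seed = seed),
            class = "interval_estimate")
}

#' One-sample t-test of participant accuracies against chance
#'
#' @param per_participant_acc Numeric vector (>= 2 participants, nonzero
#'   variance).
#' @param chance Chance level, 1/6 for six locations.
#' @return List `(t, df, p, mean)`; `p` is two-sided.
#' @export
t_vs_chance <- function(per_participant_acc, chance = chance_level()) {
  if (length(per_participant_acc) < 2L)
    stop("t-test needs at least two participants")
  if (stats::sd(per_participant_acc) == 0)
    stop("zero variance across participants: t statistic undefined")
  ht <- stats::t.test(per_participant_acc, mu = chance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(per_participant_acc))
}

#' Paired t-test between two per-participant accuracy vectors
#'
#' Tests e.g. classifier accuracy against the first-saccade heuristic rate
#' on the same participants, and attaches a participant-level bootstrap CI
#' of the mean difference.
#'
#' @param acc_a,acc_b Numeric vectors over the same participants, in the
#'   same order (give them names to have the pairing checked).
#' @param n_boot,seed Passed to [bootstrap_ci()] for the difference CI.
#' @return List `(t, df, p, mean_diff, diff_ci)`.
#' @export
paired_t <- function(acc_a, acc_b, n_boot = 10000L, seed = 1L) {
  if (length(acc_a) != length(acc_b))
    stop("paired comparison needs the same participants in both vectors")
  if (!is.null(names(acc_a)) && !is.null(names(acc_b)) &&
      !identical(names(acc_a), names(acc_b)))
    stop("participant names disagree between the two accuracy vectors")
  diffs <- acc_a - acc_b
  if (stats::sd(diffs) == 0 && mean(diffs) == 0) {
    ht <- list(statistic = c(t = 0), parameter = c(df = length(diffs) - 1L),
               p.value = 1)
  } else {
    ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  }
  ci <- bootstrap_ci(diffs, n_boot = n_boot, seed = seed)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(diffs), diff_ci = ci)
}
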