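test_that("missing samples are replaced by the fixation coordinate", {
  g <- default_geometry(2560, 1440)
  tr <- data.frame(x = c(NA, 100, NA), y = c(50, NA, NA))
  f <- fill_missing(tr, g)
  expect_equal(f$x, c(1279.5, 100, 1279.5))
  expect_equal(f$y, c(50, 719.5, 719.5))
  # fully observed trace is untouched
  tr2 <- data.frame(x = c(1, 2), y = c(3, 4))
  expect_identical(fill_missing(tr2, g), tr2)
  # fully missing trace becomes constant fixation
  tr3 <- data.frame(x = rep(NA_real_, 5), y = rep(NA_real_, 5))
  f3 <- fill_missing(tr3, g)
  expect_equal(f3$x, rep(1279.5, 5))
  expect_equal(f3$y, rep(719.5, 5))
})

test_that("padding and truncation produce exactly L samples", {
  g <- default_geometry(2560, 1440)
  short <- data.frame(x = rnorm(550, 1000), y = rnorm(550, 700))
  p <- pad_or_truncate(short, 600L, g)
  expect_equal(nrow(p), 600L)
  expect_equal(p$x[551:600], rep(1279.5, 50))
  expect_equal(p$y[551:600], rep(719.5, 50))
  expect_equal(p[1:550, ], short, ignore_attr = TRUE)
  exact <- data.frame(x = rnorm(600), y = rnorm(600))
  expect_equal(pad_or_truncate(exact, 600L, g), exact, ignore_attr = TRUE)
  long <- data.frame(x = rnorm(603), y = rnorm(603))
  tr <- pad_or_truncate(long, 600L, g)
  expect_equal(tr, long[1:600, ], ignore_attr = TRUE)
  expect_error(pad_or_truncate(exact, 0L, g), "positive")
  expect_error(pad_or_truncate(data.frame(x = NA_real_, y = 1), 5L, g), "missing")
})

test_that("fill and pad commute on fully observed traces", {
  g <- default_geometry()
  tr <- data.frame(x = rnorm(120, 1200), y = rnorm(120, 700))
  a <- pad_or_truncate(fill_missing(tr, g), 200L, g)
  b <- fill_missing(pad_or_truncate(tr, 200L, g), g)
  expect_equal(a, b)
})

test_that("assemble builds the (trials, features, samples) tensor with aligned labels", {
  g <- toy_geometry()
  set.seed(3)
  n <- 5L
  trials <- data.frame(participant_id = "p", trial_index = 1:n,
                       target_location = c(4L, 0L, 2L, 5L, 1L),
                       distractor_location = c(1L, 2L, NA, 0L, 3L),
                       rt_ms = 500, n_recorded_samples = 8L)
  traces <- lapply(1:n, function(i) data.frame(x = rnorm(8, i * 10), y = rnorm(8, -i)))
  tens <- assemble(traces, trials, "target")
  expect_equal(dim(tens$values), c(5L, 2L, 8L))
  expect_equal(tens$labels, c(4L, 0L, 2L, 5L, 1L))
  # tensor rows follow the trial order, checked by direct bookkeeping
  for (i in 1:n) {
    expect_equal(tens$values[i, 1L, ], traces[[i]]$x)
    expect_equal(tens$values[i, 2L, ], traces[[i]]$y)
  }
  expect_error(assemble(traces, trials, "distractor"), "distractor-present")
  tens2 <- assemble(traces[-3], trials[-3, ], "distractor")
  expect_equal(tens2$labels, c(1L, 2L, 0L, 3L))
})

test_that("after preprocessing every value is finite with 600 samples per feature", {
  d <- generate_dataset(synth_config(n_participants = 2L, trials_per_participant = 6L,
                                     missing_rate = 0.2, seed = 9))
  tens <- preprocess_dataset(d, "target")
  expect_equal(dim(tens$values), c(12L, 2L, 600L))
  expect_true(all(is.finite(tens$values)))
})

test_that("exclusion threshold follows the mean + 2 SD rule with sample SD", {
  g <- toy_geometry()
  props <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.9)
  len <- 10L
  traces <- lapply(props, function(p) {
    nmiss <- round(p * len)
    data.frame(x = c(rep(NA_real_, nmiss), rep(g$center_x, len - nmiss)),
               y = rep(g$center_y, len))
  })
  trials <- data.frame(participant_id = sprintf("P%02d", 1:10), trial_index = 1L,
                       target_location = 0L, distractor_location = NA_integer_,
                       rt_ms = 100, n_recorded_samples = len)
  d <- gaze_dataset(g, trials, traces)
  rep_ <- exclude_participants(d)
  expect_equal(rep_$group_mean, 0.18)
  expect_equal(rep_$group_sd, sd(props))
  expect_equal(rep_$threshold, 0.18 + 2 * sd(props))
  expect_equal(rep_$excluded, "P10")
  d2 <- apply_exclusions(d, rep_)
  expect_false("P10" %in% d2$trials$participant_id)
})

test_that("identical missing proportions exclude nobody (strict inequality)", {
  g <- toy_geometry()
  traces <- lapply(1:4, function(i)
    data.frame(x = c(NA, rep(g$center_x, 9)), y = rep(g$center_y, 10)))
  trials <- data.frame(participant_id = letters[1:4], trial_index = 1L,
                       target_location = 0L, distractor_location = NA_integer_,
                       rt_ms = 100, n_recorded_samples = 10L)
  rep_ <- exclude_participants(gaze_dataset(g, trials, traces))
  expect_equal(rep_$group_sd, 0)
  expect_length(rep_$excluded, 0L)
})

test_that("exclusion report is invariant to participant ordering", {
  d <- generate_dataset(synth_config(n_participants = 5L, trials_per_participant = 8L,
                                     missing_rate = 0.1, seed = 4))
  r1 <- exclude_participants(d)
  perm <- order(rev(seq_len(nrow(d$trials))))
  d2 <- gaze_dataset(d$geometry, d$trials[perm, ], d$traces[perm])
  r2 <- exclude_participants(d2)
  expect_equal(r1$threshold, r2$threshold)
  expect_equal(sort(r1$excluded), sort(r2$excluded))
})
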