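test_that("a fixation-only trace has no detectable saccade", {
  g <- toy_geometry()
  tr <- data.frame(x = rep(g$center_x, 100), y = rep(g$center_y, 100))
  expect_null(detect_first_saccade(tr))
  # small jitter below threshold still yields nothing
  set.seed(21)
  tr2 <- data.frame(x = g$center_x + rnorm(100, 0, 0.2),
                    y = g$center_y + rnorm(100, 0, 0.2))
  expect_null(detect_first_saccade(tr2))
})

test_that("a constructed saccade is detected with its landing point", {
  g <- default_geometry()
  loc <- location_coords(g)
  # smooth 15-sample transition from center to location 2
  ramp <- c(rep(0, 40), seq(0, 1, length.out = 15), rep(1, 45))
  tr <- data.frame(x = g$center_x + ramp * (loc[3, 1] - g$center_x),
                   y = g$center_y + ramp * (loc[3, 2] - g$center_y))
  ev <- detect_first_saccade(tr)
  expect_false(is.null(ev))
  expect_lt(abs(ev$landing_x - loc[3, 1]), 1)
  expect_lt(abs(ev$landing_y - loc[3, 2]), 1)
  expect_lt(ev$onset_sample, ev$offset_sample)
  expect_gt(ev$peak_velocity, 1)
  expect_error(detect_first_saccade(data.frame(x = c(1, NA, 3), y = 1:3)),
               "missing")
})

test_that("points map to the wedge containing them, 60 per wedge", {
  g <- default_geometry()  # horizontal: angles 0, 60, ..., 300
  loc <- location_coords(g)
  for (i in 1:6)
    expect_equal(assign_chunk(loc[i, 1], loc[i, 2], g), i - 1L)
  expect_equal(assign_chunk(g$center_x + 1e-6, g$center_y, g), 0L)
  # exhaustive enumeration: 360 points at 1-degree spacing
  ang <- (0:359) + 0.5                  # avoid exact boundaries
  px <- g$center_x + 100 * cos(ang * pi / 180)
  py <- g$center_y - 100 * sin(ang * pi / 180)
  idx <- assign_chunk(px, py, g)
  expect_equal(unname(table(idx)), rep(60L, 6), ignore_attr = TRUE)
  expect_error(assign_chunk(g$center_x, g$center_y, g), "no defined polar angle")
})

test_that("chunk assignment is rotation-equivariant under 60-degree steps", {
  g <- default_geometry()
  set.seed(22)
  px <- g$center_x + rnorm(50, 0, 200)
  py <- g$center_y + rnorm(50, 0, 200)
  keep <- !(px == g$center_x & py == g$center_y)
  base <- assign_chunk(px[keep], py[keep], g)
  rot <- rotate_point(px[keep], py[keep], g, 0, 60)
  expect_equal(assign_chunk(rot[, 1], rot[, 2], g), (base + 1L) %% 6L)
})

test_that("distractor-landing rate matches a hand count", {
  g <- default_geometry()
  loc <- location_coords(g)
  # participant with 10 distractor-present trials: 8 detected saccades of
  # which 3 land in the distractor chunk, 2 trials without a saccade
  mk_trace <- function(to_xy) {
    ramp <- c(rep(0, 30), seq(0, 1, length.out = 12), rep(1, 30))
    data.frame(x = g$center_x + ramp * (to_xy[1] - g$center_x),
               y = g$center_y + ramp * (to_xy[2] - g$center_y))
  }
  flat <- data.frame(x = rep(g$center_x, 72), y = rep(g$center_y, 72))
  distr <- 2L
  traces <- c(lapply(1:3, function(i) mk_trace(loc[distr + 1L, ])),
              lapply(1:5, function(i) mk_trace(loc[5, ])),
              list(flat, flat))
  trials <- data.frame(participant_id = "p1", trial_index = 1:10,
                       target_location = 4L, distractor_location = distr,
                       rt_ms = 800, n_recorded_samples = 72L)
  d <- gaze_dataset(g, trials, traces)
  ev <- first_saccade_events(d)
  r <- first_saccade_distractor_rate(d, ev)
  expect_equal(r$n_saccade_trials, 8L)
  expect_equal(r$n_distractor_landings, 3L)
  expect_equal(r$rate, 0.375)
  # all saccades to the target: rate 0
  traces0 <- lapply(1:4, function(i) mk_trace(loc[5, ]))
  d0 <- gaze_dataset(g, trials[1:4, ], traces0)
  r0 <- first_saccade_distractor_rate(d0, first_saccade_events(d0))
  expect_equal(r0$rate, 0)
})

test_that("uniform-angle landings hit the distractor chunk at the 1/6 chance rate", {
  set.seed(23)
  g <- default_geometry()
  ang <- runif(6000, 0, 360)
  idx <- assign_chunk(g$center_x + 150 * cos(ang * pi / 180),
                      g$center_y - 150 * sin(ang * pi / 180), g)
  expect_equal(mean(idx == 3L), 1 / 6, tolerance = 0.03)
})

test_that("generator capture probability is recovered by the detector", {
  d <- generate_dataset(synth_config(n_participants = 10L,
                                     trials_per_participant = 60L,
                                     capture_prob = 0.3, missing_rate = 0,
                                     seed = 24L))
  # velocity threshold matched to the generator noise (12-px samples give
  # ~10 px/sample fixation speeds; synthetic saccades peak near 40-60)
  ev <- first_saccade_events(d, velocity_threshold = 20)
  r <- first_saccade_distractor_rate(d, ev)
  pooled <- sum(r$n_distractor_landings) / sum(r$n_saccade_trials)
  expect_lt(abs(pooled - 0.3), 0.05)
  # zero capture: first saccades almost never land on the distractor
  d0 <- generate_dataset(synth_config(n_participants = 6L,
                                      trials_per_participant = 40L,
                                      capture_prob = 0, missing_rate = 0,
                                      seed = 25L))
  r0 <- first_saccade_distractor_rate(d0, first_saccade_events(d0, velocity_threshold = 20))
  expect_lt(sum(r0$n_distractor_landings) / sum(r0$n_saccade_trials), 0.05)
})

test_that("min-mean-distance baseline identifies dwelled-on locations", {
  g <- default_geometry()
  loc <- location_coords(g)
  parked <- data.frame(x = rep(loc[4, 1], 50), y = rep(loc[4, 2], 50))
  expect_equal(min_mean_distance_baseline(parked, g), 3L)
  central <- data.frame(x = rep(g$center_x, 50), y = rep(g$center_y, 50))
  expect_equal(min_mean_distance_baseline(central, g), 0L)  # six-way tie
  # two-segment trace: 20 samples at center then 40 at location 2; the
  # argmin follows the direct distance computation
  seg <- data.frame(x = c(rep(g$center_x, 20), rep(loc[3, 1], 40)),
                    y = c(rep(g$center_y, 20), rep(loc[3, 2], 40)))
  md <- sapply(1:6, function(i)
    mean(sqrt((seg$x - loc[i, 1])^2 + (seg$y - loc[i, 2])^2)))
  expect_equal(min_mean_distance_baseline(seg, g), which.min(md) - 1L)
  expect_equal(min_mean_distance_baseline(seg, g), 2L)
})
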