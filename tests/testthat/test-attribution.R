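make_explained_toy <- function(seed = 26L, nb = 6L, nq = 5L) {
  set.seed(seed)
  cfg <- tiny_config(input_length = 16L, n_classes = 4L)
  m <- init_network(cfg)
  bg <- array(rnorm(nb * 2 * 16), c(nb, 2, 16))
  qs <- array(rnorm(nq * 2 * 16), c(nq, 2, 16))
  list(model = m, bg = bg, qs = qs, a = explain(m, bg, qs))
}

test_that("attributions satisfy the completeness contract", {
  fx <- make_explained_toy()
  sums <- apply(fx$a$values, c(1, 4), sum)
  target <- sweep(fx$a$query_outputs, 2, fx$a$baseline_outputs)
  expect_lt(max(abs(sums - target) / pmax(abs(target), 1)), 1e-8)
})

test_that("a constant (all-zero-weight) model attributes nothing", {
  fx <- make_explained_toy()
  m <- fx$model
  for (i in seq_along(m$layers))
    if (!is.null(m$layers[[i]]$W)) { m$layers[[i]]$W[] <- 0; m$layers[[i]]$b[] <- 0 }
  a <- explain(m, fx$bg, fx$qs)
  expect_equal(max(abs(a$values)), 0)
})

test_that("a linear surrogate reproduces the closed-form Shapley values", {
  set.seed(27)
  W <- matrix(rnorm(3 * 24), 3)
  b <- rnorm(3)
  lin <- new_gaze_cnn(list(gazecnn:::layer_flatten(), gazecnn:::layer_linear(W, b)),
                      list(input_length = 12L, in_channels = 2L, n_classes = 3L))
  bg <- array(rnorm(7 * 2 * 12), c(7, 2, 12))
  qs <- array(rnorm(4 * 2 * 12), c(4, 2, 12))
  a <- explain(lin, bg, qs)
  flat <- function(arr, i) as.vector(gazecnn:::to_cmat(arr[i, , , drop = FALSE]))
  bg_mean <- rowMeans(sapply(seq_len(7), function(i) flat(bg, i)))
  for (i in 1:4) for (cls in 1:3) {
    phi <- W[cls, ] * (flat(qs, i) - bg_mean)
    dim(phi) <- c(2L, 12L)
    expect_equal(a$values[i, , , cls], phi, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("attribution is deterministic given model and inputs", {
  fx <- make_explained_toy()
  a2 <- explain(fx$model, fx$bg, fx$qs)
  expect_identical(fx$a$values, a2$values)
})

test_that("global importance is the mean absolute value over feature-class cells", {
  fx <- make_explained_toy()
  gi <- global_importance(fx$a, fx$qs)
  brute <- apply(abs(fx$a$values), c(1, 3), mean)
  expect_equal(gi$values, brute)
  # a single nonzero cell of magnitude 12 gives importance 12 / cells
  a0 <- fx$a
  a0$values[] <- 0
  a0$values[1, 1, 8, 3] <- 12
  gi0 <- global_importance(a0, fx$qs)
  ncells <- dim(a0$values)[2] * dim(a0$values)[4]
  expect_equal(gi0$values[1, 8], 12 / ncells)
  expect_equal(gi0$argmax_sample[1], 7L)          # 0-based
  expect_equal(gi0$argmax_sample[2], 0L)          # all-zero row: tie to 0
  expect_equal(gi0$argmax_gaze[1, "x"], fx$qs[1, 1, 8], ignore_attr = TRUE)
})

test_that("peak-importance times pair with response times", {
  gi <- structure(list(values = rbind(c(0, 1, 0, 0), c(0, 0, 0, 2)),
                       argmax_sample = c(1L, 3L),
                       argmax_gaze = matrix(0, 2, 2)), class = "global_importance")
  trials <- data.frame(participant_id = c("a", "a"), trial_index = 1:2,
                       rt_ms = c(400, 4))
  r <- max_shap_vs_rt(gi, trials)
  expect_equal(r$table$argmax_time_ms, c(2, 6))
  expect_equal(r$table$after_response, c(FALSE, TRUE))
  expect_equal(r$fraction_before_rt, 0.5)
})

test_that("rotation about the center is a rigid motion", {
  g <- default_geometry()
  p <- rotate_point(1500, 719.5, g, 0, 0)
  expect_equal(as.numeric(p), c(1500, 719.5))
  cc <- rotate_point(g$center_x, g$center_y, g, 10, 170)
  expect_equal(as.numeric(cc), c(g$center_x, g$center_y))
  # +90 degrees counterclockwise in the math frame moves (r, 0) to
  # (0, -r) in y-down pixel coordinates
  r <- 200
  p90 <- rotate_point(g$center_x + r, g$center_y, g, 0, 90)
  expect_equal(as.numeric(p90), c(g$center_x, g$center_y - r))
  # isometry on random point sets
  set.seed(28)
  px <- rnorm(20, g$center_x, 300); py <- rnorm(20, g$center_y, 300)
  rot <- rotate_point(px, py, g, 37, 211)
  d_before <- dist(cbind(px, py))
  d_after <- dist(rot)
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-9)
})

test_that("silverman bandwidth follows sigma-bar times n^(-1/6)", {
  set.seed(29)
  pts <- cbind(rnorm(64, 0, 10), rnorm(64, 5, 10))
  h <- silverman_bandwidth(pts)
  sbar <- mean(c(sd(pts[, 1]), sd(pts[, 2])))
  expect_equal(h, sbar * 64^(-1 / 6))
  # exact arithmetic case: sd 10 in both axes, n = 64 -> h = 5
  z <- scale(pts) * 10
  expect_equal(silverman_bandwidth(z), 10 * 64^(-1 / 6))
  expect_equal(10 * 64^(-1 / 6), 5, tolerance = 1e-12)
  # scaling equivariance and n-monotonicity
  expect_equal(silverman_bandwidth(pts * 3), 3 * h)
  expect_lt(silverman_bandwidth(rbind(pts, pts + 1e-3)), h + 1e-4)
  expect_error(silverman_bandwidth(cbind(rep(1, 5), rep(2, 5))), "zero spread")
})

test_that("kde heatmap integrates to one and peaks at the data", {
  g <- default_geometry(400, 300, eccentricity_px = 80)
  one <- matrix(c(200, 150), 1)
  k <- kde_heatmap(one, h = 25, resolution = 10, g = g)
  expect_equal(max(k$density), 1)
  peak <- which(k$density == max(k$density), arr.ind = TRUE)[1, ]
  expect_lt(abs(k$x[peak[1]] - 200), 10)
  expect_lt(abs(k$y[peak[2]] - 150), 10)
  expect_equal(k$integral_raw, 1, tolerance = 0.02)
  # two distant points of equal weight: two equal peaks
  two <- rbind(c(100, 150), c(300, 150))
  k2 <- kde_heatmap(two, h = 20, resolution = 10, g = g)
  i1 <- which.min(abs(k2$x - 100)); i2 <- which.min(abs(k2$x - 300))
  j <- which.min(abs(k2$y - 150))
  expect_equal(k2$density[i1, j], k2$density[i2, j], tolerance = 1e-6)
  # integral stays near one for a spread cloud
  set.seed(30)
  cloud <- cbind(runif(200, 100, 300), runif(200, 80, 220))
  k3 <- kde_heatmap(cloud, h = silverman_bandwidth(cloud), resolution = 10, g = g)
  expect_equal(k3$integral_raw, 1, tolerance = 0.02)
})

test_that("polar histogram conserves counts and respects bin geometry", {
  g <- default_geometry()
  loc <- location_coords(g)
  # all points at the location-2 angle fall into a single bin
  pts <- matrix(rep(loc[3, ], 7), ncol = 2, byrow = TRUE)
  h <- polar_time_histogram(pts, rep(100, 7), g, n_bins = 6L)
  expect_equal(sum(h$count), 7L)
  expect_equal(h$count[h$bin_center_deg == 120], 7L)
  expect_equal(h$mean_time[h$bin_center_deg == 120], 100)
  # random points: counts conserved, center point excluded with warning
  set.seed(31)
  p2 <- cbind(rnorm(40, g$center_x, 250), rnorm(40, g$center_y, 250))
  p2 <- rbind(p2, c(g$center_x, g$center_y))
  expect_warning(h2 <- polar_time_histogram(p2, seq_len(41), g, 12L), "center")
  expect_equal(sum(h2$count), 40L)
})
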