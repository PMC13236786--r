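# Additive feature attribution for the trained classifier.
#
# For each (query trial, background trial) pair, contributions are formed by
# backpropagating "multipliers" from the logits to the input, DeepLIFT
# style: linear stages (convolution, linear transforms, flatten, inactive
# dropout) propagate multipliers like gradients of the difference; the ReLU
# uses the rescale rule (delta-output over delta-input); max pooling routes
# each pooled unit's multiplier to a single input position (the query's
# argmax where its difference from the background is nonzero, else the
# background's argmax) with the ratio delta-output / delta-input. Every rule
# conserves the summed contribution exactly, so for each class the
# contributions over all input cells sum to logit(query) - logit(background)
# to machine precision; averaging over the background set gives attributions
# against the background-mean output (the completeness/additivity property).

#' Additive attributions for a set of query trials
#'
#' @param model A trained `gaze_cnn` (dropout is inactive during
#'   explanation).
#' @param background Background batch array `(n_b, features, samples)`;
#'   conventionally the first 100 validation trials (or all validation
#'   trials, if fewer).
#' @param queries Query batch array `(n_q, features, samples)`.
#' @param tol Relative completeness tolerance; a violation beyond it aborts
#'   with an attribution error (it would signal an unsupported layer rule).
#' @return A list of class `attribution_tensor`: `values` (array
#'   `n_q x features x samples x classes` of signed contributions),
#'   `baseline_outputs` (mean background logits), `query_outputs`,
#'   `n_background`.
#' @export
explain <- function(model, background, queries, tol = 1e-3) {
  stopifnot(length(dim(background)) == 3L, length(dim(queries)) == 3L)
  nb <- dim(background)[1L]
  nq <- dim(queries)[1L]
  nch <- dim(queries)[2L]
  L <- dim(queries)[3L]
  ncls <- model_n_classes(model)
  fb <- engine_forward(model, background, training = FALSE, keep_cache = TRUE)
  fq <- engine_forward(model, queries, training = FALSE, keep_cache = TRUE)
  plan <- explain_plan(model, fq, ncls)
  bgpre <- lapply(seq_len(nb), function(b) precompute_trial(plan, fb, b))
  vals <- array(0, dim = c(nq, nch, L, ncls))
  for (q in seq_len(nq)) {
    qpre <- precompute_trial(plan, fq, q)
    acc <- 0
    for (b in seq_len(nb)) {
      acc <- acc + pair_contributions(model, plan, qpre, bgpre[[b]], nch, L, ncls)
    }
    vals[q, , , ] <- acc / nb
  }
  baseline <- colMeans(t(fb$out))      # mean background logits, length ncls
  qout <- t(fq$out)                    # nq x ncls
  # completeness check: sum over features and samples ~ f(x) - mean f(b)
  sums <- apply(vals, c(1L, 4L), sum)
  target <- sweep(qout, 2L, baseline)
  resid <- abs(sums - target) / pmax(abs(target), 1)
  if (any(resid > tol))
    stop("attribution completeness violated (max relative residual ",
         format(max(resid), digits = 3), " > ", tol,
         "): a layer rule does not conserve contributions")
  structure(list(values = vals, baseline_outputs = baseline,
                 query_outputs = qout, n_background = nb),
            class = "attribution_tensor")
}

# Pair-independent preparation: the suffix of the stack consisting only of
# linear transforms and the flatten is a fixed linear map, so its
# multipliers (t(W1) t(W2) ... onto each class unit vector) are computed
# once and reshaped to the conv-stage layout; the per-pair loop then starts
# at the first nonlinear (data-dependent) layer below it.
explain_plan <- function(model, fq, ncls) {
  layers <- model$layers
  nl <- length(layers)
  m <- diag(ncls)
  suffix_start <- nl + 1L
  for (i in rev(seq_len(nl))) {
    ty <- layers[[i]]$type
    if (ty == "linear") {
      m <- t(layers[[i]]$W) %*% m
    } else if (ty == "flatten") {
      cq <- fq$cache[[i]]
      dim(m) <- c(cq$in_ch, cq$in_L * ncls)
    } else if (ty == "dropout") {
      # inactive: identity
    } else break
    suffix_start <- i
  }
  # indices of layers relevant per pair, from below the suffix down to 1
  list(m0 = m, suffix_start = suffix_start, layers = layers)
}

# per-trial activations the pair loop needs, sliced once
precompute_trial <- function(plan, fw, t) {
  out <- list(x = {
    L <- fw$input_L
    fw$input_cmat[, ((t - 1L) * L + 1L):(t * L), drop = FALSE]
  })
  for (i in seq_len(plan$suffix_start - 1L)) {
    ly <- plan$layers[[i]]
    cc <- fw$cache[[i]]
    if (ly$type == "relu") {
      pre <- cc$pre[, ((t - 1L) * cc$in_L + 1L):(t * cc$in_L), drop = FALSE]
      out$pre <- pre
      out$act <- pmax(pre, 0)
    } else if (ly$type == "maxpool") {
      Lp <- cc$in_L %/% ly$size
      out$arg <- cc$arg[, ((t - 1L) * Lp + 1L):(t * Lp), drop = FALSE]
    }
  }
  out
}

# Contributions of one (query, background) pair: (features x L x classes).
# Classes are carried as pseudo-trials through the conv-stage layouts so the
# same indexing machinery serves training and attribution.
pair_contributions <- function(model, plan, qpre, bpre, nch, L, ncls) {
  m <- plan$m0
  for (i in rev(seq_len(plan$suffix_start - 1L))) {
    ly <- plan$layers[[i]]
    if (ly$type == "dropout") {
      # inactive at explanation time: identity
    } else if (ly$type == "relu") {
      dz <- qpre$pre - bpre$pre
      da <- qpre$act - bpre$act
      ratio <- da / dz
      ratio[abs(dz) <= 1e-12] <- 0
      m <- m * as.numeric(ratio)       # recycles over the ncls blocks
    } else if (ly$type == "maxpool") {
      k <- ly$size
      Lp <- ncol(qpre$arg)
      Lin <- Lp * k                    # truncated tail receives no multiplier
      routed <- route_pool(qpre$act, bpre$act, qpre$arg, bpre$arg, k, Lp)
      ch <- nrow(m)
      mrat <- m * as.numeric(routed$ratio)
      mout <- matrix(0, ch, ncol(qpre$pre) * ncls)
      Lfull <- ncol(qpre$pre)
      for (j in seq_len(k)) {
        sel <- routed$j == j           # ch x Lp
        if (!any(sel)) next
        selc <- as.numeric(sel)        # recycled over class blocks
        cols_in <- as.vector(outer((seq_len(Lp) - 1L) * k + j,
                                   (seq_len(ncls) - 1L) * Lfull, `+`))
        mout[, cols_in] <- mrat * selc
      }
      m <- mout
    } else if (ly$type == "conv") {
      m <- conv_input_grad(ly, m, L, ncls)
    } else stop("unsupported layer in the per-pair stage: ", ly$type)
  }
  contr <- m * as.numeric(qpre$x - bpre$x)  # recycles dx across class blocks
  dim(contr) <- c(nch, L, ncls)
  contr
}

# routing rule for one pooled stage (ch x Lp grids):
#   prefer the query's argmax position; if the activation difference there is
#   (numerically) zero, fall back to the background's argmax; if both
#   differences vanish the pooled delta is exactly zero and nothing routes.
route_pool <- function(aq, ab, argq, argb, k, Lp) {
  ch <- nrow(aq)
  win <- function(a, j) {
    cols <- (seq_len(Lp) - 1L) * k + j
    a[, cols, drop = FALSE]
  }
  gather <- function(a, idx) {
    out <- matrix(0, ch, Lp)
    for (j in seq_len(k)) {
      sel <- idx == j
      if (any(sel)) out[sel] <- win(a, j)[sel]
    }
    out
  }
  maxq <- gather(aq, argq)
  maxb <- gather(ab, argb)
  dout <- maxq - maxb
  dq <- maxq - gather(ab, argq)        # delta at the query's argmax position
  db <- gather(aq, argb) - maxb        # delta at the background's argmax
  fallback <- abs(dq) <= 1e-12
  jsel <- argq
  jsel[fallback] <- argb[fallback]
  denom <- dq
  denom[fallback] <- db[fallback]
  ratio <- dout / denom
  ratio[abs(denom) <= 1e-12] <- 0
  list(j = jsel, ratio = ratio)
}

#' Per-sample global importance
#'
#' Collapses the signed attribution tensor to one nonnegative scalar per
#' sample and trial: the mean absolute contribution across the
#' feature-by-class cells (12 for two features and six classes). The
#' per-trial argmax sample (earliest sample on ties) is recorded together
#' with the query's gaze coordinates at that sample.
#'
#' @param a An `attribution_tensor` from [explain()].
#' @param queries The query batch the tensor was computed from (for the
#'   argmax gaze coordinates); optional.
#' @return A list of class `global_importance`: `values` (trials x samples),
#'   `argmax_sample` (0-based), `argmax_gaze` (trials x 2, `NA` without
#'   `queries`).
#' @export
global_importance <- function(a, queries = NULL) {
  d <- dim(a$values)                   # nq x nch x L x ncls
  gi <- apply(abs(a$values), c(1L, 3L), mean)
  if (is.null(dim(gi))) gi <- matrix(gi, nrow = d[1L])
  argmax <- max.col(gi, ties.method = "first") - 1L
  gz <- matrix(NA_real_, d[1L], 2L, dimnames = list(NULL, c("x", "y")))
  if (!is.null(queries)) {
    for (i in seq_len(d[1L])) {
      gz[i, 1L] <- queries[i, 1L, argmax[i] + 1L]
      gz[i, 2L] <- queries[i, 2L, argmax[i] + 1L]
    }
  }
  structure(list(values = gi, argmax_sample = argmax, argmax_gaze = gz),
            class = "global_importance")
}

#' Peak-importance time versus response time
#'
#' Converts each trial's argmax sample to milliseconds (sample x 2 ms at
#' 500 Hz, 0-based) and pairs it with the response time; trials whose
#' importance peaks after the response (in the fixation-padded region) are
#' flagged.
#'
#' @param gi A `global_importance`.
#' @param trials Trial table aligned with the queries (needs `rt_ms`).
#' @param sample_period_ms Milliseconds per sample.
#' @return A list: `table` (data frame
#'   `participant_id,trial_index,argmax_time_ms,rt_ms,after_response`),
#'   `fraction_before_rt` over trials with a recorded RT.
#' @export
max_shap_vs_rt <- function(gi, trials, sample_period_ms = 2) {
  stopifnot(length(gi$argmax_sample) == nrow(trials))
  tm <- gi$argmax_sample * sample_period_ms
  after <- !is.na(trials$rt_ms) & tm > trials$rt_ms
  tab <- data.frame(participant_id = trials$participant_id,
                    trial_index = trials$trial_index,
                    argmax_time_ms = tm, rt_ms = trials$rt_ms,
                    after_response = after)
  has_rt <- !is.na(trials$rt_ms)
  list(table = tab,
       fraction_before_rt = if (any(has_rt)) mean(tm[has_rt] <= trials$rt_ms[has_rt]) else NA_real_)
}

#' Rotate screen points about the array center
#'
#' Rigid rotation by `to_angle - from_angle` degrees (counterclockwise in
#' the conventional frame; the screen's downward y-axis is handled
#' internally), used to align every trial's distractor (or target) at a
#' common polar angle.
#'
#' @param x,y Point coordinates in pixels (vectorized).
#' @param g An [array_geometry()].
#' @param from_angle,to_angle Polar angles in degrees.
#' @return A two-column matrix of rotated `(x, y)`.
#' @export
rotate_point <- function(x, y, g, from_angle, to_angle) {
  th <- (to_angle - from_angle) * pi / 180
  dx <- x - g$center_x
  dy <- -(y - g$center_y)
  rx <- dx * cos(th) - dy * sin(th)
  ry <- dx * sin(th) + dy * cos(th)
  cbind(x = g$center_x + rx, y = g$center_y - ry)
}

#' Silverman bandwidth for 2-D gaze coordinates
#'
#' `h = sigma_bar * n^(-1/6)` with `sigma_bar` the mean of the sample
#' standard deviations of x and y -- the rule-of-thumb bandwidth for a
#' two-dimensional Gaussian kernel (the `n^(-1/(d+4))` exponent with d = 2;
#' the exponent is exposed for sensitivity checks).
#'
#' @param points Two-column matrix of coordinates, n >= 2 with nonzero
#'   spread.
#' @param exponent Bandwidth exponent, `-1/6` for the 2-D rule.
#' @return Bandwidth in pixels.
#' @export
silverman_bandwidth <- function(points, exponent = -1 / 6) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("bandwidth needs at least two points")
  sbar <- mean(c(stats::sd(points[, 1L]), stats::sd(points[, 2L])))
  if (sbar == 0) stop("zero spread: bandwidth undefined")
  sbar * n^exponent
}

#' Gaussian kernel density heatmap
#'
#' Sums an isotropic Gaussian kernel of bandwidth `h` over the points on a
#' regular grid (10-pixel resolution by default) covering the screen; the
#' raw density integrates to ~1 over the grid and the returned grid is
#' max-normalized to [0, 1] so heatmaps are comparable.
#'
#' @param points Two-column matrix of coordinates (n >= 1).
#' @param h Bandwidth in pixels (> 0), e.g. from [silverman_bandwidth()].
#' @param resolution Grid spacing in pixels.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the geometry's
#'   screen.
#' @param g An [array_geometry()] supplying the default extent.
#' @return A list of class `kde_grid`: `x`, `y` (cell-center coordinates),
#'   `density` (matrix `length(x)` x `length(y)`, max = 1), `h`,
#'   `integral_raw` (pre-normalization mass on the grid).
#' @export
kde_heatmap <- function(points, h, resolution = 10, extent = NULL,
                        g = default_geometry()) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1L, h > 0)
  if (is.null(extent))
    extent <- c(0, g$screen_w %||% 2560, 0, g$screen_h %||% 1440)
  gx <- seq(extent[1L] + resolution / 2, extent[2L], by = resolution)
  gy <- seq(extent[3L] + resolution / 2, extent[4L], by = resolution)
  n <- nrow(points)
  dxm <- outer(gx, points[, 1L], `-`)
  dym <- outer(gy, points[, 2L], `-`)
  kx <- exp(-(dxm^2) / (2 * h^2))      # |gx| x n
  ky <- exp(-(dym^2) / (2 * h^2))      # |gy| x n
  dens <- kx %*% t(ky) / (n * 2 * pi * h^2)
  integral <- sum(dens) * resolution^2
  structure(list(x = gx, y = gy, density = dens / max(dens), h = h,
                 integral_raw = integral),
            class = "kde_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polar histogram of points with per-bin mean times
#'
#' Bins points by their polar angle around the array center (bins centered
#' on multiples of the bin width so, with six bins, they coincide with the
#' six location wedges) and reports the count and the mean of `times` per
#' bin. Points at the exact center are excluded with a warning.
#'
#' @param points Two-column matrix of screen coordinates.
#' @param times Numeric vector aligned with `points` (e.g. peak-importance
#'   times in ms).
#' @param g An [array_geometry()].
#' @param n_bins Number of angular bins.
#' @return Data frame `bin_center_deg, count, mean_time`.
#' @export
polar_time_histogram <- function(points, times, g, n_bins = 6L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(times), n_bins >= 1L)
  dx <- points[, 1L] - g$center_x
  dy <- -(points[, 2L] - g$center_y)
  central <- dx == 0 & dy == 0
  if (any(central)) {
    warning(sum(central), " point(s) at the exact center excluded from the",
            " polar histogram")
    dx <- dx[!central]; dy <- dy[!central]; times <- times[!central]
  }
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  w <- 360 / n_bins
  bin <- floor(((ang + w / 2) %% 360) / w)   # 0-based, centered bins
  centers <- (0:(n_bins - 1L)) * w
  data.frame(bin_center_deg = centers,
             count = vapply(0:(n_bins - 1L), function(b) sum(bin == b), 0L),
             mean_time = vapply(0:(n_bins - 1L), function(b)
               if (any(bin == b)) mean(times[bin == b]) else NA_real_, 0))
}
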