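# Shared fixtures: everything is generated in code at test time.

# toy geometry on a small screen, horizontal meridian
toy_geometry <- function() {
  default_geometry(screen_w = 200, screen_h = 100, meridian = "horizontal",
                   eccentricity_px = 30, stimulus_radius_px = 5)
}

# hand-built dataset: n trials per participant, constant traces at center
toy_dataset <- function(pids = c("a", "b"), n_trials = 3L, len = 4L,
                        g = toy_geometry()) {
  rows <- list()
  traces <- list()
  i <- 0L
  for (p in pids) for (tr in seq_len(n_trials)) {
    i <- i + 1L
    rows[[i]] <- data.frame(participant_id = p, trial_index = tr,
                            target_location = (tr - 1L) %% 6L,
                            distractor_location = if (tr %% 2L == 0L) tr %% 6L else NA_integer_,
                            rt_ms = 100 * tr, n_recorded_samples = len)
    traces[[i]] <- data.frame(x = rep(g$center_x, len), y = rep(g$center_y, len))
  }
  gaze_dataset(g, do.call(rbind, rows), traces)
}

# small architecture that exercises every layer type quickly
tiny_config <- function(input_length = 20L, n_classes = 4L) {
  network_config(in_channels = 2L, conv_features = 4L, kernel_size = 3L,
                 stride = 1L, dropout_p = 0.25, pool_size = 2L,
                 pool_stride = 2L, hidden_sizes = c(5L, 3L),
                 n_classes = n_classes, input_length = input_length)
}

# a trial table with dense trial indices, no traces needed
bare_trials <- function(n_participants, trials_each, present_fraction = 0) {
  pid <- rep(sprintf("P%03d", seq_len(n_participants)), each = trials_each)
  idx <- rep(seq_len(trials_each), n_participants)
  n <- length(pid)
  present <- rep(FALSE, trials_each)
  if (present_fraction > 0)
    present[seq_len(round(present_fraction * trials_each))] <- TRUE
  tgt <- (idx - 1L) %% 6L
  data.frame(participant_id = pid, trial_index = idx, target_location = tgt,
             distractor_location = ifelse(rep(present, n_participants),
                                          (tgt + 1L) %% 6L, NA_integer_),
             rt_ms = 500, n_recorded_samples = 0L)
}

# direct (non-vectorized) evaluation of the standard layer stack, used as
# the independent arithmetic oracle for the forward pass
direct_forward <- function(model, xt) { # xt: channels x samples, one trial
  cfg <- model$config
  k <- cfg$kernel_size
  Lo <- ncol(xt) - k + 1L
  Wc <- model$layers[[1]]$W
  bc <- model$layers[[1]]$b
  Z <- sapply(seq_len(Lo), function(s) Wc %*% as.vector(xt[, s:(s + k - 1L)]) + bc)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  A <- pmax(Z, 0)
  ps <- cfg$pool_size
  Lp <- Lo %/% ps
  P <- sapply(seq_len(Lp), function(u)
    apply(A[, ((u - 1L) * ps + 1L):(u * ps), drop = FALSE], 1L, max))
  if (is.null(dim(P))) P <- matrix(P, nrow = cfg$conv_features)
  v <- as.vector(P)
  for (i in 6:length(model$layers))
    v <- as.vector(model$layers[[i]]$W %*% v + model$layers[[i]]$b)
  v
}
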