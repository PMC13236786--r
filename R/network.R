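# 1D convolutional classifier, implemented directly on BLAS matrix ops.
#
# Internal activation layout ("channel matrix"): a batch of n trials with c
# channels and L samples per trial is a c x (L * n) matrix whose column
# (t - 1) * L + s holds the c channel values of trial t at sample s. Dense
# stages (post-flatten) use a units x n matrix. This keeps every layer a
# plain matrix operation and makes the convolution an im2col matrix product.

#' Network architecture configuration
#'
#' The classifier is: 1D convolution (no input padding) -> ReLU ->
#' dropout -> max pooling -> flatten -> three linear transforms with no
#' intermediate activation -> 6 logits, one per candidate location. With the
#' defaults (kernel 3, stride 1, 64 features, pool size/stride 5, 600-sample
#' input) the flattened stage has 64 x floor(598 / 5) = 7,616 units; the
#' arithmetic forces unpadded convolution, since padding would give 7,680.
#'
#' @param in_channels Input channels (x- and y-position: 2).
#' @param conv_features Convolution output features.
#' @param kernel_size,stride Convolution kernel size and stride.
#' @param dropout_p Dropout probability, active during training only.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param hidden_sizes Sizes of the two intermediate linear transforms.
#' @param n_classes Output classes (6 array locations).
#' @param input_length Samples per trial (600 = 1,200 ms at 500 Hz).
#' @return A list of class `network_config` with derived fields
#'   `conv_out_length`, `pool_out_length` and `flatten_length`.
#' @export
network_config <- function(in_channels = 2L, conv_features = 64L,
                           kernel_size = 3L, stride = 1L, dropout_p = 0.25,
                           pool_size = 5L, pool_stride = 5L,
                           hidden_sizes = c(64L, 32L), n_classes = 6L,
                           input_length = 600L) {
  stopifnot(in_channels >= 1, conv_features >= 1, kernel_size >= 1,
            stride >= 1, pool_size >= 1, pool_stride == pool_size,
            n_classes >= 2, input_length >= kernel_size,
            dropout_p >= 0, dropout_p < 1, length(hidden_sizes) >= 1)
  co <- conv_output_length(input_length, kernel_size, stride)
  po <- co %/% pool_size
  structure(list(in_channels = as.integer(in_channels),
                 conv_features = as.integer(conv_features),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), dropout_p = dropout_p,
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 conv_out_length = co, pool_out_length = po,
                 flatten_length = as.integer(conv_features) * po),
            class = "network_config")
}

#' Output length of an unpadded 1D convolution
#'
#' Number of valid kernel placements: `floor((L - k) / s) + 1`.
#'
#' @param L Input length in samples; must be at least `k`.
#' @param k Kernel size.
#' @param s Stride.
#' @return Integer output length.
#' @export
conv_output_length <- function(L, k, s) {
  if (L < k) stop("input length ", L, " is shorter than the kernel (", k, ")")
  stopifnot(s >= 1)
  as.integer((L - k) %/% s + 1L)
}

# ---- layer constructors (internal) ----------------------------------------

layer_conv <- function(W, b, kernel, in_channels) {
  list(type = "conv", W = W, b = b, kernel = kernel, in_channels = in_channels)
}
layer_relu <- function() list(type = "relu")
layer_dropout <- function(p) list(type = "dropout", p = p)
layer_maxpool <- function(size) list(type = "maxpool", size = size)
layer_flatten <- function() list(type = "flatten")
layer_linear <- function(W, b) list(type = "linear", W = W, b = b)

# Fan-in scaled uniform initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_uniform <- function(nrow, ncol, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize a network with random weights
#'
#' Weights are drawn from the fan-in-scaled uniform distribution
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)) using the current RNG state, so a
#' prior `set.seed()` makes initialization reproducible.
#'
#' @param config A [network_config()].
#' @return A model of class `gaze_cnn`.
#' @export
init_network <- function(config) {
  fan_conv <- config$in_channels * config$kernel_size
  sizes <- c(config$flatten_length, config$hidden_sizes, config$n_classes)
  layers <- list(
    layer_conv(init_uniform(config$conv_features, fan_conv, fan_conv),
               stats::runif(config$conv_features, -1 / sqrt(fan_conv), 1 / sqrt(fan_conv)),
               config$kernel_size, config$in_channels),
    layer_relu(),
    layer_dropout(config$dropout_p),
    layer_maxpool(config$pool_size),
    layer_flatten())
  for (i in seq_len(length(sizes) - 1L)) {
    layers <- c(layers, list(layer_linear(
      init_uniform(sizes[i + 1L], sizes[i], sizes[i]),
      stats::runif(sizes[i + 1L], -1 / sqrt(sizes[i]), 1 / sqrt(sizes[i])))))
  }
  new_gaze_cnn(layers, config)
}

#' Build a model from an explicit layer stack
#'
#' Lower-level constructor used for hand-sized networks in validation
#' studies (e.g. a purely linear surrogate for closed-form attribution
#' checks). Most users want [init_network()].
#'
#' @param layers List of layer objects (see `layer_*` constructors).
#' @param config A [network_config()] or a list with at least
#'   `input_length`, `in_channels` and `n_classes`.
#' @return A model of class `gaze_cnn`.
#' @export
new_gaze_cnn <- function(layers, config) {
  structure(list(config = config, layers = layers), class = "gaze_cnn")
}

#' @export
print.gaze_cnn <- function(x, ...) {
  cat("<gaze_cnn> ", length(x$layers), " layers: ",
      paste(vapply(x$layers, `[[`, "", "type"), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# ---- batch layout helpers --------------------------------------------------

# (n, c, L) array -> c x (L * n) channel matrix
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(2L, 3L, 1L))
  dim(m) <- c(d[2L], d[3L] * d[1L])
  m
}

im2col <- function(cmat, k, L, n) cpp_im2col(cmat, k, L, n)

# ---- forward / backward engine (internal) ----------------------------------

# v: list(mat, L, n); L is NA after flatten. cache[[i]] stores the input
# stage dims of layer i plus whatever backward needs.
engine_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 3L)
    stop("input batch must be a (trials, features, samples) array")
  n <- d[1L]
  v <- list(mat = to_cmat(x), L = d[3L], n = n)
  cache <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    cc <- list(in_L = v$L, in_n = v$n, in_ch = nrow(v$mat))
    if (ly$type == "conv") {
      if (is.na(v$L)) stop("convolution requires a (channels, samples) stage")
      if (v$L < ly$kernel)
        stop("input length ", v$L, " is shorter than the kernel")
      col <- im2col(v$mat, ly$kernel, v$L, v$n)
      Lo <- v$L - ly$kernel + 1L
      out <- ly$W %*% col + ly$b
      if (keep_cache) cc$col <- col
      v <- list(mat = out, L = Lo, n = v$n)
    } else if (ly$type == "relu") {
      if (keep_cache) cc$pre <- v$mat
      v$mat <- pmax(v$mat, 0)
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- (stats::runif(length(v$mat)) >= ly$p) / (1 - ly$p)
        dim(mask) <- dim(v$mat)
        v$mat <- v$mat * mask
        if (keep_cache) cc$mask <- mask
      }
    } else if (ly$type == "maxpool") {
      if (is.na(v$L)) stop("max pooling requires a (channels, samples) stage")
      k <- ly$size
      Lp <- v$L %/% k
      if (Lp < 1L) stop("stage too short for pooling window of ", k)
      mp <- cpp_maxpool_fwd(v$mat, k, v$L, v$n)
      if (keep_cache) cc$arg <- mp$arg
      v <- list(mat = mp$pooled, L = Lp, n = v$n)
    } else if (ly$type == "flatten") {
      if (is.na(v$L)) stop("flatten applied to an already-dense stage")
      m <- v$mat
      dim(m) <- c(nrow(v$mat) * v$L, v$n)
      v <- list(mat = m, L = NA_integer_, n = v$n)
    } else if (ly$type == "linear") {
      if (!is.na(v$L))
        stop("linear layer requires a dense stage; add a flatten layer first")
      if (keep_cache) cc$x <- v$mat
      v$mat <- ly$W %*% v$mat + ly$b
    } else stop("unknown layer type: ", ly$type)
    if (keep_cache) cache[[i]] <- cc
  }
  res <- list(out = v$mat, cache = cache)
  if (keep_cache) {
    res$input_cmat <- to_cmat(x)
    res$input_L <- d[3L]
  }
  res
}

# dout: gradient at logits (classes x n). Returns grads parallel to layers
# (NULL for parameterless ones). Input gradients are propagated all the way
# down only when need_input = TRUE.
engine_backward <- function(model, cache, dout, need_input = FALSE) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "linear") {
      grads[[i]] <- list(dW = d %*% t(cc$x), db = rowSums(d))
      d <- t(ly$W) %*% d
    } else if (ly$type == "flatten") {
      dim(d) <- c(cc$in_ch, cc$in_L * cc$in_n)
    } else if (ly$type == "maxpool") {
      d <- cpp_maxpool_bwd(d, cc$arg, ly$size, cc$in_L, cc$in_n)
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) d <- d * cc$mask
    } else if (ly$type == "relu") {
      d <- d * (cc$pre > 0)
    } else if (ly$type == "conv") {
      grads[[i]] <- list(dW = d %*% t(cc$col), db = rowSums(d))
      if (i > 1L || need_input) {
        d <- conv_input_grad(ly, d, cc$in_L, cc$in_n)
      } else {
        d <- NULL
        break
      }
    }
  }
  list(grads = grads, dinput = d)
}

# scatter t(W) %*% dZ back onto the input channel matrix
conv_input_grad <- function(ly, dZ, L, n) {
  dcol <- t(ly$W) %*% dZ              # (ch * k) x (Lo * n)
  cpp_col2im(dcol, ly$in_channels, ly$kernel, L, n)
}

#' Forward pass: logits for a batch
#'
#' @param model A `gaze_cnn`.
#' @param x Batch array of shape `(n, features, samples)`; the sample length
#'   must match the model's expected input length.
#' @param training If `TRUE`, dropout is active (uses the RNG stream).
#' @return An `n x n_classes` matrix of logits.
#' @export
forward <- function(model, x, training = FALSE) {
  exp_len <- model$config$input_length
  if (!is.null(exp_len) && dim(x)[3L] != exp_len)
    stop("input has ", dim(x)[3L], " samples per trial; the model expects ", exp_len)
  out <- engine_forward(model, x, training = training, keep_cache = FALSE)$out
  if (any(!is.finite(out))) stop("non-finite logits produced by forward pass")
  t(out)
}

#' Predicted class per trial
#'
#' Row-wise argmax of the logits; ties go to the lowest class index.
#'
#' @param logits An `n x n_classes` matrix.
#' @return Integer vector of class indices, 0-based (matching the location
#'   labels).
#' @export
predict_classes <- function(logits) {
  if (any(!is.finite(logits))) stop("logits contain non-finite values")
  max.col(logits, ties.method = "first") - 1L
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned RDS container holding the configuration and
#' all weights; `load_model(save_model(m, f))` is exact.
#'
#' @param model A `gaze_cnn`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "gazecnn-checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gazecnn-checkpoint"))
    stop("not a gazecnn checkpoint: ", path)
  obj$model
}
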