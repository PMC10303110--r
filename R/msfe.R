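#' Exponential linear unit
#'
#' \eqn{ELU(x) = e^x - 1} for \eqn{x < 0} and \eqn{x} for \eqn{x \ge 0};
#' continuous and monotone. Used after every convolution block in the network.
#'
#' @param x numeric vector/array (finite).
#' @return same shape as \code{x}.
#' @examples
#' elu(c(-1, 0, 2.5))
#' @export
elu <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}

#' Multi-scale feature extraction (MSFE) configuration
#'
#' Two (by default) parallel branches, each a temporal convolution acting as a
#' learned frequency filter — a long kernel for low-frequency structure, a
#' short kernel for high-frequency structure — followed by batch-norm, a
#' depthwise spatial convolution that collapses the channel axis, batch-norm,
#' ELU, average pooling and dropout. Branch outputs are fused by feature-axis
#' concatenation and further processed by a convolution, batch-norm, ELU, a
#' second average pooling and dropout. An alternative per-branch placement of
#' the second convolution is available via \code{second_conv}.
#'
#' @param branch_kernel_lengths integer vector of temporal kernel lengths, one
#'   per branch (default \code{c(64, 16)}; 1/3/5-branch variants are ablation
#'   configurations).
#' @param n_temporal_filters temporal filters per branch (default 16).
#' @param depth_multiplier spatial filters learned per temporal filter
#'   (default 1).
#' @param pool1_length,pool2_length average-pooling lengths (defaults 8 and 7).
#' @param pool_stride either \code{"pool"} (stride = pool length,
#'   non-overlapping; the default) or \code{"one"} (literal stride-1 reading).
#' @param fusion_filters filters of the post-fusion convolution (default 16).
#' @param fusion_kernel_length its kernel length (default 16).
#' @param second_conv \code{"fusion"} (one convolution after concatenation,
#'   the default) or \code{"branch"} (one per branch before concatenation).
#' @param dropout_p dropout probability (default 0.3).
#' @return an object of class \code{msfe_config}.
#' @export
msfe_config <- function(branch_kernel_lengths = c(64L, 16L),
                        n_temporal_filters = 16L,
                        depth_multiplier = 1L,
                        pool1_length = 8L,
                        pool2_length = 7L,
                        pool_stride = c("pool", "one"),
                        fusion_filters = 16L,
                        fusion_kernel_length = 16L,
                        second_conv = c("fusion", "branch"),
                        dropout_p = 0.3) {
  pool_stride <- match.arg(pool_stride)
  second_conv <- match.arg(second_conv)
  if (length(branch_kernel_lengths) < 1)
    stop_validation("need at least one branch")
  for (k in branch_kernel_lengths) assert_count(k, "branch kernel length")
  assert_count(n_temporal_filters, "n_temporal_filters")
  assert_count(depth_multiplier, "depth_multiplier")
  assert_count(pool1_length, "pool1_length")
  assert_count(pool2_length, "pool2_length")
  assert_count(fusion_filters, "fusion_filters")
  assert_count(fusion_kernel_length, "fusion_kernel_length")
  assert_prob(dropout_p, "dropout_p")
  structure(list(
    branch_kernel_lengths = as.integer(branch_kernel_lengths),
    n_temporal_filters = as.integer(n_temporal_filters),
    depth_multiplier = as.integer(depth_multiplier),
    pool1_length = as.integer(pool1_length),
    pool2_length = as.integer(pool2_length),
    pool_stride = pool_stride,
    fusion_filters = as.integer(fusion_filters),
    fusion_kernel_length = as.integer(fusion_kernel_length),
    second_conv = second_conv,
    dropout_p = dropout_p
  ), class = "msfe_config")
}

# Number of output features of the MSFE block.
msfe_out_features <- function(cfg) {
  nb <- length(cfg$branch_kernel_lengths)
  if (cfg$second_conv == "branch") nb * cfg$fusion_filters else cfg$fusion_filters
}

# Output time length for input length T.
msfe_out_time <- function(cfg, T) {
  pool_out <- function(T, p, stride) {
    if (T < p) stop_shape("input time length ", T, " too short for pool ", p)
    s <- if (stride == "pool") p else 1L
    (T - p) %/% s + 1L
  }
  pool_out(pool_out(T, cfg$pool1_length, cfg$pool_stride),
           cfg$pool2_length, cfg$pool_stride)
}

# -- builder ------------------------------------------------------------------

make_msfe <- function(cfg, C) {
  self <- new_module("msfe")
  self$cfg <- cfg
  self$C <- C
  ps <- cfg$pool_stride
  stride1 <- if (ps == "pool") cfg$pool1_length else 1L
  stride2 <- if (ps == "pool") cfg$pool2_length else 1L
  Fb <- cfg$n_temporal_filters * cfg$depth_multiplier
  branches <- lapply(cfg$branch_kernel_lengths, function(k) {
    mods <- list(
      make_tconv(cfg$n_temporal_filters, k),
      make_bn(cfg$n_temporal_filters),
      make_depthwise(C, cfg$n_temporal_filters, cfg$depth_multiplier),
      make_bn(Fb),
      make_elu(),
      make_pool(cfg$pool1_length, stride1),
      make_dropout(cfg$dropout_p)
    )
    if (cfg$second_conv == "branch") {
      mods <- c(mods, list(
        make_conv1d(Fb, cfg$fusion_filters, cfg$fusion_kernel_length),
        make_bn(cfg$fusion_filters),
        make_elu(),
        make_pool(cfg$pool2_length, stride2),
        make_dropout(cfg$dropout_p)
      ))
    }
    make_sequential(mods, "msfe_branch")
  })
  self$branches <- branches
  if (cfg$second_conv == "fusion") {
    nfeat_in <- Fb * length(branches)
    self$fusion <- make_sequential(list(
      make_conv1d(nfeat_in, cfg$fusion_filters, cfg$fusion_kernel_length),
      make_bn(cfg$fusion_filters),
      make_elu(),
      make_pool(cfg$pool2_length, stride2),
      make_dropout(cfg$dropout_p)
    ), "msfe_fusion")
    self$children <- c(branches, list(self$fusion))
  } else {
    self$fusion <- NULL
    self$children <- branches
  }
  self
}

mod_forward.msat_msfe <- function(self, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || d[1] != self$C)
    stop_shape("MSFE expects [C=", self$C, ", T, B] input, got [",
               paste(d, collapse = ", "), "]")
  ys <- lapply(self$branches, function(br) mod_forward(br, x, training))
  self$branch_feats <- vapply(ys, function(y) dim(y)[1], numeric(1))
  cat_y <- do.call(cat_features, ys)
  if (is.null(self$fusion)) cat_y else mod_forward(self$fusion, cat_y, training)
}

mod_backward.msat_msfe <- function(self, dy) {
  if (!is.null(self$fusion)) dy <- mod_backward(self$fusion, dy)
  splits <- split_features(dy, self$branch_feats)
  dx <- NULL
  for (i in seq_along(self$branches)) {
    g <- mod_backward(self$branches[[i]], splits[[i]])
    dx <- if (is.null(dx)) g else dx + g
  }
  dx
}

# Concatenate [F_i, T, B] arrays along the feature axis.
cat_features <- function(...) {
  ys <- list(...)
  d <- dim(ys[[1]])
  Fs <- vapply(ys, function(y) dim(y)[1], numeric(1))
  out <- array(0, dim = c(sum(Fs), d[2], d[3]))
  at <- 0L
  for (y in ys) {
    out[at + seq_len(dim(y)[1]), , ] <- y
    at <- at + dim(y)[1]
  }
  out
}

split_features <- function(x, Fs) {
  out <- vector("list", length(Fs))
  at <- 0L
  for (i in seq_along(Fs)) {
    out[[i]] <- x[at + seq_len(Fs[i]), , , drop = FALSE]
    at <- at + Fs[i]
  }
  out
}

#' Build a standalone MSFE block
#'
#' @param cfg an [msfe_config()].
#' @param C number of input channels.
#' @param seed integer seed for Glorot initialization.
#' @return an MSFE module usable with [msfe_forward()] and
#'   [count_parameters()].
#' @export
build_msfe <- function(cfg, C, seed = 1L) {
  assert_count(C, "C")
  set.seed(derive_seed(seed, 11L))
  make_msfe(cfg, C)
}

#' Run the MSFE block forward
#'
#' Maps a trial tensor \code{[C, T, B]} (or a single trial \code{[C, T]}) to
#' pooled multi-scale features \code{[fusion_filters, T_out, B]} where
#' \code{T_out = floor(floor(T / pool1) / pool2)} under non-overlapping
#' pooling. Deterministic when \code{training = FALSE} (dropout off,
#' batch-norm running statistics).
#'
#' @param block a module from [build_msfe()].
#' @param x numeric array \code{[C, T, B]} or matrix \code{[C, T]}.
#' @param training logical; enables dropout and batch statistics.
#' @return feature array \code{[features, T_out, B]}.
#' @export
msfe_forward <- function(block, x, training = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  mod_forward(block, x, training)
}
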