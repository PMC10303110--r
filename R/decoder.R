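#' Temporal decoder configuration
#'
#' The temporal decoder is a modified temporal convolutional network (TCN):
#' \code{n_blocks} residual blocks, each holding \code{layers_per_block}
#' dilated causal convolutions (kernel length \code{kernel_length}), each
#' followed by batch-norm, ELU and dropout. All layers inside block \code{j}
#' share dilation \code{dilation_base^(j-1)}. A residual connection (identity,
#' or a 1x1 convolution when the feature counts differ) joins input and block
#' output, and an ELU follows every block.
#'
#' @param n_blocks number of residual blocks \code{n} (default 2).
#' @param layers_per_block convolutions per block \code{m} (default 2).
#' @param kernel_length kernel size \code{K} (default 4).
#' @param dilation_base dilation growth factor \code{b} (default 2, must be
#'   >= 2).
#' @param n_filters feature maps per convolution (defaults to the MSFE output
#'   feature count when the full model is assembled).
#' @param dropout_p dropout probability (default 0.3).
#' @return an object of class \code{temporal_decoder_config}.
#' @export
temporal_decoder_config <- function(n_blocks = 2L, layers_per_block = 2L,
                                    kernel_length = 4L, dilation_base = 2L,
                                    n_filters = 16L, dropout_p = 0.3) {
  assert_count(n_blocks, "n_blocks")
  assert_count(layers_per_block, "layers_per_block")
  assert_count(kernel_length, "kernel_length")
  assert_count(dilation_base, "dilation_base", min = 2L)
  assert_count(n_filters, "n_filters")
  assert_prob(dropout_p, "dropout_p")
  structure(list(
    n_blocks = as.integer(n_blocks),
    layers_per_block = as.integer(layers_per_block),
    kernel_length = as.integer(kernel_length),
    dilation_base = as.integer(dilation_base),
    n_filters = as.integer(n_filters),
    dropout_p = dropout_p
  ), class = "temporal_decoder_config")
}

#' Dilated causal convolution of a sequence
#'
#' Computes \eqn{F(t) = \sum_{i=0}^{k-1} f(i) \, x_{t - d i}} with zero
#' padding on the left (\eqn{x_j = 0} for \eqn{j < 1}), so the output has the
#' same length as the input and position \code{t} depends only on
#' \code{x[1..t]}.
#'
#' @param x numeric input sequence.
#' @param f numeric kernel, \code{f[1]} multiplying the current sample.
#' @param d integer dilation (>= 1).
#' @return numeric sequence of \code{length(x)}.
#' @examples
#' dilated_causal_conv(c(1, 2, 3, 4), c(1, 1), d = 2)  # x[t] + x[t - 2]
#' @export
dilated_causal_conv <- function(x, f, d = 1L) {
  if (length(f) < 1) stop_validation("kernel must have length >= 1")
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d))
    stop_validation("dilation d must be a positive integer")
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(f)) {
    shift <- d * (i - 1L)
    if (shift >= n) break
    idx <- seq_len(n - shift)
    out[idx + shift] <- out[idx + shift] + f[i] * x[idx]
  }
  out
}

#' Receptive field of the temporal decoder
#'
#' Closed form \eqn{r = 1 + m (K - 1)(b^n - 1)/(b - 1)} for \code{n} residual
#' blocks of \code{m} dilated causal convolutions with kernel size \code{K}
#' and dilation base \code{b}: the number of input time steps that can
#' influence one output step. For the network defaults
#' (\code{m = 2, K = 4, b = 2, n = 2}) this is 19.
#'
#' @param cfg a [temporal_decoder_config()].
#' @return integer receptive field (>= 1).
#' @export
receptive_field <- function(cfg) {
  stopifnot(inherits(cfg, "temporal_decoder_config"))
  m <- cfg$layers_per_block; K <- cfg$kernel_length
  b <- cfg$dilation_base; n <- cfg$n_blocks
  as.integer(1 + m * (K - 1) * (b^n - 1) / (b - 1))
}

# -- residual block -----------------------------------------------------------

make_resblock <- function(Fin, Fout, m, K, dilation, dropout_p,
                          linear = FALSE) {
  self <- new_module("resblock")
  layers <- list()
  fin <- Fin
  for (l in seq_len(m)) {
    layers <- c(layers, list(make_conv1d(fin, Fout, K, dilation = dilation,
                                         causal = TRUE)))
    if (!linear) {
      layers <- c(layers, list(make_bn(Fout), make_elu(),
                               make_dropout(dropout_p)))
    }
    fin <- Fout
  }
  self$body <- make_sequential(layers, "resblock_body")
  self$res <- if (Fin != Fout) make_conv1d(Fin, Fout, 1L) else NULL
  self$linear <- linear
  self$children <- c(list(self$body), if (!is.null(self$res)) list(self$res))
  self
}

mod_forward.msat_resblock <- function(self, x, training = FALSE) {
  out <- mod_forward(self$body, x, training)
  r <- if (is.null(self$res)) x else mod_forward(self$res, x, training)
  s <- out + r
  if (self$linear) return(s)
  y <- elu_fwd_cpp(s)
  dim(y) <- dim(s)
  self$cache <- list(y = y)
  y
}

mod_backward.msat_resblock <- function(self, dy) {
  if (!self$linear) {
    dy2 <- elu_bwd_cpp(dy, self$cache$y)
    dim(dy2) <- dim(dy)
    dy <- dy2
    self$cache <- NULL
  }
  dx <- mod_backward(self$body, dy)
  dx + if (is.null(self$res)) dy else mod_backward(self$res, dy)
}

# -- decoder ------------------------------------------------------------------

make_decoder <- function(cfg, Fin, linear = FALSE) {
  self <- new_module("decoder")
  self$cfg <- cfg
  blocks <- list()
  fin <- Fin
  for (j in seq_len(cfg$n_blocks)) {
    dil <- cfg$dilation_base^(j - 1L)
    blocks <- c(blocks, list(
      make_resblock(fin, cfg$n_filters, cfg$layers_per_block,
                    cfg$kernel_length, dil, cfg$dropout_p, linear = linear)))
    fin <- cfg$n_filters
  }
  self$children <- blocks
  self
}

mod_forward.msat_decoder <- function(self, x, training = FALSE) {
  if (dim(x)[1] != dim_decoder_in(self))
    stop_shape("decoder expects ", dim_decoder_in(self), " features, got ",
               dim(x)[1])
  for (blk in self$children) x <- mod_forward(blk, x, training)
  x
}

mod_backward.msat_decoder <- function(self, dy) {
  for (blk in rev(self$children)) dy <- mod_backward(blk, dy)
  dy
}

dim_decoder_in <- function(self) {
  first_conv <- self$children[[1]]$body$children[[1]]
  first_conv$Fin
}

#' Build a standalone temporal decoder
#'
#' @param cfg a [temporal_decoder_config()].
#' @param n_features input feature count (defaults to \code{cfg$n_filters}).
#' @param seed seed for Glorot initialization.
#' @param linear if \code{TRUE}, batch-norm, ELU and dropout are omitted so
#'   the decoder is a linear causal map — used to probe the receptive field.
#' @return a decoder module; apply with [temporal_decoder_forward()].
#' @export
build_temporal_decoder <- function(cfg, n_features = cfg$n_filters, seed = 1L,
                                   linear = FALSE) {
  set.seed(derive_seed(seed, 13L))
  make_decoder(cfg, n_features, linear = linear)
}

#' Run the temporal decoder forward
#'
#' Preserves the time length and is causal end to end: output at time
#' \code{t} depends only on inputs at times \code{<= t}.
#'
#' @param decoder module from [build_temporal_decoder()].
#' @param x array \code{[features, N, B]} or matrix \code{[features, N]}.
#' @param training logical.
#' @return array of the same shape as \code{x}.
#' @export
temporal_decoder_forward <- function(decoder, x, training = FALSE) {
  was_mat <- is.matrix(x)
  if (was_mat) dim(x) <- c(dim(x), 1L)
  y <- mod_forward(decoder, x, training)
  if (was_mat) dim(y) <- dim(y)[1:2]
  y
}

#' Measure the receptive field of a built decoder empirically
#'
#' Perturbs every input position with finite differences on a linearized
#' decoder (build with \code{linear = TRUE}) and returns the width of the
#' influence window: from the earliest input position whose perturbation
#' changes the output at time \code{t}, up to \code{t} itself. For dilation
#' base 2 the influential set is contiguous and the width equals its count;
#' for larger bases the set has holes and the window width is what the
#' closed-form receptive field measures. Equals
#' \code{min(receptive_field(cfg), t)} for 1-based \code{t}.
#'
#' @param decoder a decoder module, ideally built with \code{linear = TRUE}.
#' @param t 1-based output time index to probe.
#' @param N sequence length used for the probe (defaults to \code{t}).
#' @param tol change-detection threshold.
#' @return integer width of the influence window (0 if nothing influences
#'   \code{t}, which cannot happen for a convolutional decoder).
#' @export
empirical_receptive_field <- function(decoder, t, N = t, tol = 1e-9) {
  assert_count(t, "t")
  if (t > N) stop_validation("t (", t, ") exceeds probe length N (", N, ")")
  Fin <- dim_decoder_in(decoder)
  x0 <- array(0, dim = c(Fin, N, 1L))
  y0 <- mod_forward(decoder, x0, training = FALSE)[, t, 1L]
  influential <- integer()
  for (p in seq_len(N)) {
    xp <- x0
    xp[1L, p, 1L] <- 1
    yp <- mod_forward(decoder, xp, training = FALSE)[, t, 1L]
    if (max(abs(yp - y0)) > tol) influential <- c(influential, p)
  }
  if (length(influential) == 0) return(0L)
  as.integer(t - min(influential) + 1L)
}
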