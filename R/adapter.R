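#' Subject-adapter configuration
#'
#' A residual bottleneck: a feedforward down-projection from \code{input_dim}
#' to \code{bottleneck_dim}, an ELU, and an up-projection back to
#' \code{input_dim}, added to the input (residual connection). With
#' \code{zero_init_up} the up-projection starts at zero so a freshly inserted
#' adapter is exactly the identity and the pre-trained network is preserved at
#' the start of fine-tuning.
#'
#' @param input_dim feature dimension \code{d} the adapter operates on.
#' @param bottleneck_dim bottleneck width \code{r_b}, \code{1 <= r_b < d}
#'   (default \code{max(1, d \%/\% 4)}).
#' @param zero_init_up zero-initialize the up-projection (default TRUE).
#' @return an object of class \code{adapter_config}.
#' @export
adapter_config <- function(input_dim, bottleneck_dim = NULL,
                           zero_init_up = TRUE) {
  assert_count(input_dim, "input_dim", min = 2L)
  if (is.null(bottleneck_dim)) bottleneck_dim <- max(1L, input_dim %/% 4L)
  assert_count(bottleneck_dim, "bottleneck_dim")
  if (bottleneck_dim >= input_dim)
    stop_validation("bottleneck_dim (", bottleneck_dim,
                    ") must be smaller than input_dim (", input_dim, ")")
  assert_flag(zero_init_up, "zero_init_up")
  structure(list(input_dim = as.integer(input_dim),
                 bottleneck_dim = as.integer(bottleneck_dim),
                 zero_init_up = zero_init_up),
            class = "adapter_config")
}

make_adapter <- function(cfg) {
  self <- new_module("adapter")
  d <- cfg$input_dim; r <- cfg$bottleneck_dim
  self$d <- d; self$r <- r
  self$D <- glorot(c(r, d), d, r)
  self$b_D <- rep(0, r)
  self$U <- if (cfg$zero_init_up) matrix(0, d, r) else glorot(c(d, r), r, d)
  self$b_U <- rep(0, d)
  self$param_names <- c("D", "b_D", "U", "b_U")
  self
}

mod_forward.msat_adapter <- function(self, x, training = FALSE) {
  dims <- dim(x)
  if (dims[1] != self$d)
    stop_shape("adapter expects ", self$d, " features, got ", dims[1])
  xm <- x; dim(xm) <- c(dims[1], prod(dims[-1]))
  pre <- self$D %*% xm + self$b_D
  h <- pre
  neg <- pre < 0
  h[neg] <- exp(pre[neg]) - 1
  y <- xm + self$U %*% h + self$b_U
  dim(y) <- dims
  self$cache <- list(xm = xm, pre = pre, h = h, dims = dims)
  y
}

mod_backward.msat_adapter <- function(self, dy) {
  cc <- self$cache
  dym <- dy; dim(dym) <- dim(cc$xm)
  acc_grad(self, "U", dym %*% t(cc$h))
  acc_grad(self, "b_U", rowSums(dym))
  dh <- crossprod(self$U, dym) * elu_prime(cc$pre)
  acc_grad(self, "D", dh %*% t(cc$xm))
  acc_grad(self, "b_D", rowSums(dh))
  dx <- dym + crossprod(self$D, dh)
  dim(dx) <- cc$dims
  self$cache <- NULL
  dx
}

#' Apply a subject adapter to features
#'
#' Computes \code{x + U ELU(D x + b_D) + b_U} along the feature axis; shape
#' preserving. Accepts a feature vector, a \code{[d x M]} matrix of column
#' features, or a \code{[d, N, B]} feature tensor.
#'
#' @param x input with feature dimension \code{d} first.
#' @param adapter an adapter module (from [insert_adapters()] or
#'   \code{msatnet:::make_adapter}).
#' @return same shape as \code{x}.
#' @export
adapter_forward <- function(x, adapter) {
  shape <- dim(x)
  if (is.null(shape)) dim(x) <- c(length(x), 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  y <- mod_forward(adapter, x, training = FALSE)
  if (is.null(shape)) y <- as.numeric(y) else dim(y) <- shape
  y
}

#' Insert a subject adapter into a built model
#'
#' Adds one adapter on the attention-block output, just before the
#' classification head. With a zero-initialized up-projection the augmented
#' model computes exactly the same function as the original until the adapter
#' is trained.
#'
#' @param model a model from [build_model()].
#' @param cfg an [adapter_config()]; \code{input_dim} must match the model
#'   feature width (defaults to it when omitted).
#' @param seed seed for the down-projection initialization.
#' @return the model (modified in place), invisibly.
#' @export
insert_adapters <- function(model, cfg = NULL, seed = 1L) {
  stopifnot(inherits(model, "msat_model"))
  if (!is.null(model$adapter))
    stop_validation("model already contains an adapter")
  d <- model$feature_dim
  if (is.null(cfg)) cfg <- adapter_config(d)
  if (cfg$input_dim != d)
    stop_shape("adapter input_dim ", cfg$input_dim,
               " does not match model feature width ", d)
  set.seed(derive_seed(seed, 17L))
  model$adapter <- make_adapter(cfg)
  model$adapter_cfg <- cfg
  invisible(model)
}

#' Freeze everything except the adapter
#'
#' Marks every non-adapter module (including the classification head) as
#' frozen: the optimizer skips their parameters and frozen batch-norm layers
#' stop updating running statistics, so a fine-tuning run leaves all
#' non-adapter parameters bit-identical.
#'
#' @param model a model that already contains an adapter
#'   (see [insert_adapters()]).
#' @return the model, invisibly.
#' @export
freeze_all_but_adapters <- function(model) {
  stopifnot(inherits(model, "msat_model"))
  if (is.null(model$adapter))
    stop_validation("no adapter present; call insert_adapters() first")
  for (st in model$stages) set_frozen(st, TRUE)
  set_frozen(model$adapter, FALSE)
  invisible(model)
}
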