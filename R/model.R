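#' Full classifier configuration
#'
#' Assembles the multi-scale feature extractor (MSFE), the adaptive temporal
#' transformer block (temporal decoder followed by multi-head self-attention),
#' an optional subject adapter, and a flatten + fully-connected + softmax
#' classification head into \eqn{Y_{class} = F(X)}. Ablation modes drop the
#' decoder and/or attention unit to reproduce the reduced comparison models by
#' construction.
#'
#' @param n_classes number of classes (>= 2).
#' @param msfe an [msfe_config()].
#' @param decoder a [temporal_decoder_config()], or \code{NULL} to take
#'   defaults with \code{n_filters} matched to the MSFE output width.
#' @param attention_heads number of self-attention heads (default 2).
#' @param adapter an [adapter_config()] or \code{NULL}; adapters are usually
#'   inserted after pretraining with [insert_adapters()].
#' @param max_norm_dense max-norm bound applied per output row of the final
#'   dense layer after every optimizer step (default 0.25).
#' @param attention_skip add a residual connection around the attention unit
#'   (default FALSE).
#' @param ablation one of \code{"full"}, \code{"msfe_only"},
#'   \code{"msfe+decoder"}, \code{"msfe+attention"}.
#' @return an object of class \code{msat_config}.
#' @export
msat_config <- function(n_classes,
                        msfe = msfe_config(),
                        decoder = NULL,
                        attention_heads = 2L,
                        adapter = NULL,
                        max_norm_dense = 0.25,
                        attention_skip = FALSE,
                        ablation = c("full", "msfe_only", "msfe+decoder",
                                     "msfe+attention")) {
  ablation <- match.arg(ablation)
  assert_count(n_classes, "n_classes", min = 2L)
  assert_count(attention_heads, "attention_heads")
  if (!is.numeric(max_norm_dense) || max_norm_dense <= 0)
    stop_validation("max_norm_dense must be > 0")
  assert_flag(attention_skip, "attention_skip")
  stopifnot(inherits(msfe, "msfe_config"))
  d_msfe <- msfe_out_features(msfe)
  if (is.null(decoder)) decoder <- temporal_decoder_config(n_filters = d_msfe)
  stopifnot(inherits(decoder, "temporal_decoder_config"))
  structure(list(
    n_classes = as.integer(n_classes),
    msfe = msfe,
    decoder = decoder,
    attention_heads = as.integer(attention_heads),
    adapter = adapter,
    max_norm_dense = max_norm_dense,
    attention_skip = attention_skip,
    ablation = ablation
  ), class = "msat_config")
}

has_decoder <- function(cfg) cfg$ablation %in% c("full", "msfe+decoder")
has_attention <- function(cfg) cfg$ablation %in% c("full", "msfe+attention")

#' Build the end-to-end classifier
#'
#' Constructs all layers with seeded Glorot initialization. The forward pass
#' maps a \code{[C, T, B]} trial tensor to a \code{[n_classes x B]} softmax
#' probability matrix.
#'
#' @param cfg an [msat_config()].
#' @param C number of EEG channels.
#' @param T samples per trial.
#' @param seed integer initialization seed.
#' @return an object of class \code{msat_model}.
#' @export
build_model <- function(cfg, C, T, seed = 1L) {
  stopifnot(inherits(cfg, "msat_config"))
  assert_count(C, "C"); assert_count(T, "T")
  d_msfe <- msfe_out_features(cfg$msfe)
  N <- msfe_out_time(cfg$msfe, T)
  if (N < 1) stop_shape("T = ", T, " too short: MSFE output length ", N)
  d_feat <- if (has_decoder(cfg)) cfg$decoder$n_filters else d_msfe
  if (has_attention(cfg) && d_feat %% cfg$attention_heads != 0)
    stop_validation("feature width ", d_feat, " not divisible by ",
                    cfg$attention_heads, " attention heads")

  set.seed(derive_seed(seed, 23L))
  model <- new.env(parent = emptyenv())
  class(model) <- "msat_model"
  model$cfg <- cfg
  model$C <- as.integer(C); model$T <- as.integer(T)
  model$N <- N
  model$feature_dim <- d_feat
  model$seed <- as.integer(seed)
  stages <- list(msfe = make_msfe(cfg$msfe, C))
  if (has_decoder(cfg))
    stages$decoder <- make_decoder(cfg$decoder, d_msfe)
  if (has_attention(cfg))
    stages$attention <- make_attention(d_feat, cfg$attention_heads)
  stages$flatten <- make_flatten()
  stages$dense <- make_dense(d_feat * N, cfg$n_classes,
                             max_norm = cfg$max_norm_dense)
  model$stages <- stages
  model$adapter <- NULL
  if (!is.null(cfg$adapter)) insert_adapters(model, cfg$adapter, seed = seed)
  model
}

model_modules <- function(model) {
  mods <- list()
  for (st in model$stages) mods <- c(mods, collect_modules(st))
  if (!is.null(model$adapter)) mods <- c(mods, collect_modules(model$adapter))
  mods
}

model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) != 3L || dim(x)[1] != model$C || dim(x)[2] != model$T)
    stop_shape("model expects [", model$C, ", ", model$T, ", B] input, got [",
               paste(dim(x), collapse = ", "), "]")
  y <- mod_forward(model$stages$msfe, x, training)
  if (!is.null(model$stages$decoder))
    y <- mod_forward(model$stages$decoder, y, training)
  if (!is.null(model$stages$attention)) {
    a <- mod_forward(model$stages$attention, y, training)
    y <- if (model$cfg$attention_skip) y + a else a
  }
  if (!is.null(model$adapter))
    y <- mod_forward(model$adapter, y, training)
  y <- mod_forward(model$stages$flatten, y, training)
  mod_forward(model$stages$dense, y, training)
}

model_backward <- function(model, dlogits) {
  dy <- mod_backward(model$stages$dense, dlogits)
  dy <- mod_backward(model$stages$flatten, dy)
  if (!is.null(model$adapter)) dy <- mod_backward(model$adapter, dy)
  if (!is.null(model$stages$attention)) {
    da <- mod_backward(model$stages$attention, dy)
    dy <- if (model$cfg$attention_skip) dy + da else da
  }
  if (!is.null(model$stages$decoder))
    dy <- mod_backward(model$stages$decoder, dy)
  mod_backward(model$stages$msfe, dy)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

#' Predict classes for epoched trials
#'
#' Runs the model in inference mode (deterministic: dropout off, batch-norm
#' running statistics). Ties in the argmax break toward the lower class index.
#'
#' @param object an \code{msat_model}.
#' @param es an [epoch_set()] or a \code{[C, T, B]} array.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return list with \code{labels} (0-based integer vector) and
#'   \code{probabilities} (\code{[K x n_classes]} matrix, rows summing to 1).
#' @export
predict.msat_model <- function(object, es, batch_size = 128L, ...) {
  x <- if (inherits(es, "epoch_set")) es$data else es
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  K <- dim(x)[3]
  probs <- matrix(0, K, object$cfg$n_classes)
  for (start in seq(1L, K, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, K)
    logits <- model_forward(object, x[, , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(softmax_cols(logits))
  }
  labels <- max.col(probs, ties.method = "first") - 1L
  list(labels = labels, probabilities = probs)
}

#' Max-norm weight constraint
#'
#' Rescales each weight row \code{w} to \code{w * min(1, c / ||w||_2)}. Given
#' a matrix, the constraint applies per row; given a vector, to the whole
#' vector. Applied to the final dense layer after every optimizer step during
#' training (bound 0.25 by default).
#'
#' @param w numeric vector or matrix of weights.
#' @param c positive norm bound.
#' @return rescaled weights, same shape.
#' @export
apply_max_norm <- function(w, c) {
  if (!is.numeric(c) || c <= 0) stop_validation("max-norm bound must be > 0")
  if (is.matrix(w)) {
    nrm <- sqrt(rowSums(w * w))
    scale <- pmin(1, c / pmax(nrm, .Machine$double.eps))
    w * scale
  } else {
    nrm <- sqrt(sum(w * w))
    if (nrm <= c) w else w * (c / nrm)
  }
}

#' Count trainable parameters
#'
#' @param block a layer module, an \code{msat_model}, or a list of modules.
#' @return integer count of trainable scalar parameters.
#' @seealso [parameter_audit()] for the per-layer breakdown.
#' @export
count_parameters <- function(block) {
  if (inherits(block, "msat_model"))
    return(sum(vapply(model_modules(block), n_params_of, numeric(1))))
  if (is_module(block))
    return(sum(vapply(collect_modules(block), n_params_of, numeric(1))))
  if (is.list(block))
    return(sum(vapply(block, count_parameters, numeric(1))))
  stop_validation("cannot count parameters of a ", class(block)[1])
}

#' Per-layer parameter audit
#'
#' @param model an \code{msat_model} or a single module.
#' @return data.frame with columns \code{module}, \code{layer}, \code{count};
#'   \code{sum(count)} equals [count_parameters()] of the same object.
#' @export
parameter_audit <- function(model) {
  audit_one <- function(mod, path) {
    rows <- data.frame(module = character(), layer = character(),
                       count = numeric())
    n_own <- n_params_of(mod)
    if (n_own > 0)
      rows <- rbind(rows, data.frame(module = path, layer = mod$type,
                                     count = n_own))
    for (i in seq_along(mod$children))
      rows <- rbind(rows, audit_one(mod$children[[i]],
                                    paste0(path, "/", i)))
    rows
  }
  if (inherits(model, "msat_model")) {
    out <- data.frame(module = character(), layer = character(),
                      count = numeric())
    for (nm in names(model$stages))
      out <- rbind(out, audit_one(model$stages[[nm]], nm))
    if (!is.null(model$adapter))
      out <- rbind(out, audit_one(model$adapter, "adapter"))
    return(out)
  }
  audit_one(model, model$type)
}

#' Temporal decoder + attention block
#'
#' Applies the temporal decoder (if supplied) and then multi-head
#' self-attention over the time axis of each batch element. No positional
#' encoding is added; the decoder supplies the temporal structure.
#'
#' @param x array \code{[d, N, B]} or matrix \code{[d, N]}.
#' @param decoder a decoder module, or \code{NULL} to bypass.
#' @param attn attention parameters from [attention_params()].
#' @param training logical (affects decoder dropout/batch-norm only).
#' @return array/matrix of the same shape.
#' @export
att_forward <- function(x, decoder, attn, training = FALSE) {
  was_mat <- is.matrix(x)
  if (was_mat) dim(x) <- c(dim(x), 1L)
  if (!is.null(decoder)) x <- mod_forward(decoder, x, training)
  y <- array(0, dim = dim(x))
  for (b in seq_len(dim(x)[3]))
    y[, , b] <- t(multi_head_attention(t(matrix(x[, , b], dim(x)[1],
                                                dim(x)[2])), attn))
  if (was_mat) dim(y) <- dim(y)[1:2]
  y
}

#' @export
print.msat_model <- function(x, ...) {
  cat("MSATNet classifier\n")
  cat("  input: [", x$C, "channels x", x$T, "samples ]\n")
  cat("  ablation:", x$cfg$ablation,
      if (!is.null(x$adapter)) "(+ subject adapter)" else "", "\n")
  cat("  feature sequence: d =", x$feature_dim, ", N =", x$N, "\n")
  cat("  classes:", x$cfg$n_classes, "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
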