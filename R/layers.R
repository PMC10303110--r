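# Neural-network layer framework.
#
# Every layer is an environment ("module") holding its parameters, gradient
# accumulators and Adam state. Forward passes cache whatever the backward pass
# needs; backward passes accumulate parameter gradients and return the input
# gradient. Tensors are base-R arrays, feature axis first:
#   raw trials        [C, T, B]
#   temporal-conv out [F, C, T, B]
#   sequence features [F, T, B]
#   flattened         [F * T, B]
# All heavy lifting is matrix multiplication (BLAS).

new_module <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$param_names <- character()
  self$buffer_names <- character()
  self$frozen <- FALSE
  self$children <- list()
  class(self) <- c(paste0("msat_", type), "msat_module")
  self
}

is_module <- function(x) inherits(x, "msat_module")

# Flat list of a module and all descendants.
collect_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, collect_modules(ch))
  out
}

mod_forward <- function(self, x, training = FALSE) UseMethod("mod_forward")
mod_backward <- function(self, dy) UseMethod("mod_backward")

zero_grads <- function(m) {
  for (mod in collect_modules(m))
    for (p in mod$param_names) mod[[paste0("g_", p)]] <- NULL
  invisible(m)
}

acc_grad <- function(mod, name, g) {
  slot <- paste0("g_", name)
  cur <- mod[[slot]]
  mod[[slot]] <- if (is.null(cur)) g else cur + g
}

# Deep copy of all parameters and buffers (e.g. batch-norm running stats).
get_state <- function(m) {
  lapply(collect_modules(m), function(mod) {
    vals <- lapply(c(mod$param_names, mod$buffer_names), function(p) mod[[p]])
    names(vals) <- c(mod$param_names, mod$buffer_names)
    vals
  })
}

set_state <- function(m, state) {
  mods <- collect_modules(m)
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods))
    for (p in names(state[[i]])) mods[[i]][[p]] <- state[[i]][[p]]
  invisible(m)
}

n_params_of <- function(mod) {
  sum(vapply(mod$param_names, function(p) length(mod[[p]]), numeric(1)))
}

set_frozen <- function(m, frozen) {
  for (mod in collect_modules(m)) mod$frozen <- frozen
  invisible(m)
}

# Glorot-uniform draw for a weight array given fan-in / fan-out.
glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

elu_prime <- function(x) {
  d <- rep(1, length(x))
  neg <- x < 0
  d[neg] <- exp(x[neg])
  dim(d) <- dim(x)
  d
}

# -- temporal convolution on raw trials --------------------------------------
# [C, T, B] -> [F, C, T, B]; one input map, F filters of length k applied to
# every channel independently, zero-padded to keep T ("same" length).

make_tconv <- function(n_filters, k) {
  self <- new_module("tconv")
  self$F <- n_filters; self$k <- k
  self$W <- glorot(c(n_filters, k), fan_in = k, fan_out = k * n_filters)
  self$param_names <- "W"
  self
}

mod_forward.msat_tconv <- function(self, x, training = FALSE) {
  d <- dim(x); C <- d[1]; T <- d[2]; B <- d[3]
  left <- (self$k - 1L) %/% 2L
  self$cache <- list(x = x, C = C, T = T, B = B, left = left)
  tconv_fwd_cpp(x, C, T, B, self$W, left)
}

mod_backward.msat_tconv <- function(self, dy) {
  cc <- self$cache
  res <- tconv_bwd_cpp(cc$x, dy, cc$C, cc$T, cc$B, self$W, cc$left)
  acc_grad(self, "W", res$dW)
  self$cache <- NULL
  res$dx
}

# -- depthwise spatial convolution -------------------------------------------
# [F, C, T, B] -> [F*D, T, B]; per feature map, D learned spatial filters over
# all C channels (collapses the channel axis; EEGNet-style depthwise conv).

make_depthwise <- function(C, n_maps, depth_mult) {
  self <- new_module("depthwise")
  self$C <- C; self$Fin <- n_maps; self$D <- depth_mult
  self$W <- glorot(c(C, n_maps, depth_mult), fan_in = C, fan_out = C * depth_mult)
  self$param_names <- "W"
  self
}

mod_forward.msat_depthwise <- function(self, x, training = FALSE) {
  d <- dim(x)
  self$cache <- list(x = x, dims = d)
  depthwise_fwd_cpp(x, d[1], d[2], d[3], d[4], self$W, self$D)
}

mod_backward.msat_depthwise <- function(self, dy) {
  cc <- self$cache; d <- cc$dims
  res <- depthwise_bwd_cpp(cc$x, dy, d[1], d[2], d[3], d[4], self$W, self$D)
  acc_grad(self, "W", res$dW)
  self$cache <- NULL
  res$dx
}

# -- batch normalization ------------------------------------------------------
# Normalizes per feature (axis 1) over everything else. Defaults follow common
# EEG-decoder practice: momentum 0.99, epsilon 1e-3. A frozen module always
# uses its running statistics and stops updating them.

make_bn <- function(n_feat, momentum = 0.99, eps = 1e-3) {
  self <- new_module("bn")
  self$F <- n_feat; self$momentum <- momentum; self$eps <- eps
  self$gamma <- rep(1, n_feat)
  self$beta <- rep(0, n_feat)
  self$run_mean <- rep(0, n_feat)
  self$run_var <- rep(1, n_feat)
  self$param_names <- c("gamma", "beta")
  self$buffer_names <- c("run_mean", "run_var")
  self
}

mod_forward.msat_bn <- function(self, x, training = FALSE) {
  d <- dim(x); F <- d[1]
  use_batch <- training && !self$frozen
  res <- bn_fwd_cpp(x, F, self$gamma, self$beta, self$run_mean,
                    self$run_var, self$eps, use_batch)
  if (use_batch) {
    mom <- self$momentum
    self$run_mean <- mom * self$run_mean + (1 - mom) * res$mu
    self$run_var <- mom * self$run_var + (1 - mom) * res$var
  }
  y <- res$y
  dim(y) <- d
  self$cache <- list(xhat = res$xhat, invstd = res$invstd, dims = d,
                     batch_stats = use_batch)
  y
}

mod_backward.msat_bn <- function(self, dy) {
  cc <- self$cache
  res <- bn_bwd_cpp(dy, cc$xhat, cc$dims[1], self$gamma, cc$invstd,
                    cc$batch_stats)
  acc_grad(self, "gamma", res$dgamma)
  acc_grad(self, "beta", res$dbeta)
  dx <- res$dx
  dim(dx) <- cc$dims
  self$cache <- NULL
  dx
}

# -- ELU activation ----------------------------------------------------------

make_elu <- function() new_module("elu")

mod_forward.msat_elu <- function(self, x, training = FALSE) {
  y <- elu_fwd_cpp(x)
  dim(y) <- dim(x)
  self$cache <- list(y = y)
  y
}

mod_backward.msat_elu <- function(self, dy) {
  dx <- elu_bwd_cpp(dy, self$cache$y)
  dim(dx) <- dim(dy)
  self$cache <- NULL
  dx
}

# Identity stand-in (linearized probes).
make_identity <- function() new_module("identity")
mod_forward.msat_identity <- function(self, x, training = FALSE) x
mod_backward.msat_identity <- function(self, dy) dy

# -- average pooling over time -----------------------------------------------
# [F, T, B] -> [F, T', B]; default stride equals the pool length
# (non-overlapping), a stride-1 literal reading is also supported.

make_pool <- function(p, stride = p) {
  self <- new_module("pool")
  self$p <- p; self$stride <- stride
  self
}

mod_forward.msat_pool <- function(self, x, training = FALSE) {
  d <- dim(x); F <- d[1]; T <- d[2]; B <- d[3]
  p <- self$p; s <- self$stride
  if (T < p) stop_shape("time length ", T, " shorter than pool length ", p)
  To <- (T - p) %/% s + 1L
  y <- array(0, dim = c(F, To, B))
  base <- (seq_len(To) - 1L) * s
  for (i in seq_len(p)) y <- y + x[, base + i, , drop = FALSE]
  self$cache <- list(dims = d, To = To)
  y / p
}

mod_backward.msat_pool <- function(self, dy) {
  cc <- self$cache; p <- self$p; s <- self$stride
  dx <- array(0, dim = cc$dims)
  base <- (seq_len(cc$To) - 1L) * s
  g <- dy / p
  for (i in seq_len(p))
    dx[, base + i, ] <- dx[, base + i, , drop = FALSE] + g
  self$cache <- NULL
  dx
}

# -- dropout ------------------------------------------------------------------

make_dropout <- function(p) {
  self <- new_module("dropout")
  self$p <- p
  self
}

mod_forward.msat_dropout <- function(self, x, training = FALSE) {
  if (!training || self$p <= 0 || self$frozen) {
    self$cache <- NULL
    return(x)
  }
  mask <- (stats::runif(length(x)) >= self$p) / (1 - self$p)
  dim(mask) <- dim(x)
  self$cache <- list(mask = mask)
  x * mask
}

mod_backward.msat_dropout <- function(self, dy) {
  if (is.null(self$cache)) return(dy)
  dx <- dy * self$cache$mask
  self$cache <- NULL
  dx
}

# -- general 1-D convolution over sequence features ---------------------------
# [Fin, T, B] -> [Fout, T, B]; dilation d; causal (left) or centered padding.
# Causal: out[t] = sum_i W(i) x[t - d*i], x[j <= 0] = 0.

make_conv1d <- function(Fin, Fout, k, dilation = 1L, causal = FALSE,
                        bias = FALSE) {
  if (k < 1 || dilation < 1) stop_validation("kernel and dilation must be >= 1")
  self <- new_module("conv1d")
  self$Fin <- Fin; self$Fout <- Fout; self$k <- k
  self$dil <- dilation; self$causal <- causal; self$has_bias <- bias
  self$W <- glorot(c(Fout, Fin * k), fan_in = Fin * k, fan_out = Fout * k)
  self$param_names <- "W"
  if (bias) {
    self$b <- rep(0, Fout)
    self$param_names <- c("W", "b")
  }
  self
}

conv1d_offsets <- function(self) {
  k <- self$k; d <- self$dil
  if (self$causal) {
    left <- d * (k - 1L)
    offs <- left - d * (seq_len(k) - 1L)   # tap i reads x[t - d*i]
  } else {
    span <- d * (k - 1L)
    left <- span %/% 2L
    offs <- d * (seq_len(k) - 1L)
  }
  list(left = left, right = d * (k - 1L) - left, offs = offs)
}

mod_forward.msat_conv1d <- function(self, x, training = FALSE) {
  d <- dim(x); Fin <- d[1]; T <- d[2]; B <- d[3]
  geo <- conv1d_offsets(self)
  shift <- as.integer(geo$offs - geo$left)
  y <- conv1d_fwd_cpp(x, Fin, T, B, self$W, shift)
  if (self$has_bias) y <- y + self$b
  self$cache <- list(x = x, T = T, B = B, shift = shift)
  y
}

mod_backward.msat_conv1d <- function(self, dy) {
  cc <- self$cache
  if (self$has_bias) {
    dym <- dy; dim(dym) <- c(self$Fout, cc$T * cc$B)
    acc_grad(self, "b", rowSums(dym))
  }
  res <- conv1d_bwd_cpp(cc$x, dy, self$Fin, cc$T, cc$B, self$W, cc$shift)
  acc_grad(self, "W", res$dW)
  self$cache <- NULL
  res$dx
}

# -- flatten ------------------------------------------------------------------

make_flatten <- function() new_module("flatten")

mod_forward.msat_flatten <- function(self, x, training = FALSE) {
  d <- dim(x)
  self$cache <- list(dims = d)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

mod_backward.msat_flatten <- function(self, dy) {
  dim(dy) <- self$cache$dims
  self$cache <- NULL
  dy
}

# -- dense --------------------------------------------------------------------

make_dense <- function(n_in, n_out, max_norm = NULL) {
  self <- new_module("dense")
  self$n_in <- n_in; self$n_out <- n_out; self$max_norm <- max_norm
  self$W <- glorot(c(n_out, n_in), fan_in = n_in, fan_out = n_out)
  self$b <- rep(0, n_out)
  self$param_names <- c("W", "b")
  self
}

mod_forward.msat_dense <- function(self, x, training = FALSE) {
  self$cache <- list(x = x)
  self$W %*% x + self$b
}

mod_backward.msat_dense <- function(self, dy) {
  acc_grad(self, "W", dy %*% t(self$cache$x))
  acc_grad(self, "b", rowSums(dy))
  dx <- crossprod(self$W, dy)
  self$cache <- NULL
  dx
}

# -- sequential container -----------------------------------------------------

make_sequential <- function(children, type = "sequential") {
  self <- new_module(type)
  if (type != "sequential")
    class(self) <- c(paste0("msat_", type), "msat_sequential", "msat_module")
  self$children <- children
  self
}

mod_forward.msat_sequential <- function(self, x, training = FALSE) {
  for (ch in self$children) x <- mod_forward(ch, x, training)
  x
}

mod_backward.msat_sequential <- function(self, dy) {
  for (ch in rev(self$children)) dy <- mod_backward(ch, dy)
  dy
}

# -- Adam ---------------------------------------------------------------------

adam_step <- function(modules, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (mod in modules) {
    if (mod$frozen) next
    for (p in mod$param_names) {
      g <- mod[[paste0("g_", p)]]
      if (is.null(g)) next
      st <- mod$adam[[p]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      if (is.null(mod$adam)) mod$adam <- list()
      mod$adam[[p]] <- st
      mod[[p]] <- mod[[p]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(NULL)
}
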