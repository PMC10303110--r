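#' Multi-head self-attention over a feature sequence
#'
#' Scaled dot-product self-attention with \code{H} parallel heads over a
#' sequence of \code{N} time steps with \code{d} features. Each head \code{h}
#' projects the full input \code{X} with its own matrices
#' \eqn{W^Q_h, W^K_h, W^V_h \in R^{d \times d/H}} (equivalent to one fused
#' \eqn{d \times d} map), computes row-softmax attention weights
#' \eqn{A_h = \mathrm{softmax}(Q_h K_h^\top / \sqrt{d_k})}, and the head
#' outputs are concatenated and mixed by \eqn{W_o \in R^{d \times d}}. No
#' positional encoding is added: in the full network the temporal decoder
#' upstream supplies the temporal structure.
#'
#' @param X numeric matrix \code{[N x d]}, one row per time step.
#' @param params attention parameter set from [attention_params()].
#' @param return_weights if \code{TRUE}, also return the per-head attention
#'   weight matrices.
#' @return the \code{[N x d]} output matrix, or (with weights) a list with
#'   elements \code{out} and \code{weights} (a list of \code{[N x N]}
#'   matrices, one per head; every row sums to 1).
#' @seealso [attention_params()]
#' @export
multi_head_attention <- function(X, params, return_weights = FALSE) {
  if (!is.matrix(X) || !is.numeric(X)) stop_validation("X must be a numeric matrix")
  d <- ncol(X)
  if (d != params$d)
    stop_shape("X has ", d, " features but params expect ", params$d)
  H <- params$H
  dk <- d %/% H
  Z <- matrix(0, nrow(X), d)
  weights <- vector("list", H)
  for (h in seq_len(H)) {
    Q <- X %*% params$Wq[, , h]
    K <- X %*% params$Wk[, , h]
    V <- X %*% params$Wv[, , h]
    A <- row_softmax(tcrossprod(Q, K) / sqrt(dk))
    weights[[h]] <- A
    Z[, (h - 1L) * dk + seq_len(dk)] <- A %*% V
  }
  out <- Z %*% params$Wo
  if (return_weights) list(out = out, weights = weights) else out
}

#' Initialize multi-head attention parameters
#'
#' Draws Glorot-uniform per-head projection matrices and the output projection
#' for [multi_head_attention()]. \code{d} must be divisible by \code{H}; key,
#' query and value widths are all \code{d / H}.
#'
#' @param d model (feature) dimension.
#' @param H number of attention heads (the network default is 2).
#' @return list with arrays \code{Wq}, \code{Wk}, \code{Wv} of dim
#'   \code{[d, d/H, H]}, matrix \code{Wo} \code{[d x d]}, and sizes
#'   \code{d}, \code{H}, \code{dk}.
#' @export
attention_params <- function(d, H = 2L) {
  assert_count(d, "d"); assert_count(H, "H")
  if (d %% H != 0) stop_validation("d (", d, ") must be divisible by H (", H, ")")
  dk <- d %/% H
  list(
    d = as.integer(d), H = as.integer(H), dk = as.integer(dk),
    Wq = glorot(c(d, dk, H), d, dk),
    Wk = glorot(c(d, dk, H), d, dk),
    Wv = glorot(c(d, dk, H), d, dk),
    Wo = glorot(c(d, d), d, d)
  )
}

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# -- trainable attention module ----------------------------------------------
# Wraps the same arithmetic as multi_head_attention for [d, N, B] tensors and
# adds the backward pass. Tests assert the two code paths agree exactly.

make_attention <- function(d, H) {
  self <- new_module("attention")
  p <- attention_params(d, H)
  self$d <- p$d; self$H <- p$H; self$dk <- p$dk
  self$Wq <- p$Wq; self$Wk <- p$Wk; self$Wv <- p$Wv; self$Wo <- p$Wo
  self$param_names <- c("Wq", "Wk", "Wv", "Wo")
  self
}

attn_param_list <- function(self) {
  list(d = self$d, H = self$H, dk = self$dk,
       Wq = self$Wq, Wk = self$Wk, Wv = self$Wv, Wo = self$Wo)
}

# Batched forward: batch elements are stacked into one [B*N, d] matrix so the
# projections and softmax run as single BLAS/vector ops; only the [N x N]
# score products loop over the batch.
mod_forward.msat_attention <- function(self, x, training = FALSE) {
  dims <- dim(x); d <- dims[1]; N <- dims[2]; B <- dims[3]
  if (d != self$d) stop_shape("attention expects ", self$d, " features, got ", d)
  H <- self$H; dk <- self$dk
  Xall <- aperm(x, c(2, 3, 1)); dim(Xall) <- c(N * B, d)   # rows (n, b)
  Zall <- matrix(0, N * B, d)
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    Q <- Xall %*% self$Wq[, , h]
    K <- Xall %*% self$Wk[, , h]
    V <- Xall %*% self$Wv[, , h]
    S <- matrix(0, N * B, N)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * N + seq_len(N)
      S[rows, ] <- tcrossprod(Q[rows, , drop = FALSE],
                              K[rows, , drop = FALSE])
    }
    A <- row_softmax(S / sqrt(dk))
    for (b in seq_len(B)) {
      rows <- (b - 1L) * N + seq_len(N)
      Zall[rows, (h - 1L) * dk + seq_len(dk)] <-
        A[rows, , drop = FALSE] %*% V[rows, , drop = FALSE]
    }
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A)
  }
  Yall <- Zall %*% self$Wo
  dim(Yall) <- c(N, B, d)
  self$cache <- list(Xall = Xall, Zall = Zall, heads = heads,
                     N = N, B = B)
  aperm(Yall, c(3, 1, 2))
}

mod_backward.msat_attention <- function(self, dy) {
  dims <- dim(dy); d <- dims[1]
  cc <- self$cache; N <- cc$N; B <- cc$B
  H <- self$H; dk <- self$dk
  sc <- 1 / sqrt(dk)
  dYall <- aperm(dy, c(2, 3, 1)); dim(dYall) <- c(N * B, d)
  acc_grad(self, "Wo", crossprod(cc$Zall, dYall))
  dZ <- tcrossprod(dYall, self$Wo)
  dXall <- matrix(0, N * B, d)
  dWq <- self$Wq * 0; dWk <- self$Wk * 0; dWv <- self$Wv * 0
  for (h in seq_len(H)) {
    hc <- cc$heads[[h]]
    dZh <- dZ[, (h - 1L) * dk + seq_len(dk), drop = FALSE]
    dA <- matrix(0, N * B, N)
    dV <- matrix(0, N * B, dk)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * N + seq_len(N)
      dA[rows, ] <- tcrossprod(dZh[rows, , drop = FALSE],
                               hc$V[rows, , drop = FALSE])
      dV[rows, ] <- crossprod(hc$A[rows, , drop = FALSE],
                              dZh[rows, , drop = FALSE])
    }
    tmp <- dA * hc$A
    dS <- tmp - hc$A * rowSums(tmp)          # softmax backward, rowwise
    dQ <- matrix(0, N * B, dk)
    dK <- matrix(0, N * B, dk)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * N + seq_len(N)
      dQ[rows, ] <- (dS[rows, , drop = FALSE] %*%
                       hc$K[rows, , drop = FALSE]) * sc
      dK[rows, ] <- (crossprod(dS[rows, , drop = FALSE],
                               hc$Q[rows, , drop = FALSE])) * sc
    }
    dWq[, , h] <- crossprod(cc$Xall, dQ)
    dWk[, , h] <- crossprod(cc$Xall, dK)
    dWv[, , h] <- crossprod(cc$Xall, dV)
    dXall <- dXall + tcrossprod(dQ, self$Wq[, , h]) +
      tcrossprod(dK, self$Wk[, , h]) + tcrossprod(dV, self$Wv[, , h])
  }
  acc_grad(self, "Wq", dWq); acc_grad(self, "Wk", dWk)
  acc_grad(self, "Wv", dWv)
  dim(dXall) <- c(N, B, d)
  self$cache <- NULL
  aperm(dXall, c(3, 1, 2))
}
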