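# Independent oracles, deliberately written with explicit elementwise loops
# so they share no code path with the implementation they check.

# Brute-force multi-head self-attention: every projection, score, softmax and
# contraction by direct summation.
brute_force_attention <- function(X, params) {
  N <- nrow(X); d <- ncol(X); H <- params$H; dk <- d %/% H
  Z <- matrix(0, N, H * dk)
  for (h in seq_len(H)) {
    Q <- matrix(0, N, dk); K <- matrix(0, N, dk); V <- matrix(0, N, dk)
    for (n in seq_len(N)) for (j in seq_len(dk)) {
      for (i in seq_len(d)) {
        Q[n, j] <- Q[n, j] + X[n, i] * params$Wq[i, j, h]
        K[n, j] <- K[n, j] + X[n, i] * params$Wk[i, j, h]
        V[n, j] <- V[n, j] + X[n, i] * params$Wv[i, j, h]
      }
    }
    for (n in seq_len(N)) {
      scores <- numeric(N)
      for (m in seq_len(N)) {
        s <- 0
        for (j in seq_len(dk)) s <- s + Q[n, j] * K[m, j]
        scores[m] <- s / sqrt(dk)
      }
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      for (j in seq_len(dk))
        Z[n, (h - 1) * dk + j] <- sum(w * V[, j])
    }
  }
  out <- matrix(0, N, d)
  for (n in seq_len(N)) for (j in seq_len(d))
    out[n, j] <- sum(Z[n, ] * params$Wo[, j])
  out
}

# Direct-summation dilated causal convolution.
brute_force_dcc <- function(x, f, d) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (i in seq_along(f)) {
      src <- t - d * (i - 1)
      if (src >= 1) out[t] <- out[t] + f[i] * x[src]
    }
  out
}

# Periodogram band power computed with its own FFT call per channel.
oracle_band_power <- function(es, band, channel) {
  ch <- match(channel, es$channel_names)
  T <- dim(es$data)[2]
  freqs <- (seq_len(T) - 1) * es$fs / T
  sel <- which(freqs >= band[1] & freqs <= band[2])
  vapply(seq_len(dim(es$data)[3]), function(k) {
    sp <- abs(stats::fft(es$data[ch, , k]))^2 / T
    mean(sp[sel])
  }, numeric(1))
}

# Band-power + regularized linear model baseline used for the separability
# dial; falls back to multinomial logistic via glm-free ridge on indicators.
bandpower_features <- function(es) {
  cbind(mu_C3 = band_power(es, c(8, 13), "C3"),
        mu_Cz = band_power(es, c(8, 13), "Cz"),
        mu_C4 = band_power(es, c(8, 13), "C4"),
        be_C3 = band_power(es, c(18, 26), "C3"),
        be_Cz = band_power(es, c(18, 26), "Cz"),
        be_C4 = band_power(es, c(18, 26), "C4"))
}

ridge_classifier_accuracy <- function(train, test) {
  Xtr <- scale(log(bandpower_features(train)))
  ctr <- attr(Xtr, "scaled:center"); sdr <- attr(Xtr, "scaled:scale")
  Xte <- scale(log(bandpower_features(test)), center = ctr, scale = sdr)
  n_cl <- length(train$class_names)
  Y <- sapply(seq_len(n_cl) - 1L, function(cl) as.numeric(train$labels == cl))
  A <- crossprod(cbind(1, Xtr)) + diag(1e-2, ncol(Xtr) + 1)
  Bc <- solve(A, crossprod(cbind(1, Xtr), Y))
  pred <- max.col(cbind(1, Xte) %*% Bc, ties.method = "first") - 1L
  mean(pred == test$labels)
}
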