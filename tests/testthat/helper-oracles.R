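# Independent brute-force oracles used to verify the fast implementations.

# Direct O(N^2) summation of the Gaussian-window STFT definition:
# F(t, w_k) = sum_tau x(tau) g(t - tau) exp(-i w_k tau), zero-padded signal,
# w_k = 2 pi k / (2 (n_freq - 1)). No FFT anywhere.
oracle_stft <- function(x, cfg) {
  n <- length(x)
  half <- (cfg$window_len - 1) / 2
  nfft <- 2 * (cfg$n_freq - 1)
  gfun <- function(u) {
    w <- exp(-u^2 / (2 * cfg$window_sd^2)) / (cfg$window_sd * sqrt(2 * pi))
    w[abs(u) > half] <- 0 # truncated window
    w
  }
  times <- seq(0, n - 1, by = cfg$hop)
  out <- matrix(0 + 0i, length(times), cfg$n_freq)
  for (ti in seq_along(times)) {
    t0 <- times[ti]
    for (k in seq_len(cfg$n_freq)) {
      w <- 2 * pi * (k - 1) / nfft
      tau <- (t0 - half):(t0 + half)
      xv <- numeric(length(tau))
      inside <- tau >= 0 & tau < n
      xv[inside] <- x[tau[inside] + 1]
      out[ti, k] <- sum(xv * gfun(t0 - tau) * exp(-1i * w * tau))
    }
  }
  out
}

# Dense-loop positional self-attention for one head: per query i, logits over
# keys j, explicit softmax, weighted value sum. Token rows.
oracle_psa <- function(X, Wq, Wk, Wv, v_pos, r_enc, scale = TRUE) {
  n <- nrow(X)
  Q <- X %*% t(Wq); K <- X %*% t(Wk); V <- X %*% t(Wv)
  pos <- matrix(r_enc %*% v_pos, n, n)
  out <- matrix(0, n, ncol(Q))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    logit <- numeric(n)
    for (j in seq_len(n)) {
      logit[j] <- sum(Q[i, ] * K[j, ]) / (if (scale) sqrt(nrow(Wq)) else 1) +
        pos[i, j]
    }
    e <- exp(logit - max(logit))
    A[i, ] <- e / sum(e)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + A[i, j] * V[j, ]
  }
  list(values = out, attention = A)
}

# Independent tally-by-loop confusion counting.
oracle_confusion <- function(truth, pred, classes) {
  k <- length(classes)
  m <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  per <- lapply(classes, function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    tn <- sum(truth != c & pred != c)
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  })
  list(matrix = m, per_class = do.call(rbind, per))
}

# Independently coded per-class metric formulas from the confusion cells.
oracle_metrics <- function(tp, tn, fp, fn, f1_factor = 2) {
  sen <- if (tp + fn == 0) 0 else tp / (tp + fn)
  ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
  list(
    Acc = (tp + tn) / (tp + tn + fp + fn),
    Sen = sen,
    Spe = if (tn + fp == 0) 0 else tn / (tn + fp),
    Ppv = ppv,
    F1 = if (ppv + sen == 0) 0 else f1_factor * ppv * sen / (ppv + sen),
    MCC = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den == 0) 0 else (tp * tn - fp * fn) / den
    }
  )
}

# AUC as the normalized Mann-Whitney U statistic (ties count 1/2).
oracle_auc_mwu <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}

# tiny architecture used across the model tests
tiny_config <- function(...) {
  args <- list(n_blocks = 2, n_gpsa = 1, n_heads = 2, embed_dim = 4,
               image_size = 8, patch_size = 4, ffn_mult = 2, dropout = 0,
               l2 = 0, n_classes = 3, classes = c("A", "B", "C"))
  over <- list(...)
  args[names(over)] <- over
  do.call(convit_config, args)
}

random_images <- function(n, side = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(stats::runif(side^2), side, side))
}
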