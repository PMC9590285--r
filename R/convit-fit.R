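#' ConViT architecture configuration
#'
#' The published architecture is 12 propagation blocks, each a self-attention
#' layer plus a two-layer GELU feed-forward network; the attention in the
#' first ten blocks is gated positional self-attention (GPSA), the last two
#' keep plain self-attention (SA). 160 x 160 input images are split into an
#' 8 x 8 grid of 20 x 20 patches embedded in 12 dimensions. Defaults below
#' reproduce that layout; desk-scale experiments typically shrink `n_blocks`.
#'
#' @param n_blocks Total propagation blocks.
#' @param n_gpsa How many leading blocks use GPSA (the rest use SA).
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param embed_dim Token embedding dimension.
#' @param image_size,patch_size Image side and patch side in pixels;
#'   `image_size` must be a multiple of `patch_size`.
#' @param ffn_mult Hidden width of the FFN as a multiple of `embed_dim`.
#' @param dropout Dropout rate applied inside the FFN during training.
#' @param l2 L2 penalty coefficient on the FFN weights.
#' @param n_classes Number of output classes.
#' @param classes Class labels.
#' @param scale_content_gpsa Apply `1/sqrt(d)` scaling to the content logits
#'   inside GPSA (the gated attention is used unscaled by default; SA blocks
#'   are always scaled).
#' @param init_sd Named list of initialization standard deviations for the
#'   weight groups: `proj` (patch embedding; `NULL` = `1/patch_size`), `qk`
#'   (query/key), `v` (value), `out` (attention output), `head`
#'   (classification head). Optional entries `w1`, `w2` override the He
#'   defaults (`sqrt(2/fan_in)`) of the FFN layers; a small `w2` (and `out`)
#'   keeps the residual stream dominated by patch content at initialization
#'   instead of random FFN features, which matters at small step budgets.
#' @param pos_embed `"none"` (default) relies on GPSA's relative encodings
#'   alone, as in the published architecture; `"sinusoidal"` additionally adds
#'   the fixed [sinusoidal_encoding()] to the patch tokens.
#' @param pe_scale Amplitude of the sinusoidal encoding.
#' @return An object of class `"convit_config"`.
#' @export
convit_config <- function(n_blocks = 12L, n_gpsa = 10L, n_heads = 4L,
                          embed_dim = 12L, image_size = 160L, patch_size = 20L,
                          ffn_mult = 4L, dropout = 0.5, l2 = 1e-4,
                          n_classes = 5L, classes = aami_classes(),
                          scale_content_gpsa = FALSE,
                          init_sd = list(proj = NULL, qk = 0.02, v = 0.2,
                                         out = 0.2, head = 0.02),
                          pos_embed = c("none", "sinusoidal"), pe_scale = 0.5) {
  pos_embed <- match.arg(pos_embed)
  if (n_gpsa > n_blocks) stop("n_gpsa cannot exceed n_blocks")
  if (embed_dim %% n_heads != 0) stop("n_heads must divide embed_dim")
  if (image_size %% patch_size != 0) {
    stop("image_size must be a multiple of patch_size")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (length(classes) != n_classes) stop("classes must have length n_classes")
  structure(list(n_blocks = as.integer(n_blocks), n_gpsa = as.integer(n_gpsa),
                 n_heads = as.integer(n_heads), embed_dim = as.integer(embed_dim),
                 image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 grid_side = as.integer(image_size %/% patch_size),
                 ffn_mult = as.integer(ffn_mult), dropout = dropout, l2 = l2,
                 n_classes = as.integer(n_classes), classes = classes,
                 scale_content_gpsa = scale_content_gpsa,
                 init_sd = init_sd, pos_embed = pos_embed,
                 pe_scale = pe_scale),
            class = "convit_config")
}

#' Training configuration
#'
#' Defaults follow the published training recipe: learning rate 1e-4, batch
#' size 32, 120 epochs, decay 0.02 every 10 epochs, focal loss with
#' `gamma = 2`. The decay is read as multiplying the learning rate by
#' `(1 - 0.02)` every `decay_every` epochs; `decay_mode = "weight"` instead
#' applies it as plain weight decay at the same cadence.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (>= 1).
#' @param lr_decay Decay factor applied every `decay_every` epochs.
#' @param decay_every Epoch cadence of the decay.
#' @param decay_mode `"lr"` or `"weight"`.
#' @param gamma Focal-loss focusing exponent.
#' @param class_weights Optional named per-class loss weights.
#' @param seed RNG seed for shuffling, init and dropout.
#' @param val_every Evaluate the validation set every this many epochs (the
#'   final epoch is always evaluated). Pure monitoring cadence: evaluation
#'   draws no random numbers, so it never changes the trained model.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L, epochs = 120L,
                         lr_decay = 0.02, decay_every = 10L,
                         decay_mode = c("lr", "weight"), gamma = 2,
                         class_weights = NULL, seed = 1L, val_every = 1L) {
  decay_mode <- match.arg(decay_mode)
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0 || batch_size < 1) stop("invalid training parameters")
  if (val_every < 1) stop("val_every must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), decay_mode = decay_mode,
                 gamma = gamma, class_weights = class_weights,
                 seed = as.integer(seed), val_every = as.integer(val_every)),
            class = "train_config")
}

#' Learning rate at a given epoch under the decay schedule
#' @param control A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return The Adam step size used during that epoch.
#' @export
lr_at_epoch <- function(control, epoch) {
  if (control$decay_mode != "lr") return(control$learning_rate)
  control$learning_rate *
    (1 - control$lr_decay)^((epoch - 1) %/% control$decay_every)
}

# ---- parameter tree utilities -----------------------------------------------

.tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, .tree_map, f = f) else f(a)
}
.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

# ---- initialization ---------------------------------------------------------

# Random init: small Gaussian weights everywhere; GPSA positional vectors are
# convolution-initialized on a spiral of small offsets with unit locality
# strength and the gate starts at sigmoid(1) ~ 0.73 toward positional
# attention, so early training behaves like a soft convolution.
.convit_init <- function(cfg) {
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  De <- cfg$embed_dim
  H <- cfg$ffn_mult * De
  sds <- cfg$init_sd
  proj_sd <- if (is.null(sds$proj)) 1 / cfg$patch_size else sds$proj
  centers <- .spiral_offsets(cfg$n_heads)
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    blk <- list(
      ln1 = list(g = rep(1, De), b = rep(0, De)),
      Wq = rn(De, De, sds$qk), Wk = rn(De, De, sds$qk),
      Wv = rn(De, De, sds$v),
      Wout = rn(De, De, sds$out), bout = rep(0, De),
      ln2 = list(g = rep(1, De), b = rep(0, De)),
      W1 = rn(H, De, sds$w1 %||% sqrt(2 / De)), b1 = rep(0, H),
      W2 = rn(De, H, sds$w2 %||% sqrt(2 / H)), b2 = rep(0, De))
    if (b <= cfg$n_gpsa) {
      blk$upos <- sapply(seq_len(cfg$n_heads), function(h) {
        -1 * c(1, -2 * centers[h, 1], -2 * centers[h, 2])
      })
      blk$lambda <- rep(1, cfg$n_heads)
    }
    blk
  })
  list(proj = list(W = rn(De, cfg$patch_size^2, proj_sd),
                   b = rep(0, De)),
       blocks = blocks,
       ln_f = list(g = rep(1, De), b = rep(0, De)),
       head = list(W = rn(cfg$n_classes, De, sds$head),
                   b = rep(0, cfg$n_classes)))
}

# first n offsets of an outward grid spiral around (0,0): distinct small
# relative positions for the conv-initialized heads
.spiral_offsets <- function(n) {
  cand <- expand.grid(row = -3:3, col = -3:3)
  cand <- cand[order(cand$row^2 + cand$col^2, cand$row, cand$col), ]
  as.matrix(cand[seq_len(n), ])
}

# positional attention matrices (shared across a batch): per GPSA block, a
# list over heads of row-stochastic N x N matrices
.pos_cache <- function(params, cfg, r_enc) {
  out <- lapply(seq_len(cfg$n_blocks), function(b) {
    if (b > cfg$n_gpsa) return(NULL)
    up <- params$blocks[[b]]$upos
    lapply(seq_len(cfg$n_heads), function(h) {
      .softmax_rows(.pos_logits(r_enc, up[, h]))
    })
  })
  attr(out, "r_enc") <- r_enc
  if (identical(cfg$pos_embed, "sinusoidal")) {
    attr(out, "pe") <- sinusoidal_encoding(cfg$grid_side, cfg$embed_dim,
                                           cfg$pe_scale)
  }
  out
}

# ---- layer-norm forward/backward (row-wise over tokens) ---------------------

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  inv <- 1 / sqrt(.rowMeans(xc^2, n, d) + eps)
  xhat <- xc * inv
  list(Y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  n <- nrow(dY); d <- ncol(dY)
  dxhat <- dY * rep(g, each = n)
  dX <- cache$inv * (dxhat - .rowMeans(dxhat, n, d) -
                       cache$xhat * .rowMeans(dxhat * cache$xhat, n, d))
  list(dX = dX, dg = .colSums(dY * cache$xhat, n, d), db = .colSums(dY, n, d))
}

# ---- forward pass -----------------------------------------------------------

# P: stacked patch matrix (B * n_tokens) x patch_size^2, rows grouped by
# sample. All token-wise operations (layer norm, linear maps, the FFN) run on
# the whole stack at once; only the attention matrices are per sample.
# Returns class probabilities (vector for B = 1, else B x K matrix) and, when
# keep_cache, everything backward needs. Dropout masks are drawn from the
# current RNG stream when train = TRUE.
.convit_forward <- function(params, cfg, P, pos, train = FALSE,
                            keep_cache = FALSE, B = 1L) {
  BN <- nrow(P); De <- cfg$embed_dim
  N <- BN %/% B # tokens per sample
  Dh <- De %/% cfg$n_heads
  X <- tcrossprod(P, params$proj$W) + rep(params$proj$b, each = BN)
  pe <- attr(pos, "pe", exact = TRUE)
  if (!is.null(pe)) X <- X + pe[rep.int(seq_len(N), B), , drop = FALSE]
  caches <- if (keep_cache) vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    pb <- params$blocks[[b]]
    gpsa <- b <= cfg$n_gpsa
    l1 <- .ln_fwd(X, pb$ln1$g, pb$ln1$b)
    Z <- l1$Y
    Qa <- tcrossprod(Z, pb$Wq); Ka <- tcrossprod(Z, pb$Wk); Va <- tcrossprod(Z, pb$Wv)
    HV <- matrix(0, BN, De)
    heads <- if (keep_cache) vector("list", cfg$n_heads)
    # per head: per-sample content logits stacked into one (B*N) x N matrix so
    # softmax / gating / renormalization run as single vectorized calls
    for (h in seq_len(cfg$n_heads)) {
      hc <- ((h - 1L) * Dh + 1L):(h * Dh)
      Qh <- Qa[, hc, drop = FALSE]; Kh <- Ka[, hc, drop = FALSE]
      L <- matrix(0, BN, N)
      for (smp in seq_len(B)) {
        rows <- ((smp - 1L) * N + 1L):(smp * N)
        L[rows, ] <- tcrossprod(Qh[rows, , drop = FALSE],
                                Kh[rows, , drop = FALSE])
      }
      if (gpsa) {
        if (cfg$scale_content_gpsa) L <- L / sqrt(Dh)
        C <- .softmax_rows(L)
        g <- 1 / (1 + exp(-pb$lambda[h]))
        Pst <- pos[[b]][[h]][rep.int(seq_len(N), B), , drop = FALSE]
        A0 <- (1 - g) * C + g * Pst
        s <- .rowSums(A0, BN, N)
        A <- A0 / s
        if (keep_cache) heads[[h]] <- list(A = A, C = C, s = s, g = g, Pst = Pst)
      } else {
        A <- .softmax_rows(L / sqrt(Dh))
        if (keep_cache) heads[[h]] <- list(A = A)
      }
      Vh <- Va[, hc, drop = FALSE]
      for (smp in seq_len(B)) {
        rows <- ((smp - 1L) * N + 1L):(smp * N)
        HV[rows, hc] <- A[rows, , drop = FALSE] %*% Vh[rows, , drop = FALSE]
      }
    }
    attn <- tcrossprod(HV, pb$Wout) + rep(pb$bout, each = BN)
    X2 <- X + attn
    l2c <- .ln_fwd(X2, pb$ln2$g, pb$ln2$b)
    Z2 <- l2c$Y
    H1 <- tcrossprod(Z2, pb$W1) + rep(pb$b1, each = BN)
    Phi <- stats::pnorm(H1)
    G <- H1 * Phi
    M <- if (train && cfg$dropout > 0) {
      (matrix(stats::runif(length(G)), nrow(G)) >= cfg$dropout) /
        (1 - cfg$dropout)
    } else NULL
    Gd <- if (is.null(M)) G else G * M
    FF <- tcrossprod(Gd, pb$W2) + rep(pb$b2, each = BN)
    Xn <- X2 + FF
    if (keep_cache) {
      caches[[b]] <- list(l1 = l1, Z = Z, Qa = Qa, Ka = Ka, Va = Va,
                          heads = heads, HV = HV, l2c = l2c, Z2 = Z2,
                          H1 = H1, Phi = Phi, M = M, Gd = Gd, X = X, X2 = X2)
    }
    X <- Xn
  }
  lf <- .ln_fwd(X, params$ln_f$g, params$ln_f$b)
  pooled <- rowsum(lf$Y, group = rep(seq_len(B), each = N), reorder = FALSE) / N
  logits <- tcrossprod(pooled, params$head$W) + rep(params$head$b, each = B)
  probs <- .softmax_rows(logits)
  if (B == 1L) {
    probs <- as.vector(probs); logits <- as.vector(logits)
  }
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- list(blocks = caches, lf = lf, pooled = pooled, P = P,
                      X_last = X, N = N, BN = BN)
  }
  out
}

# focal loss values and gradients w.r.t. logits for a batch: probs is B x K,
# yidx and w length-B vectors. Returns the summed loss and B x K dlogits.
.focal_grad <- function(probs, yidx, gamma, w = 1) {
  if (!is.matrix(probs)) probs <- matrix(probs, 1)
  B <- nrow(probs)
  pt <- pmax(probs[cbind(seq_len(B), yidx)], 1e-12)
  loss <- -w * (1 - pt)^gamma * log(pt)
  dpt <- if (gamma == 0) -1 / pt else {
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  }
  onehot <- matrix(0, B, ncol(probs))
  onehot[cbind(seq_len(B), yidx)] <- 1
  dlogits <- (w * dpt * pt) * (onehot - probs)
  list(loss = sum(loss), dlogits = dlogits)
}

# ---- backward pass ------------------------------------------------------------

# Mirrors .convit_forward's batch layout: weight gradients come out as sums
# over the B stacked samples. dlogits is B x K.
.convit_backward <- function(params, cfg, fwd, dlogits, pos, B = 1L) {
  cache <- fwd$cache
  BN <- cache$BN; N <- BN %/% B
  De <- cfg$embed_dim; Dh <- De %/% cfg$n_heads
  if (!is.matrix(dlogits)) dlogits <- matrix(dlogits, 1)
  g <- list(proj = list(W = NULL, b = NULL), blocks = vector("list", cfg$n_blocks),
            ln_f = list(g = NULL, b = NULL), head = list(W = NULL, b = NULL))
  g$head$W <- crossprod(dlogits, cache$pooled)
  g$head$b <- colSums(dlogits)
  dpooled <- dlogits %*% params$head$W # B x De
  dZf <- dpooled[rep(seq_len(B), each = N), , drop = FALSE] / N
  lb <- .ln_bwd(dZf, cache$lf, params$ln_f$g)
  g$ln_f <- list(g = lb$dg, b = lb$db)
  dX <- lb$dX
  for (b in rev(seq_len(cfg$n_blocks))) {
    pb <- params$blocks[[b]]
    cb <- cache$blocks[[b]]
    gpsa <- b <= cfg$n_gpsa
    # FFN branch
    dFF <- dX
    dGd <- dFF %*% pb$W2
    dW2 <- crossprod(dFF, cb$Gd)
    db2 <- .colSums(dFF, BN, De)
    dG <- if (is.null(cb$M)) dGd else dGd * cb$M
    dH1 <- dG * (cb$Phi + cb$H1 * stats::dnorm(cb$H1))
    dW1 <- crossprod(dH1, cb$Z2)
    db1 <- .colSums(dH1, BN, ncol(dH1))
    dZ2 <- dH1 %*% pb$W1
    l2b <- .ln_bwd(dZ2, cb$l2c, pb$ln2$g)
    dX2 <- dX + l2b$dX
    # attention branch
    dAttn <- dX2
    dWout <- crossprod(dAttn, cb$HV)
    dbout <- .colSums(dAttn, BN, De)
    dHV <- dAttn %*% pb$Wout
    dQa <- matrix(0, BN, De); dKa <- matrix(0, BN, De); dVa <- matrix(0, BN, De)
    dupos <- if (gpsa) matrix(0, 3, cfg$n_heads)
    dlambda <- if (gpsa) numeric(cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      hc <- ((h - 1L) * Dh + 1L):(h * Dh)
      hd <- cb$heads[[h]] # A (and C, s, g) stacked over samples: (B*N) x N
      dHVh <- dHV[, hc, drop = FALSE]
      Vh <- cb$Va[, hc, drop = FALSE]
      dA <- matrix(0, BN, N)
      for (smp in seq_len(B)) {
        rows <- ((smp - 1L) * N + 1L):(smp * N)
        dA[rows, ] <- tcrossprod(dHVh[rows, , drop = FALSE],
                                 Vh[rows, , drop = FALSE])
        dVa[rows, hc] <- crossprod(hd$A[rows, , drop = FALSE],
                                   dHVh[rows, , drop = FALSE])
      }
      if (gpsa) {
        Pst <- hd$Pst
        dA0 <- (dA - .rowSums(dA * hd$A, BN, N)) / hd$s
        gte <- hd$g
        dC <- (1 - gte) * dA0
        dP <- gte * dA0
        dlambda[h] <- gte * (1 - gte) * sum(dA0 * (Pst - hd$C))
        dLc <- hd$C * (dC - .rowSums(dC * hd$C, BN, N))
        if (cfg$scale_content_gpsa) dLc <- dLc / sqrt(Dh)
        dLp <- Pst * (dP - .rowSums(dP * Pst, BN, N))
        # sum the per-sample N x N positional-logit gradients, then project
        dLp_sum <- rowsum(dLp, group = rep.int(seq_len(N), B), reorder = FALSE)
        dupos[, h] <- crossprod(attr(pos, "r_enc"), as.vector(dLp_sum))
      } else {
        dLc <- hd$A * (dA - .rowSums(dA * hd$A, BN, N)) / sqrt(Dh)
      }
      Qh <- cb$Qa[, hc, drop = FALSE]; Kh <- cb$Ka[, hc, drop = FALSE]
      for (smp in seq_len(B)) {
        rows <- ((smp - 1L) * N + 1L):(smp * N)
        dQa[rows, hc] <- dLc[rows, , drop = FALSE] %*% Kh[rows, , drop = FALSE]
        dKa[rows, hc] <- crossprod(dLc[rows, , drop = FALSE],
                                   Qh[rows, , drop = FALSE])
      }
    }
    dZ <- dQa %*% pb$Wq + dKa %*% pb$Wk + dVa %*% pb$Wv
    l1b <- .ln_bwd(dZ, cb$l1, pb$ln1$g)
    dX <- dX2 + l1b$dX
    blkg <- list(ln1 = list(g = l1b$dg, b = l1b$db),
                 Wq = crossprod(dQa, cb$Z), Wk = crossprod(dKa, cb$Z),
                 Wv = crossprod(dVa, cb$Z),
                 Wout = dWout, bout = dbout,
                 ln2 = list(g = l2b$dg, b = l2b$db),
                 W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    if (gpsa) { blkg$upos <- dupos; blkg$lambda <- dlambda }
    # keep field order identical to the parameter tree
    g$blocks[[b]] <- blkg[names(pb)]
  }
  g$proj$W <- crossprod(dX, cache$P)
  g$proj$b <- .colSums(dX, BN, De)
  g
}

# mean loss and mean gradient tree over a set of samples (used by the batch
# step and by the finite-difference gradient tests); the whole set is run as
# one stacked batch
.convit_loss_and_grads <- function(params, cfg, Plist, yidx, pos,
                                   gamma = 2, train = FALSE,
                                   want_grads = TRUE, weights = NULL) {
  n <- length(Plist)
  Pstack <- do.call(rbind, Plist)
  fwd <- .convit_forward(params, cfg, Pstack, pos, train = train,
                         keep_cache = want_grads, B = n)
  probs <- if (is.matrix(fwd$probs)) fwd$probs else matrix(fwd$probs, 1)
  fg <- .focal_grad(probs, yidx, gamma, if (is.null(weights)) 1 else weights)
  hits <- sum(max.col(probs, "first") == yidx)
  loss <- fg$loss / n
  acc <- NULL
  if (want_grads) {
    acc <- .convit_backward(params, cfg, fwd, fg$dlogits, pos, B = n)
    acc <- .tree_map(acc, function(x) x / n)
    if (cfg$l2 > 0) { # L2 penalty on the FFN weights
      for (b in seq_len(cfg$n_blocks)) {
        loss <- loss + cfg$l2 * (sum(params$blocks[[b]]$W1^2) +
                                   sum(params$blocks[[b]]$W2^2))
        acc$blocks[[b]]$W1 <- acc$blocks[[b]]$W1 +
          2 * cfg$l2 * params$blocks[[b]]$W1
        acc$blocks[[b]]$W2 <- acc$blocks[[b]]$W2 +
          2 * cfg$l2 * params$blocks[[b]]$W2
      }
    }
  } else if (cfg$l2 > 0) {
    for (b in seq_len(cfg$n_blocks)) {
      loss <- loss + cfg$l2 * (sum(params$blocks[[b]]$W1^2) +
                                 sum(params$blocks[[b]]$W2^2))
    }
  }
  list(loss = loss, grads = acc, hits = hits)
}

# ---- Adam -------------------------------------------------------------------

.adam_state <- function(params) {
  list(m = .tree_map(params, function(x) x * 0),
       v = .tree_map(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- fitting ----------------------------------------------------------------

# coerce images (list of spectrogram_image / matrices, or H x W x n array)
# into a list of patch matrices
.as_patch_list <- function(x, cfg) {
  imgs <- if (is.array(x) && length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  } else if (is.list(x)) x else stop("x must be a list of images or a 3-D array")
  lapply(imgs, function(im) {
    m <- if (inherits(im, "spectrogram_image")) im$pixels else im
    if (nrow(m) != cfg$image_size || ncol(m) != cfg$image_size) {
      stop("image is ", nrow(m), "x", ncol(m), ", expected ",
           cfg$image_size, "x", cfg$image_size)
    }
    patchify(m, cfg$patch_size)
  })
}

#' Fit a ConViT spectrogram classifier
#'
#' Trains a convolutional vision transformer on spectrogram images using
#' hand-written backpropagation and the Adam optimizer, minimizing the focal
#' loss (plus an L2 penalty on the feed-forward weights). The learning rate
#' decays by `lr_decay` every `decay_every` epochs. Given a fixed seed and
#' single-threaded BLAS the fit is deterministic.
#'
#' @param x Training images: list of `"spectrogram_image"`/matrices or a
#'   3-D array `image_size x image_size x n`.
#' @param y Training labels (character or factor, levels in
#'   `config$classes`).
#' @param val_x,val_y Optional validation set, evaluated every
#'   `control$val_every` epochs.
#' @param config A [convit_config()].
#' @param control A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `"convit"`: list with `params` (weights),
#'   `config`, `control`, `classes`, `history` (per-epoch data frame with
#'   `epoch, lr, train_loss, train_acc, val_loss, val_acc`).
#' @seealso [predict.convit()], [ecg_pipeline()]
#' @export
convit <- function(x, y, val_x = NULL, val_y = NULL,
                   config = convit_config(), control = train_config(),
                   verbose = FALSE) {
  y <- as.character(y)
  if (!all(y %in% config$classes)) {
    stop("labels outside config$classes: ",
         paste(setdiff(unique(y), config$classes), collapse = ", "))
  }
  Plist <- .as_patch_list(x, config)
  if (length(Plist) == 0) stop("empty training set")
  if (length(Plist) != length(y)) stop("x and y lengths differ")
  yidx <- match(y, config$classes)
  vP <- if (!is.null(val_x)) .as_patch_list(val_x, config)
  vy <- if (!is.null(val_y)) match(as.character(val_y), config$classes)
  w <- if (!is.null(control$class_weights)) {
    as.numeric(control$class_weights[y])
  } else NULL
  r_enc <- patch_grid_encoding(config$grid_side)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(control$seed)
  params <- .convit_init(config)
  state <- .adam_state(params)
  n <- length(Plist)
  hist <- data.frame()
  for (epoch in seq_len(control$epochs)) {
    lr <- lr_at_epoch(control, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1, n, by = control$batch_size)) {
      bi <- ord[start:min(start + control$batch_size - 1, n)]
      pos <- .pos_cache(params, config, r_enc)
      lg <- .convit_loss_and_grads(params, config, Plist[bi], yidx[bi], pos,
                                   gamma = control$gamma, train = TRUE,
                                   weights = w[bi])
      if (!is.finite(lg$loss)) {
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (learning rate ", lr, ")")
      }
      st <- .adam_step(params, lg$grads, state, lr)
      params <- st$params; state <- st$state
      if (control$decay_mode == "weight" && epoch %% control$decay_every == 0) {
        params <- .tree_map(params, function(p) p * (1 - control$lr_decay))
      }
      ep_loss <- ep_loss + lg$loss * length(bi)
      ep_hits <- ep_hits + lg$hits
    }
    row <- data.frame(epoch = epoch, lr = lr, train_loss = ep_loss / n,
                      train_acc = ep_hits / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    val_every <- control$val_every %||% 1L
    if (!is.null(vP) &&
        (epoch %% val_every == 0L || epoch == control$epochs)) {
      pos <- .pos_cache(params, config, r_enc)
      vl <- .convit_loss_and_grads(params, config, vP, vy, pos,
                                   gamma = control$gamma, train = FALSE,
                                   want_grads = FALSE)
      row$val_loss <- vl$loss
      row$val_acc <- vl$hits / length(vy)
    }
    hist <- rbind(hist, row)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f%s",
                      epoch, lr, row$train_loss, row$train_acc,
                      if (!is.na(row$val_acc)) sprintf("  val_acc %.3f",
                                                       row$val_acc)
                      else ""))
    }
  }
  structure(list(params = params, config = config, control = control,
                 classes = config$classes, history = hist,
                 n_train = n),
            class = "convit")
}

#' Predict classes or probabilities for spectrogram images
#'
#' @param object A fitted [convit()] model.
#' @param newdata Images in the same form accepted by [convit()].
#' @param type `"class"` for hard labels, `"prob"` for the per-class
#'   probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Character vector or probability matrix. Evaluation is
#'   deterministic: dropout is off.
#' @export
predict.convit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  Plist <- .as_patch_list(newdata, cfg)
  r_enc <- patch_grid_encoding(cfg$grid_side)
  pos <- .pos_cache(object$params, cfg, r_enc)
  probs <- .convit_forward(object$params, cfg, do.call(rbind, Plist), pos,
                           B = length(Plist))$probs
  if (!is.matrix(probs)) probs <- matrix(probs, 1)
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, "first")]
}

#' @export
print.convit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("ConViT classifier: %d blocks (%d GPSA + %d SA), %d heads, D_emb = %d\n",
              cfg$n_blocks, cfg$n_gpsa, cfg$n_blocks - cfg$n_gpsa,
              cfg$n_heads, cfg$embed_dim))
  cat(sprintf("  input %dx%d -> %dx%d patches of %dx%d px; classes: %s\n",
              cfg$image_size, cfg$image_size, cfg$grid_side, cfg$grid_side,
              cfg$patch_size, cfg$patch_size, paste(x$classes, collapse = " ")))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs on %d images; final train acc %.3f%s\n",
              nrow(x$history), x$n_train, h$train_acc,
              if (!is.na(h$val_acc)) sprintf(", val acc %.3f", h$val_acc) else ""))
  invisible(x)
}

#' @export
summary.convit <- function(object, ...) {
  npar <- sum(unlist(.tree_map(object$params, length)))
  gates <- vapply(seq_len(object$config$n_gpsa), function(b) {
    mean(1 / (1 + exp(-object$params$blocks[[b]]$lambda)))
  }, numeric(1))
  out <- list(config = object$config, n_parameters = npar,
              history = object$history, mean_gate_per_gpsa_block = gates)
  class(out) <- "summary.convit"
  out
}

#' @export
print.summary.convit <- function(x, ...) {
  cat(sprintf("ConViT with %d trainable parameters\n", x$n_parameters))
  cat("mean positional gate sigma(lambda) per GPSA block:",
      paste(sprintf("%.3f", x$mean_gate_per_gpsa_block), collapse = " "), "\n")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("final epoch: train loss %.4f, train acc %.3f", h$train_loss,
              h$train_acc))
  if (!is.na(h$val_acc)) cat(sprintf(", val loss %.4f, val acc %.3f",
                                     h$val_loss, h$val_acc))
  cat("\n")
  invisible(x)
}

#' @export
coef.convit <- function(object, ...) object$params

#' Plot training history
#'
#' Loss and accuracy per epoch, training and (if recorded) validation.
#'
#' @param x A fitted [convit()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.convit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "focal loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' Checkpoints are plain JSON (weights plus configuration), portable across
#' platforms.
#'
#' @param object A `"convit"` model.
#' @param path File path.
#' @return `path` / the restored `"convit"` object.
#' @export
write_convit <- function(object, path) {
  stopifnot(inherits(object, "convit"))
  jsonlite::write_json(
    list(params = object$params, config = unclass(object$config),
         control = unclass(object$control), classes = object$classes,
         history = object$history, n_train = object$n_train),
    path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_convit
#' @export
read_convit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  # Parameters are re-read without simplification: simplifyVector would
  # transpose the homogeneous list of blocks into a column structure.
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)$params
  if (length(j$config$init_sd$proj) == 0) j$config$init_sd["proj"] <- list(NULL)
  cfg <- do.call(convit_config,
                 j$config[setdiff(names(j$config), "grid_side")])
  ctl <- do.call(train_config, j$control)
  restore <- function(p, ref) {
    if (is.list(ref)) {
      nms <- names(ref)
      if (is.null(nms)) { # unnamed level (e.g. the list of blocks): by index
        lapply(seq_along(ref), function(i) restore(p[[i]], ref[[i]]))
      } else {
        stats::setNames(lapply(nms, function(nm) restore(p[[nm]], ref[[nm]])),
                        nms)
      }
    } else p
  }
  params <- .convit_init(cfg) # template for shapes/field order
  params <- .tree_map2(params, restore(raw, params), function(a, b) {
    # matrices were written column-major; unlist preserves that order
    if (is.matrix(a)) matrix(as.numeric(unlist(b)), nrow(a), ncol(a))
    else as.numeric(unlist(b))
  })
  structure(list(params = params, config = cfg, control = ctl,
                 classes = j$classes, history = j$history,
                 n_train = j$n_train),
            class = "convit")
}
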