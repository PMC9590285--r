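# Building blocks of the ConViT classifier: patch embedding, positional
# self-attention (PSA), its convolutional initialization, and gated positional
# self-attention (GPSA). Tokens are kept as rows: X is N x D_emb.

#' Split a spectrogram image into patch vectors
#'
#' Divides a square image into non-overlapping `patch_size` x `patch_size`
#' blocks (default: 160 -> an 8 x 8 grid of 20 x 20 patches) and flattens each
#' block into a row, in row-major patch order.
#'
#' @param image A `"spectrogram_image"` or a square numeric matrix.
#' @param patch_size Patch side length in pixels.
#' @return `n_patches` x `patch_size^2` matrix; attribute `grid_side` carries
#'   the patch-grid dimension.
#' @export
patchify <- function(image, patch_size = 20L) {
  m <- if (inherits(image, "spectrogram_image")) image$pixels else image
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("image must be square")
  side <- nrow(m)
  if (side %% patch_size != 0) {
    stop("image side ", side, " is not a multiple of patch_size ", patch_size)
  }
  g <- side %/% patch_size
  out <- matrix(0, g * g, patch_size^2)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      blk <- m[((i - 1) * patch_size + 1):(i * patch_size),
               ((j - 1) * patch_size + 1):(j * patch_size)]
      out[(i - 1) * g + j, ] <- as.vector(blk)
    }
  }
  attr(out, "grid_side") <- g
  attr(out, "patch_size") <- patch_size
  out
}

#' Reassemble an image from its patches
#'
#' Exact inverse of [patchify()]: `unpatchify(patchify(img))` reproduces the
#' image bitwise.
#'
#' @param patches Matrix from [patchify()].
#' @param patch_size Patch side length (taken from the attribute if present).
#' @return Square numeric matrix.
#' @export
unpatchify <- function(patches, patch_size = attr(patches, "patch_size")) {
  g <- as.integer(sqrt(nrow(patches)))
  if (g * g != nrow(patches)) stop("patch count is not a perfect square")
  side <- g * patch_size
  m <- matrix(0, side, side)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      m[((i - 1) * patch_size + 1):(i * patch_size),
        ((j - 1) * patch_size + 1):(j * patch_size)] <-
        matrix(patches[(i - 1) * g + j, ], patch_size, patch_size)
    }
  }
  m
}

#' Relative positional encodings of a square token grid
#'
#' For tokens laid out row-major on a `side` x `side` grid, returns the
#' 3-dimensional relative encoding \eqn{r_{ij} = (\|\delta\|^2, \delta_1,
#' \delta_2)} of every (query i, key j) pair, where \eqn{\delta} is the key's
#' grid offset from the query.
#'
#' @param side Token-grid side length (8 for 160/20).
#' @return `side^2 * side^2` x 3 matrix; `matrix(r_enc[, k], N, N)` is indexed
#'   `[query, key]`.
#' @export
patch_grid_encoding <- function(side = 8L) {
  pos <- expand.grid(col = seq_len(side) - 1L, row = seq_len(side) - 1L)
  # row-major token order: token m sits at (row = (m-1) %/% side, col = (m-1) %% side)
  d1 <- outer(pos$row, pos$row, function(q, k) k - q)
  d2 <- outer(pos$col, pos$col, function(q, k) k - q)
  cbind(as.vector(d1^2 + d2^2), as.vector(d1), as.vector(d2))
}

#' Fixed 2-D sinusoidal positional encoding for the patch-token grid
#'
#' ConViT carries positional information only through the relative encodings
#' inside GPSA, which makes the attention translation-equivariant; after
#' mean-pooling, the classifier is then nearly blind to *where* on the
#' time-frequency plane the energy sits -- exactly what distinguishes beat
#' classes on a spectrogram. At full training scale the learned patch
#' projection compensates; at small step budgets it cannot. This fixed
#' (non-learned) encoding, added to the patch tokens, restores absolute
#' position: dimensions cycle through sin/cos of the token's grid row and
#' column at geometrically increasing frequencies.
#'
#' @param side Token-grid side length.
#' @param d Embedding dimension.
#' @param scale Multiplier applied to the unit-amplitude sinusoids.
#' @return `side^2` x `d` matrix, token rows in row-major grid order.
#' @export
sinusoidal_encoding <- function(side, d, scale = 1) {
  tok <- seq_len(side * side) - 1L
  r <- tok %/% side
  cl <- tok %% side
  pe <- matrix(0, side * side, d)
  for (k in seq_len(d)) {
    w <- 2 * pi / (2 * side / 2^((k - 1L) %/% 4L))
    pe[, k] <- switch(((k - 1L) %% 4L) + 1L,
                      sin(w * r), cos(w * r), sin(w * cl), cos(w * cl))
  }
  scale * pe
}

# row-wise softmax (row maxima via max.col, much faster than apply; the
# dispatch-free .rowSums matters on this hot path)
.softmax_rows <- function(L) {
  n <- nrow(L)
  rmax <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
  e <- exp(L - rmax)
  e / .rowSums(e, n, ncol(L))
}

# positional attention logits for one head: N x N matrix of v_pos . r_ij
.pos_logits <- function(r_enc, v_pos) {
  n <- as.integer(sqrt(nrow(r_enc)))
  matrix(r_enc %*% v_pos, n, n)
}

#' Single-head positional self-attention (PSA)
#'
#' Attention logits are the sum of a scaled content term and a positional
#' term: \eqn{A_{ij} = \mathrm{softmax}_j(Q_i \cdot K_j / \sqrt{d} +
#' v_{pos}^T r_{ij})}; the head output is \eqn{A V}. Rows (queries) of the
#' attention matrix sum to 1.
#'
#' @param X Token matrix, N x D_emb.
#' @param W_qry,W_key,W_val Head projection matrices, D x D_emb.
#' @param v_pos Positional embedding vector, length >= 3.
#' @param r_enc Relative encodings from [patch_grid_encoding()].
#' @param scale Divide the content logits by `sqrt(D)` (default TRUE).
#' @return List with `values` (N x D) and `attention` (N x N).
#' @export
psa_head <- function(X, W_qry, W_key, W_val, v_pos, r_enc, scale = TRUE) {
  Q <- X %*% t(W_qry); K <- X %*% t(W_key); V <- X %*% t(W_val)
  logits <- Q %*% t(K)
  if (scale) logits <- logits / sqrt(nrow(W_qry))
  A <- .softmax_rows(logits + .pos_logits(r_enc, v_pos))
  list(values = A %*% V, attention = A)
}

#' Gated positional self-attention (GPSA)
#'
#' Blends content attention and position-only attention with a learned gate:
#' \eqn{A = (1-\sigma(\lambda))\,\mathrm{softmax}(K^T Q) +
#' \sigma(\lambda)\,\mathrm{softmax}(v_{pos}^T r)} followed by row
#' normalization; output \eqn{A V}. At \eqn{\lambda \to -\infty} this is pure
#' content attention, at \eqn{\lambda \to +\infty} pure positional attention
#' (a soft convolution when `v_pos` is convolution-initialized).
#'
#' @inheritParams psa_head
#' @param lambda Gating scalar; the gate is `sigmoid(lambda)`.
#' @param scale_content Apply `1/sqrt(D)` to the content logits (off by
#'   default: the gated form is used as printed, without the scaling).
#' @return List with `values`, `attention`, `gate`, and the two component
#'   attentions `content`, `positional`.
#' @export
gpsa_head <- function(X, W_qry, W_key, W_val, v_pos, lambda, r_enc,
                      scale_content = FALSE) {
  Q <- X %*% t(W_qry); K <- X %*% t(W_key); V <- X %*% t(W_val)
  logits <- Q %*% t(K)
  if (scale_content) logits <- logits / sqrt(nrow(W_qry))
  C <- .softmax_rows(logits)
  P <- .softmax_rows(.pos_logits(r_enc, v_pos))
  g <- 1 / (1 + exp(-lambda))
  A0 <- (1 - g) * C + g * P
  A <- A0 / rowSums(A0)
  list(values = A %*% V, attention = A, gate = g, content = C, positional = P)
}

#' Convolutional initialization of a positional attention head
#'
#' Sets \eqn{W^{qry} = W^{key} = 0}, \eqn{W^{val} = I} and
#' \eqn{v_{pos} = -\alpha\,(1, -2\Delta_1, -2\Delta_2)}, so the head's
#' positional logits equal \eqn{-\alpha\|\delta - \Delta\|^2} up to a
#' constant: attention peaks at relative offset \eqn{\Delta}, and for large
#' \eqn{\alpha} the head is a hard shift by \eqn{\Delta} — the mechanism by
#' which a multi-head layer can express a convolution.
#'
#' @param delta Length-2 integer offset (rows, cols) the head attends to.
#' @param alpha Locality strength; larger = sharper.
#' @param d_emb Token embedding dimension.
#' @param d Head dimension (defaults to `d_emb`, giving `W_val = I`).
#' @return List with `W_qry`, `W_key`, `W_val`, `v_pos`.
#' @export
conv_init_head <- function(delta, alpha = 1, d_emb = 12L, d = d_emb) {
  W0 <- matrix(0, d, d_emb)
  Wv <- diag(1, d, d_emb)
  list(W_qry = W0, W_key = W0, W_val = Wv,
       v_pos = -alpha * c(1, -2 * delta[1], -2 * delta[2]))
}

#' Offsets for a square grid of conv-initialized heads
#'
#' Centers \eqn{\Delta^h} covering a `k` x `k` offset grid (e.g. `k = 3` gives
#' the nine offsets of a 3x3 convolution kernel).
#'
#' @param n_heads Number of heads; must be a perfect square.
#' @return `n_heads` x 2 integer matrix of (row, col) offsets.
#' @export
conv_head_centers <- function(n_heads) {
  k <- as.integer(sqrt(n_heads))
  if (k * k != n_heads) {
    stop("n_heads must be a perfect square to lay heads on a filter grid")
  }
  half <- (k - 1) / 2
  as.matrix(expand.grid(row = seq_len(k) - 1 - half,
                        col = seq_len(k) - 1 - half))[, c("row", "col")]
}

# exact GELU and its derivative: gelu(x) = x * Phi(x)
.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
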