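test_that("patchify produces the 8x8 grid of 20x20 patches and inverts exactly", {
  set.seed(41)
  img <- matrix(runif(160 * 160), 160, 160)
  p <- patchify(img, 20)
  expect_equal(dim(p), c(64, 400))
  expect_identical(unpatchify(p), img)

  cimg <- matrix(0.37, 160, 160)
  pc <- patchify(cimg, 20)
  expect_true(all(pc == 0.37))
  expect_equal(nrow(unique(pc)), 1)

  expect_error(patchify(matrix(0, 150, 150), 20), "multiple")
  expect_error(patchify(matrix(0, 10, 20)), "square")
})

test_that("psa_head matches a dense-loop oracle and normalizes rows", {
  set.seed(42)
  r_enc <- patch_grid_encoding(2) # 4 tokens
  X <- matrix(rnorm(4 * 4), 4, 4)
  Wq <- matrix(rnorm(8, 0, 0.5), 2, 4)
  Wk <- matrix(rnorm(8, 0, 0.5), 2, 4)
  Wv <- matrix(rnorm(8, 0, 0.5), 2, 4)
  v <- rnorm(3)
  got <- psa_head(X, Wq, Wk, Wv, v, r_enc)
  want <- oracle_psa(X, Wq, Wk, Wv, v, r_enc)
  expect_lt(max(abs(got$values - want$values)), 1e-10)
  expect_lt(max(abs(got$attention - want$attention)), 1e-10)
  expect_equal(rowSums(got$attention), rep(1, 4), tolerance = 1e-12)

  # zero positional term + identical tokens -> uniform attention
  Xc <- matrix(1, 4, 4)
  u <- psa_head(Xc, Wq, Wk, Wv, c(0, 0, 0), r_enc)
  expect_equal(unname(u$attention), matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("conv-initialized heads act as token-grid shifts at large alpha", {
  r_enc <- patch_grid_encoding(8)
  set.seed(43)
  X <- matrix(rnorm(64 * 12), 64, 12)
  for (delta in list(c(0, 0), c(1, 0), c(0, -1), c(-1, 1))) {
    h <- conv_init_head(delta, alpha = 100, d_emb = 12)
    out <- psa_head(X, h$W_qry, h$W_key, h$W_val, h$v_pos, r_enc,
                    scale = FALSE)$values
    # expected: token (i,j) takes the value of token (i+d1, j+d2) where that
    # token exists (interior); compare on interior queries
    for (i in 0:7) for (j in 0:7) {
      ti <- i + delta[1]; tj <- j + delta[2]
      if (ti < 0 || ti > 7 || tj < 0 || tj > 7) next
      q <- i * 8 + j + 1
      s <- ti * 8 + tj + 1
      expect_lt(max(abs(out[q, ] - X[s, ])), 1e-6)
    }
  }
  # content term is exactly zero under the zero init
  h0 <- conv_init_head(c(1, 1), alpha = 100, d_emb = 12)
  expect_true(all(h0$W_qry == 0) && all(h0$W_key == 0))
  expect_equal(h0$W_val, diag(12))
})

test_that("nine conv-initialized heads reproduce a 3x3 delta-filter convolution", {
  r_enc <- patch_grid_encoding(8)
  set.seed(44)
  X <- matrix(rnorm(64 * 12), 64, 12)
  centers <- conv_head_centers(9)
  expect_error(conv_head_centers(5), "square")
  # direct 3x3 convolution oracle with delta filters: output of head h at
  # token (i,j) = input token at (i,j) + Delta_h; zero-padded off-grid
  for (h in seq_len(9)) {
    d <- centers[h, ]
    hd <- conv_init_head(d, alpha = 100, d_emb = 12)
    out <- psa_head(X, hd$W_qry, hd$W_key, hd$W_val, hd$v_pos, r_enc,
                    scale = FALSE)$values
    conv <- matrix(0, 64, 12)
    for (i in 0:7) for (j in 0:7) {
      ti <- i + d[1]; tj <- j + d[2]
      if (ti >= 0 && ti <= 7 && tj >= 0 && tj <= 7) {
        conv[i * 8 + j + 1, ] <- X[ti * 8 + tj + 1, ]
      }
    }
    interior <- which(apply(conv != 0, 1, any))
    expect_lt(max(abs(out[interior, ] - conv[interior, ])), 1e-6)
  }
})

test_that("gating limits recover pure content / pure positional attention", {
  set.seed(45)
  r_enc <- patch_grid_encoding(2)
  X <- matrix(rnorm(16), 4, 4)
  Wq <- matrix(rnorm(8, 0, 0.5), 2, 4); Wk <- matrix(rnorm(8, 0, 0.5), 2, 4)
  Wv <- matrix(rnorm(8, 0, 0.5), 2, 4)
  v <- rnorm(3)
  pure_pos <- gpsa_head(X, Wq, Wk, Wv, v, lambda = 50, r_enc = r_enc)
  pure_con <- gpsa_head(X, Wq, Wk, Wv, v, lambda = -50, r_enc = r_enc)
  expect_lt(max(abs(pure_pos$attention - pure_pos$positional)), 1e-6)
  expect_lt(max(abs(pure_con$attention - pure_con$content)), 1e-6)

  half <- gpsa_head(X, Wq, Wk, Wv, v, lambda = 0, r_enc = r_enc)
  expect_equal(half$gate, 0.5)
  blend <- 0.5 * half$content + 0.5 * half$positional
  expect_lt(max(abs(half$attention - blend / rowSums(blend))), 1e-12)
  # rows sum to 1 in all regimes
  for (g in list(pure_pos, pure_con, half)) {
    expect_equal(rowSums(g$attention), rep(1, 4), tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_config(l2 = 1e-3)
  set.seed(46)
  params <- ecgconvit:::.convit_init(cfg)
  r_enc <- patch_grid_encoding(cfg$grid_side)
  mkpos <- function(p) {
    pos <- ecgconvit:::.pos_cache(p, cfg, r_enc)
    attr(pos, "r_enc") <- r_enc
    pos
  }
  Plist <- lapply(random_images(3, 8, seed = 46), patchify, patch_size = 4)
  yidx <- c(1L, 3L, 2L)
  lg <- ecgconvit:::.convit_loss_and_grads(params, cfg, Plist, yidx,
                                           mkpos(params), gamma = 2)
  loss_at <- function(p) {
    ecgconvit:::.convit_loss_and_grads(p, cfg, Plist, yidx, mkpos(p),
                                       gamma = 2, want_grads = FALSE)$loss
  }
  spots <- list(
    list(get = function(g) g$proj$W[2, 5],
         set = function(p, e) { p$proj$W[2, 5] <- p$proj$W[2, 5] + e; p }),
    list(get = function(g) g$blocks[[1]]$upos[2, 1],
         set = function(p, e) { p$blocks[[1]]$upos[2, 1] <- p$blocks[[1]]$upos[2, 1] + e; p }),
    list(get = function(g) g$blocks[[1]]$lambda[2],
         set = function(p, e) { p$blocks[[1]]$lambda[2] <- p$blocks[[1]]$lambda[2] + e; p }),
    list(get = function(g) g$blocks[[2]]$W1[3, 2],
         set = function(p, e) { p$blocks[[2]]$W1[3, 2] <- p$blocks[[2]]$W1[3, 2] + e; p }),
    list(get = function(g) g$blocks[[2]]$Wk[2, 3],
         set = function(p, e) { p$blocks[[2]]$Wk[2, 3] <- p$blocks[[2]]$Wk[2, 3] + e; p }),
    list(get = function(g) g$head$W[1, 3],
         set = function(p, e) { p$head$W[1, 3] <- p$head$W[1, 3] + e; p }),
    list(get = function(g) g$ln_f$b[1],
         set = function(p, e) { p$ln_f$b[1] <- p$ln_f$b[1] + e; p })
  )
  eps <- 1e-6
  for (sp in spots) {
    numg <- (loss_at(sp$set(params, eps)) - loss_at(sp$set(params, -eps))) /
      (2 * eps)
    expect_equal(sp$get(lg$grads), numg,
                 tolerance = 1e-4 + 1e-3 * abs(numg))
  }
})

test_that("forward pass is deterministic in eval mode and sums to one", {
  cfg <- tiny_config()
  set.seed(47)
  imgs <- random_images(4, 8, seed = 47)
  m <- convit(imgs, c("A", "B", "C", "A"), config = cfg,
              control = train_config(epochs = 1, batch_size = 4, seed = 1))
  p1 <- predict(m, imgs, type = "prob")
  p2 <- predict(m, imgs, type = "prob")
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  # tiny input perturbation cannot blow up the output
  imgs2 <- imgs
  imgs2[[1]][3, 3] <- imgs2[[1]][3, 3] + 1e-9
  p3 <- predict(m, imgs2[1], type = "prob")
  expect_lt(max(abs(p3 - p1[1, , drop = FALSE])), 1e-4)
})

test_that("the learning-rate schedule decays 2% every 10 epochs", {
  ctl <- train_config(learning_rate = 1e-4, lr_decay = 0.02, decay_every = 10)
  expect_equal(lr_at_epoch(ctl, 1), 1e-4)
  expect_equal(lr_at_epoch(ctl, 10), 1e-4)
  expect_equal(lr_at_epoch(ctl, 11), 1e-4 * 0.98)
  expect_equal(lr_at_epoch(ctl, 21), 1e-4 * 0.98^2)
  expect_equal(lr_at_epoch(ctl, 120), 1e-4 * 0.98^11)
})

test_that("untrained balanced loss sits at the closed-form focal value", {
  # uniform probabilities over 5 classes: FL = -(1 - 0.2)^2 * ln 0.2
  p <- matrix(0.2, 4, 5, dimnames = list(NULL, aami_classes()))
  expect_equal(focal_loss(p, c("N", "V", "S", "F"), gamma = 2),
               -(0.8)^2 * log(0.2), tolerance = 1e-12)
})

test_that("training is seed-deterministic and records history", {
  cfg <- tiny_config()
  imgs <- random_images(6, 8, seed = 48)
  y <- c("A", "B", "C", "A", "B", "C")
  ctl <- train_config(epochs = 3, batch_size = 3, seed = 5)
  m1 <- convit(imgs, y, config = cfg, control = ctl)
  m2 <- convit(imgs, y, config = cfg, control = ctl)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 3)
  expect_true(all(c("epoch", "lr", "train_loss", "train_acc") %in%
                    names(m1$history)))
  expect_error(convit(imgs, rep("X", 6), config = cfg, control = ctl),
               "classes")
})

test_that("a tiny model overfits a small separable batch", {
  # two blocks, no dropout: must reach 100% accuracy on 12 images
  cfg <- tiny_config()
  set.seed(49)
  # three visually distinct patterns + noise
  base <- list(matrix(rep(c(1, 0), each = 32), 8, 8),
               matrix(rep(c(0, 1), 32), 8, 8),
               diag(8))
  imgs <- lapply(rep(1:3, 4), function(k) {
    pmin(pmax(base[[k]] + matrix(rnorm(64, 0, 0.05), 8, 8), 0), 1)
  })
  y <- rep(c("A", "B", "C"), 4)
  m <- convit(imgs, y, config = cfg,
              control = train_config(epochs = 150, batch_size = 12,
                                     learning_rate = 3e-3, seed = 2))
  expect_equal(mean(predict(m, imgs) == y), 1)
})

test_that("model checkpoints round-trip through JSON", {
  cfg <- tiny_config()
  imgs <- random_images(4, 8, seed = 50)
  m <- convit(imgs, c("A", "B", "C", "A"), config = cfg,
              control = train_config(epochs = 2, batch_size = 4, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_convit(m, path)
  m2 <- read_convit(path)
  expect_equal(predict(m2, imgs, type = "prob"),
               predict(m, imgs, type = "prob"), tolerance = 1e-12)
})
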