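#' End-to-end desk-scale classification pipeline
#'
#' Runs the full beat-classification workflow on synthetic data: generate
#' labelled five-class beats, hold out a test set (double 80:20 split), SMOTE-
#' balance the train+validation pool, convert every beat to a TSST spectrogram
#' image, train a compact ConViT with focal loss, and evaluate the six
#' per-class metrics plus ROC/AUC on the untouched test set.
#'
#' SMOTE is applied after the first 80:20 split, on the train+validation pool
#' only, before the second split — the test set never sees synthetic beats.
#'
#' @param n_per_class Beats generated per class.
#' @param noise_sd,jitter_sd Synthetic-beat noise parameters.
#' @param seed Seed controlling generation, splitting, SMOTE and training.
#' @param config ConViT architecture; the default is a compact 4-block model
#'   (3 GPSA + 1 SA) that trains on one CPU in minutes.
#' @param control Training recipe; default 30 epochs, otherwise the published
#'   settings (lr 1e-4, batch 32, focal gamma 2, decay 0.02/10 epochs).
#' @param smote_targets Per-class targets for the pool, `"max"` to balance up
#'   to the largest class, or a single number: every class is oversampled to
#'   that multiple of the largest class count, so SMOTE doubles as a data
#'   augmenter. The default 2 both balances and enlarges the pool, which
#'   buys the optimizer proportionally more update steps per epoch — the
#'   decisive factor at this small step budget — while keeping the whole run
#'   comfortably inside a 15-minute single-CPU budget.
#' @param tfa_config [stft_config()] used for the TSST images.
#' @param raster_mode `"linear"` or `"log"` spectrogram compression.
#' @param transform `"tsst"` (default) or `"stft"` for the baseline images.
#' @param verbose Print training progress.
#' @return List of class `"ecg_pipeline_result"`: `model` (the fitted
#'   [convit()]), `report` (test-set [metrics()]), `confusion`, `roc`,
#'   `split`, `test_accuracy`, and sizes.
#' @export
ecg_pipeline <- function(n_per_class = 300L, noise_sd = 0.05, jitter_sd = 2,
                         seed = 1L,
                         config = convit_config(
                           n_blocks = 4L, n_gpsa = 3L, dropout = 0.1,
                           init_sd = list(proj = NULL, qk = 0.02, v = 0.2,
                                          out = 0.05, head = 0.02, w2 = 0.02)),
                         control = train_config(epochs = 30L, seed = seed,
                                                val_every = 5L),
                         smote_targets = 2,
                         tfa_config = stft_config(),
                         raster_mode = "log",
                         transform = c("tsst", "stft"),
                         verbose = FALSE) {
  transform <- match.arg(transform)
  spec <- synth_spec(stats::setNames(rep(n_per_class, 5), aami_classes()),
                     noise_sd = noise_sd, jitter_sd = jitter_sd, seed = seed)
  beats <- generate_beats(spec)
  n <- nrow(beats$x)
  split <- split_dataset(n, seed = seed)
  # SMOTE-balance the train+val pool; the test set stays untouched
  pool_idx <- sort(c(split$train, split$val))
  pool <- beat_set(beats$x[pool_idx, , drop = FALSE], beats$label[pool_idx],
                   fs = beats$fs)
  if (is.numeric(smote_targets) && length(smote_targets) == 1 &&
      is.null(names(smote_targets))) {
    have <- table(pool$label)
    smote_targets <- stats::setNames(
      rep(as.integer(round(smote_targets * max(have))), length(have)),
      names(have))
  }
  pool_aug <- smote(pool, target_counts = smote_targets, seed = seed)
  # second 8:2 split of the augmented pool: train / validation
  inner <- split_dataset(nrow(pool_aug$x), seed = seed + 1L)
  inner <- list(train = sort(c(inner$train, inner$val)), val = inner$test)
  images_of <- function(xmat) {
    lapply(seq_len(nrow(xmat)), function(i) {
      g <- if (transform == "tsst") tsst(xmat[i, ], tfa_config) else
        stft(xmat[i, ], tfa_config)
      rasterize(g, mode = raster_mode, size = config$image_size)
    })
  }
  tr_img <- images_of(pool_aug$x[inner$train, , drop = FALSE])
  va_img <- images_of(pool_aug$x[inner$val, , drop = FALSE])
  te_img <- images_of(beats$x[split$test, , drop = FALSE])
  model <- convit(tr_img, pool_aug$label[inner$train],
                  val_x = va_img, val_y = pool_aug$label[inner$val],
                  config = config, control = control, verbose = verbose)
  probs <- predict(model, te_img, type = "prob")
  pred <- model$classes[max.col(probs, "first")]
  truth <- beats$label[split$test]
  cm <- confusion(truth, pred)
  rep <- metrics(cm)
  roc <- roc_auc(probs, truth)
  structure(list(model = model, report = rep, confusion = cm, roc = roc,
                 split = split, test_accuracy = rep$overall_accuracy,
                 n_train = length(inner$train), n_val = length(inner$val),
                 n_test = length(split$test), transform = transform,
                 seed = seed),
            class = "ecg_pipeline_result")
}

#' @export
print.ecg_pipeline_result <- function(x, ...) {
  cat(sprintf("ECG %s pipeline (seed %d): %d train / %d val / %d test beats\n",
              toupper(x$transform), x$seed, x$n_train, x$n_val, x$n_test))
  cat(sprintf("Test overall accuracy: %.4f\n", x$test_accuracy))
  print(x$report)
  aucs <- vapply(x$roc, function(r) r$auc, numeric(1))
  cat("AUC: ", paste(sprintf("%s %.4f", names(aucs), aucs), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
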