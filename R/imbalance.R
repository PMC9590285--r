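#' SMOTE minority oversampling in beat space
#'
#' Synthesizes new minority-class beats from the k-nearest-neighbour structure
#' of each class: a base beat \eqn{Z} is drawn from the class, a neighbour
#' \eqn{Z_r} is drawn uniformly among its `k_neighbors` nearest same-class
#' beats (Euclidean distance in the 300-dimensional sample space), and with
#' \eqn{r \sim U(0,1)} the synthetic beat is
#' \deqn{Z_{new} = Z + r\,(Z_r - Z)}
#' in `"interpolate"` mode (the standard SMOTE construction: every synthetic
#' point lies on the segment between two originals), or
#' \deqn{Z_{new} = Z + r\,|Z - Z_r|}
#' elementwise in `"paper_literal"` mode. Originals are preserved unchanged
#' and synthetic beats inherit the class label.
#'
#' @param beats A `"beat_set"`.
#' @param target_counts Named integer vector of desired per-class output
#'   counts; classes absent from it are passed through. Each target must be at
#'   least the existing count. `"max"` balances every class present up to the
#'   largest class.
#' @param k_neighbors Number of nearest neighbours considered (default 5).
#' @param seed Integer seed; output is deterministic per seed.
#' @param mode `"interpolate"` (default) or `"paper_literal"`.
#' @return A `"beat_set"` with originals first (bit-identical) and synthetic
#'   beats appended, flagged in `$synthetic`.
#' @export
smote <- function(beats, target_counts = "max", k_neighbors = 5L, seed = 1L,
                  mode = c("interpolate", "paper_literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(beats, "beat_set"))
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  have <- table(beats$label)
  if (identical(target_counts, "max")) {
    target_counts <- stats::setNames(rep(max(have), length(have)), names(have))
  }
  extra <- target_counts - as.integer(have[names(target_counts)])
  if (anyNA(extra)) {
    stop("target for class absent from data: ",
         paste(names(target_counts)[is.na(extra)], collapse = ", "))
  }
  if (any(extra < 0)) {
    stop("target below existing count for class ",
         paste(names(target_counts)[extra < 0], collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  new_x <- list(); new_lab <- character()
  for (cls in names(target_counts)) {
    n_new <- extra[[cls]]
    if (n_new == 0) next
    rows <- which(beats$label == cls)
    if (length(rows) < k_neighbors + 1) {
      stop("class ", cls, " has ", length(rows), " beats; SMOTE with k = ",
           k_neighbors, " needs at least ", k_neighbors + 1)
    }
    xc <- beats$x[rows, , drop = FALSE]
    nn <- .knn_index(xc, k_neighbors)
    base <- sample.int(nrow(xc), n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    r <- stats::runif(n_new)
    z <- xc[base, , drop = FALSE]
    zr <- xc[nn[cbind(base, pick)], , drop = FALSE]
    syn <- if (mode == "interpolate") z + r * (zr - z) else z + r * abs(z - zr)
    new_x[[cls]] <- syn
    new_lab <- c(new_lab, rep(cls, n_new))
  }
  allx <- rbind(beats$x, do.call(rbind, new_x))
  beat_set(allx,
           c(beats$label, new_lab),
           fs = beats$fs,
           source_symbol = c(beats$source_symbol, new_lab),
           synthetic = c(beats$synthetic, rep(TRUE, length(new_lab))),
           r_index = beats$r_index)
}

# k nearest same-set neighbours by Euclidean distance, self excluded,
# distance ties broken by row index. Returns n x k index matrix.
.knn_index <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Focal loss for multi-class probabilities
#'
#' \deqn{FL(p_t) = -(1 - p_t)^\gamma \log(p_t)} where \eqn{p_t} is the
#' probability the model assigns to the true class. The \eqn{(1-p_t)^\gamma}
#' factor suppresses the loss of easy (confidently correct) samples so
#' training gradients concentrate on hard minority beats; at `gamma = 0` the
#' focal loss is exactly the cross-entropy.
#'
#' @param probs Numeric matrix of per-class probabilities (rows = samples,
#'   columns named by class) or a single probability vector.
#' @param true_class Character/factor vector of true labels (or a single
#'   label).
#' @param gamma Focusing exponent, >= 0 (default 2, the value used for beat
#'   classification here).
#' @param class_weights Optional named per-class weights multiplying each
#'   sample's loss.
#' @param reduce `"mean"` for the batch loss, `"none"` for per-sample losses.
#' @return Nonnegative loss (scalar or vector).
#' @export
focal_loss <- function(probs, true_class, gamma = 2, class_weights = NULL,
                       reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  if (gamma < 0) stop("gamma must be >= 0")
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1,
                                        dimnames = list(NULL, names(probs)))
  true_class <- as.character(true_class)
  if (is.null(colnames(probs))) {
    stop("probs must have class names as column names")
  }
  if (nrow(probs) != length(true_class)) stop("probs/true_class length mismatch")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) stop("probability rows must sum to 1")
  ci <- match(true_class, colnames(probs))
  if (anyNA(ci)) stop("true_class contains labels absent from probs columns")
  pt <- probs[cbind(seq_len(nrow(probs)), ci)]
  if (any(pt <= 0)) {
    warning("clamping zero true-class probabilities at 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  loss <- -(1 - pt)^gamma * log(pt)
  if (!is.null(class_weights)) {
    w <- class_weights[true_class]
    if (anyNA(w)) stop("class_weights missing for some true classes")
    loss <- loss * as.numeric(w)
  }
  if (reduce == "mean") mean(loss) else as.numeric(loss)
}
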