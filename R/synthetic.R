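#' Built-in synthetic beat templates
#'
#' Five morphologically distinct 300-sample beat templates at a nominal
#' 360 Hz, one per AAMI class, each a sum of Gaussian bumps standing in for
#' the P wave, QRS complex and T wave. The R bump sits at sample 150 (the
#' window centre used by [extract_windows()]). Morphologies are caricatures of
#' the class physiology: N has a full P-QRS-T; V a wide, tall ectopic QRS with
#' discordant T and no P; S a premature narrow QRS with altered P; F an
#' intermediate fusion shape; Q a paced-like broad low complex.
#'
#' @return Named list (classes `F, N, Q, S, V`) of data frames with columns
#'   `amplitude`, `center` (0-based sample index) and `width` (samples).
#' @export
beat_templates <- function() {
  tpl <- list(
    N = data.frame( # P, Q, R, S, T
      amplitude = c(0.15, -0.10, 1.00, -0.20, 0.30),
      center    = c(100,   140,  150,  160,   215),
      width     = c(8,     3,    4,    3,     18)),
    V = data.frame( # wide ectopic QRS, discordant T, no P
      amplitude = c(-0.30, 1.20, -0.60),
      center    = c(135,   150,  205),
      width     = c(10,    12,   22)),
    S = data.frame( # premature beat: early inverted P, narrow QRS, small T
      amplitude = c(-0.12, 0.85, -0.15, 0.20),
      center    = c(115,   150,  158,   200),
      width     = c(6,     3,    3,     14)),
    F = data.frame( # fusion: medium-width QRS, blended T
      amplitude = c(0.08, 1.00, -0.35, 0.15),
      center    = c(105,  150,  162,   210),
      width     = c(7,    7,    8,     16)),
    Q = data.frame( # paced/unknown: broad low-slung complex
      amplitude = c(0.50, 0.45, -0.25),
      center    = c(146,  162,  195),
      width     = c(14,   10,   20))
  )
  tpl[order(names(tpl))]
}

#' Render a beat template to a waveform
#'
#' @param template One element of [beat_templates()] (or any data frame with
#'   `amplitude`, `center`, `width` columns).
#' @param n_samples Beat length in samples.
#' @param jitter Optional vector of per-bump centre shifts, in samples.
#' @return Numeric vector of length `n_samples`.
#' @export
render_template <- function(template, n_samples = 300L, jitter = NULL) {
  t <- seq.int(0L, n_samples - 1L)
  ctr <- template$center + if (is.null(jitter)) 0 else jitter
  y <- numeric(n_samples)
  for (i in seq_len(nrow(template))) {
    y <- y + template$amplitude[i] * exp(-(t - ctr[i])^2 / (2 * template$width[i]^2))
  }
  y
}

#' Specification for a synthetic beat dataset
#'
#' @param per_class_counts Named nonnegative integer vector, names from
#'   `{F, N, Q, S, V}`; number of beats per class.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian amplitude noise.
#' @param jitter_sd Standard deviation of the random shift (in samples)
#'   applied to every Gaussian bump centre, per beat.
#' @param seed Integer RNG seed; identical specs give identical datasets.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(per_class_counts, noise_sd = 0.05, jitter_sd = 0,
                       seed = 1L) {
  classes <- names(beat_templates())
  if (is.null(names(per_class_counts)) ||
      !all(names(per_class_counts) %in% classes)) {
    stop("per_class_counts must be named with classes among {F, N, Q, S, V}")
  }
  if (any(per_class_counts < 0)) stop("invalid spec: negative class count")
  if (noise_sd < 0) stop("invalid spec: negative noise_sd")
  if (jitter_sd < 0) stop("invalid spec: negative jitter_sd")
  counts <- stats::setNames(integer(length(classes)), classes)
  counts[names(per_class_counts)] <- as.integer(per_class_counts)
  structure(list(per_class_counts = counts, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate labelled synthetic beats
#'
#' Draws beats as template + jitter + Gaussian noise, 300 samples each at a
#' nominal 360 Hz. Reproducible: the same spec always yields bitwise-identical
#' output.
#'
#' @param spec A [synth_spec()].
#' @param n_samples Samples per beat.
#' @return A `"beat_set"`: list with `x` (matrix, one beat per row), `label`
#'   (character vector of AAMI classes), `fs` (Hz), `synthetic` (logical).
#' @export
generate_beats <- function(spec, n_samples = 300L) {
  stopifnot(inherits(spec, "synth_spec"))
  tpl <- beat_templates()
  total <- sum(spec$per_class_counts)
  x <- matrix(0, nrow = total, ncol = n_samples)
  label <- character(total)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  row <- 0L
  for (cls in names(spec$per_class_counts)) {
    nc <- spec$per_class_counts[[cls]]
    if (nc == 0L) next
    tp <- tpl[[cls]]
    for (i in seq_len(nc)) {
      row <- row + 1L
      jit <- if (spec$jitter_sd > 0) {
        stats::rnorm(nrow(tp), 0, spec$jitter_sd)
      } else NULL
      y <- render_template(tp, n_samples, jit)
      if (spec$noise_sd > 0) y <- y + stats::rnorm(n_samples, 0, spec$noise_sd)
      x[row, ] <- y
      label[row] <- cls
    }
  }
  # the synthetic flag marks SMOTE-oversampled beats, not generator output
  beat_set(x, label, fs = 360, synthetic = rep(FALSE, total))
}

#' Construct a beat set
#'
#' The common container for windowed beats: a numeric matrix with one beat per
#' row plus parallel label metadata.
#'
#' @param x Numeric matrix, one beat per row.
#' @param label Character vector of AAMI class labels (`F,N,Q,S,V`).
#' @param fs Sampling frequency in Hz.
#' @param source_symbol Optional original annotation symbols.
#' @param synthetic Optional logical vector flagging oversampled beats.
#' @param r_index Position of the R peak within the window (0-based).
#' @return An object of class `"beat_set"`.
#' @export
beat_set <- function(x, label, fs = 360, source_symbol = NULL,
                     synthetic = NULL, r_index = 150L) {
  x <- as.matrix(x)
  label <- as.character(label)
  stopifnot(nrow(x) == length(label))
  bad <- setdiff(unique(label), aami_classes())
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  structure(list(x = x, label = label, fs = fs,
                 source_symbol = source_symbol %||% label,
                 synthetic = synthetic %||% rep(FALSE, nrow(x)),
                 r_index = r_index),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set: %d beats x %d samples @ %g Hz>\n",
              nrow(x$x), ncol(x$x), x$fs))
  print(table(label = x$label))
  invisible(x)
}

#' The five AAMI heartbeat classes
#' @return `c("F", "N", "Q", "S", "V")`.
#' @export
aami_classes <- function() c("F", "N", "Q", "S", "V")

#' Analytic test signals
#'
#' Small deterministic signals used to exercise the time-frequency transforms:
#' impulses have closed-form STFT and group delay, sinusoids and chirps probe
#' the frequency axis.
#'
#' @param kind One of `"impulse"`, `"two_impulse"`, `"sinusoid"`, `"chirp"`,
#'   `"zero"`.
#' @param length Signal length in samples.
#' @param params Named list: `pos` (impulse, 0-based), `pos1`/`pos2`
#'   (two_impulse), `freq` in cycles/sample (sinusoid), `f0`/`f1` (chirp
#'   start/end frequency in cycles/sample).
#' @return Numeric vector of `length` samples.
#' @export
make_test_signal <- function(kind = c("impulse", "two_impulse", "sinusoid",
                                      "chirp", "zero"),
                             length = 300L, params = list()) {
  kind <- match.arg(kind)
  if (length <= 0) stop("length must be positive")
  n <- as.integer(length)
  t <- seq.int(0L, n - 1L)
  chk <- function(p) {
    if (is.null(p) || p < 0 || p >= n) stop("impulse position out of range")
    as.integer(p)
  }
  switch(kind,
    zero = numeric(n),
    impulse = { x <- numeric(n); x[chk(params$pos) + 1L] <- 1; x },
    two_impulse = {
      x <- numeric(n)
      x[chk(params$pos1) + 1L] <- 1
      x[chk(params$pos2) + 1L] <- 1
      x
    },
    sinusoid = sin(2 * pi * (params$freq %||% 0.1) * t),
    chirp = {
      f0 <- params$f0 %||% 0.01; f1 <- params$f1 %||% 0.2
      sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * n)))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Save/restore the global RNG state so generators are reproducible without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
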