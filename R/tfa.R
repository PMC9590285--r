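#' Short-time Fourier transform configuration
#'
#' Parameters of the Gaussian-window STFT underlying the time-reassigned
#' synchrosqueezing transform. The window is a truncated Gaussian
#' \eqn{g(u) = \exp(-u^2 / 2\sigma^2) / (\sigma\sqrt{2\pi})} evaluated on
#' `window_len` samples centred on each analysis time.
#'
#' Defaults are tuned for 300-sample beats at 360 Hz: `n_freq = 160` one-sided
#' frequency bins span 0 to 180 Hz so the spectrogram raster needs minimal
#' resampling, and `hop = 1` keeps full time resolution for reassignment.
#'
#' @param window_sd Gaussian standard deviation, in samples.
#' @param window_len Window truncation length in samples; must be odd.
#' @param hop Analysis hop in samples (>= 1).
#' @param n_freq Number of one-sided frequency bins (>= 2).
#' @param fs Sampling frequency in Hz.
#' @return An object of class `"stft_config"`.
#' @export
stft_config <- function(window_sd = 8, window_len = 65, hop = 1,
                        n_freq = 160, fs = 360) {
  if (window_len %% 2 != 1) stop("window_len must be odd")
  if (hop < 1) stop("hop must be >= 1")
  if (n_freq < 2) stop("n_freq must be >= 2")
  if (window_sd <= 0) stop("window_sd must be positive")
  structure(list(window_sd = window_sd, window_len = window_len,
                 hop = hop, n_freq = n_freq, fs = fs),
            class = "stft_config")
}

# Gaussian analysis window g(u) and its time-weighted companion u*g(u),
# evaluated at u = t - tau for a frame centred on t.
.tfa_windows <- function(cfg) {
  half <- (cfg$window_len - 1L) / 2L
  u <- seq.int(-half, half) # u = t - tau as tau runs over the frame
  g <- exp(-u^2 / (2 * cfg$window_sd^2)) / (cfg$window_sd * sqrt(2 * pi))
  list(u = u, g = g, tg = u * g, half = half)
}

# Core frame-wise FFT STFT. Returns complex n_time x n_freq matrix with the
# phase referenced to absolute signal time: F[t,w] = sum_tau x(tau) w(t-tau)
# exp(-i w tau), signal zero-padded outside its support.
.stft_engine <- function(x, cfg, win) {
  geo <- .stft_geometry(length(x), cfg)
  Fw <- .stft_windowed_frames(x, cfg, geo, win)
  Fm <- stats::mvfft(Fw)[seq_len(cfg$n_freq), , drop = FALSE]
  t(Fm) * .stft_phase(geo, cfg$n_freq) # n_time x n_freq
}

# Both windowed STFTs in one complex FFT: the two windowed frame matrices are
# real, so mvfft(A + 1i*B) recovers both by Hermitian symmetry
# (F_A[k] = (Z[k] + conj(Z[-k]))/2, F_B[k] = (Z[k] - conj(Z[-k]))/2i).
# Returns list(a, b) of n_time x n_freq matrices matching .stft_engine.
.stft_engine_pair <- function(x, cfg, win_a, win_b) {
  geo <- .stft_geometry(length(x), cfg)
  Z <- stats::mvfft(.stft_windowed_frames(x, cfg, geo, win_a) +
                      1i * .stft_windowed_frames(x, cfg, geo, win_b))
  kk <- seq_len(cfg$n_freq)
  conj_idx <- c(1L, geo$nfft:2L)[kk] # index of frequency -k, 1-based
  Zk <- Z[kk, , drop = FALSE]
  Zc <- Conj(Z[conj_idx, , drop = FALSE])
  phase <- .stft_phase(geo, cfg$n_freq)
  list(a = t((Zk + Zc) / 2) * phase,
       b = t((Zk - Zc) / (2i)) * phase)
}

.stft_geometry <- function(n, cfg) {
  half <- (cfg$window_len - 1L) / 2L
  times <- seq.int(0L, n - 1L, by = cfg$hop)
  nfft <- 2L * (cfg$n_freq - 1L)
  if (nfft < cfg$window_len) {
    stop("n_freq too small for window_len (need 2*(n_freq-1) >= window_len)")
  }
  list(n = n, half = half, times = times, nt = length(times), nfft = nfft)
}

# windowed frame matrix: rows = position within frame (tau = t - half + m),
# cols = t. rev(win): the weight for frame position m (tau = t-half+m) is
# w(half-m).
.stft_windowed_frames <- function(x, cfg, geo, win) {
  frames <- matrix(0, nrow = geo$nfft, ncol = geo$nt)
  xi <- c(rep(0, geo$half), x, rep(0, geo$half)) # pad: indexing stays in bounds
  # tau runs t0-half .. t0+half; in padded coords that is t0+1 .. t0+window_len
  wl <- cfg$window_len
  idx <- rep.int(geo$times, rep.int(wl, geo$nt)) + rep.int(seq_len(wl), geo$nt)
  frames[rep.int((seq_len(geo$nt) - 1L) * geo$nfft, rep.int(wl, geo$nt)) +
           rep.int(seq_len(wl), geo$nt)] <- xi[idx] * rev(win)
  frames
}

# phase re-reference from frame-local tau' = tau-(t-half) to absolute tau:
# exp(-2i pi (t-half) k / nfft) takes only nfft distinct values (roots of
# unity), so index into precomputed roots; memoized on the grid geometry
# since the pipeline transforms thousands of equally-sized beats
.tfa_cache <- new.env(parent = emptyenv())
.stft_phase <- function(geo, n_freq) {
  key <- paste(geo$n, geo$nt, geo$half, geo$nfft, n_freq, sep = "|")
  got <- .tfa_cache[[key]]
  if (!is.null(got)) return(got)
  kbin <- seq_len(n_freq) - 1L
  roots <- exp(-2i * pi * (seq_len(geo$nfft) - 1L) / geo$nfft)
  ph <- roots[(outer(geo$times - geo$half, kbin) %% geo$nfft) + 1L]
  dim(ph) <- c(geo$nt, n_freq)
  .tfa_cache[[key]] <- ph
  ph
}

.tf_grid <- function(values, cfg, kind) {
  n <- nrow(values)
  structure(list(values = values,
                 time_axis = seq.int(0L, by = cfg$hop, length.out = n),
                 freq_axis = (seq_len(ncol(values)) - 1L) /
                   (2L * (ncol(values) - 1L)) * cfg$fs,
                 config = cfg, kind = kind),
            class = "tf_grid")
}

#' Gaussian-window short-time Fourier transform
#'
#' Computes \eqn{F_x^g(t,\omega) = \sum_\tau x(\tau)\, g(t-\tau)\,
#' e^{-j\omega\tau}} on a regular time/frequency grid, with the signal taken
#' as zero outside its support. The squared magnitude of the result is the
#' spectrogram (time-frequency representation).
#'
#' @param x Numeric signal vector, at least `window_len` samples long.
#' @param cfg An [stft_config()].
#' @return A `"tf_grid"`: list with complex `values` (`n_time` x `n_freq`),
#'   `time_axis` (sample indices, 0-based), `freq_axis` (Hz, 0 to fs/2),
#'   `config` and `kind = "stft"`.
#' @export
stft <- function(x, cfg = stft_config()) {
  if (!is.numeric(x)) stop("x must be a numeric vector")
  if (length(x) < cfg$window_len) stop("signal shorter than analysis window")
  win <- .tfa_windows(cfg)
  .tf_grid(.stft_engine(x, cfg, win$g), cfg, "stft")
}

#' Group-delay (time-reassignment) map
#'
#' Estimates, for every time-frequency cell, the time at which the local
#' signal energy is actually concentrated:
#' \eqn{\hat t(t,\omega) = \Re\{t - F_x^{\tau g}(t,\omega) / F_x^g(t,\omega)\}},
#' where \eqn{\tau g(u) = u\,g(u)} is the time-weighted Gaussian window.
#' Cells whose STFT magnitude does not exceed `eps` are masked out.
#'
#' @param x Numeric signal vector.
#' @param cfg An [stft_config()].
#' @param eps Magnitude threshold; if `NULL`, defaults to `1e-8 * max|F|`.
#' @return List of class `"group_delay_map"` with `values` (real matrix,
#'   units = sample index; `NA` where masked), `valid_mask`, and the two
#'   underlying grids `stft_g`, `stft_tg`.
#' @export
group_delay <- function(x, cfg = stft_config(), eps = NULL) {
  win <- .tfa_windows(cfg)
  pair <- .stft_engine_pair(x, cfg, win$g, win$tg)
  Fg <- pair$a
  Ftg <- pair$b
  if (!is.null(eps) && eps <= 0) stop("eps must be positive")
  if (is.null(eps)) eps <- 1e-8 * max(Mod(Fg))
  mask <- Mod(Fg) > eps
  that <- matrix(NA_real_, nrow(Fg), ncol(Fg))
  tt <- seq.int(0L, by = cfg$hop, length.out = nrow(Fg))
  that[mask] <- Re(matrix(tt, nrow(Fg), ncol(Fg))[mask] - Ftg[mask] / Fg[mask])
  structure(list(values = that, valid_mask = mask,
                 stft_g = .tf_grid(Fg, cfg, "stft"),
                 stft_tg = .tf_grid(Ftg, cfg, "stft"),
                 config = cfg),
            class = "group_delay_map")
}

#' Time-reassigned synchrosqueezing transform (TSST)
#'
#' Post-processes the STFT by moving each complex coefficient along the time
#' axis to its group delay: within every frequency bin, \eqn{F(t,\omega)} is
#' added into the output time bin nearest \eqn{\hat t(t,\omega)}. This
#' squeezes the energy of impulsive events (such as the QRS complex) into
#' single time columns while leaving the frequency axis untouched. Masked
#' (below-threshold) coefficients stay at their original time, so the complex
#' sum over time is conserved exactly per frequency bin.
#'
#' @inheritParams group_delay
#' @return A `"tf_grid"` with `kind = "tsst"`.
#' @export
tsst <- function(x, cfg = stft_config(), eps = NULL) {
  gd <- group_delay(x, cfg, eps)
  Fg <- gd$stft_g$values
  nt <- nrow(Fg); nf <- ncol(Fg)
  # reassigned time bin: nearest frame to t-hat, clipped to the grid
  bin <- round(gd$values / cfg$hop) + 1
  bin[is.na(bin)] <- row(Fg)[is.na(bin)] # masked cells stay in place
  bin <- pmin(pmax(bin, 1), nt)
  lin <- as.integer(bin + (col(Fg) - 1) * nt) # destination linear index
  S <- matrix(complex(real = 0), nt, nf)
  # scatter-add by destination: sort, then take group sums off a cumulative sum
  o <- order(lin)
  sl <- lin[o]
  cv <- cumsum(as.vector(Fg)[o])
  last <- c(which(sl[-1L] != sl[-length(sl)]), length(sl))
  S[sl[last]] <- cv[last] - c(0 + 0i, cv[last[-length(last)]])
  .tf_grid(S, cfg, "tsst")
}

#' Rasterize a time-frequency grid into a spectrogram image
#'
#' Converts the squared magnitude of a [stft()] or [tsst()] grid into a
#' nonnegative image of fixed size (default 160 x 160) suitable as classifier
#' input: optional log compression `log(1 + k * p / max(p))`, bilinear
#' resampling, then min-max scaling to `[0, 1]` (so the brightest pixel is
#' exactly 1). Rows index frequency (low at row 1),
#' columns index time. An all-zero grid maps to an all-zero image.
#'
#' @param grid A `"tf_grid"`.
#' @param mode `"linear"` or `"log"` compression of the power.
#' @param size Output image side length in pixels.
#' @param log_k Compression strength for `mode = "log"`.
#' @return An object of class `"spectrogram_image"`: list with `pixels`
#'   (size x size matrix in `[0, 1]`) and `meta` (transform kind).
#' @export
rasterize <- function(grid, mode = c("linear", "log"), size = 160L,
                      log_k = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "tf_grid"))
  p <- Mod(grid$values)^2
  if (nrow(p) < 2 || ncol(p) < 2) stop("grid too small to rasterize")
  # p is time x freq; image wants freq rows x time cols
  img <- .bilinear_resize(t(p), size, size)
  img[img < 0] <- 0 # bilinear interpolation of |.|^2 cannot overshoot below 0
  if (max(img) > 0) {
    if (mode == "log") img <- log1p(log_k * img / max(img))
    img <- (img - min(img)) / (max(img) - min(img))
  }
  structure(list(pixels = img,
                 meta = list(kind = grid$kind, mode = mode)),
            class = "spectrogram_image")
}

# Separable bilinear resize of a matrix to nr x nc (edge-clamped).
.bilinear_resize <- function(m, nr, nc) {
  interp_axis <- function(n_in, n_out) {
    if (n_out == 1L) return(list(lo = 1L, hi = 1L, w = 0))
    pos <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2)
    list(lo = as.integer(lo) + 1L, hi = as.integer(lo) + 2L, w = pos - lo)
  }
  ay <- interp_axis(nrow(m), nr)
  ax <- interp_axis(ncol(m), nc)
  rowsint <- m[ay$lo, , drop = FALSE] * (1 - ay$w) + m[ay$hi, , drop = FALSE] * ay$w
  rowsint[, ax$lo, drop = FALSE] * rep(1 - ax$w, each = nr) +
    rowsint[, ax$hi, drop = FALSE] * rep(ax$w, each = nr)
}

#' Export a spectrogram image
#'
#' Writes an 8-bit grayscale PNG (`value = round(255 * pixel)`); requires the
#' \pkg{png} package.
#'
#' @param img A `"spectrogram_image"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files")
  }
  stopifnot(inherits(img, "spectrogram_image"))
  # flip so low frequencies sit at the bottom of the picture
  png::writePNG(img$pixels[rev(seq_len(nrow(img$pixels))), , drop = FALSE], path)
  invisible(path)
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid %s: %d time frames x %d frequency bins, 0-%.1f Hz>\n",
              x$kind, nrow(x$values), ncol(x$values), max(x$freq_axis)))
  invisible(x)
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image %dx%d (%s, %s), range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$meta$kind, x$meta$mode,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
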