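# Minimal WFDB-dialect reader: .hea header, .dat signal (formats 212 and 16),
# .atr annotations (MIT format). Covers the subset needed to window beats from
# ambulatory ECG records; multi-signal records read the first signal.

# annotation code -> symbol, per the standard WFDB code table (beat codes
# plus the non-beat codes we must at least skip over)
.wfdb_ann_symbols <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q", "~",
  NA, "|", NA, "s", "T", "*", "D", "\"", "=", "p", "B", "^", "t", "+",
  "u", "?", "!", "[", "]", "e", "n", NA, "x", "f", "(", ")", "r"
)

#' Read a WFDB-style record
#'
#' Parses the `.hea` header, the `.dat` signal file (format 212 packed 12-bit
#' or format 16 little-endian int16) and, when present, the `.atr` MIT-format
#' annotation file. Only the first signal of a multi-signal record is
#' returned. Gain and baseline from the header convert raw ADC units to
#' physical units.
#'
#' @param path Record path, with or without the `.hea` extension.
#' @return An [annotated_record()].
#' @export
read_wfdb_record <- function(path) {
  base <- sub("\\.(hea|dat|atr)$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("no such record header: ", hea)
  hdr <- .read_hea(hea)
  dat <- file.path(dirname(hea), hdr$signal$file_name[1])
  if (!file.exists(dat)) stop("missing signal file: ", dat)
  raw_sig <- .read_dat(dat, hdr)
  s <- hdr$signal[1, ]
  samples <- (raw_sig[, 1] - s$baseline) / s$gain
  atr <- paste0(base, ".atr")
  ann <- if (file.exists(atr)) .read_atr(atr) else
    list(index = integer(), symbol = character())
  keep <- !is.na(ann$symbol)
  annotated_record(samples, fs = hdr$fs,
                   ann_index = ann$index[keep], ann_symbol = ann$symbol[keep])
}

.read_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) {
    stop("WFDB header parse error in ", path, ": record line '", lines[1],
         "' needs name, n_sig, fs, n_samples")
  }
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3])) # fs may carry /counter suffixes
  n_samp <- as.integer(top[4])
  if (length(lines) < 1 + n_sig) {
    stop("WFDB header parse error in ", path, ": expected ", n_sig,
         " signal specification line(s)")
  }
  sig <- do.call(rbind, lapply(lines[1 + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2) stop("WFDB header parse error in ", path,
                            ": bad signal line '", l, "'")
    fmt <- as.integer(sub("x.*$", "", f[2])) # strip samples-per-frame suffix
    gainfield <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gainfield))
    baseline <- if (grepl("\\(", gainfield)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    } else 0
    if (is.na(gain) || gain == 0) gain <- 200
    data.frame(file_name = f[1], format = fmt, gain = gain,
               baseline = baseline, stringsAsFactors = FALSE)
  }))
  list(n_sig = n_sig, fs = fs, n_samples = n_samp, signal = sig)
}

.read_dat <- function(path, hdr) {
  n_sig <- hdr$n_sig
  n <- hdr$n_samples
  fmt <- hdr$signal$format[1]
  raw <- readBin(path, "raw", n = file.size(path))
  total <- n * n_sig
  if (fmt == 16) {
    v <- readBin(raw, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
    if (length(v) < total) stop("signal file ", path, " truncated")
  } else if (fmt == 212) {
    need <- ceiling(total / 2) * 3
    if (length(raw) < need) stop("signal file ", path, " truncated")
    b <- as.integer(raw[seq_len(need)])
    b0 <- b[seq(1, need, by = 3)]
    b1 <- b[seq(2, need, by = 3)]
    b2 <- b[seq(3, need, by = 3)]
    s1 <- bitwAnd(b1, 0x0F) * 256L + b0
    s2 <- bitwAnd(b1, 0xF0) * 16L + b2
    v <- as.vector(rbind(s1, s2))[seq_len(total)]
    v <- ifelse(v > 2047L, v - 4096L, v) # 12-bit two's complement
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  matrix(v, ncol = n_sig, byrow = TRUE)
}

# MIT annotation format: stream of 2-byte little-endian words; high 6 bits =
# type code, low 10 bits = sample interval from the previous annotation.
# Pseudo-codes: 59 SKIP (4-byte interval follows), 60 NUM, 61 SUB, 62 CHN,
# 63 AUX (length + padded bytes follow); code 0 with interval 0 terminates.
.read_atr <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.size(path)))
  idx <- integer(); sym <- character()
  t_cur <- 0; i <- 1L
  nb <- length(raw)
  while (i + 1L <= nb) {
    word <- raw[i] + raw[i + 1L] * 256L
    i <- i + 2L
    code <- word %/% 1024L
    interval <- word %% 1024L
    if (code == 0L && interval == 0L) break
    if (code == 59L) { # SKIP: next two words hold a long interval, high first
      if (i + 3L > nb) stop("annotation file ", path, " truncated in SKIP")
      hi <- raw[i] + raw[i + 1L] * 256L
      lo <- raw[i + 2L] + raw[i + 3L] * 256L
      i <- i + 4L
      t_cur <- t_cur + hi * 65536 + lo
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modify bookkeeping we do not track
    } else if (code == 63L) { # AUX: interval = byte count, padded to even
      i <- i + interval + (interval %% 2L)
    } else {
      t_cur <- t_cur + interval
      idx <- c(idx, t_cur)
      sym <- c(sym, if (code <= length(.wfdb_ann_symbols))
        .wfdb_ann_symbols[code] else NA_character_)
    }
  }
  list(index = as.integer(idx), symbol = sym)
}
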