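#' Map an MIT-BIH annotation symbol to its AAMI class
#'
#' The five-way AAMI grouping used throughout the package:
#' `N` (normal, bundle-branch block, escape: `N L R e j`),
#' `S` (supraventricular ectopic: `A a J S`),
#' `V` (ventricular ectopic: `V E`),
#' `F` (fusion: `F`),
#' `Q` (paced/unknown: `/ f U`).
#'
#' @param symbol Single annotation character (vectorized).
#' @return Character vector of AAMI classes.
#' @export
map_to_aami <- function(symbol) {
  map <- c(F = "F",
           N = "N", L = "N", R = "N", e = "N", j = "N",
           "/" = "Q", f = "Q", U = "Q",
           A = "S", a = "S", J = "S", S = "S",
           V = "V", E = "V")
  out <- map[symbol]
  if (anyNA(out)) {
    stop("unmapped annotation symbol(s): ",
         paste(unique(symbol[is.na(out)]), collapse = " "))
  }
  unname(out)
}

#' Annotation symbols with an AAMI class
#' @return The 15 MIT-BIH symbols covered by [map_to_aami()].
#' @export
mappable_symbols <- function() {
  c("F", "N", "L", "R", "e", "j", "/", "f", "U", "A", "a", "J", "S", "V", "E")
}

#' Construct an annotated ECG record
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling frequency in Hz (360 expected; a warning is emitted
#'   otherwise since window lengths are calibrated for 360 Hz).
#' @param ann_index Integer vector of 0-based annotation sample indices,
#'   strictly increasing, within the record.
#' @param ann_symbol Character vector of annotation symbols, parallel to
#'   `ann_index`.
#' @return An object of class `"annotated_record"`.
#' @export
annotated_record <- function(samples, fs = 360, ann_index = integer(),
                             ann_symbol = character()) {
  stopifnot(length(ann_index) == length(ann_symbol))
  if (length(ann_index) > 0) {
    if (is.unsorted(ann_index, strictly = TRUE)) {
      stop("annotation indices must be strictly increasing")
    }
    if (min(ann_index) < 0 || max(ann_index) >= length(samples)) {
      stop("annotation index outside the record")
    }
  }
  if (fs != 360) warning("record sampling frequency is ", fs, " Hz, not 360 Hz")
  structure(list(samples = as.numeric(samples), fs = fs,
                 ann_index = as.integer(ann_index),
                 ann_symbol = as.character(ann_symbol)),
            class = "annotated_record")
}

#' Cut beat windows around annotated R peaks
#'
#' Extracts one 300-sample window per mappable annotation, with the R peak at
#' in-window index 150 (0-based): samples `[r-150, r+150)`. Annotations whose
#' window would cross a record boundary are skipped and counted; annotations
#' whose symbol has no AAMI class are skipped and counted separately.
#'
#' @param record An [annotated_record()].
#' @param width Window length in samples.
#' @param r_offset Samples kept before the R peak.
#' @return A `"beat_set"` with attributes `n_skipped_edge` and
#'   `n_skipped_symbol`.
#' @export
extract_windows <- function(record, width = 300L, r_offset = 150L) {
  stopifnot(inherits(record, "annotated_record"))
  mappable <- record$ann_symbol %in% mappable_symbols()
  idx <- record$ann_index[mappable]
  sym <- record$ann_symbol[mappable]
  start <- idx - r_offset # 0-based window start
  ok <- start >= 0 & (start + width) <= length(record$samples)
  n_edge <- sum(!ok)
  rows <- lapply(start[ok] + 1L, function(s) record$samples[s:(s + width - 1L)])
  x <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, width)
  bs <- beat_set(x, if (any(ok)) map_to_aami(sym[ok]) else character(),
                 fs = record$fs, source_symbol = sym[ok], r_index = r_offset)
  attr(bs, "n_skipped_edge") <- n_edge
  attr(bs, "n_skipped_symbol") <- sum(!mappable)
  bs
}

#' Train/validation/test split by double 80:20
#'
#' Splits `n` items the way the study design prescribes: a random permutation
#' under `seed`, the last 20% (floor) becomes the test set, then 20% (floor)
#' of the remainder becomes the validation set and the rest trains. For
#' `n = 100` this yields 64/16/20.
#'
#' @param n Number of items (>= 5).
#' @param seed Integer seed; the split is deterministic per seed.
#' @param ratio Held-out fraction used at both levels.
#' @return Object of class `"dataset_split"`: list with integer index vectors
#'   `train`, `val`, `test` (1-based, pairwise disjoint, exhaustive), plus
#'   `seed` and `ratio`.
#' @export
split_dataset <- function(n, seed = 1L, ratio = 0.2) {
  if (n < 5) stop("need at least 5 items to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(n * ratio)
  m <- n - n_test
  n_val <- floor(m * ratio)
  structure(list(train = sort(perm[seq_len(m - n_val)]),
                 val = sort(perm[if (n_val > 0) (m - n_val + 1L):m else integer()]),
                 test = sort(perm[if (n_test > 0) (m + 1L):n else integer()]),
                 seed = as.integer(seed), ratio = ratio),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: train %d / val %d / test %d (seed %d)>\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Write / read a split manifest as JSON
#' @param split A [split_dataset()] result.
#' @param path File path.
#' @return `path` / a `"dataset_split"`.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.integer(s$train), val = as.integer(s$val),
                 test = as.integer(s$test), seed = as.integer(s$seed),
                 ratio = s$ratio),
            class = "dataset_split")
}

#' Read ECG data from disk
#'
#' Two dialects: `"wfdb"` reads a WFDB-style record (`.hea` header, `.dat`
#' signal in format 212 or 16, `.atr` MIT-format annotations) and returns an
#' [annotated_record()]; `"csv_beats"` reads pre-cut beats (header
#' `s0..s299,symbol[,synthetic]`) and returns a `"beat_set"`.
#'
#' @param path Record path: for `wfdb`, the record name with or without
#'   extension; for `csv_beats`, the CSV file.
#' @param dialect `"wfdb"` or `"csv_beats"`.
#' @return An `"annotated_record"` or a `"beat_set"`.
#' @export
read_record <- function(path, dialect = c("wfdb", "csv_beats")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         wfdb = read_wfdb_record(path),
         csv_beats = read_csv_beats(path))
}

#' Write/read beats in the CSV dialect
#'
#' One row per beat: columns `s0..s<n-1>` (amplitudes), `symbol` (AAMI class
#' or source annotation symbol) and `synthetic` (0/1).
#'
#' @param beats A `"beat_set"`.
#' @param path CSV file path.
#' @return `path` / a `"beat_set"`.
#' @export
write_csv_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_set"))
  df <- as.data.frame(beats$x)
  names(df) <- paste0("s", seq_len(ncol(beats$x)) - 1L)
  df$symbol <- beats$label
  df$synthetic <- as.integer(beats$synthetic)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csv_beats
#' @export
read_csv_beats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (length(scols) == 0 || !"symbol" %in% names(df)) {
    stop("csv_beats format error in ", path,
         ": expected columns s0..s<n-1> and symbol")
  }
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  x <- as.matrix(df[, scols, drop = FALSE])
  if (anyNA(x)) {
    bad <- which(apply(is.na(x), 1, any))[1]
    stop("csv_beats format error in ", path, ": non-numeric or missing sample",
         " value in data row ", bad)
  }
  syn <- if ("synthetic" %in% names(df)) df$synthetic != 0 else NULL
  sym <- as.character(df$symbol)
  # the symbol column may carry AAMI classes directly or raw annotation symbols
  lab <- ifelse(sym %in% aami_classes(), sym, NA_character_)
  if (anyNA(lab)) lab[is.na(lab)] <- map_to_aami(sym[is.na(lab)])
  beat_set(x, lab, source_symbol = sym, synthetic = syn)
}
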