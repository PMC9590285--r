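test_that("map_to_aami follows the five-class table and rejects the rest", {
  expect_equal(map_to_aami("L"), "N")
  expect_equal(map_to_aami("a"), "S")
  expect_equal(map_to_aami(c("N", "L", "R", "e", "j")), rep("N", 5))
  expect_equal(map_to_aami(c("/", "f", "U")), rep("Q", 3))
  expect_equal(map_to_aami(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(map_to_aami(c("V", "E")), rep("V", 2))
  expect_equal(map_to_aami("F"), "F")
  # total on the table's symbols, error on everything else
  expect_equal(length(map_to_aami(mappable_symbols())), 15)
  expect_error(map_to_aami("+"), "unmapped")
  expect_error(map_to_aami("~"), "unmapped")
})

test_that("extract_windows cuts centred 300-sample windows", {
  sig <- seq(0, 999) / 1000
  rec <- annotated_record(sig, fs = 360, ann_index = 500, ann_symbol = "N")
  bs <- extract_windows(rec)
  expect_equal(nrow(bs$x), 1)
  # window = samples[350 .. 650) (0-based), R peak at in-window index 150
  expect_equal(unname(bs$x[1, ]), sig[351:650])
  expect_equal(bs$x[1, 151], sig[501])
  expect_equal(bs$label, "N")
  expect_equal(bs$r_index, 150)
})

test_that("edge and unmappable annotations are skipped and counted", {
  sig <- rnorm(1000)
  rec <- annotated_record(sig, fs = 360,
                          ann_index = c(100, 400, 600, 920),
                          ann_symbol = c("N", "+", "V", "L"))
  bs <- extract_windows(rec)
  # 100 needs samples[-50, 250): edge skip; 920 needs [770, 1070): edge skip;
  # '+' is not a beat symbol
  expect_equal(nrow(bs$x), 1)
  expect_equal(bs$label, "V")
  expect_equal(attr(bs, "n_skipped_edge"), 2)
  expect_equal(attr(bs, "n_skipped_symbol"), 1)
  # bookkeeping: emitted + edge-skipped == mappable annotations
  expect_equal(nrow(bs$x) + attr(bs, "n_skipped_edge"), 3)
})

test_that("zero-signal record yields all-zero labelled windows", {
  rec <- annotated_record(numeric(2000), fs = 360,
                          ann_index = c(500, 900, 1300),
                          ann_symbol = c("V", "V", "V"))
  bs <- extract_windows(rec)
  expect_equal(nrow(bs$x), 3)
  expect_true(all(bs$x == 0))
  expect_equal(bs$label, rep("V", 3))
})

test_that("annotated_record validates its invariants", {
  expect_error(annotated_record(1:100, fs = 360, ann_index = c(50, 50),
                                ann_symbol = c("N", "N")), "increasing")
  expect_error(annotated_record(1:100, fs = 360, ann_index = 150,
                                ann_symbol = "N"), "outside")
  expect_warning(annotated_record(1:100, fs = 250), "250")
})

test_that("split_dataset applies the double 80:20 with floor rounding", {
  s <- split_dataset(100, seed = 7)
  expect_equal(length(s$train), 64)
  expect_equal(length(s$val), 16)
  expect_equal(length(s$test), 20)

  s5 <- split_dataset(5, seed = 1)
  expect_equal(length(s5$test), 1)
  expect_equal(length(s5$val), 0)
  expect_equal(length(s5$train), 4)

  expect_error(split_dataset(4), "at least 5")
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  for (n in c(5, 17, 100, 321)) {
    s <- split_dataset(n, seed = 42)
    all_idx <- sort(c(s$train, s$val, s$test))
    expect_equal(all_idx, seq_len(n))
    expect_equal(length(intersect(s$train, s$test)), 0)
    expect_equal(length(intersect(s$train, s$val)), 0)
    expect_equal(length(intersect(s$val, s$test)), 0)
  }
  expect_identical(split_dataset(100, seed = 3), split_dataset(100, seed = 3))
  expect_false(identical(split_dataset(100, seed = 3)$test,
                         split_dataset(100, seed = 4)$test))
})

test_that("split manifests round-trip through JSON", {
  s <- split_dataset(50, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_json(s, path)
  expect_equal(read_split_json(path), s)
})

test_that("csv_beats dialect round-trips and validates", {
  beats <- generate_beats(synth_spec(c(N = 2L, V = 1L), noise_sd = 0.01,
                                     seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_beats(beats, path)
  back <- read_record(path, dialect = "csv_beats")
  expect_equal(back$x, beats$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$label, beats$label)
  expect_equal(back$synthetic, beats$synthetic)

  # symbol column may carry raw annotation symbols
  df <- data.frame(s0 = 0.1, s1 = 0.2, symbol = "L")
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE, quote = FALSE)
  expect_equal(read_csv_beats(p2)$label, "N")

  # truncated row -> format error
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("s0,s1,s2,symbol", "0.1,0.2,0.3,N", "0.1,0.2,,N"), p3)
  expect_error(read_csv_beats(p3), "format error")
})
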