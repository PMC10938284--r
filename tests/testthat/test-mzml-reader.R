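# Indexed mzML loading: writer/reader round trips, axis auto-detection,
# offset-list parsing, first-spectrum axis configuration, error paths.

test_that("round trip is exact across widths, compressions and axis orders", {
  cases <- expand.grid(vt = c("float64", "float32"),
                       cp = c("none", "zlib"),
                       ord = c("mz_first", "intensity_first"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    sp <- random_spectra(3, c(4, 12), seed = 500 + k)
    f <- tmp_mzml()
    write_mzml(sp, f, value_type = cases$vt[k], compression = cases$cp[k],
               axis_order = cases$ord[k])
    got <- read_mzml(f)
    expect_identical(plain_spectra(got),
                     expected_after_roundtrip(sp, cases$vt[k]),
                     info = paste(cases[k, ], collapse = "/"))
  }
})

test_that("axis order is auto-detected from the first spectrum", {
  sp <- random_spectra(4, c(5, 9), seed = 17)
  f1 <- tmp_mzml(); f2 <- tmp_mzml()
  write_mzml(sp, f1, axis_order = "mz_first")
  write_mzml(sp, f2, axis_order = "intensity_first")
  expect_identical(plain_spectra(read_mzml(f1)), plain_spectra(read_mzml(f2)))
})

test_that("mixed per-axis encodings are honored", {
  sp <- random_spectra(3, c(5, 9), seed = 23)
  f <- tmp_mzml()
  write_mzml(sp, f, value_type = c("float64", "float32"),
             compression = c("zlib", "none"))
  got <- read_mzml(f)
  expect_identical(plain_spectra(got),
                   expected_after_roundtrip(sp, c("float64", "float32")))
})

test_that("zero-length spectra load as empty vectors", {
  sp <- msio:::new_ms_spectra(list(list(mz = numeric(0),
                                        intensity = numeric(0))))
  f <- tmp_mzml()
  write_mzml(sp, f)
  got <- read_mzml(f)
  expect_length(got, 1)
  expect_identical(got[[1]]$mz, numeric(0))
  expect_identical(got[[1]]$intensity, numeric(0))
})

test_that("a file with zero spectra loads as an empty spectra set", {
  f <- tmp_mzml()
  write_mzml(list(), f)
  expect_length(read_mzml(f), 0)
})

test_that("parse_offset_list recovers the writer's true byte offsets", {
  sp <- random_spectra(5, c(3, 10), seed = 31)
  f <- tmp_mzml()
  gt <- write_mzml(sp, f)
  s <- msio:::ms_stream(f)
  on.exit(close(s))
  offs <- msio:::parse_offset_list(s, gt$index_list_offset)
  expect_identical(offs, gt$offsets)
  expect_true(all(diff(offs) > 0))
  # every offset points exactly at "<spectrum"
  for (o in offs)
    expect_identical(msio:::read_span(s, o, o + 9), "<spectrum")
})

test_that("an offset past the end of the file is a corrupt index", {
  sp <- random_spectra(2, c(3, 5), seed = 37)
  f <- tmp_mzml()
  gt <- write_mzml(sp, f)
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  old <- sprintf(">%.0f</offset>", gt$offsets[1])
  new <- sprintf(">%s</offset>",
                 strrep("9", nchar(sprintf("%.0f", gt$offsets[1]))))
  txt <- sub(old, new, txt, fixed = TRUE)
  writeBin(charToRaw(txt), f)
  s <- msio:::ms_stream(f)
  on.exit(close(s))
  expect_error(msio:::parse_offset_list(s, gt$index_list_offset),
               class = "msio_corrupt_index_error")
})

test_that("config_spec_dim reads roles, encodings, order and skip distance", {
  sp <- random_spectra(1, c(5, 5), seed = 41)
  f <- tmp_mzml()
  gt <- write_mzml(sp, f, value_type = c("float64", "float32"),
                   compression = c("zlib", "none"),
                   axis_order = "intensity_first")
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  m <- regexpr("(?s)<spectrum .*?</spectrum>", txt, perl = TRUE)
  cfg <- msio:::config_spec_dim(regmatches(txt, m))
  expect_identical(cfg$mz$role, "mz")
  expect_identical(cfg$mz$position, 2L)
  expect_identical(cfg$intensity$position, 1L)
  expect_identical(cfg$mz$encoding$value_type, "float64")
  expect_identical(cfg$mz$encoding$compression, "zlib")
  expect_identical(cfg$intensity$encoding$value_type, "float32")
  expect_identical(cfg$intensity$encoding$compression, "none")
  expect_identical(cfg$skip_bytes, gt$skip_bytes)
})

test_that("a spectrum without an intensity-array accession is malformed", {
  sp <- random_spectra(2, c(4, 6), seed = 43)
  f <- tmp_mzml()
  write_mzml(sp, f)
  corrupt_fixture(f, "drop_accession")
  expect_error(read_mzml(f), class = "msio_malformed_error")
})

test_that("a truncated zlib stream is reported with its spectrum ordinal", {
  sp <- random_spectra(10, c(6, 12), seed = 47)
  f <- tmp_mzml()
  write_mzml(sp, f, compression = "zlib")
  corrupt_fixture(f, "truncate_zlib", spectrum = 7)
  err <- expect_error(read_mzml(f), class = "msio_inflate_error")
  expect_match(conditionMessage(err), "spectrum 7")
  expect_identical(err$index, 7L)
})

test_that("non-indexed input is rejected with an index-required error", {
  f <- tempfile(fileext = ".mzML")
  writeBin(charToRaw('<mzML version="1.1.0"><run/></mzML>'), f)
  err <- expect_error(read_mzml(f), class = "msio_not_indexed_error")
  expect_match(conditionMessage(err), basename(f), fixed = TRUE)
})

test_that("strict mode flags a mid-file axis-order change", {
  sp <- random_spectra(3, c(4, 4), seed = 53)
  f <- tmp_mzml()
  write_mzml(sp, f, compression = "none")
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  # swap the role accessions of the LAST spectrum only (equal length)
  parts <- strsplit(txt, '<spectrum index="2"', fixed = TRUE)[[1]]
  tail_txt <- gsub("MS:1000514", "MS:10005xx", parts[2], fixed = TRUE)
  tail_txt <- gsub("MS:1000515", "MS:1000514", tail_txt, fixed = TRUE)
  tail_txt <- gsub("MS:10005xx", "MS:1000515", tail_txt, fixed = TRUE)
  writeBin(charToRaw(paste0(parts[1], '<spectrum index="2"', tail_txt)), f)
  expect_identical(length(read_mzml(f)), 3L)        # default mode trusts file
  err <- expect_error(read_mzml(f, strict = TRUE),
                      class = "msio_malformed_spectrum_error")
  expect_match(conditionMessage(err), "spectrum 3")
})

test_that("integer-typed arrays are rejected as unsupported", {
  sp <- random_spectra(1, c(4, 4), seed = 59)
  f <- tmp_mzml()
  write_mzml(sp, f, compression = "none")
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  txt <- sub("MS:1000523", "MS:1000522", txt, fixed = TRUE)  # 64-bit integer
  writeBin(charToRaw(txt), f)
  expect_error(read_mzml(f), class = "msio_unsupported_encoding_error")
})

test_that("the reader agrees with an independent mzML implementation", {
  skip_if_not_installed("mzR")
  sp <- random_spectra(5, c(10, 40), seed = 61)
  f <- tmp_mzml()
  write_mzml(sp, f, value_type = "float64", compression = "zlib")
  own <- read_mzml(f)
  h <- mzR::openMSfile(f)
  on.exit(mzR::close(h))
  ref <- mzR::peaks(h)
  expect_length(ref, length(own))
  for (i in seq_along(own)) {
    expect_identical(own[[i]]$mz, unname(ref[[i]][, 1]))
    expect_identical(own[[i]]$intensity, unname(ref[[i]][, 2]))
  }
})
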