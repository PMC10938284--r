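# imzML/ibd loading: round trips, missing pixels, skip-vs-naive equivalence,
# locator and mode error paths.

write_pair <- function(px, dims, ...) {
  base <- tempfile()
  write_imzml(px, dims, base, ...)
  paste0(base, ".imzML")
}

test_that("a 4x3 image with distinct pixel spectra round-trips bit-exact", {
  px <- random_pixels(4, 3, len_range = c(4, 9), seed = 71)
  f <- write_pair(px, c(4, 3))
  img <- read_imzml(f)
  expect_identical(img$dims$max_x, 4L)
  expect_identical(img$dims$max_y, 3L)
  expect_identical(img$dims$n_spectra, 12L)
  expect_identical(img$pixels, px)
})

test_that("missing pixels are returned without error", {
  px <- random_pixels(4, 3, n = 10, seed = 73)
  f <- write_pair(px, c(4, 3))
  img <- read_imzml(f)
  expect_length(img$pixels, 10)
  expect_identical(img$dims$n_spectra, 10L)
  expect_identical(img$dims$max_x * img$dims$max_y, 12L)
  expect_identical(img$pixels, px)
})

test_that("a single pixel at (1,1) loads", {
  px <- random_pixels(1, 1, len_range = c(3, 3), seed = 79)
  img <- read_imzml(write_pair(px, c(1, 1)))
  expect_length(img$pixels, 1)
  expect_identical(img$pixels[[1]]$x, 1L)
  expect_identical(img$pixels[[1]]$y, 1L)
})

test_that("pixels come back in file order, not grid order", {
  px <- random_pixels(5, 4, shuffle = TRUE, seed = 83)
  coords <- vapply(px, function(p) c(p$x, p$y), numeric(2))
  expect_true(is.unsorted(coords[2, ]))   # the shuffle really shuffled
  img <- read_imzml(write_pair(px, c(5, 4)))
  expect_identical(img$pixels, px)
})

test_that("declared grid dimensions may exceed the stored pixel count", {
  px <- random_pixels(4, 3, n = 12, seed = 89)
  img <- read_imzml(write_pair(px, c(85, 50)))
  expect_identical(img$dims$max_x, 85L)
  expect_identical(img$dims$max_y, 50L)
  expect_identical(img$dims$n_spectra, 12L)
})

test_that("zlib-compressed ibd arrays are declared and honored", {
  px <- random_pixels(3, 2, len_range = c(10, 30), seed = 97)
  f <- write_pair(px, c(3, 2), compression = "zlib")
  img <- read_imzml(f)
  expect_identical(img$pixels, px)
  # the ibd really is compressed: payload bytes differ from the raw stream
  gt <- write_imzml(px, c(3, 2), tempfile(), compression = "none")
  expect_lt(0, abs(file.size(sub("imzML$", "ibd", f)) -
                     file.size(gt$ibd_path)))
})

test_that("float32 pixel arrays round through 32-bit precision", {
  px <- random_pixels(2, 2, len_range = c(5, 8), seed = 101)
  img <- read_imzml(write_pair(px, c(2, 2), value_type = "float32"))
  for (i in seq_along(px)) {
    expect_identical(img$pixels[[i]]$mz, msio:::float32_round(px[[i]]$mz))
    expect_identical(img$pixels[[i]]$intensity,
                     msio:::float32_round(px[[i]]$intensity))
  }
})

test_that("skip-byte and naive scan strategies agree on randomized fixtures", {
  for (k in 1:10) {
    px <- random_pixels(4, 3,
                        n = sample(c(6, 10, 12), 1),
                        shuffle = k %% 2 == 0,
                        seed = 110 + k)
    f <- write_pair(px, c(4, 3), jitter = if (k > 5) 6 else 0,
                    seed = 200 + k)
    a <- read_imzml(f, method = "skip")
    b <- read_imzml(f, method = "naive")
    expect_identical(a$pixels, b$pixels, info = paste("fixture", k))
    expect_identical(a$pixels, px, info = paste("fixture", k))
  }
})

test_that("locator extents stay inside the ibd file", {
  px <- random_pixels(3, 3, seed = 131)
  base <- tempfile()
  gt <- write_imzml(px, c(3, 3), base)
  ends <- vapply(gt$locators, function(l)
    max(l$mz$offset + l$mz$enc_bytes,
        l$intensity$offset + l$intensity$enc_bytes), numeric(1))
  expect_true(all(ends <= file.size(gt$ibd_path)))
})

test_that("a missing ibd sibling is a paired-file error", {
  px <- random_pixels(2, 2, seed = 137)
  base <- tempfile()
  gt <- write_imzml(px, c(2, 2), base)
  unlink(gt$ibd_path)
  expect_error(read_imzml(gt$imzml_path), class = "msio_paired_file_error")
})

test_that("a locator pointing outside the ibd names the pixel ordinal", {
  px <- random_pixels(3, 3, seed = 139)
  f <- write_pair(px, c(3, 3))
  corrupt_fixture(f, "locator_overrun")
  err <- expect_error(read_imzml(f), class = "msio_corrupt_locator_error")
  expect_match(conditionMessage(err), "pixel 1")
})

test_that("continuous-mode documents are rejected as unsupported", {
  px <- random_pixels(2, 2, seed = 149)
  f <- write_pair(px, c(2, 2))
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  txt <- sub("IMS:1000031", "IMS:1000030", txt, fixed = TRUE)
  writeBin(charToRaw(txt), f)
  expect_error(read_imzml(f), class = "msio_unsupported_mode_error")
})

test_that("an unknown compression accession in the axis group is rejected", {
  px <- random_pixels(2, 2, seed = 151)
  f <- write_pair(px, c(2, 2), compression = "numpress")
  expect_error(read_imzml(f), class = "msio_unsupported_encoding_error")
})

test_that("a pixel without a y position is malformed", {
  px <- random_pixels(2, 2, seed = 157)
  f <- write_pair(px, c(2, 2))
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  txt <- sub("IMS:1000051", "IMS:9000051", txt, fixed = TRUE)
  writeBin(charToRaw(txt), f)
  err <- expect_error(read_imzml(f), class = "msio_malformed_pixel_error")
  expect_match(conditionMessage(err), "pixel 1")
})

test_that("a zero pixel count in <spectrumList> is malformed", {
  px <- random_pixels(2, 2, seed = 163)
  f <- write_pair(px, c(2, 2))
  txt <- readChar(f, file.size(f), useBytes = TRUE)
  txt <- sub('<spectrumList count="4">', '<spectrumList count="0">', txt,
             fixed = TRUE)
  writeBin(charToRaw(txt), f)
  expect_error(read_imzml(f), class = "msio_malformed_error")
})

test_that("an ibd UUID mismatch warns but still loads", {
  px <- random_pixels(2, 2, seed = 167)
  base <- tempfile()
  gt <- write_imzml(px, c(2, 2), base)
  bytes <- readBin(gt$ibd_path, "raw", file.size(gt$ibd_path))
  bytes[1] <- as.raw(0xFF)
  writeBin(bytes, gt$ibd_path)
  expect_warning(img <- read_imzml(gt$imzml_path), "UUID")
  expect_identical(img$pixels, px)
})

test_that("fixtures are well-formed XML", {
  skip_if_not_installed("xml2")
  px <- random_pixels(3, 2, seed = 173)
  f <- write_pair(px, c(3, 2), jitter = 5, seed = 3)
  expect_s3_class(xml2::read_xml(f), "xml_document")
  sp <- random_spectra(3, c(4, 8), seed = 179)
  g <- tmp_mzml()
  write_mzml(sp, g, jitter = 5, seed = 4)
  expect_s3_class(xml2::read_xml(g), "xml_document")
})
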