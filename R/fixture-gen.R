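# Deterministic synthetic-data writers: valid indexed mzML files and
# processed-mode imzML/ibd pairs with a ground-truth record (true byte
# offsets, skip distances, per-pixel locators), plus corrupted variants for
# error-path tests.  Identical arguments and seed give byte-identical files.

nbytes <- function(x) nchar(x, type = "bytes")

# Opening tag with optional attribute-order shuffling and trailing-space
# jitter (<= `jitter` extra spaces), so readers cannot depend on attribute
# order or exact tag lengths.  Jitter is capped at 8 bytes per tag to stay
# well inside the skip-hint safety margin.
tag_str <- function(name, attrs = character(0), jitter = 0,
                    self_close = FALSE) {
  ord <- seq_along(attrs)
  if (jitter > 0 && length(attrs) > 1) ord <- sample(ord)
  body <- if (length(attrs))
    paste0(" ", paste(sprintf('%s="%s"', names(attrs)[ord], attrs[ord]),
                      collapse = " "))
  else ""
  extra <- if (jitter > 0) strrep(" ", sample.int(jitter + 1, 1) - 1) else ""
  paste0("<", name, body, extra, if (self_close) "/>" else ">")
}

cv_str <- function(cv_ref, accession, name, value = NULL, jitter = 0) {
  attrs <- c(cvRef = cv_ref, accession = accession, name = name)
  if (!is.null(value)) attrs <- c(attrs, value = as.character(value))
  tag_str("cvParam", attrs, jitter = jitter, self_close = TRUE)
}

# accessions written for each value type / compression choice
value_type_cv <- function(value_type, jitter = 0) {
  if (value_type == "float64")
    cv_str("MS", "MS:1000523", "64-bit float", jitter = jitter)
  else
    cv_str("MS", "MS:1000521", "32-bit float", jitter = jitter)
}
compression_cv <- function(compression, jitter = 0) {
  switch(compression,
    zlib = cv_str("MS", "MS:1000574", "zlib compression", jitter = jitter),
    none = cv_str("MS", "MS:1000576", "no compression", jitter = jitter),
    numpress = cv_str("MS", "MS:1002312", "MS-Numpress linear prediction compression",
                      jitter = jitter),
    msio_stop("parameter", sprintf("unknown compression '%s'", compression))
  )
}
role_cv <- function(role, jitter = 0) {
  if (role == "mz")
    cv_str("MS", "MS:1000514", "m/z array", jitter = jitter)
  else
    cv_str("MS", "MS:1000515", "intensity array", jitter = jitter)
}

# writers accept "numpress" to emit a deliberately unsupported compression
# accession (payload bytes stay uncompressed; readers must refuse early)
writer_encoding <- function(value_type, compression) {
  array_encoding(value_type,
                 if (compression == "numpress") "none" else compression)
}

run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

#' Generate reproducible random spectra
#'
#' Pseudo-random centroid-like spectra: per-spectrum point counts drawn
#' uniformly from `len_range`, m/z values uniform over `mz_range` and sorted
#' ascending, intensities uniform over `[0, intensity_max]`.
#'
#' @param n number of spectra (0 allowed).
#' @param len_range integer range `c(min, max)` of points per spectrum.
#' @param mz_range m/z range.
#' @param intensity_max upper intensity bound.
#' @param seed optional seed; the same seed reproduces identical spectra
#'   without touching the global RNG state.
#' @return an `ms_spectra` object.
#' @export
random_spectra <- function(n, len_range = c(50L, 200L),
                           mz_range = c(100, 1000), intensity_max = 1e5,
                           seed = NULL) {
  stopifnot(n >= 0)
  run_seeded(seed, function() {
    new_ms_spectra(lapply(seq_len(n), function(i) {
      len <- sample(seq.int(len_range[1], len_range[2]), 1)
      list(mz = sort(stats::runif(len, mz_range[1], mz_range[2])),
           intensity = stats::runif(len, 0, intensity_max))
    }))
  })
}

#' Generate reproducible random pixel spectra on a grid
#'
#' Pixels are laid out row-major on a `max_x` by `max_y` grid; with
#' `n < max_x * max_y` a random subset of grid cells is kept (the
#' missing-pixel case), and `shuffle = TRUE` permutes the file order of the
#' pixels while keeping their grid coordinates.
#'
#' @param max_x,max_y grid size in pixels.
#' @param len_range points per pixel spectrum, `c(min, max)`.
#' @param mz_range m/z range.
#' @param n number of stored pixels (default: the full grid).
#' @param shuffle permute pixel file order.
#' @param seed optional seed.
#' @return a list of pixels, each a list with `x`, `y`, `mz`, `intensity`.
#' @export
random_pixels <- function(max_x, max_y, len_range = c(20L, 80L),
                          mz_range = c(100, 1000), n = NULL, shuffle = FALSE,
                          seed = NULL) {
  max_x <- as.integer(max_x)
  max_y <- as.integer(max_y)
  total <- max_x * max_y
  if (is.null(n)) n <- total
  stopifnot(n >= 1, n <= total)
  run_seeded(seed, function() {
    cells <- if (n < total) sort(sample.int(total, n)) else seq_len(total)
    if (shuffle) cells <- sample(cells)
    lapply(cells, function(cell) {
      len <- sample(seq.int(len_range[1], len_range[2]), 1)
      list(x = (cell - 1L) %% max_x + 1L,
           y = (cell - 1L) %/% max_x + 1L,
           mz = sort(stats::runif(len, mz_range[1], mz_range[2])),
           intensity = stats::runif(len, 0, 1e5))
    })
  })
}

#' Write an indexed mzML fixture file
#'
#' Emits a valid `<indexedmzML>` document: spectrum list with per-spectrum
#' `<binaryDataArrayList>` carrying the controlled-vocabulary accessions for
#' array role, float width and compression, followed by the `<indexList>`
#' and `<indexListOffset>`.  Byte offsets are computed while writing, so the
#' returned ground truth is exact by construction.
#'
#' @param spectra an `ms_spectra` object or list of spectra.
#' @param path output file.
#' @param value_type `"float64"` or `"float32"`; length 1 or 2 (m/z,
#'   intensity).
#' @param compression `"none"`, `"zlib"` or `"numpress"` (writes an
#'   unsupported compression accession, for error-path tests); length 1 or 2.
#' @param axis_order `"mz_first"` or `"intensity_first"`.
#' @param jitter max extra whitespace bytes per tag (0-8); also shuffles
#'   attribute order.
#' @param seed seed for the jitter randomness.
#' @return invisibly, the ground-truth record: `path`, `offsets` (0-based
#'   byte offset of every `<spectrum`), `index_list_offset`, `skip_bytes`
#'   (distance from `<spectrum` to `<binaryDataArrayList` in the first
#'   spectrum) and `n`.
#' @export
write_mzml <- function(spectra, path, value_type = "float64",
                       compression = "zlib",
                       axis_order = c("mz_first", "intensity_first"),
                       jitter = 0, seed = NULL) {
  axis_order <- match.arg(axis_order)
  vt <- rep_len(value_type, 2)
  cp <- rep_len(compression, 2)
  names(vt) <- names(cp) <- c("mz", "intensity")
  enc <- list(mz = writer_encoding(vt[["mz"]], cp[["mz"]]),
              intensity = writer_encoding(vt[["intensity"]], cp[["intensity"]]))
  jitter <- min(max(jitter, 0), 8)
  n <- length(spectra)

  res <- run_seeded(seed, function() {
    head_txt <- paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">\n',
      ' <mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="fixture">\n',
      '  <cvList count="1">\n',
      '   <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
      '  </cvList>\n',
      '  <fileDescription>\n',
      '   <fileContent>\n',
      '    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
      '   </fileContent>\n',
      '  </fileDescription>\n',
      '  <softwareList count="1">\n',
      '   <software id="msio" version="0.1.0">\n',
      '    <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msio fixture writer"/>\n',
      '   </software>\n',
      '  </softwareList>\n',
      '  <instrumentConfigurationList count="1">\n',
      '   <instrumentConfiguration id="IC1">\n',
      '    <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
      '   </instrumentConfiguration>\n',
      '  </instrumentConfigurationList>\n',
      '  <dataProcessingList count="1">\n',
      '   <dataProcessing id="dp1">\n',
      '    <processingMethod order="1" softwareRef="msio">\n',
      '     <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
      '    </processingMethod>\n',
      '   </dataProcessing>\n',
      '  </dataProcessingList>\n',
      '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
      sprintf('   <spectrumList count="%d" defaultDataProcessingRef="dp1">\n', n)
    )

    array_str <- function(role, values) {
      b64 <- encode_binary_array(values, enc[[role]])
      paste0(
        "    ",
        tag_str("binaryDataArray", c(encodedLength = nbytes(b64)),
                jitter = jitter), "\n",
        "     ", value_type_cv(vt[[role]], jitter), "\n",
        "     ", compression_cv(cp[[role]], jitter), "\n",
        "     ", role_cv(role, jitter), "\n",
        "     <binary>", b64, "</binary>\n",
        "    </binaryDataArray>\n"
      )
    }

    order_roles <- if (axis_order == "mz_first") c("mz", "intensity")
                   else c("intensity", "mz")
    spectrum_str <- function(i) {
      sp <- spectra[[i]]
      paste0(
        tag_str("spectrum",
                c(index = i - 1L, id = sprintf("scan=%d", i),
                  defaultArrayLength = length(sp$mz)),
                jitter = jitter), "\n",
        "    ", cv_str("MS", "MS:1000511", "ms level", 1, jitter), "\n",
        '    ', tag_str("binaryDataArrayList", c(count = "2"),
                        jitter = jitter), "\n",
        paste0(vapply(order_roles, function(r) array_str(r, sp[[r]]),
                      character(1)), collapse = ""),
        "    </binaryDataArrayList>\n",
        "   </spectrum>\n"
      )
    }

    off <- nbytes(head_txt)
    offsets <- numeric(n)
    specs <- character(n)
    for (i in seq_len(n)) {
      specs[i] <- spectrum_str(i)
      offsets[i] <- off
      off <- off + nbytes(specs[i])
    }
    tail1 <- "   </spectrumList>\n  </run>\n </mzML>\n"
    index_list_offset <- as.numeric(off + nbytes(tail1))
    index_txt <- paste0(
      '<indexList count="1">\n',
      '  <index name="spectrum">\n',
      if (n > 0)
        paste0(sprintf('   <offset idRef="scan=%d">%.0f</offset>\n',
                       seq_len(n), offsets), collapse = "")
      else "",
      '  </index>\n',
      '</indexList>\n'
    )
    tail2 <- paste0(
      sprintf('<indexListOffset>%.0f</indexListOffset>\n', index_list_offset),
      ' <fileChecksum>0000000000000000000000000000000000000000</fileChecksum>\n',
      '</indexedmzML>\n'
    )
    skip_bytes <- if (n > 0)
      as.numeric(regexpr("<binaryDataArrayList", specs[1],
                         fixed = TRUE, useBytes = TRUE)) - 1
    else NA_real_
    list(text = paste0(head_txt, paste0(specs, collapse = ""), tail1,
                       index_txt, tail2),
         offsets = offsets, index_list_offset = index_list_offset,
         skip_bytes = skip_bytes)
  })

  con <- file(path, "wb")
  writeBin(charToRaw(res$text), con)
  close(con)
  invisible(list(path = path, offsets = res$offsets,
                 index_list_offset = res$index_list_offset,
                 skip_bytes = res$skip_bytes, n = n))
}

MSIO_IBD_UUID <- as.raw(c(0x6d, 0x73, 0x69, 0x6f, 0x2d, 0x66, 0x69, 0x78,
                          0x74, 0x75, 0x72, 0x65, 0x2d, 0x69, 0x62, 0x64))

format_uuid <- function(raw16) {
  hex <- sprintf("%02x", as.integer(raw16))
  sprintf("{%s-%s-%s-%s-%s}",
          paste(hex[1:4], collapse = ""), paste(hex[5:6], collapse = ""),
          paste(hex[7:8], collapse = ""), paste(hex[9:10], collapse = ""),
          paste(hex[11:16], collapse = ""))
}

#' Write a processed-mode imzML / ibd fixture pair
#'
#' Emits `<basename>.imzML` plus `<basename>.ibd` (16-byte UUID header, then
#' the per-pixel m/z and intensity byte streams).  Axis encodings are
#' declared in `<referenceableParamGroup>` elements; every spectrum carries
#' its pixel coordinates (IMS:1000050/51) and external offset, element count
#' and encoded byte length (IMS:1000102/03/04).
#'
#' @param pixels list of pixels (`x`, `y`, `mz`, `intensity`), e.g. from
#'   [random_pixels()]; file order is preserved.
#' @param dims grid size `c(max_x, max_y)` (may exceed the pixels present).
#' @param basename output path without extension.
#' @inheritParams write_mzml
#' @return invisibly, the ground truth: `imzml_path`, `ibd_path`, `dims`,
#'   and `locators` (per pixel and axis: 0-based ibd offset, element count,
#'   encoded byte length).
#' @export
write_imzml <- function(pixels, dims, basename, value_type = "float64",
                        compression = "none", jitter = 0, seed = NULL) {
  vt <- rep_len(value_type, 2)
  cp <- rep_len(compression, 2)
  names(vt) <- names(cp) <- c("mz", "intensity")
  enc <- list(mz = writer_encoding(vt[["mz"]], cp[["mz"]]),
              intensity = writer_encoding(vt[["intensity"]], cp[["intensity"]]))
  jitter <- min(max(jitter, 0), 8)
  n <- length(pixels)
  max_x <- as.integer(dims[[1]])
  max_y <- as.integer(dims[[2]])

  imzml_path <- paste0(basename, ".imzML")
  ibd_path <- paste0(basename, ".ibd")

  # ibd stream + ground-truth locators
  chunks <- vector("list", 2L * n + 1L)
  chunks[[1]] <- MSIO_IBD_UUID
  locators <- vector("list", n)
  cur <- 16
  for (i in seq_len(n)) {
    loc <- list()
    for (role in c("mz", "intensity")) {
      bytes <- float_to_bytes(pixels[[i]][[role]], enc[[role]])
      if (cp[[role]] == "zlib") bytes <- deflate_bytes(bytes)
      loc[[role]] <- list(offset = cur, count = length(pixels[[i]][[role]]),
                          enc_bytes = length(bytes))
      chunks[[2L * (i - 1L) + (if (role == "mz") 2L else 3L)]] <- bytes
      cur <- cur + length(bytes)
    }
    locators[[i]] <- loc
  }
  con <- file(ibd_path, "wb")
  writeBin(do.call(c, chunks), con)
  close(con)

  xml <- run_seeded(seed, function() {
    group_str <- function(id, role) {
      paste0(
        sprintf('  <referenceableParamGroup id="%s">\n', id),
        "   ", role_cv(role, jitter), "\n",
        "   ", value_type_cv(vt[[role]], jitter), "\n",
        "   ", compression_cv(cp[[role]], jitter), "\n",
        "  </referenceableParamGroup>\n"
      )
    }
    pixel_array_str <- function(role, ref_id, loc) {
      paste0(
        "      ", tag_str("binaryDataArray", c(encodedLength = "0"),
                          jitter = jitter), "\n",
        sprintf('       <referenceableParamGroupRef ref="%s"/>\n', ref_id),
        "       ", cv_str("IMS", "IMS:1000102", "external offset",
                          sprintf("%.0f", loc$offset), jitter), "\n",
        "       ", cv_str("IMS", "IMS:1000103", "external array length",
                          loc$count, jitter), "\n",
        "       ", cv_str("IMS", "IMS:1000104", "external encoded length",
                          loc$enc_bytes, jitter), "\n",
        "       <binary/>\n",
        "      </binaryDataArray>\n"
      )
    }
    spectrum_str <- function(i) {
      p <- pixels[[i]]
      paste0(
        "    ",
        tag_str("spectrum",
                c(index = i - 1L, id = sprintf("spectrum=%d", i),
                  defaultArrayLength = "0"),
                jitter = jitter), "\n",
        '     <scanList count="1">\n',
        "      ", tag_str("scan", jitter = jitter), "\n",
        "       ", cv_str("IMS", "IMS:1000050", "position x", p$x, jitter),
        "\n",
        "       ", cv_str("IMS", "IMS:1000051", "position y", p$y, jitter),
        "\n",
        "      </scan>\n",
        "     </scanList>\n",
        '     <binaryDataArrayList count="2">\n',
        pixel_array_str("mz", "mzArray", locators[[i]]$mz),
        pixel_array_str("intensity", "intensityArray",
                        locators[[i]]$intensity),
        "     </binaryDataArrayList>\n",
        "    </spectrum>\n"
      )
    }
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="fixture">\n',
      ' <cvList count="2">\n',
      '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
      '  <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
      ' </cvList>\n',
      ' <fileDescription>\n',
      '  <fileContent>\n',
      '   ', cv_str("IMS", "IMS:1000031", "processed"), "\n",
      '   ', cv_str("IMS", "IMS:1000080", "universally unique identifier",
                    format_uuid(MSIO_IBD_UUID)), "\n",
      '  </fileContent>\n',
      ' </fileDescription>\n',
      ' <referenceableParamGroupList count="2">\n',
      group_str("mzArray", "mz"),
      group_str("intensityArray", "intensity"),
      ' </referenceableParamGroupList>\n',
      ' <scanSettingsList count="1">\n',
      '  <scanSettings id="scansettings1">\n',
      '   ', cv_str("IMS", "IMS:1000042", "max count of pixels x", max_x),
      "\n",
      '   ', cv_str("IMS", "IMS:1000043", "max count of pixels y", max_y),
      "\n",
      '  </scanSettings>\n',
      ' </scanSettingsList>\n',
      ' <run id="run1">\n',
      sprintf('   <spectrumList count="%d">\n', n),
      paste0(vapply(seq_len(n), spectrum_str, character(1)), collapse = ""),
      '   </spectrumList>\n',
      ' </run>\n',
      '</mzML>\n'
    )
  })

  con <- file(imzml_path, "wb")
  writeBin(charToRaw(xml), con)
  close(con)
  invisible(list(imzml_path = imzml_path, ibd_path = ibd_path,
                 dims = new_image_dims(max_x, max_y, n),
                 locators = locators, n = n))
}

#' Corrupt a fixture file in a targeted way
#'
#' Produces, deterministically, one named defect for error-path tests.
#' Byte lengths are preserved where the mzML spectrum index would otherwise
#' be invalidated, so the defect surfaces exactly where intended.
#'
#' @param path a fixture written by [write_mzml()] or [write_imzml()].
#' @param mode one of:
#'   * `"truncate_index"` - removes the `<indexList>` and everything after it
#'     (mzML; the file is no longer indexed),
#'   * `"truncate_zlib"` - overwrites the tail of the target spectrum's first
#'     base64 payload so its zlib stream no longer inflates (mzML written
#'     with zlib compression),
#'   * `"drop_accession"` - invalidates the intensity-array role accession of
#'     the first spectrum (equal-length replacement),
#'   * `"locator_overrun"` - points the first pixel's external offset past
#'     the end of the ibd file (imzML).
#' @param spectrum 1-based target spectrum for `"truncate_zlib"`.
#' @return `path`, invisibly.
#' @export
corrupt_fixture <- function(path,
                            mode = c("truncate_index", "truncate_zlib",
                                     "drop_accession", "locator_overrun"),
                            spectrum = 1L) {
  mode <- match.arg(mode)
  txt <- readChar(path, file.size(path), useBytes = TRUE)

  txt <- switch(mode,
    truncate_index = {
      cut <- regexpr("<indexList", txt, fixed = TRUE, useBytes = TRUE)
      if (cut < 0) msio_stop("parameter", "no <indexList> to truncate")
      substr(txt, 1, cut - 1)
    },
    truncate_zlib = {
      m <- gregexpr("(?s)<binary>(.*?)</binary>", txt, perl = TRUE,
                    useBytes = TRUE)[[1]]
      k <- 2L * (spectrum - 1L) + 1L
      if (m[1] < 0 || length(m) < k)
        msio_stop("parameter",
                  sprintf("no binary payload for spectrum %d", spectrum))
      st <- attr(m, "capture.start")[k, 1]
      ln <- attr(m, "capture.length")[k, 1]
      if (ln < 8)
        msio_stop("parameter", "payload too short to corrupt")
      substr(txt, st + ln - 8, st + ln - 1) <- "AAAAAAAA"
      txt
    },
    drop_accession = {
      sub("MS:1000515", "MS:9999915", txt, fixed = TRUE, useBytes = TRUE)
    },
    locator_overrun = {
      m <- gregexpr("<cvParam\\b[^>]*>", txt, perl = TRUE, useBytes = TRUE)[[1]]
      if (m[1] < 0) msio_stop("parameter", "no cvParam elements found")
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      done <- FALSE
      for (k in seq_along(starts)) {
        tag <- substr(txt, starts[k], starts[k] + lens[k] - 1)
        if (grepl("IMS:1000102", tag, fixed = TRUE, useBytes = TRUE)) {
          new_tag <- sub('value\\s*=\\s*"[0-9]+"', 'value="999999999"', tag,
                         perl = TRUE, useBytes = TRUE)
          txt <- paste0(substr(txt, 1, starts[k] - 1), new_tag,
                        substr(txt, starts[k] + lens[k], nbytes(txt)))
          done <- TRUE
          break
        }
      }
      if (!done)
        msio_stop("parameter", "no external-offset cvParam found")
      txt
    }
  )

  con <- file(path, "wb")
  writeBin(charToRaw(txt), con)
  close(con)
  invisible(path)
}
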