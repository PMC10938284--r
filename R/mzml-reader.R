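# Indexed mzML loading: tail index -> offset list -> axis configuration from
# the first spectrum -> per-spectrum binary decoding.

# PSI-MS controlled-vocabulary accessions used by the reader.
MS_ACC <- list(
  MZ_ARRAY        = "MS:1000514",
  INTENSITY_ARRAY = "MS:1000515",
  FLOAT32         = "MS:1000521",
  FLOAT64         = "MS:1000523",
  ZLIB            = "MS:1000574",
  NO_COMPRESSION  = "MS:1000576",
  INT32           = "MS:1000519",
  INT64           = "MS:1000522"
)

# Compression accessions we recognise but do not support (MS-Numpress family).
MS_UNSUPPORTED_COMPRESSION <- c(
  "MS:1002312", "MS:1002313", "MS:1002314", "MS:1002315",
  "MS:1002745", "MS:1002746", "MS:1002747", "MS:1002748"
)

# Interpret the cvParams of one binary-data description (a <binaryDataArray>
# or a <referenceableParamGroup>): array role, float width, compression.
parse_axis_params <- function(text, what = "binary data array") {
  accs <- vapply(extract_cvparams(text), function(tag) {
    a <- read_attribute(tag, "accession")
    if (is.null(a)) "" else a
  }, character(1), USE.NAMES = FALSE)

  has <- function(a) a %in% accs
  role <- if (has(MS_ACC$MZ_ARRAY) && has(MS_ACC$INTENSITY_ARRAY)) {
    msio_stop("malformed", sprintf("%s claims both array roles", what))
  } else if (has(MS_ACC$MZ_ARRAY)) "mz"
    else if (has(MS_ACC$INTENSITY_ARRAY)) "intensity"
    else NA_character_

  if (has(MS_ACC$INT32) || has(MS_ACC$INT64))
    msio_stop("unsupported_encoding",
              sprintf("%s uses an integer value type, which is not supported",
                      what))
  value_type <- if (has(MS_ACC$FLOAT64)) "float64"
                else if (has(MS_ACC$FLOAT32)) "float32"
                else NA_character_

  if (any(accs %in% MS_UNSUPPORTED_COMPRESSION))
    msio_stop("unsupported_encoding",
              sprintf("%s declares an unsupported compression scheme (%s)",
                      what, accs[accs %in% MS_UNSUPPORTED_COMPRESSION][1]))
  compression <- if (has(MS_ACC$ZLIB)) "zlib"
                 else if (has(MS_ACC$NO_COMPRESSION)) "none"
                 else "none"   # absent accession: arrays default to raw

  list(role = role, value_type = value_type, compression = compression)
}

new_axis_config <- function(role, value_type, compression, position,
                            skip_bytes) {
  structure(
    list(role = role,
         encoding = array_encoding(value_type, compression),
         position = position,
         skip_bytes = skip_bytes),
    class = "ms_axis_config"
  )
}

# The two <binaryDataArray> elements of a text fragment, in file order.
binary_array_blocks <- function(text) {
  m <- gregexpr("(?s)<binaryDataArray\\b[^>]*>.*?</binaryDataArray>",
                text, perl = TRUE, useBytes = TRUE)[[1]]
  if (m[1] < 0) return(character(0))
  unlist(regmatches(text, list(m)), use.names = FALSE)
}

#' Configure the spectrum axes from the first spectrum of an mzML file
#'
#' Determines, once per file, which binary array is the m/z axis and which
#' the intensity axis (MS:1000514 / MS:1000515), their float widths and
#' compression schemes, their order of appearance, and the byte distance
#' from `<spectrum>` to its `<binaryDataArrayList>` (reused as a skip hint
#' for every later spectrum).
#'
#' @param first_spectrum_text text of one complete `<spectrum>` element.
#' @return a list with `mz` and `intensity` axis configurations and
#'   `skip_bytes`.
#' @noRd
config_spec_dim <- function(first_spectrum_text) {
  bdal <- regexpr("<binaryDataArrayList", first_spectrum_text,
                  fixed = TRUE, useBytes = TRUE)
  if (bdal < 0)
    msio_stop("malformed", "first spectrum has no <binaryDataArrayList>")
  skip_bytes <- as.numeric(bdal) - 1

  blocks <- binary_array_blocks(first_spectrum_text)
  if (length(blocks) < 2)
    msio_stop("malformed",
              sprintf("first spectrum has %d binary arrays; expected 2",
                      length(blocks)))

  axes <- vector("list", 2L)
  for (k in 1:2) {
    p <- parse_axis_params(blocks[k], sprintf("binary array %d", k))
    if (is.na(p$role))
      msio_stop("malformed",
                sprintf("binary array %d carries neither MS:1000514 nor MS:1000515", k))
    if (is.na(p$value_type))
      msio_stop("malformed",
                sprintf("binary array %d lacks a float-width accession", k))
    axes[[k]] <- new_axis_config(p$role, p$value_type, p$compression, k,
                                 skip_bytes)
  }
  if (axes[[1]]$role == axes[[2]]$role)
    msio_stop("malformed",
              sprintf("both binary arrays claim the %s role", axes[[1]]$role))

  cfg <- if (axes[[1]]$role == "mz") list(mz = axes[[1]], intensity = axes[[2]])
         else list(mz = axes[[2]], intensity = axes[[1]])
  cfg$skip_bytes <- skip_bytes
  cfg
}

#' Parse the spectrum offset list of an indexed mzML file
#'
#' Reads the `<indexList>` at `index_offset` and returns the byte offsets of
#' all `<offset>` entries under the index named `"spectrum"`, in file order.
#'
#' @param s an `ms_stream`.
#' @param index_offset 0-based byte offset of `<indexList>` (from
#'   `read_tail_offset`).
#' @return numeric vector of 0-based byte offsets.
#' @noRd
parse_offset_list <- function(s, index_offset) {
  stream_seek(s, index_offset)
  hit <- find_tag(s, "indexList")
  if (is.null(hit) || hit$start_offset != index_offset)
    msio_stop("corrupt_index",
              sprintf("no <indexList> at byte %.0f of '%s'",
                      index_offset, s$path))
  block <- read_until(s, "</indexList>")
  if (is.null(block))
    msio_stop("malformed_index", sprintf("unterminated <indexList> in '%s'",
                                         s$path))

  im <- gregexpr("<index\\b[^>]*>", block, perl = TRUE, useBytes = TRUE)[[1]]
  spec_section <- NULL
  if (im[1] > 0) {
    starts <- as.integer(im)
    lens <- attr(im, "match.length")
    for (k in seq_along(starts)) {
      tag <- substr(block, starts[k], starts[k] + lens[k] - 1)
      nm <- read_attribute(tag, "name")
      if (!is.null(nm) && nm == "spectrum") {
        rest <- substr(block, starts[k] + lens[k], nchar(block, type = "bytes"))
        endm <- regexpr("</index>", rest, fixed = TRUE, useBytes = TRUE)
        spec_section <- if (endm > 0) substr(rest, 1, endm - 1) else rest
        break
      }
    }
  }
  if (is.null(spec_section))
    msio_stop("malformed_index",
              sprintf("'%s' has no spectrum index", s$path))

  om <- gregexpr("<offset\\b[^>]*>\\s*[0-9]+\\s*</offset>", spec_section,
                 perl = TRUE, useBytes = TRUE)[[1]]
  if (om[1] < 0) return(numeric(0))
  entries <- unlist(regmatches(spec_section, list(om)), use.names = FALSE)
  offsets <- as.numeric(sub(".*?>\\s*([0-9]+)\\s*<.*", "\\1", entries))
  bad <- which(offsets >= s$size)
  if (length(bad) > 0)
    msio_stop("corrupt_index",
              sprintf("offset entry %d (%.0f) lies past the end of '%s'",
                      bad[1], offsets[bad[1]], s$path))
  offsets
}

# Extract the base64 payload from a <binaryDataArray> element's content.
binary_payload <- function(content) {
  m <- regexpr("(?s)<binary\\b[^>]*>(.*?)</binary>", content,
               perl = TRUE, useBytes = TRUE)
  if (m > 0) {
    st <- attr(m, "capture.start")[1]
    ln <- attr(m, "capture.length")[1]
    return(substr(content, st, st + ln - 1))
  }
  if (grepl("<binary\\b[^>]*/>", content, perl = TRUE, useBytes = TRUE))
    return("")
  msio_stop("malformed", "binary data array has no <binary> element")
}

# Skip-byte margin: hints are approximate, so land slightly short of the
# target and let the forward scan close the gap.
MS_SKIP_MARGIN <- 64

read_one_spectrum <- function(s, offset, cfg, strict = FALSE) {
  stream_seek(s, offset + max(0, cfg$skip_bytes - MS_SKIP_MARGIN))
  bhit <- find_tag(s, "binaryDataArrayList", stop_tag = "/spectrum")
  if (is.null(bhit)) {
    # hint overshot (unusually short spectrum header): fall back to a scan
    # from the spectrum start
    stream_seek(s, offset)
    bhit <- find_tag(s, "binaryDataArrayList", stop_tag = "/spectrum")
  }
  if (is.null(bhit))
    msio_stop("malformed_spectrum", "no <binaryDataArrayList> found")

  vals <- vector("list", 2L)
  for (k in 1:2) {
    el <- read_element(s, "binaryDataArray", stop_tag = "/binaryDataArrayList")
    if (is.null(el))
      msio_stop("malformed_spectrum",
                sprintf("only %d of 2 binary arrays present", k - 1L))
    if (strict) {
      p <- parse_axis_params(el$content)
      want <- if (cfg$mz$position == k) cfg$mz else cfg$intensity
      if (!is.na(p$role) && p$role != want$role)
        msio_stop("malformed_spectrum",
                  sprintf("axis order changes mid-file (array %d is '%s', expected '%s')",
                          k, p$role, want$role))
      if (!is.na(p$value_type) && p$value_type != want$encoding$value_type)
        msio_stop("malformed_spectrum",
                  sprintf("value type changes mid-file in array %d", k))
      if (p$compression != want$encoding$compression)
        msio_stop("malformed_spectrum",
                  sprintf("compression changes mid-file in array %d", k))
    }
    enc <- if (cfg$mz$position == k) cfg$mz$encoding else cfg$intensity$encoding
    vals[[k]] <- decode_binary_array(binary_payload(el$content), enc)
  }

  mz <- vals[[cfg$mz$position]]
  intensity <- vals[[cfg$intensity$position]]
  if (length(mz) != length(intensity))
    msio_stop("malformed_spectrum",
              sprintf("m/z and intensity lengths differ (%d vs %d)",
                      length(mz), length(intensity)))
  list(mz = mz, intensity = intensity)
}

# Re-raise a reader error with the 1-based spectrum/pixel ordinal attached,
# preserving the specific condition subclass.
msio_rethrow_indexed <- function(e, what, i) {
  stop(structure(
    class = unique(c(class(e)[1], "msio_error", "error", "condition")),
    list(message = sprintf("%s %d: %s", what, i, conditionMessage(e)),
         call = NULL, index = i)
  ))
}

#' Decode all spectra of an indexed mzML file given its offset list
#'
#' Applies the same reading sequence to every spectrum: seek to its offset,
#' jump by the skip hint, locate `<binaryDataArrayList>`, decode the two
#' `<binary>` payloads and assign them to axes by position.
#'
#' @param s an `ms_stream`.
#' @param offsets from `parse_offset_list`.
#' @param cfg from `config_spec_dim`.
#' @param strict re-check the axis declaration of every spectrum.
#' @return an `ms_spectra` object.
#' @noRd
load_spectra <- function(s, offsets, cfg, strict = FALSE) {
  out <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    out[[i]] <- tryCatch(
      read_one_spectrum(s, offsets[i], cfg, strict),
      msio_error = function(e) msio_rethrow_indexed(e, "spectrum", i)
    )
  }
  new_ms_spectra(out, source = s$path)
}

new_ms_spectra <- function(spectra, source = NULL) {
  structure(spectra, class = "ms_spectra", source = source)
}

#' Read an indexed mzML file
#'
#' Loads every spectrum of an indexed mzML file (`<indexedmzML>` wrapper with
#' a byte-offset `<indexList>`).  The index is located through
#' `<indexListOffset>` in the file tail, the axis layout (array roles, float
#' widths, compression, order) is read once from the first spectrum, and
#' every spectrum is then decoded in offset-list order.  Non-indexed mzML
#' files are rejected.
#'
#' @param path an indexed mzML file.
#' @param strict re-check the axis declaration of every spectrum and fail on
#'   mid-file changes (off by default; mzML writers keep the layout constant
#'   within a file).
#' @return an `ms_spectra` object: a list of spectra, each a list with
#'   numeric `mz` and `intensity` vectors of equal length.
#' @examples
#' sp <- random_spectra(3, c(5, 10), seed = 1)
#' f <- tempfile(fileext = ".mzML")
#' write_mzml(sp, f)
#' spectra <- read_mzml(f)
#' length(spectra)
#' @seealso [read_imzml()], [bpc()], [tic()], [write_mzml()]
#' @export
read_mzml <- function(path, strict = FALSE) {
  index_offset <- read_tail_offset(path)
  s <- ms_stream(path)
  on.exit(close(s))
  offsets <- parse_offset_list(s, index_offset)
  if (length(offsets) == 0)
    return(new_ms_spectra(list(), source = path))

  stream_seek(s, offsets[1])
  first <- read_element(s, "spectrum")
  if (is.null(first))
    msio_stop("malformed", sprintf("no <spectrum> at first index offset of '%s'",
                                   path))
  first_text <- paste0(first$element_text, first$content, "</spectrum>")
  cfg <- config_spec_dim(first_text)
  load_spectra(s, offsets, cfg, strict = strict)
}

#' @export
print.ms_spectra <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<ms_spectra> %d spectr%s", n, if (n == 1) "um" else "a"))
  src <- attr(x, "source")
  if (!is.null(src)) cat(sprintf(" from '%s'", src))
  cat("\n")
  if (n > 0) {
    lens <- vapply(x, function(sp) length(sp$mz), numeric(1))
    cat(sprintf("  points per spectrum: min %d, median %d, max %d\n",
                min(lens), as.integer(stats::median(lens)), max(lens)))
  }
  invisible(x)
}

#' @export
`[.ms_spectra` <- function(x, i) {
  new_ms_spectra(unclass(x)[i], source = attr(x, "source"))
}
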