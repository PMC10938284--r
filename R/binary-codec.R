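# Encoding and decoding of mzML/imzML binary arrays: base64 text, optional
# zlib (RFC 1950) compression, little-endian IEEE-754 floats.

#' Describe the binary encoding of a data array
#'
#' mzML binary arrays are little-endian IEEE-754 floats, 32- or 64-bit,
#' optionally zlib-compressed before base64 encoding.  Integer-typed arrays
#' and lossy compressions (e.g. MS-Numpress) are not supported.
#'
#' @param value_type `"float64"` or `"float32"`.
#' @param compression `"none"` or `"zlib"`.
#' @return an object of class `ms_array_encoding` with fields `value_type`,
#'   `compression` and `width` (bytes per value).
#' @examples
#' array_encoding("float64", "zlib")
#' @export
array_encoding <- function(value_type = c("float64", "float32"),
                           compression = c("none", "zlib")) {
  value_type <- match.arg(value_type)
  compression <- match.arg(compression)
  structure(
    list(value_type = value_type, compression = compression,
         width = if (value_type == "float64") 8L else 4L),
    class = "ms_array_encoding"
  )
}

# Hard cap for inflated output so corrupt streams cannot exhaust memory.
MS_INFLATE_CAP <- 2^28

inflate_bytes <- function(bytes, cap = MS_INFLATE_CAP) {
  tryCatch(
    .Call(msio_inflate, bytes, as.numeric(cap)),
    error = function(e)
      msio_stop("inflate", paste0("zlib inflate failed: ", conditionMessage(e)))
  )
}

deflate_bytes <- function(bytes) {
  # memCompress(type = "gzip") emits an RFC-1950 zlib stream, which is what
  # mzML's "zlib compression" (MS:1000574) denotes.
  memCompress(bytes, type = "gzip")
}

float_to_bytes <- function(values, enc) {
  writeBin(as.double(values), raw(), size = enc$width, endian = "little")
}

bytes_to_float <- function(bytes, enc, what = "binary array") {
  if (length(bytes) %% enc$width != 0L)
    msio_stop("alignment",
              sprintf("%s has %d bytes, not a multiple of the %d-byte %s width",
                      what, length(bytes), enc$width, enc$value_type))
  readBin(bytes, "double", n = length(bytes) %/% enc$width,
          size = enc$width, endian = "little")
}

# Round through the 32-bit float representation (identity for float64).
float32_round <- function(values) {
  readBin(writeBin(as.double(values), raw(), size = 4L, endian = "little"),
          "double", n = length(values), size = 4L, endian = "little")
}

#' Decode a base64-encoded binary array
#'
#' Strips whitespace, base64-decodes, inflates when the encoding declares
#' zlib compression, and reinterprets the bytes as little-endian floats of
#' the declared width.
#'
#' @param text base64 character scalar (line wrapping tolerated); `""` yields
#'   an empty vector.
#' @param enc an [array_encoding()].
#' @param expected_count optional element count; a mismatch is an error.
#' @return a numeric vector.
#' @examples
#' enc <- array_encoding("float64", "zlib")
#' decode_binary_array(encode_binary_array(c(1, 2.5, -3), enc), enc)
#' @export
decode_binary_array <- function(text, enc, expected_count = NULL) {
  stopifnot(inherits(enc, "ms_array_encoding"))
  text <- gsub("[ \t\r\n]+", "", text)
  if (!nzchar(text)) {
    if (!is.null(expected_count) && expected_count != 0)
      msio_stop("length",
                sprintf("empty payload where %d values were expected",
                        expected_count))
    return(numeric(0))
  }
  bytes <- tryCatch(
    jsonlite::base64_dec(text),
    error = function(e)
      msio_stop("decode", paste0("invalid base64 payload: ",
                                 conditionMessage(e)))
  )
  if (enc$compression == "zlib") {
    cap <- if (is.null(expected_count)) MS_INFLATE_CAP
           else max(64, expected_count * enc$width + 64)
    bytes <- inflate_bytes(bytes, cap = cap)
  }
  values <- bytes_to_float(bytes, enc)
  if (!is.null(expected_count) && length(values) != expected_count)
    msio_stop("length",
              sprintf("decoded %d values where %d were expected",
                      length(values), expected_count))
  values
}

#' Encode a numeric vector as an mzML binary-array payload
#'
#' Exact inverse of [decode_binary_array()] for the same encoding; the
#' float32 path rounds values to 32-bit precision first.  Used by the
#' fixture writers.
#'
#' @param values finite numeric vector (empty allowed).
#' @param enc an [array_encoding()].
#' @return a base64 character scalar (no line wrapping).
#' @export
encode_binary_array <- function(values, enc) {
  stopifnot(inherits(enc, "ms_array_encoding"))
  if (length(values) == 0) return("")
  bytes <- float_to_bytes(values, enc)
  if (enc$compression == "zlib") bytes <- deflate_bytes(bytes)
  gsub("[\r\n]", "", jsonlite::base64_enc(bytes))
}

#' @export
print.ms_array_encoding <- function(x, ...) {
  cat(sprintf("<ms_array_encoding> %s, %s compression\n",
              x$value_type,
              if (x$compression == "none") "no" else x$compression))
  invisible(x)
}
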