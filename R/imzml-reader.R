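# Processed-mode imzML + ibd loading: axis encodings from
# <referenceableParamGroup>, image dimensions from <scanSettings> and
# <spectrumList count>, then one pass over the <spectrum> elements reading
# pixel coordinates and external-byte locators into the ibd stream.

# Imaging-MS controlled-vocabulary accessions used by the reader.
IMS_ACC <- list(
  POS_X      = "IMS:1000050",
  POS_Y      = "IMS:1000051",
  MAX_X      = "IMS:1000042",
  MAX_Y      = "IMS:1000043",
  EXT_OFFSET = "IMS:1000102",
  EXT_LENGTH = "IMS:1000103",
  EXT_BYTES  = "IMS:1000104",   # external encoded length (bytes)
  CONTINUOUS = "IMS:1000030",
  PROCESSED  = "IMS:1000031",
  UUID       = "IMS:1000080"
)

new_image_dims <- function(max_x, max_y, n_spectra) {
  structure(list(max_x = max_x, max_y = max_y, n_spectra = n_spectra),
            class = "ms_image_dims")
}

#' @export
print.ms_image_dims <- function(x, ...) {
  cat(sprintf("<ms_image_dims> %d x %d grid, %d stored spectra\n",
              x$max_x, x$max_y, x$n_spectra))
  invisible(x)
}

# Axis configuration from the <referenceableParamGroup> elements of the
# document header.  Returns mz/intensity axis configs plus a map from group
# id to role so spectra can associate locators through their group refs.
axes_config_img <- function(header_text) {
  m <- gregexpr("(?s)<referenceableParamGroup\\b[^>]*>.*?</referenceableParamGroup>",
                header_text, perl = TRUE, useBytes = TRUE)[[1]]
  if (m[1] < 0)
    msio_stop("malformed", "no <referenceableParamGroup> elements found")
  groups <- unlist(regmatches(header_text, list(m)), use.names = FALSE)

  cfg <- list(mz = NULL, intensity = NULL)
  roles <- list()
  for (g in groups) {
    open_tag <- regmatches(g, regexpr("<referenceableParamGroup\\b[^>]*>", g,
                                      perl = TRUE, useBytes = TRUE))
    id <- read_attribute(open_tag, "id")
    p <- parse_axis_params(g, sprintf("referenceableParamGroup '%s'",
                                      if (is.null(id)) "?" else id))
    if (is.na(p$role)) next   # instrument/scan groups without an array role
    if (is.na(p$value_type))
      msio_stop("malformed",
                sprintf("%s axis group lacks a float-width accession", p$role))
    if (!is.null(cfg[[p$role]]))
      msio_stop("malformed",
                sprintf("multiple referenceableParamGroups claim the %s role",
                        p$role))
    cfg[[p$role]] <- new_axis_config(p$role, p$value_type, p$compression,
                                     position = NA_integer_, skip_bytes = 0)
    if (!is.null(id)) roles[[id]] <- p$role
  }
  if (is.null(cfg$mz) || is.null(cfg$intensity))
    msio_stop("malformed",
              "referenceableParamGroups do not define both an m/z and an intensity axis")
  cfg$group_roles <- roles
  cfg
}

# ImageDims from the document header (scanSettings cvParams) and the
# <spectrumList> opening tag.
img_dimensions <- function(header_text, spectrum_list_tag) {
  max_x <- cvparam_value(header_text, IMS_ACC$MAX_X)
  max_y <- cvparam_value(header_text, IMS_ACC$MAX_Y)
  count <- read_attribute(spectrum_list_tag, "count")
  if (is.null(max_x) || is.null(max_y))
    msio_stop("malformed",
              "scan settings lack the maximal x/y pixel-count accessions")
  if (is.null(count))
    msio_stop("malformed", "<spectrumList> lacks a count attribute")
  dims <- new_image_dims(as.integer(max_x), as.integer(max_y),
                         as.integer(count))
  if (is.na(dims$max_x) || is.na(dims$max_y) || is.na(dims$n_spectra) ||
      dims$max_x < 1 || dims$max_y < 1 || dims$n_spectra < 1)
    msio_stop("malformed",
              sprintf("invalid image dimensions (max_x=%s, max_y=%s, count=%s)",
                      max_x, max_y, count))
  dims
}

# Locators (ibd offset / element count / encoded byte length) for both axes
# of one spectrum, from its <binaryDataArray> blocks.
pixel_locators <- function(blocks, cfg, what = "pixel") {
  loc <- list()
  for (b in blocks) {
    role <- NA_character_
    refm <- regexpr("<referenceableParamGroupRef\\b[^>]*>", b,
                    perl = TRUE, useBytes = TRUE)
    if (refm > 0) {
      ref <- read_attribute(regmatches(b, refm), "ref")
      if (!is.null(ref) && !is.null(cfg$group_roles[[ref]]))
        role <- cfg$group_roles[[ref]]
    }
    if (is.na(role)) {
      p <- parse_axis_params(b, what)
      role <- p$role
    }
    if (is.na(role))
      msio_stop("malformed_pixel",
                sprintf("%s binary array has no resolvable axis role", what))
    off <- cvparam_value(b, IMS_ACC$EXT_OFFSET)
    cnt <- cvparam_value(b, IMS_ACC$EXT_LENGTH)
    nbytes <- cvparam_value(b, IMS_ACC$EXT_BYTES)
    if (is.null(off) || is.null(cnt))
      msio_stop("malformed_pixel",
                sprintf("%s %s array lacks external offset/length accessions",
                        what, role))
    enc <- cfg[[role]]$encoding
    count <- as.numeric(cnt)
    loc[[role]] <- list(
      offset = as.numeric(off),
      count = count,
      enc_bytes = if (!is.null(nbytes)) as.numeric(nbytes)
                  else count * enc$width
    )
  }
  if (is.null(loc$mz) || is.null(loc$intensity))
    msio_stop("malformed_pixel",
              sprintf("%s does not provide locators for both axes", what))
  loc
}

#' Decode pixel coordinates and ibd locators from one spectrum element
#'
#' The x/y grid position comes from the IMS:1000050/IMS:1000051 cvParams of
#' the `<scan>` element; the per-axis ibd byte offset and element count come
#' from the IMS:1000102/IMS:1000103 cvParams, associated to an axis through
#' the enclosing `<referenceableParamGroupRef>` (or a direct array-role
#' accession).
#'
#' @param spectrum_text text of one complete `<spectrum>` element.
#' @param cfg from `axes_config_img`.
#' @return list with `x`, `y` and `locators` (per-axis offset/count/bytes).
#' @noRd
get_spectrum_attributes <- function(spectrum_text, cfg) {
  x <- cvparam_value(spectrum_text, IMS_ACC$POS_X)
  y <- cvparam_value(spectrum_text, IMS_ACC$POS_Y)
  if (is.null(x) || is.null(y))
    msio_stop("malformed_pixel",
              "spectrum lacks x/y pixel-position accessions")
  blocks <- binary_array_blocks(spectrum_text)
  if (length(blocks) < 2)
    msio_stop("malformed_pixel",
              sprintf("spectrum has %d binary arrays; expected 2",
                      length(blocks)))
  list(x = as.integer(x), y = as.integer(y),
       locators = pixel_locators(blocks, cfg))
}

# Scan forward for a cvParam with the given accession; NULL if the stop tag
# comes first.
find_accession_value <- function(s, accession, stop_tag) {
  repeat {
    hit <- find_tag(s, "cvParam", stop_tag = stop_tag)
    if (is.null(hit)) return(NULL)
    acc <- read_attribute(hit$element_text, "accession")
    if (!is.null(acc) && acc == accession)
      return(read_attribute(hit$element_text, "value"))
  }
}

# Skip-byte variant of get_spectrum_attributes: jump close to the known
# landmarks of the spectrum element (distances learned from the first
# spectrum, minus a safety margin) instead of scanning every byte.
parse_pixel_skip <- function(s, spec_hit, hints, cfg) {
  s0 <- spec_hit$start_offset
  jump <- s0 + max(0, hints$to_scan - MS_SKIP_MARGIN)
  if (jump > s$pos) stream_seek(s, jump)
  x <- find_accession_value(s, IMS_ACC$POS_X, stop_tag = "/spectrum")
  y <- find_accession_value(s, IMS_ACC$POS_Y, stop_tag = "/spectrum")
  if (is.null(x) || is.null(y))
    msio_stop("malformed_pixel",
              "spectrum lacks x/y pixel-position accessions")
  jump <- s0 + max(0, hints$to_bdal - MS_SKIP_MARGIN)
  if (jump > s$pos) stream_seek(s, jump)
  blocks <- character(2)
  for (k in 1:2) {
    el <- read_element(s, "binaryDataArray", stop_tag = "/spectrum")
    if (is.null(el))
      msio_stop("malformed_pixel",
                sprintf("only %d of 2 binary arrays present", k - 1L))
    blocks[k] <- paste0(el$element_text, el$content, "</binaryDataArray>")
  }
  list(x = as.integer(x), y = as.integer(y),
       locators = pixel_locators(blocks, cfg))
}

# Landmark byte distances within a spectrum element, learned from its text.
skip_hints <- function(spectrum_text) {
  dist_to <- function(lit) {
    m <- regexpr(lit, spectrum_text, fixed = TRUE, useBytes = TRUE)
    if (m < 0) 0 else as.numeric(m) - 1
  }
  list(to_scan = dist_to("<scan"), to_bdal = dist_to("<binaryDataArrayList"))
}

read_ibd_array <- function(ibd_con, ibd_size, loc, enc, role) {
  if (loc$offset + loc$enc_bytes > ibd_size)
    msio_stop("corrupt_locator",
              sprintf("%s locator [offset %.0f + %.0f bytes] lies outside the ibd file (%.0f bytes)",
                      role, loc$offset, loc$enc_bytes, ibd_size))
  if (loc$enc_bytes == 0) return(numeric(0))
  seek(ibd_con, where = loc$offset, origin = "start")
  bytes <- readBin(ibd_con, "raw", n = loc$enc_bytes)
  if (length(bytes) < loc$enc_bytes)
    msio_stop("corrupt_locator",
              sprintf("short read for %s array (wanted %.0f bytes, got %d)",
                      role, loc$enc_bytes, length(bytes)))
  if (enc$compression == "zlib")
    bytes <- inflate_bytes(bytes, cap = max(64, loc$count * enc$width + 64))
  values <- bytes_to_float(bytes, enc, what = paste(role, "array"))
  if (length(values) != loc$count)
    msio_stop("length",
              sprintf("%s array decoded to %d values where %.0f were declared",
                      role, length(values), loc$count))
  values
}

#' Read the pixel spectra of a processed-mode imzML document
#'
#' One pass over the `n_spectra` `<spectrum>` elements.  With
#' `method = "skip"` the scanner jumps by landmark byte distances learned
#' from the first spectrum (with a safety margin and post-jump tag
#' verification); with `method = "naive"` every element is read in full and
#' parsed from its text.  Both methods return identical pixel sequences, in
#' file order.
#'
#' @param s an `ms_stream` positioned before the first `<spectrum>`.
#' @param ibd_con open binary connection to the ibd file.
#' @param ibd_size ibd file size in bytes.
#' @param dims an `ms_image_dims`.
#' @param cfg from `axes_config_img`.
#' @param method `"skip"` or `"naive"`.
#' @return list of pixels, each a list with `x`, `y`, `mz`, `intensity`.
#' @noRd
load_img_data <- function(s, ibd_con, ibd_size, dims, cfg,
                          method = c("skip", "naive")) {
  method <- match.arg(method)
  n <- dims$n_spectra
  out <- vector("list", n)
  hints <- NULL
  for (i in seq_len(n)) {
    out[[i]] <- tryCatch({
      hit <- find_tag(s, "spectrum", stop_tag = "/spectrumList")
      if (is.null(hit))
        msio_stop("malformed",
                  sprintf("file declares %d spectra but only %d were found",
                          n, i - 1L))
      if (method == "naive" || is.null(hints)) {
        content <- read_until(s, "</spectrum>")
        if (is.null(content))
          msio_stop("malformed_pixel", "unterminated <spectrum> element")
        el_text <- paste0(hit$element_text, content, "</spectrum>")
        if (is.null(hints)) hints <- skip_hints(el_text)
        attrs <- get_spectrum_attributes(el_text, cfg)
      } else {
        attrs <- parse_pixel_skip(s, hit, hints, cfg)
      }
      list(
        x = attrs$x, y = attrs$y,
        mz = read_ibd_array(ibd_con, ibd_size, attrs$locators$mz,
                            cfg$mz$encoding, "m/z"),
        intensity = read_ibd_array(ibd_con, ibd_size, attrs$locators$intensity,
                                   cfg$intensity$encoding, "intensity")
      )
    }, msio_error = function(e) msio_rethrow_indexed(e, "pixel", i))
  }
  out
}

#' Read a processed-mode imzML / ibd pair
#'
#' Loads a mass spectrometry imaging data set: the `.imzML` XML document
#' describes per-pixel grid coordinates and byte locators into the sibling
#' `.ibd` binary file, which holds each pixel's m/z and intensity vectors as
#' raw little-endian floats (no base64).  Only the "processed" storage mode
#' (per-pixel m/z axes) is supported; continuous-mode documents are
#' rejected.
#'
#' The ibd's leading 16-byte UUID is skipped; when the document carries a
#' UUID cvParam a mismatch is reported as a warning, not an error.
#'
#' @param path the `.imzML` file; the ibd file must sit next to it with the
#'   same basename.
#' @param method spectrum-scan strategy, `"skip"` (landmark byte-distance
#'   jumps learned from the first spectrum) or `"naive"` (full text scan).
#'   Both yield identical results.
#' @return an object of class `ms_pixels`: a list with `pixels` (file-order
#'   list of per-pixel `x`, `y`, `mz`, `intensity`) and `dims` (grid size and
#'   stored-spectrum count; the count may be smaller than the grid product
#'   when pixels are missing).
#' @examples
#' px <- random_pixels(4, 3, len_range = c(4, 8), seed = 1)
#' base <- tempfile()
#' write_imzml(px, dims = c(4, 3), base)
#' img <- read_imzml(paste0(base, ".imzML"))
#' img$dims
#' @seealso [get_slice()], [triq()], [save_bitmap()], [write_imzml()]
#' @export
read_imzml <- function(path, method = c("skip", "naive")) {
  method <- match.arg(method)
  ibd_path <- paste0(tools::file_path_sans_ext(path), ".ibd")
  if (!file.exists(path))
    msio_stop("io", sprintf("file not found: '%s'", path))
  if (!file.exists(ibd_path))
    msio_stop("paired_file",
              sprintf("'%s' has no sibling ibd file ('%s' not found)",
                      path, ibd_path))

  s <- ms_stream(path)
  on.exit(close(s), add = TRUE)
  header_text <- read_until(s, "<spectrumList", consume = FALSE)
  if (is.null(header_text))
    msio_stop("malformed", sprintf("'%s' has no <spectrumList>", path))

  if (grepl(IMS_ACC$CONTINUOUS, header_text, fixed = TRUE, useBytes = TRUE))
    msio_stop("unsupported_mode",
              sprintf("'%s' declares continuous storage mode; only processed-mode imzML is supported",
                      path))

  cfg <- axes_config_img(header_text)
  sl_hit <- find_tag(s, "spectrumList")
  dims <- img_dimensions(header_text, sl_hit$element_text)

  ibd_size <- file.size(ibd_path)
  ibd_con <- file(ibd_path, "rb")
  on.exit(close(ibd_con), add = TRUE)

  doc_uuid <- cvparam_value(header_text, IMS_ACC$UUID)
  if (!is.null(doc_uuid) && ibd_size >= 16) {
    ibd_uuid <- paste(sprintf("%02x", as.integer(readBin(ibd_con, "raw", 16))),
                      collapse = "")
    doc_hex <- tolower(gsub("[^0-9a-fA-F]", "", doc_uuid))
    if (nzchar(doc_hex) && doc_hex != ibd_uuid)
      warning(sprintf("ibd UUID (%s) does not match the document UUID (%s)",
                      ibd_uuid, doc_hex), call. = FALSE)
  }

  pixels <- load_img_data(s, ibd_con, ibd_size, dims, cfg, method)
  structure(list(pixels = pixels, dims = dims, path = path),
            class = "ms_pixels")
}

#' @export
print.ms_pixels <- function(x, ...) {
  cat(sprintf("<ms_pixels> %d pixel spectra on a %d x %d grid ('%s')\n",
              length(x$pixels), x$dims$max_x, x$dims$max_y,
              basename(x$path)))
  invisible(x)
}
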