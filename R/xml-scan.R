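# Forward-only byte scanner over mzML/imzML documents.
#
# mzML structural markup is ASCII, so tags are located by byte-oriented
# substring search on buffered windows of the file; no document tree is ever
# built.  All offsets are 0-based byte offsets, matching the offsets stored
# in the <indexList> of an indexed mzML file.

MS_CHUNK <- 65536L

#' Open a seekable byte stream over a file
#'
#' Creates the scanner state used by [find_tag()] and friends: an open
#' read-only connection, a logical read position and one cached buffer window
#' so that sequential scans do not re-read the file byte by byte.
#'
#' @param path file to open.
#' @param chunk_size buffer window size in bytes.
#' @return an environment of class `ms_stream`.
#' @noRd
ms_stream <- function(path, chunk_size = MS_CHUNK) {
  if (!file.exists(path))
    msio_stop("io", sprintf("file not found: '%s'", path))
  s <- new.env(parent = emptyenv())
  s$path <- path
  s$size <- file.size(path)
  s$con <- file(path, "rb")
  s$pos <- 0
  s$buf_start <- 0
  s$buf_txt <- ""
  s$buf_len <- 0
  s$chunk <- as.integer(chunk_size)
  class(s) <- "ms_stream"
  s
}

#' @noRd
close.ms_stream <- function(con, ...) close(con$con)

stream_seek <- function(s, pos) {
  s$pos <- pos
  invisible(s)
}

# Make sure the cached window covers [from, from + len) (clipped at EOF) and
# return list(txt, start).  Reads at least one chunk so sequential callers
# hit the cache.
stream_window <- function(s, from, len) {
  if (from >= s$size) return(NULL)
  to <- min(from + len, s$size)
  if (from < s$buf_start || to > s$buf_start + s$buf_len) {
    n <- min(max(to - from, s$chunk), s$size - from)
    seek(s$con, where = from, origin = "start")
    raw <- readBin(s$con, "raw", n = n)
    s$buf_start <- from
    s$buf_len <- length(raw)
    s$buf_txt <- rawToChar(raw)
  }
  list(txt = s$buf_txt, start = s$buf_start, len = s$buf_len)
}

# Exact byte span [from, to) as a character scalar.
read_span <- function(s, from, to) {
  if (to <= from) return("")
  if (from >= s$buf_start && to <= s$buf_start + s$buf_len)
    return(substr(s$buf_txt, from - s$buf_start + 1, to - s$buf_start))
  seek(s$con, where = from, origin = "start")
  rawToChar(readBin(s$con, "raw", n = to - from))
}

# First occurrence (0-based offset) of any of `needles` at or after `from`;
# returns list(off = NA) when none is found before EOF.
locate_any <- function(s, from, needles) {
  max_len <- max(nchar(needles, type = "bytes"))
  overlap <- max_len - 1L
  pos <- from
  while (pos < s$size) {
    w <- stream_window(s, pos, s$chunk)
    seg_end <- w$start + w$len
    seg <- substr(w$txt, pos - w$start + 1, w$len)
    best_off <- NA_real_
    best_which <- NA_integer_
    for (k in seq_along(needles)) {
      m <- regexpr(needles[k], seg, fixed = TRUE, useBytes = TRUE)
      if (m > 0) {
        off <- pos + (as.numeric(m) - 1)
        if (is.na(best_off) || off < best_off) {
          best_off <- off
          best_which <- k
        }
      }
    }
    if (!is.na(best_off))
      return(list(off = best_off, which = best_which,
                  len = nchar(needles[best_which], type = "bytes")))
    if (seg_end >= s$size) break
    pos <- seg_end - overlap
  }
  list(off = NA_real_, which = NA_integer_, len = 0L)
}

locate_literal <- function(s, from, literal) {
  locate_any(s, from, literal)$off
}

# Characters that may legally follow a tag name inside its opening tag.
is_tag_boundary <- function(ch) {
  nzchar(ch) && ch %in% c(" ", "\t", "\r", "\n", ">", "/")
}

#' Locate the next occurrence of an XML tag
#'
#' Scans forward from the stream's current position for `<tag_name` followed
#' by whitespace, `>` or `/`.  When `stop_tag` is given and occurs first, the
#' search stops there and `NULL` is returned (the position is left at the
#' stop tag).  On a match the stream position is advanced past the closing
#' `>` of the opening tag.
#'
#' @param s an `ms_stream`.
#' @param tag_name tag to find (without `<`); closing tags can be matched by
#'   passing e.g. `"/spectrum"`.
#' @param stop_tag optional tag that aborts the search.
#' @return `NULL`, or a list with `tag_name`, `start_offset` (0-based byte
#'   offset of `<`), `element_text` (the opening tag through its `>`) and
#'   `self_closing`.
#' @noRd
find_tag <- function(s, tag_name, stop_tag = NULL) {
  stopifnot(nzchar(tag_name))
  needles <- paste0("<", c(tag_name, stop_tag))
  pos <- s$pos
  repeat {
    hit <- locate_any(s, pos, needles)
    if (is.na(hit$off)) return(NULL)
    nxt <- read_span(s, hit$off + hit$len, hit$off + hit$len + 1)
    if (!is_tag_boundary(nxt)) {
      pos <- hit$off + 1           # prefix of a longer tag name; keep going
      next
    }
    if (hit$which == 2L) {         # stop tag reached first
      stream_seek(s, hit$off)
      return(NULL)
    }
    gt <- locate_literal(s, hit$off, ">")
    if (is.na(gt))
      msio_stop("malformed",
                sprintf("unterminated <%s> tag at byte %.0f in '%s'",
                        tag_name, hit$off, s$path))
    el <- read_span(s, hit$off, gt + 1)
    stream_seek(s, gt + 1)
    return(list(tag_name = tag_name, start_offset = hit$off,
                element_text = el,
                self_closing = endsWith(el, "/>")))
  }
}

# Text between the current position and `literal`; position advances past
# the literal (or to its start when consume = FALSE).  NULL when absent.
read_until <- function(s, literal, consume = TRUE) {
  off <- locate_literal(s, s$pos, literal)
  if (is.na(off)) return(NULL)
  out <- read_span(s, s$pos, off)
  stream_seek(s, if (consume) off + nchar(literal, type = "bytes") else off)
  out
}

# Opening tag + content + closing tag for the next `tag_name` element, or
# NULL.  `content` is "" for self-closing elements.
read_element <- function(s, tag_name, stop_tag = NULL) {
  hit <- find_tag(s, tag_name, stop_tag)
  if (is.null(hit)) return(NULL)
  if (hit$self_closing) {
    hit$content <- ""
    return(hit)
  }
  content <- read_until(s, paste0("</", tag_name, ">"))
  if (is.null(content))
    msio_stop("malformed",
              sprintf("missing </%s> for element at byte %.0f in '%s'",
                      tag_name, hit$start_offset, s$path))
  hit$content <- content
  hit
}

#' Extract an attribute value from an opening tag
#'
#' Exact string between the quotes of `attr_name="..."` (or single quotes);
#' no type coercion.  Attribute order in the tag is irrelevant and partial
#' name matches (e.g. `Length` inside `encodedLength`) do not count.
#'
#' @param element_text a single opening tag.
#' @param attr_name attribute name.
#' @return the value string, or `NULL` when the attribute is absent.
#' @noRd
read_attribute <- function(element_text, attr_name) {
  pat <- paste0("(?<![\\w:.-])", attr_name,
                "\\s*=\\s*(?:\"([^\"]*)\"|'([^']*)')")
  m <- regexpr(pat, element_text, perl = TRUE, useBytes = TRUE)
  if (m < 0) return(NULL)
  st1 <- attr(m, "capture.start")[1]; ln1 <- attr(m, "capture.length")[1]
  st2 <- attr(m, "capture.start")[2]; ln2 <- attr(m, "capture.length")[2]
  val <- if (st1 > 0) substr(element_text, st1, st1 + ln1 - 1)
         else substr(element_text, st2, st2 + ln2 - 1)
  if (!all(validUTF8(val)))
    msio_stop("decode", sprintf("attribute '%s' is not valid UTF-8", attr_name))
  val
}

# All cvParam opening tags inside a text fragment, as a character vector.
extract_cvparams <- function(text) {
  m <- gregexpr("<cvParam\\b[^>]*>", text, perl = TRUE, useBytes = TRUE)[[1]]
  if (m[1] < 0) return(character(0))
  unlist(regmatches(text, list(m)), use.names = FALSE)
}

# value="..." of the first cvParam in `text` carrying `accession`.
cvparam_value <- function(text, accession) {
  for (tag in extract_cvparams(text)) {
    acc <- read_attribute(tag, "accession")
    if (!is.null(acc) && acc == accession) return(read_attribute(tag, "value"))
  }
  NULL
}

#' Read the spectrum-index offset from the tail of an indexed mzML file
#'
#' Scans only the final `window` bytes of the file for
#' `<indexListOffset>`; the recorded offset must point at an `<indexList>`
#' element.
#'
#' @param path an mzML file.
#' @param window tail window size in bytes.
#' @return the 0-based byte offset of `<indexList>`.
#' @noRd
read_tail_offset <- function(path, window = 1024L) {
  if (!file.exists(path))
    msio_stop("io", sprintf("file not found: '%s'", path))
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  from <- max(0, size - window)
  seek(con, where = from, origin = "start")
  tail_txt <- rawToChar(readBin(con, "raw", n = size - from))
  m <- regexpr("<indexListOffset>\\s*([0-9]+)\\s*</indexListOffset>",
               tail_txt, perl = TRUE, useBytes = TRUE)
  if (m < 0) {
    if (grepl("<indexListOffset", tail_txt, fixed = TRUE, useBytes = TRUE))
      msio_stop("corrupt_index",
                sprintf("non-numeric <indexListOffset> in '%s'", path))
    msio_stop("not_indexed",
              sprintf("'%s' has no <indexListOffset> in its final %d bytes; an indexed mzML file (<indexedmzML>) is required",
                      path, window))
  }
  st <- attr(m, "capture.start")[1]
  ln <- attr(m, "capture.length")[1]
  off <- as.numeric(substr(tail_txt, st, st + ln - 1))
  if (!is.finite(off) || off >= size)
    msio_stop("corrupt_index",
              sprintf("<indexListOffset> %.0f is outside '%s' (size %.0f)",
                      off, path, size))
  seek(con, where = off, origin = "start")
  probe <- rawToChar(readBin(con, "raw", n = min(32, size - off)))
  if (!grepl("^\\s*<indexList[\\s>]", probe, perl = TRUE, useBytes = TRUE))
    msio_stop("corrupt_index",
              sprintf("<indexListOffset> of '%s' does not point at <indexList>",
                      path))
  off
}
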