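# 8-bit indexed-color BMP export: BITMAPFILEHEADER + BITMAPINFOHEADER +
# 256-entry BGRA color table + bottom-up pixel rows padded to 4 bytes.

write_u16 <- function(con, x) {
  writeBin(as.integer(x), con, size = 2, endian = "little")
}
write_u32 <- function(con, x) {
  writeBin(as.integer(x), con, size = 4, endian = "little")
}

#' Save a quantized image as an 8-bit indexed BMP
#'
#' Writes a Windows BMP (BITMAPINFOHEADER, 256-entry BGRA color table,
#' bottom-up rows padded to 4-byte multiples) where each pixel's palette
#' index is its quantization level.  Row 1 of the level matrix (y = 1) is
#' the top row of the exported image; the bottom-up storage order of the BMP
#' format is handled internally.
#'
#' @param levels an `ms_triq` object from [triq()], or an integer matrix of
#'   palette indices in `[0, 255]`.
#' @param path output file.
#' @param palette a 256 x 3 RGB matrix (0-255 channels); defaults to
#'   [viridis_palette()].
#' @return `path`, invisibly.
#' @examples
#' q <- triq(matrix(runif(12), 3, 4), L = 256, p = 0.95)
#' f <- tempfile(fileext = ".bmp")
#' save_bitmap(q, f)
#' @export
save_bitmap <- function(levels, path, palette = viridis_palette()) {
  if (inherits(levels, "ms_triq")) {
    if (levels$L > 256)
      msio_stop("unsupported_depth",
                sprintf("%d levels exceed the 256 entries of an 8-bit palette",
                        levels$L))
    levels <- levels$levels
  }
  if (!is.matrix(levels))
    msio_stop("parameter", "'levels' must be a matrix or an ms_triq object")
  lv <- as.integer(levels)
  if (anyNA(lv) || any(lv < 0L) || any(lv > 255L))
    msio_stop("unsupported_depth",
              "palette indices must lie in [0, 255] for 8-bit export")
  palette <- as.matrix(palette)
  if (nrow(palette) != 256 || ncol(palette) != 3)
    msio_stop("parameter", "'palette' must be a 256 x 3 RGB matrix")

  height <- nrow(levels)
  width <- ncol(levels)
  stride <- (width + 3L) %/% 4L * 4L
  data_size <- stride * height
  header_size <- 14L + 40L + 256L * 4L

  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e)
                    msio_stop("io", sprintf("cannot write '%s'", path)))
  on.exit(close(con))

  # BITMAPFILEHEADER
  writeBin(charToRaw("BM"), con)
  write_u32(con, header_size + data_size)
  write_u16(con, 0L); write_u16(con, 0L)
  write_u32(con, header_size)
  # BITMAPINFOHEADER
  write_u32(con, 40L)
  write_u32(con, width)
  write_u32(con, height)           # positive height: bottom-up rows
  write_u16(con, 1L)               # planes
  write_u16(con, 8L)               # bits per pixel
  write_u32(con, 0L)               # BI_RGB, uncompressed
  write_u32(con, data_size)
  write_u32(con, 2835L); write_u32(con, 2835L)   # 72 dpi
  write_u32(con, 256L)             # palette entries used
  write_u32(con, 0L)
  # color table: B, G, R, reserved
  tab <- rbind(as.integer(palette[, 3]), as.integer(palette[, 2]),
               as.integer(palette[, 1]), 0L)
  writeBin(as.raw(as.vector(tab)), con)
  # pixel rows, bottom image row first, each padded to the stride
  pad <- as.raw(rep(0L, stride - width))
  m <- matrix(lv, nrow = height)
  for (r in rev(seq_len(height)))
    writeBin(c(as.raw(m[r, ]), pad), con)

  invisible(path)
}
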