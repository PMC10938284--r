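# Independent oracles used across the suite.  These deliberately share no
# code with the package: the BMP decoder parses bytes straight off the BMP
# specification, and the TrIQ oracle evaluates the quantization definition
# by direct enumeration.

# Direct evaluation of the TrIQ definition: T is the smallest observed value
# whose empirical cumulative probability reaches p; values are clipped at T
# and floor-quantized to L levels.
triq_brute <- function(values, L, p) {
  v <- as.vector(values)
  n <- length(v)
  v_min <- min(v)
  cand <- sort(unique(v))
  ok <- vapply(cand, function(t) sum(v <= t) / n >= p, logical(1))
  threshold <- cand[which(ok)[1]]
  lev <- vapply(v, function(x) {
    if (threshold == v_min) return(0)
    min(floor((min(x, threshold) - v_min) / (threshold - v_min) * (L - 1)),
        L - 1)
  }, numeric(1))
  list(threshold = threshold,
       levels = matrix(as.integer(lev), nrow(values), ncol(values)))
}

# Minimal independent reader for 8-bit indexed BMP files (BITMAPINFOHEADER,
# BGRA color table, bottom-up padded rows).
read_bmp_indexed <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(i) sum(as.integer(raw[i:(i + 1)]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i:(i + 3)]) * c(1, 256, 65536, 16777216))
  stopifnot(rawToChar(raw[1:2]) == "BM")
  data_off <- u32(11)
  hdr_size <- u32(15)
  width <- u32(19)
  height <- u32(23)
  bpp <- u16(29)
  compression <- u32(31)
  stopifnot(hdr_size == 40, bpp == 8, compression == 0)
  pal_off <- 14 + hdr_size
  palette <- matrix(0L, 256, 3,
                    dimnames = list(NULL, c("red", "green", "blue")))
  for (k in 1:256) {
    b <- pal_off + (k - 1) * 4
    palette[k, ] <- as.integer(raw[c(b + 3, b + 2, b + 1)])
  }
  stride <- (width + 3) %/% 4 * 4
  levels <- matrix(0L, height, width)
  for (r in seq_len(height)) {
    row_start <- data_off + (height - r) * stride
    levels[r, ] <- as.integer(raw[(row_start + 1):(row_start + width)])
  }
  list(width = width, height = height, palette = palette, levels = levels,
       declared_size = u32(3), file_size = as.numeric(length(raw)))
}

# Strip the ms_spectra class so spectra lists compare structurally.
plain_spectra <- function(x) {
  lapply(unclass(x), function(sp) list(mz = sp$mz, intensity = sp$intensity))
}

# Expected spectra after a write/read cycle at the given per-axis value
# types (float32 axes round through 32-bit precision).
expected_after_roundtrip <- function(spectra, value_type) {
  vt <- rep_len(value_type, 2)
  lapply(unclass(spectra), function(sp) list(
    mz = if (vt[1] == "float32") msio:::float32_round(sp$mz) else sp$mz,
    intensity = if (vt[2] == "float32") msio:::float32_round(sp$intensity)
                else sp$intensity
  ))
}

tmp_mzml <- function() tempfile(fileext = ".mzML")
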