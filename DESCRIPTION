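Package: msio
Title: Reading and Visualizing Mass Spectrometry Data in mzML and imzML Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight reader for HUPO-PSI mass spectrometry data: indexed
    mzML files are loaded through their byte-offset spectrum index, and
    processed-mode imzML/ibd pairs are loaded into per-pixel spectra. Binary
    arrays (base64, optionally zlib-compressed, little-endian float32/float64)
    are decoded with a bounded inflate routine. Downstream operations cover
    base-peak and total-ion chromatograms, m/z-window ion-image slicing,
    Threshold Intensity Quantization (TrIQ) contrast optimization, and export
    of indexed-palette bitmaps with the viridis color map. A deterministic
    fixture generator writes valid synthetic mzML and imzML/ibd files (plus
    corrupted variants) so every reader path is testable offline, and a small
    command-line tool exposes the demonstrated workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    viridisLite,
    withr,
    optparse,
    tools,
    grDevices,
    stats
Suggests:
    testthat (>= 3.0.0),
    xml2,
    mzR
Config/testthat/edition: 3
NeedsCompilation: yes
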