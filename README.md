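# msio — reading and visualizing mzML / imzML mass spectrometry data

`msio` is an R toolkit for the two HUPO-PSI community formats of mass
spectrometry: **mzML** (spectra from LC-MS, direct-infusion and ambient
ionization experiments) and **imzML** (mass spectrometry imaging, MSI).
It is aimed at people who build custom MS processing workflows — for
instance around ambient ionization sources or MSI experiments — and need
fast, dependency-light access to raw spectra rather than a full proteomics
pipeline.

The package reads the files with its own lightweight forward scanner
instead of a general XML DOM parser:

* **mzML** — indexed files (`<indexedmzML>`) are opened through their
  byte-offset spectrum index: the `<indexListOffset>` element is found in
  the file tail, the `<indexList>` gives one byte offset per spectrum, and
  the axis layout (which binary array is m/z vs intensity via the
  controlled-vocabulary accessions `MS:1000514` / `MS:1000515`, the float
  width, the compression, the array order) is determined **once** from the
  first spectrum and reused for all others. Binary payloads are base64,
  optionally zlib-compressed, little-endian IEEE-754 floats; inflation goes
  through a bounded C routine so truncated streams fail cleanly instead of
  exhausting memory.
* **imzML** — "processed"-mode XML/ibd pairs: per-pixel grid coordinates
  (`IMS:1000050/51`) and external byte locators (`IMS:1000102/03/04`) are
  parsed from the XML, and each pixel's m/z and intensity vectors are read
  straight from the binary ibd file. The scan loop can jump by approximate
  byte distances learned from the first spectrum (the *skip-byte*
  strategy) with a safety margin and post-jump verification; a naive
  full-scan mode exists and returns identical results.

On top of the readers:

* `bpc()` / `tic()` — base-peak and total-ion chromatograms,
* `get_slice()` — an ion image: per pixel, the summed (or maximum)
  intensity inside a closed m/z window `[mz − tol, mz + tol]`,
* `triq()` — **Threshold Intensity Quantization**: contrast optimization
  that caps intensities at the smallest observed value `T` whose empirical
  cumulative probability reaches `p`, then quantizes linearly to `L`
  levels, `level(v) = ⌊(min(v,T) − v_min)/(T − v_min) · (L−1)⌋`, so a few
  hot pixels no longer compress the dynamic range of the rest of the image,
* `save_bitmap()` + `viridis_palette()` — export as an 8-bit
  indexed-color BMP with the perceptually uniform viridis map,
* `write_mzml()` / `write_imzml()` / `random_spectra()` /
  `random_pixels()` / `corrupt_fixture()` — a deterministic synthetic-data
  generator that writes valid (and deliberately broken) files with exact
  ground truth, so the whole reader stack is testable offline.

A small command-line tool is installed under `exec/msio`:

```
msio info FILE
msio bpc FILE -o out.csv
msio image FILE --mz 885.55 --tol 0.005 [--levels 256] [--prob 0.95] [--agg sum|max] -o out.bmp
```

## Worked example

```r
library(msio)

## spectra: write a small synthetic indexed mzML file and read it back
sp <- random_spectra(5, c(20, 60), seed = 10)
f  <- file.path(tempdir(), "demo.mzML")
write_mzml(sp, f, compression = "zlib")
spectra <- read_mzml(f)
spectra
#> <ms_spectra> 5 spectra from '/tmp/.../demo.mzML'
#>   points per spectrum: min 20, median 28, max 59
round(bpc(spectra), 1)   # per-scan base-peak intensity
#> [1] 95465.4 98373.2 99863.4 99780.2 97692.6
round(tic(spectra), 1)   # per-scan total ion current
#> [1] 1260986 2421020 1391880 3146482 1162529

## imaging: a 6 x 5 pixel grid, ion image, TrIQ, bitmap
px <- random_pixels(6, 5, len_range = c(20, 40), seed = 11)
base <- file.path(tempdir(), "demo_img")
write_imzml(px, c(6, 5), base)
img <- read_imzml(paste0(base, ".imzML"))
img
#> <ms_pixels> 30 pixel spectra on a 6 x 5 grid ('demo_img.imzML')

slice <- get_slice(img, target_mz = 550, tol = 50)
slice
#> <ms_ion_image> 6 x 5, m/z 550.0000 +/- 50.0000, max 3.016e+05
q <- triq(slice, L = 256, p = 0.95)
q
#> <ms_triq> 6 x 5, 256 levels, p = 0.95, threshold = 292022
save_bitmap(q, file.path(tempdir(), "TrIQ.bmp"))   # viridis by default
```

The TrIQ threshold of 292022 means 95% of the image's window intensities
lie at or below that value; everything above it is clipped into the top
palette level instead of stretching the color scale.

Real instrument data works the same way: `read_mzml("run.mzML")` or
`read_imzml("tissue.imzML")` on files converted with msconvert or exported
by imaging platforms (processed mode).

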