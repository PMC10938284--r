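---
title: "msio: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msio: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msio)
```

This vignette explains how `msio` reads mzML and imzML mass spectrometry
data, which design choices were genuinely open and how they were settled,
what the synthetic fixture generator does and does not emulate, and the
numerical details a careful user should know.

## Why a dedicated scanner instead of an XML parser

mzML files routinely reach hundreds of megabytes to gigabytes, and almost
all of that volume is base64 payload inside `<binary>` elements.  Building
a DOM for such a document costs far more memory and time than the
information extracted from it justifies.  `msio` therefore uses a
forward-only byte scanner: it searches buffered windows of the file for
`<tagname` followed by whitespace, `/` or `>`, pulls attribute values out
of the opening tag with a small regular expression, and never materializes
a tree.  Three properties make this safe in practice:

* mzML structural markup is ASCII (element and attribute names, CV
  accessions), so byte-oriented matching is exact; attribute *values* are
  decoded as UTF-8 and validated on extraction.
* The base64 alphabet contains no `<`, so payload bytes can never be
  mistaken for markup while scanning forward.
* Matching requires a tag-name boundary character, so `<spectrum` never
  matches inside `<spectrumList`.

The scanner does **not** handle XML comments or CDATA sections containing
tag-like text, namespace-prefixed element names, DTDs, or entity
references.  None of the mainstream mzML/imzML writers emit those inside
the elements `msio` visits; behavior on such input is unspecified, and the
fixture generator never produces it.

Buffered windows are 64 KiB with an overlap of the needle length, so tags
spanning a window boundary are still found.  Tail scanning for
`<indexListOffset>` reads only the final 1024 bytes of the file
(configurable): that window comfortably covers the index-offset element,
checksum and closing tags in observed writers, and guarantees the "find
the index" step costs O(1) regardless of file size.

## mzML loading

`read_mzml()` requires an *indexed* mzML file and fails with a clear
`msio_not_indexed_error` otherwise.  Indexing is optional in the standard
but emitted by essentially every converter, and using it avoids scanning
gigabytes of payload just to enumerate spectra.  A full-scan fallback for
non-indexed files is a documented extension point, deliberately not
implemented.

The loading sequence is:

1. `<indexListOffset>` from the file tail; the offset must point at an
   `<indexList>` element or the index is reported corrupt.
2. The spectrum offset list: all `<offset>` entries under
   `<index name="spectrum">`, in file order.  Offsets at or beyond the file
   size raise a corrupt-index error.
3. Axis configuration from the **first spectrum only**: array role
   (`MS:1000514` m/z, `MS:1000515` intensity), float width (`MS:1000521`
   32-bit, `MS:1000523` 64-bit), compression (`MS:1000574` zlib,
   `MS:1000576` none), order of appearance, and the byte distance from
   `<spectrum` to `<binaryDataArrayList` (the *skip hint*).  Integer-typed
   arrays and MS-Numpress compressions are rejected as unsupported rather
   than guessed at.  Files omitting a compression accession are treated as
   uncompressed, which is what such writers mean.
4. Every spectrum in offset order: seek, jump by the skip hint minus a
   safety margin, verify and locate `<binaryDataArrayList>`, decode the two
   `<binary>` payloads, and assign them to axes by position.

Reading the layout once per file assumes the axis order, width and
compression are constant across spectra — true of every writer we are
aware of.  `read_mzml(strict = TRUE)` re-checks the declaration of every
spectrum and raises a `malformed_spectrum` error naming the offending
ordinal if the layout changes mid-file; it is off by default because the
re-check costs text parsing per spectrum for a condition that does not
occur in practice.

Per-spectrum metadata (MS level, retention time, precursors) is not
parsed: chromatogram extraction here is positional, and the package's
scope is raw vector access, not experiment reconstruction.

### Error reporting

Every anticipated failure is a classed condition (`msio_error` plus a
subclass such as `msio_inflate_error`, `msio_corrupt_index_error`,
`msio_malformed_pixel_error`), and failures inside the per-spectrum loop
are re-raised with the 1-based spectrum or pixel ordinal in the message
and an `index` field on the condition.  A damaged file therefore reports
*where* it is damaged, and the CLI can distinguish usage errors (exit 2)
from data errors (exit 1) without string matching.

## Binary arrays and the bounded inflate

Payloads are base64 (whitespace stripped first, since writers line-wrap),
optionally zlib (RFC 1950), and always little-endian IEEE-754 — the byte
order the format mandates; no big-endian writer exists.  Decompression
uses a small C wrapper over zlib rather than `memDecompress()`: the base R
routine grows its output buffer without bound when handed a truncated
stream (it cannot distinguish "need more output space" from "input ended
early"), which on a damaged file can exhaust machine memory before
failing.  The wrapper caps output at the declared element count when one
is known (256 MiB otherwise) and converts zlib status codes into catchable
`msio_inflate_error`s.

Float32 data round-trips through 32-bit precision by construction;
`encode_binary_array()` rounds to float32 first so encode→decode is an
exact inverse.  Overflowing float32 (e.g. 1e300) encodes as infinity and
round-trips as such.

## imzML loading

Only the *processed* storage mode — each pixel carries its own m/z axis —
is supported, matching the files this package targets; a continuous-mode
declaration (`IMS:1000030`) raises an explicit unsupported-mode error
rather than misreading shared axes.  Axis encodings come from the
`<referenceableParamGroup>` elements; pixel coordinates from
`IMS:1000050/51` under `<scan>`; and each array's ibd locator from
`IMS:1000102` (byte offset), `IMS:1000103` (element count) and, when
present, `IMS:1000104` (encoded byte length, required to delimit
zlib-compressed ibd blocks).  Locator-to-axis association accepts both
common placements: a `<referenceableParamGroupRef>` naming an axis group,
or a direct array-role accession on the `<binaryDataArray>` itself.

Coordinates are kept 1-based exactly as stored, for round-trip fidelity;
the grid conversion happens only inside `get_slice()`.  Files may store
fewer pixels than `max_x × max_y` — the `count` attribute of
`<spectrumList>` is authoritative for the read loop, and missing grid
cells simply stay empty (zero in ion images).  The loader does not reject
coordinates outside the declared grid (some writers overrun their own
scan settings); `get_slice()` raises the out-of-grid error where it would
corrupt an image.

The ibd's leading 16-byte UUID is skipped; when the document also carries
a UUID cvParam, a mismatch is a *warning*, not an error — a wrong UUID is
a provenance smell, not proof the data are unreadable.

### The skip-byte strategy

Within the spectrum read loop the scanner can jump by byte distances
learned from the first spectrum (distance to `<scan`, distance to
`<binaryDataArrayList`) instead of examining every byte.  Two safeguards
keep this a pure optimization:

* each jump lands a **64-byte safety margin** short of the learned
  distance, absorbing per-spectrum length variation (attribute-width
  changes, writer whitespace); and
* after the jump the scanner still *searches forward* for the target tag,
  so a conservative jump can never misread — at worst it rescans a few
  bytes.

If an extremely irregular file shrank an element by more than the margin,
the jump could leap past a target tag; the scanner then fails to find the
accession before `</spectrum>` and raises a malformed-pixel error naming
the pixel — a loud failure, never a silent misread.  `read_imzml()` also
exposes `method = "naive"`, a fully independent full-text parse of every
spectrum element; the test suite and the acceptance script hold the two
implementations to byte-identical output on randomized fixtures, including
missing-pixel, shuffled-order and whitespace/attribute-order-jittered
variants.

## Ion images, TrIQ, bitmaps

`get_slice()` aggregates, per pixel, the intensities whose m/z lies in the
**closed** interval `[target − tol, target + tol]`.  Two open choices were
settled as follows:

* **Sum, not max**, is the default aggregate: narrow windows frequently
  split a centroid's intensity across neighboring points, and summing is
  robust to that; `agg = "max"` is available for peak-height maps.
* **Closed on both ends**: boundary ties are included, deterministically.
  Note the usual floating-point caveat — `885.55 + 0.005` is a binary
  double, so a stored m/z that is analytically *equal* to the window edge
  may fall on either side of the computed bound.  Choose tolerances away
  from data values when exact edge behavior matters.

`triq(image, L, p)` implements Threshold Intensity Quantization.  With
`v_min` the image minimum and `n` the pixel count, the threshold is

> T = the smallest **observed** value v such that
> #\{values ≤ v\}/n ≥ p,

computed from the exact sorted values — not from a binned histogram, which
would introduce a bin-count parameter and shift T by up to a bin width for
no benefit at these image sizes.  Values are clipped at T and mapped by
`⌊(v − v_min)/(T − v_min) · (L − 1)⌋`, with everything ≥ T in the top
level `L − 1`.  Consequences, all covered by property tests: the mapping
is monotone; output occupies `[0, L−1]` and the top level is always
attained; the fraction of pixels at or below T is ≥ p and T is minimal
with that property; and a constant image quantizes to all zeros
(degenerate T = v_min).  Defaults `L = 256`, `p = 0.95` are the
conventional choices for 8-bit display with mild outlier suppression.

`save_bitmap()` writes an 8-bit indexed BMP (BITMAPINFOHEADER, 256-entry
BGRA table, bottom-up rows padded to 4-byte strides) — a deliberately
dependency-free, byte-exact format whose layout the tests verify with an
independent decoder.  Row 1 / y = 1 appears at the *top* of the exported
image; the bottom-up storage convention of BMP is handled internally.
The palette is the canonical 256-entry viridis map (via `viridisLite`),
chosen for perceptual uniformity — rainbow maps systematically distort
apparent abundance.  More than 256 levels cannot be represented at 8-bit
depth and raise an unsupported-depth error rather than silently rescaling.

Plotting chromatograms is intentionally out of scope: `bpc()`/`tic()`
return plain vectors (and the CLI writes `scan,value` CSV) for whatever
plotting system the user prefers.

## The fixture generator

`write_mzml()`/`write_imzml()` emit fully valid files — the mzML fixtures
parse under independent readers (the test suite cross-checks spectra
bit-exactly against the `mzR`/ProteoWizard stack and validates
well-formedness with `xml2`) — while returning exact ground truth: every
spectrum's byte offset, the index-list offset, the first-spectrum skip
distance, and every pixel's ibd locators.  The writer assembles elements
as strings and accumulates byte offsets *while writing*, emitting the
index after the spectra; offsets are therefore exact by construction and
need no second patching pass, which would otherwise tie the ground truth
to a serializer's whitespace policy.

What the fixtures emulate: both float widths, both compressions, both
axis orders, line-wrapped base64, attribute-order shuffling and bounded
whitespace jitter (≤ 8 bytes per tag, safely inside the 64-byte skip
margin), missing pixels, shuffled pixel file order, zlib-compressed ibd
blocks, and four deterministic corruption modes (`truncate_index`,
`truncate_zlib`, `drop_accession`, `locator_overrun`) that each trigger
exactly one reader error class.  Length-preserving corruption is used
where a length change would invalidate the byte index and mask the
targeted defect.

What they do **not** emulate: vendor-specific metadata dialects,
chromatogram lists, continuous-mode imzML, numpress payloads, non-UTF-8
text, multi-gigabyte scale, or real instrument noise structure.  Passing
the suite therefore demonstrates format-level correctness and robustness
to structural variation, not validated behavior on every vendor's
conversion quirks.

`random_spectra()`/`random_pixels()` draw uniform m/z positions (sorted
ascending) and uniform non-negative intensities with per-spectrum point
counts from a caller-chosen range — adequate as reader payloads, where
only exact recovery matters, not spectral realism.  Both restore the
global RNG state after seeded generation.

## Problem sizes and determinism

The test suite exercises 50 randomized mzML fixtures across all
width/compression/order combinations, 50 randomized imzML fixtures for the
skip-vs-naive equivalence, 1,000 random matrices for the TrIQ properties,
and odd-width BMP layouts; `scripts/acceptance.R` recomputes the same
quantities from scratch and additionally runs the full
slice → TrIQ → bitmap pipeline on an 85 × 50 grid carrying 4,250 synthetic
pixel spectra (a Gaussian abundance blob of a centroid at m/z ≈ 885.55
over a uniform background), reporting the grid dimensions, stored-pixel
count, TrIQ coverage at p = 0.95, top level, and bitmap round-trip.  All
randomness is seed-derived, so identical invocations produce identical
files and identical numbers.

## Known limitations

* Non-indexed mzML is rejected, not scanned.
* Spectrum metadata (MS level, retention time, precursor, polarity) is not
  exposed; chromatograms are indexed by scan position.
* Continuous-mode imzML, integer arrays, numpress, and 3D/z coordinates
  are unsupported by design.
* Attribute values containing a literal `>` would confuse the opening-tag
  delimiter search; XML escapes `>` in practice (`&gt;`), and no MS writer
  emits it raw.
* The scanner trusts structural well-formedness; it is a reader for files
  produced by real writers, not a validator.
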