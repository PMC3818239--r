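---
title: "Methods: how scopeqc measures confocal performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how scopeqc measures confocal performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopeqc)
```

## Why monitor a confocal microscope

Confocal microscopes drift. Lasers age and flicker, chromatic correction
depends on which correction lens happens to be mounted, spectral sliders
slip out of calibration, motorised stages lose repeatability, and the
Z focus creeps with temperature. None of this is visible in a single
pretty image; all of it corrupts quantitative experiments. `scopeqc`
turns a standard set of simple test recordings — a mirror slide, a
fluorescent plastic slide, multi-colour and sub-resolution beads, a
transmitted-light time lapse — into numbers that can be tracked over
months, per system and per objective lens.

The package is batch-oriented: recordings are dropped into one directory
per objective with keyword file names (`bead.tif`, `psf.tif`,
`field488.tif`, `stage1.tif`, ...), each TIFF accompanied by a small
metadata sidecar, and `run_suite()` (or the `scopeqc run` CLI) analyses
whatever it finds. Results go to a tab-delimited file (the source of
truth) and to an append-only HTML record.

## Data model and conventions

* Pixels live in an `ImageStack` indexed `[t, c, z, y, x]`; absent axes
  have extent 1. XZ reflection scans use a real Z axis with Y extent 1.
* Indices are 1-based (R convention); the physical coordinate of pixel
  `i` along an axis is `(i - 1) * spacing` (pixel-centre convention), so
  every distance below is linear in the pixel size or Z step.
* Standard deviations are population SDs (divide by N) everywhere.
* Vendor formats are out of scope. The package reads and writes its own
  interchange subset: uncompressed 8/16-bit grayscale multi-page TIFF
  plus a declarative sidecar (`<stem>.meta.json` or a flat-YAML
  equivalent) carrying `pixel_size_xy_um`, `z_step_um`,
  `frame_interval_s`, `channel_wavelengths_nm`, `wavelength_axis_nm`,
  `stage_positions_um`, `bit_depth`, `size_t`, `size_z`. If a TIFF embeds
  its own metadata and it disagrees, the sidecar wins and a warning is
  logged: explicit, inspectable metadata beats trusting whatever a
  vendor writer produced.

## Profile analysis: the shared core

Most assays reduce to a 1-D intensity profile. `extract_profile()` reads
a line with orthogonal averaging (each sample is the mean across a band
of rows or columns); `peak_and_fwhm()` locates the maximum sample (ties
break to the lowest position, for determinism) and measures the full
width at half maximum.

Two numerical choices matter:

* **Baseline correction.** The half-maximum level is
  `min + (max - min)/2`, not `max/2`. Reflection and PSF profiles ride
  on a detector offset; measuring half-way above the profile minimum
  makes the FWHM invariant under affine intensity rescaling
  `a*I + b`. Whether the original tools in this field correct for
  baseline is typically undocumented; here it is a stated contract,
  covered by an invariance test.
* **Linear interpolation of the crossings.** The half-level crossings
  are interpolated linearly between the outermost sample pairs
  straddling the level on each side of the peak. The recordings this is
  designed for oversample heavily (Z steps of 0.015–0.03 µm against
  FWHMs of ~0.5 µm), where higher-order interpolation changes nothing
  measurable; the convergence test (FWHM error shrinking monotonically
  with spacing) documents the residual discretisation error, which is
  below half a sample spacing.

`fit_gaussian()` fits `A*exp(-(x-mu)^2/(2*sigma^2)) + b` by
least squares (BFGS on the residual sum of squares), initialised from
`peak_and_fwhm()` (`sigma = fwhm/2.355`). On noiseless sampled Gaussians
this recovers parameters to 1e-6 relative. A failed or degenerate fit is
flagged, and moment-based estimates are carried as the fallback rather
than silently reporting garbage.

## The assays

**Laser stability** (`frame_statistics`, `linescan_noise`,
`multiscale_histograms`). Per-frame mean and SD of a transmitted-light
time lapse; the headline `max_percent_change` is
`(max - min)/overall mean * 100` of the frame means. Noise histograms
cover six timescales: adjacent-pixel differences along the centre row of
the first 100 frames (pixel dwell time, µs), adjacent-row means within
those frames (line time, ms), and frame-mean differences at the nearest
integer frame lag to 20 s, 1 min, 10 min and 1 h. Differences are
expressed as percent of the whole-series mean — normalising by the
series mean rather than the previous point keeps near-zero frames from
exploding the statistic. Bins are fixed (0.5 % wide, spanning ±10 %,
open-ended overflow): a fixed grid makes histograms comparable across
sessions, which is the whole point of a monitoring tool.

**Axial resolution and chromatic correction**
(`axial_channels_analysis`). A mirror imaged in reflection gives one
horizontal band per laser line in an XZ scan. The Z profile at the
centre column (or a user-chosen column, the programmatic stand-in for a
manually drawn line), averaged over 10 pixels in X, yields per channel
the peak Z and FWHM. The FWHM is the axial resolution; signed
differences `peak_z[i] - peak_z[j]` form the chromatic-shift matrix,
reported both pairwise (antisymmetric by construction) and relative to
the shortest-wavelength channel.

**Z-galvo drift** (`zgalvo_drift`). The same reflection band tracked
through time: peak Z versus time gives the drift (endpoint range as
`total_drift`, least-squares slope as `drift_rate_um_per_min` — the
slope is robust to single-frame outliers, the endpoints match the
traditional way such drift is quoted); the FWHM trace is a simple
vibration indicator. Frames without a detectable peak are recorded as
missing and never interpolated.

**Field illumination** (`field_uniformity`). The flat-field frame is
smoothed with a disc mean filter (radius 5 px, reflect padding — border
pixels must not be artificially darkened when the statistic is a
fall-off percentage), then centre-row and centre-column profiles are
read with 10 px averaging. `percent_difference = (max - min)/max * 100`
over the two profiles' samples: the percentage fall-off from the
brightest point along the centre lines. Because the normalisation is a
genuine open choice, `(max - min)/mean * 100` is emitted to the TSV as
well. Frames with ≥ 1 % saturated pixels are flagged rather than
silently analysed.

**Bead co-registration** (`bead_centroids`). Per channel: slice-wise
median filter (radius 7 px), channel-specific threshold at half the
filtered stack maximum, binarisation of the whole stack, and the
unweighted 3-D centroid of the mask in µm. Distances between channel
centroids (Euclidean in XY, absolute in Z) quantify chromatic
misalignment. Choices worth stating: the centroid is that of the binary
mask because the procedure binarises first — the intensity-weighted
centroid is emitted alongside for comparison; the "one bead per stack"
acquisition rule is enforced by rejecting stacks with more than one
26-connected component of ≥ 5 voxels above threshold, but small
sub-threshold specks do not abort an analysis.

**PSF metrology** (`psf_metrics`). Same centroid procedure on a
sub-resolution bead, then raw (unfiltered) X/Y/Z line profiles through
the centroid voxel are each Gaussian-fitted; the fitted FWHMs are the
lateral and axial resolution. Lateral FWHM is reported per axis and as
their mean, since conventions differ between facilities. A 1-D cut
through a 3-D Gaussian is itself Gaussian with the same sigma, so a cut
that misses the true centre by up to half a voxel biases the amplitude
but not the measured width — which is why the noiseless recovery
tolerance can be 2 %.

**Spectral accuracy** (`lambda_response`). The per-step mean intensity
of a lambda scan forms the detector's response; reflection peaks are
local maxima with topographic prominence ≥ 10 % of the spectrum maximum
(a fixed floor gives deterministic behaviour on noisy baselines — the
peaks of a healthy detector are visually dominant, so the exact floor is
uncritical). Each reference laser line is matched to the nearest peak
within 20 nm; an unmatched line is reported *absent*, which is the
diagnostic signature of a dead spectral slider. Two lines landing on one
peak flag it as *merged* (broad slider).

**Stage repeatability and accuracy** (`track_bead`,
`repeatability_stats`, `accuracy_stats`). Per frame: median filter,
per-frame half-maximum threshold, mask the original frame, and take the
intensity-weighted centroid of the surviving pixels (this assay masks
rather than binarises, so weighting is the natural estimator — the
deliberate asymmetry with the bead assay is documented above). The mean
of the surviving intensities doubles as a Z-focus-drift proxy.
Repeatability is the per-axis mean/SD and maximum excursion of the
centroid cloud; accuracy compares commanded moves (differences of the
sidecar's `stage_positions_um`) with measured moves. The stage-to-image
sign convention — commanded +X moves the bead −X in the image, as the
specimen moves opposite to the field — is explicit and overridable via
an `axes_sign` sidecar field, because hardware wiring differs; the test
suite asserts that inverted metadata shows up as residuals ≈ 2× the
commanded move, i.e. the failure is detectable rather than silent.
`stage1..3` recordings are independent repeatability measurements
(different beads); `stageacc1..3` are concatenated for accuracy (same
bead, absolute commanded positions).

**Galvo grid** (`grid_passthrough`). Contrast-stretched (0.5/99.5
percentiles, degenerate-range guard) and saved for visual inspection
only; no distortion metric is derived.

## The synthetic-data generator

`generate_fixture()` produces every input kind with exact ground truth:
Gaussian reflection bands (optionally drifting or width-jittered),
Gaussian vignettes, 3-D Gaussian beads with per-channel sub-voxel
offsets, constant frames with additive/multiplicative/frame-level noise
and optional linear or sinusoidal drift, sums of Gaussian spectral
peaks, and 2-D beads at commanded-plus-error stage positions with
matching (or deliberately corrupted) metadata. Defaults are chosen once
to mirror realistic acquisitions — e.g. PSF voxels of 0.03 × 0.03 ×
0.15 µm against sigmas of 0.1/0.1/0.3 µm, Z steps of 0.03 µm for
reflection scans, stage jitter of 0.3 µm over 100 revisits — and are not
tuned to test outcomes. Noise is Gaussian read noise plus an optional
signal-scaled (shot-like) term; at the tolerances tested, full Poisson
simulation would change nothing. Pixel values are rounded to integers
and clamped to the bit depth, exactly as written to TIFF, so every
fixture round-trips bit-exactly.

What a green test does *not* establish: the generator contains no
diffraction (its PSF is a Gaussian, not an Airy pattern), no aberration,
no depth-dependent attenuation, no structured detector noise, and its
beads are ideal Gaussian blobs. Green means the measurement chain
recovers known truth under the stated model — it cannot certify any
physical instrument.

## Reporting

All scalar results append to `measurements.tsv` (one row per parameter:
timestamp, system, objective, assay, parameter, value, units). Values
are serialised with 7 significant digits, guaranteeing re-reading within
5e-7 relative; the TSV is the source of truth from which the HTML can be
rebuilt (`scopeqc report --rebuild`). The HTML record is a static tree,
one page per objective under a per-system index: each run appends a
dated section and never touches earlier sections (the navigation block
is the only mutable region), which the tests verify byte-for-byte. A
hand-mangled page is backed up and rebuilt from the TSV rather than
crashing the run. Per-assay failures are isolated: a monitoring tool
should report what it can.

## Known limitations

* Only the package's own TIFF subset is read; vendor files must be
  exported first.
* No vibration spectrum analysis (the FWHM trace is an indicator, not a
  diagnosis), no grid-distortion metrics, no flat-field correction maps,
  no detector linearity/CV measurement.
* The one-bead rule is enforced, not worked around: fields with
  multiple beads are rejected instead of segmented.
* Merged spectral peaks are reported as one peak with a flag; no
  deconvolution is attempted.
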