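---
title: "Quantifying transcription-factor condensates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condquant)
```

## The problem

When a transcription factor such as yeast Met4 or Met32 concentrates into
nuclear condensates, the fluorescence of a tagged copy stops being evenly
spread over the nucleoplasm and collects into puncta. `condquant`
implements the quantitative readouts used to establish and characterize
this behavior:

1. **Pixel-intensity dispersion per nucleus.** For the pixel values
   $x_1,\dots,x_n$ of one segmented nucleus with constant background $b$,
   the package reports the background-subtracted mean
   $\mu = \bar{x} - b$, the sample variance $s^2$ of the raw values, the
   coefficient of variation $\mathrm{CV} = s/\mu$ and the Fano number
   $F = s^2/\mu$. The Fano number is the key condensate metric: for a
   freely diffusing fluorophore imaged in photon units, shot noise gives
   $F \approx 1$ regardless of expression level, while any spatial
   concentration of signal inflates it. Because absolute camera units are
   arbitrary, Fano numbers are reported *normalized*: the mean Fano of a
   free-fluorophore reference condition is defined as 1 and every cell's
   Fano is divided by that reference mean.
2. **Per-cell pixel co-localization.** For two co-imaged factors, the
   Pearson correlation of the two channels' pixel values inside each
   nucleus measures co-condensation; a shared punctate pattern drives
   $r$ toward 1, unrelated patterns toward 0.
3. **Locus-dot-centered averaging.** A tetO/tetR-mCherry (or lacO/LacI)
   array renders one genomic locus a diffraction-limited dot. The package
   finds, per cell, the z plane and (y, x) position where the smoothed dot
   channel peaks, crops the signal channel (same-z plane or maximum
   intensity projection) to a window centered on the dot, averages those
   windows across hundreds of cells, and cuts a line profile through the
   center. If the locus sits inside condensates, the averaged profile
   peaks at offset 0; the formal test compares per-cell center-window
   means between conditions.
4. **FRAP kinetics.** Recovery series are normalized to percent of
   pre-bleach intensity and fitted with the single-exponential model
   $I(t) = D + (P - D)\,(1 - e^{-kt})$, $t$ measured from the bleach. The
   half recovery time $t_{1/2} = \ln 2 / k$ is the headline quantity,
   reported as mean ± SD over replicates; the mobile fraction is
   $(P - D)/(100 - D)$.
5. **Droplet partitioning.** For in vitro droplet fields, droplets are
   segmented on the scaffold channel and the partition coefficient of any
   channel is the ratio of the mean in-droplet intensity to the mean of
   the dilute phase.

Every stage is exercised against a synthetic-microscopy generator with
known ground truth, because the method's correctness claims (parameter
recovery, monotonicity, contrast reproduction) are only testable when the
truth is known.

## The generative model

`simulate_nucleus_scene()` draws scenes under a deliberately simple
optical model:

* **Nuclei** are circles (2D mode) or spheres sampled at z planes
  (3D mode), default diameter 2.0 µm at 0.1 µm/pixel — the scale of a
  yeast nucleus. Stacks default to 10 z planes at 0.4 µm spacing.
* **Signal** is an expected photon image: a diffuse component spread
  uniformly over the nuclear cross-section plus 1–5 isotropic Gaussian
  puncta (radius 2–4 px, σ = radius/2) that together carry a configurable
  *intensity fraction* of the cell's total photons. The fraction is the
  single knob that maps monotonically onto the downstream Fano number.
  Total photons per cell default to 20,000 (~64 photons/pixel over the
  nucleus) and vary lognormally across cells (sdlog 0.1, a moderate
  cell-to-cell expression spread under strong induction).
* **The chromatin dot** is a diffraction-limited Gaussian (σ = 1 px
  lateral) in channel 2 carrying 70% of that channel's photons over a
  diffuse nucleoplasmic rest. Its position is either *coupled* (placed at
  a punctum center) or *independent* (uniform in the nucleus) — the
  generative contrast between a condensate-associated locus and a control
  locus.
* **Optics and noise**: every plane is convolved with a Gaussian PSF
  (σ = 1 px ≈ 100 nm, appropriate for a high-NA confocal at these pixel
  sizes), then Poisson photon noise and optional Gaussian read noise are
  applied. The PSF kernel is normalized on the image grid, so noise-free
  images conserve the configured photon totals exactly — a tested
  invariant.

What the generator does **not** emulate: vectorial/aberrated PSFs,
axial PSF blur between z planes, photobleaching during acquisition,
autofluorescence texture, cell-cycle shape variation, or clumped cells.
Passing tests therefore demonstrate that the *estimators* are correct and
well-calibrated under controlled conditions, not that segmentation would
survive every pathology of real micrographs.

FRAP series (`simulate_frap()`) follow the acquisition used for
condensate droplets: three pre-bleach frames, then one frame every 3 s
for 270 s, the first post-bleach frame sitting at the bleach depth at
t = 0. Defaults: half time 64 s (the condensate-scale recovery the
package is calibrated around), plateau 85%, depth 25%, per-frame Gaussian
noise as a percentage of the plateau. Droplet fields
(`simulate_droplet_field()`) are disks (radius 3–6 px) at
partition-ratio × dilute-level intensity on a positive dilute background.

## Segmentation design

The default pipeline is Gaussian smooth (σ 1 px) → relative threshold →
fill holes → drop components under 30 px → label, run on the mean z
projection (single-plane images analyzed as-is).

Two choices deserve explanation because they departed from the obvious
first draft:

* **Threshold mode.** Plain Otsu fails on strongly punctate nuclei: with
  40% of photons in a few bright puncta, the between-class optimum
  separates *puncta from everything else*, so the "nucleus" shrinks to
  its puncta and every downstream statistic is computed on the wrong
  pixel set. The default `"nucleus"` mode therefore thresholds in two
  passes: Otsu on the log-compressed smoothed image (log1p of the
  max-normalized image) finds the foreground even under a dominated
  dynamic range, and the final threshold is half the median foreground
  intensity — the half-height criterion that places the boundary at the
  blurred rim's midpoint. Plain `"otsu"` remains available and is the
  default for droplet fields, which are genuinely bimodal. Both modes
  operate on max-normalized images and are exactly invariant to global
  intensity scaling (a tested property). On noise-free synthetic nuclei
  the recovered areas are within 10% of truth across puncta fractions
  0–0.6, and centroids within 1 px.
* **Interior erosion for dispersion statistics.** The PSF smears the
  nuclear rim over ~2σ, so pixels just inside any threshold boundary sit
  on an intensity ramp. That ramp is an optical artifact, yet it
  contributes spatial variance of order $0.02\,\mu$ to the Fano number —
  enough to push a free fluorophore's Fano to ~2 at realistic photon
  counts and destroy the Poisson baseline that normalization relies on.
  CV/Fano (and per-cell co-localization) are therefore computed on the
  region mask eroded by 2 px (`erode_px`), while the region's reported
  boundary, area and centroid always refer to the full mask. With
  erosion, 50 Poisson-noise free-fluorophore cells give a mean Fano of
  1.004–1.007.

Touching-object splitting (watershed) is deliberately absent: the nuclear
fields this targets are sparse, and for droplets, fused objects are real
objects of interest, not segmentation errors.

## Dot tracking and averaging choices

* "Dot intensity" is the smoothed single-pixel maximum, the simplest
  reading of "the z plane where the dot is brightest"; ties break toward
  the lowest z, then row-major (y, x), making detection fully
  deterministic.
* Alignment is integer-pixel: camera-grid images are averaged as-is.
  Sub-pixel interpolation would smear the center-bin definition that the
  enrichment test depends on.
* The averaging window radius defaults to w = 10 px (~1 µm at
  0.1 µm/px); the center window for enrichment tests is |d| ≤ 2 px.
  Window pixels outside an image contribute nothing — means are
  missing-aware with per-pixel contributing-cell counts, and averaging
  then profiling equals profiling then averaging (tested).
* Cells failing the dot-prominence check (smoothed peak / smoothed
  median < 3) are excluded, mirroring the practice of analyzing only
  cells with a visible array dot.

## FRAP fitting choices

A single-exponential model is the minimal model consistent with
reporting one half recovery time; a deliberate non-goal is
reaction–diffusion modeling. Initialization is deterministic
(D = first post-bleach value, P = mean of the last five frames,
k = ln2 / time of the first half-recovery crossing) with up to three
jittered restarts, and fits use bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, D, P, k ≥ 0). Replicates are fitted separately —
the replicate mean ± SD is the primary report — with the averaged-curve
fit and the model-free crossing estimator emitted alongside, since with
real data it is often unknowable which of the two a legacy analysis used.
On a noiseless grid over (D, P, k) the fit recovers parameters to
numerical tolerance, and at 2% noise the half-time estimator's bias over
200 replicates is below 2% (both tested).

## Numerical and degenerate-input conventions

* Canonical array order is `(z, channel, y, x)`; y increases downward,
  x rightward; indices are 1-based at pixel centers. Intensities are
  floating point internally regardless of the on-disk integer type.
* Sample (n−1) variance throughout; with hundreds of nuclear pixels the
  n vs n−1 distinction is negligible, but n−1 matches the default of the
  numeric environments such analyses are usually scripted in.
* Cells with non-positive background-subtracted mean have undefined
  CV/Fano: they are flagged and excluded from condition aggregates rather
  than silently polluting means.
* Zero-variance channels make per-cell Pearson r undefined (flagged).
* A flat or all-zero image segments to an empty region list (logged
  upstream, not an error); an all-zero dot channel is a no-dot failure.
* The reference-normalization identity is exact: the summary mean is
  computed as mean(condition)/mean(reference), so a condition normalized
  against itself reports exactly 1.0 in floating point.
* No multiple-testing correction is applied: group comparisons are
  single pairwise tests per condition pair, and raw p values are
  reported. The pooled-variance Student's t-test is the default, with
  Welch's test behind a switch.

## Problem sizes

The shipped analyses and tests run at sizes chosen to make every
statistical claim decidable while keeping a full run on a laptop-class
single core in minutes: 50 cells per condition for Fano/CV and
co-localization calibration, 100 cells per condition for dot-centered
averaging, 100 cells per group for reporter quantification, three FRAP
replicates of 93 frames, and 10-droplet fields in triplicate. Larger
populations only tighten the already-passing tolerances.

## Known limitations

* The background model is a single constant per condition; structured
  background (uneven illumination, autofluorescent vacuoles) is out of
  scope.
* 3D mode samples a spherical nucleus at z planes but blurs only
  laterally; axial PSF extent is not modeled, so same-z analyses on
  synthetic data are slightly sharper than real optics would give.
* The co-localization control population is constructed with independent
  spatial signals and therefore centers near r = 0; real negative
  controls (two unrelated chromatin factors) share nuclear envelope and
  chromatin texture and typically sit modestly above 0.
* Droplet segmentation does not split touching droplets; size
  distributions of dense fields will be biased toward large objects, by
  design.
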