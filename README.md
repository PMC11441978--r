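# condquant

Quantification of transcription-factor condensates in fluorescence
microscopy, with a ground-truth synthetic-microscopy generator that makes
every stage testable.

## The problem

Stress-responsive transcription factors — yeast Met4 and its co-factor
Met32 are the motivating case — can concentrate into nuclear condensates:
instead of filling the nucleoplasm evenly, the tagged protein collects
into puncta that sit on target gene loci and correlate with elevated
transcription. Establishing this from images takes a specific set of
quantitative readouts, which this package implements as tested, reusable
functions:

* **Puncta metrics** per nucleus: background-subtracted mean, CV
  (sd/mean) and the **Fano number** (variance/mean) of nuclear pixel
  intensities, normalized so a free-fluorophore reference averages
  exactly 1. A well-mixed fluorophore in photon units gives Fano ≈ 1
  (shot-noise limit); condensates inflate it by orders of magnitude.
* **Per-cell co-localization**: Pearson correlation of two channels'
  pixel values inside each nucleus (co-condensing factors vs unrelated
  controls).
* **Locus-dot-centered averaging**: detect a tetO/tetR-mCherry chromatin
  dot in each z-stack, align the GFP maximum-intensity projections on the
  dot across hundreds of cells, average, and cut a line profile — the
  readout for "does this locus sit inside the condensate?" — with a
  t-test on per-cell center enrichment.
* **FRAP**: normalization to percent of pre-bleach, single-exponential
  fit I(t) = D + (P − D)(1 − e^(−kt)), half recovery time ln2/k as
  mean ± SD over replicates, mobile fraction (P − D)/(100 − D).
* **Droplet analysis**: segmentation of in vitro droplet fields, size
  distributions, two-channel overlap, and partition coefficients
  (in-droplet mean / dilute-phase mean).
* **Synthetic microscopy**: nuclear scenes (diffuse signal + Gaussian
  puncta carrying a configurable intensity fraction, optional locus dot
  coupled to or independent of the puncta, Gaussian PSF, Poisson/read
  noise, z-stacks), FRAP series and droplet fields — all with known
  ground truth and bit-reproducible seeding.

See `vignettes/condensate-quantification.Rmd` for the models, parameter
defaults and design rationale.

## Worked example

Fifty simulated cells per condition, Poisson noise, puncta carrying 0,
20, 40 or 60% of each cell's photons (`analysis/02_puncta_fano.R`):

```r
library(condquant)
cfg <- scene_config(puncta_fraction = 0.4, noise = "poisson")
pop <- simulate_population(cfg, 50, seed = 20260931)
stats <- do.call(rbind, lapply(pop, function(s)
  nucleus_pixel_stats(s$stack, channel = "gfp")[1, ]))
head(stats$fano)
#> [1]  60.41140  37.72837  54.63700 133.39791 118.41861  98.21699
```

The shipped analysis prints:

```
        condition  n mean_cv mean_fano norm_fano norm_fano_sem p_vs_reference stars
 free_fluorophore 50   0.126      1.01       1.0        0.0155             NA
       puncta_f20 50   0.453     15.03      14.9        1.0650       4.55e-23   ***
       puncta_f40 50   0.814     54.08      53.5        4.4199       1.15e-20   ***
       puncta_f60 50   1.110    112.43     111.1        9.9738       6.76e-19   ***
```

Reading it: the free fluorophore sits at the Poisson baseline (raw Fano
1.01, normalized to 1 by construction), and the mean Fano rises strictly
with the fraction of photons in puncta — the punctateness metric doing
its job. The stars are two-sided Student's t-tests against the reference
(\*\*\* p < 0.001).

The other drivers under `analysis/` exercise the remaining modules the
same way; on one run they print, e.g.:

```
mean per-cell r: shared 0.749 (n=93) vs independent 0.014 (n=149); p = 3.4e-96 ***
center enrichment (|d| <= 2 px): 87.1 vs 35.7, p = 1.02e-23 ***
half recovery time: 63.2 +/- 1.4 s (mean +/- SD of 3 replicates; truth 64 s)
pooled client partition: full-length 4.94 vs truncated 2.00; p = 4.94e-72 ***
```

Each writes its tables (per-cell statistics, line profiles, normalized
FRAP curves, droplet partition tables) under `results/`.

## Layout

```
R/                  package code (containers, generator, segmentation,
                    puncta statistics, dot tracker, FRAP, droplets)
analysis/           numbered narrative drivers over the package
tests/testthat/     unit, property and end-to-end validation suites
scripts/acceptance.R  headline-quantity reproduction script
vignettes/          methods vignette
```
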