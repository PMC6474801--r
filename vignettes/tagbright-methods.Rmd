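---
title: "Models and design choices in tagbright"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in tagbright}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagbright)
```

# What the package measures

Self-labeling protein tags (HaloTag, SNAP-tag) attach organic fluorophores
to fusion proteins in living cells. How bright the resulting label is
depends not only on the dye but on the tag it sits on: far-red rhodamines
such as SiR and JF646 can be several-fold brighter on HaloTag than on
SNAP-tag. `tagbright` implements the quantification used to establish such
comparisons:

* **Tissue stills** (fly egg chambers): a difference-of-Gaussians (DoG)
  band-pass, a Rényi-entropy automatic threshold, compositing of all
  connected regions above a minimum area, and the background-corrected
  mean (in-mask mean minus out-of-mask mean) per image.
* **Cultured-cell fields**: detection of reporter-positive (transfected)
  cells, a k·σ co-labeling classifier, per-cell background-corrected dye
  intensity, Gaussian distribution fits, fold ratios with bootstrap CIs,
  and two-tailed unpaired t-tests.
* **STED time series**: frame summing, kymographs, mono-exponential
  photobleaching fits, and initial-intensity estimation.
* **Line profiles**: Gaussian FWHM fits (resolution) and equal-width
  double-Gaussian fits (apparent donut diameter of clathrin-coated pits).
* **Photophysics**: Beer–Lambert arithmetic (A = εcl), conjugate
  extinction coefficients, saturation checks, and ε·Φ brightness folds.

Because the underlying microscope data are not deposited anywhere, the
package ships a seeded synthetic-microscopy generator whose ground truth is
known exactly; every analysis stage is validated by parameter recovery on
those scenes.

# The segmentation model

The tissue quantifier maps "signal" as follows. The raw channel is filtered
with `G(σ) − G(kσ)` (defaults σ = 4 px, k = 1.4, so the coarse kernel has
σ₂ = 5.6 px), using unit-sum separable Gaussian kernels and reflection
boundaries, so constant offsets vanish exactly and bright band-like
structures of scale ~σ become positive. A threshold is chosen on a 256-bin
histogram of the filtered image by the Rényi-entropy method: the cut `t`
maximizes the summed order-α entropies of the background and foreground
class distributions, with α → 1 giving the classical maximum-entropy
(Shannon) threshold. The default `renyi_combined` method reproduces the
three-threshold blend (α = 0.5, 1, 2 with proximity-dependent weights) used
by the familiar auto-threshold tool family; `renyi_single` exposes one α
directly. Ties in the objective break toward the lower bin, making results
deterministic.

Pixels above threshold are labeled under **8-connectivity** and every
component of at least `min_area_px` pixels (inclusive; default 500 px,
which is 16.24 µm² at 180.2 nm pixels) is composited into the signal mask.
Signal and background means are always measured on the **raw** image —
the DoG copy only decides *where* to measure. Whether the original
tool measured on raw or filtered data is not documented anywhere we could
find; raw-image measurement is the physically meaningful choice (filtered
intensities are band-pass amplitudes, not fluorescence) and we fix it as
an explicit interpretation. The background is the full complement of the
mask within the analyzed region.

Two useful invariances follow from this construction and are enforced by
tests: adding a constant to the image changes nothing (DoG kills DC), and
scaling the image by c > 0 scales the corrected signal by exactly c — which
is why fold *ratios* between conditions are robust to most segmentation
imperfections.

# Per-cell analyses

Transfected cells are detected on the reporter channel with the same
machinery at a coarser band-pass (defaults σ = 6, k = 1.6, minimum cell
area 200 px). Touching cells are merged — there is no watershed splitting,
a documented limitation for dense fields.

The published co-labeling criterion is visual ("structure visible"). We
operationalize it as: a cell is co-labeled when its background-corrected
dye mean exceeds `k·sd` of the dye channel outside all cells (default
k = 3). Because a cell mean averages hundreds of pixels, its sampling SD is
far below the pixel SD, so the false-positive rate at k = 3 is well under
1%; the threshold is in units of the same scale as the data, making the
classification invariant to global intensity rescaling.

Labeling efficiency is the percentage of reporter-positive cells classified
co-labeled. Fold ratios are ratios of condition means with a seeded
nonparametric bootstrap CI (2000 resamples). The default test is Student's
pooled-variance two-tailed unpaired t-test (the conventional unpaired
default in graphing software), with Welch's correction behind a flag;
significance stars follow the usual map (ns > 0.05 … **** < 0.0001), with
boundary values falling on the less significant side.

# STED time series and profiles

Raw STED frames are **summed** (not averaged) in non-overlapping blocks —
4 frames for cultured-cell movies, 5 for egg-chamber movies — with the
frame interval scaled accordingly; trailing partial blocks are dropped and
summation happens in double precision. A 0.5-px Gaussian blur is provided
for display only; nothing quantitative ever runs on blurred data. Because
acquisition-rate statements in methods sections are often internally
inconsistent, the frame interval is always explicit user input and never
derived from a frames-per-second figure.

The bleaching model is mono-exponential with an offset,
`I(t) = offset + I0·2^(−t/halflife)`, fitted by Levenberg–Marquardt least
squares. No richer model is attempted: a single half-life plus a floor is
the minimal photobleaching description, and the offset absorbs residual
background. Curves with non-negative slope are flagged `no_decay` and not
fitted. The initial intensity defaults to the first summed frame's
corrected value.

Line profiles are sampled bilinearly at 1-px steps and averaged across a
perpendicular width. The FWHM readout is `2√(2 ln 2)·σ` from a Gaussian +
baseline fit initialized at the half-maximum crossings. Donut profiles are
fitted with **two equal-width Gaussians plus baseline**; the equal-width
constraint is what keeps 100-nm-scale fits stable near the resolution
limit. The published figures show fits without stating a model, so both fit
models here are declared interpretations. A donut is only *called* when
(i) the two-peak model beats the single-peak model by ΔAIC ≥ 4 and (ii)
the fitted model actually has a hollow center — its midpoint value dips at
least 35% below its peak. Without (ii), any broad noisy blob can be
"explained" by two heavily overlapping components; with it, rings imaged
under a confocal-width PSF are reliably flagged unresolved, which is
exactly how such structures present in practice.

# The synthetic generator

Each scene renders a noiseless structural image in arbitrary detector
counts, convolves it with an isotropic Gaussian PSF (FWHM 250 nm for
confocal scenes, 60 nm for STED), and applies
`Poisson(photon_scale·(I + background)) / photon_scale + N(0, read_sigma)`
per pixel, clipped at zero — the standard shot-plus-read detector model.
Everything is seeded: identical configurations are bit-identical.

Geometry is deliberately stylized; summary statistics, not anatomy, are
what the analyses consume:

* **HeLa fields**: non-touching disk "cells" on a jittered grid; the
  reporter channel shows the transfected subset; co-labeled cells carry
  2–3 bright Golgi-like blob disks whose amplitude is
  `base_intensity × tag_ratio` (Halo) or `base_intensity` (SNAP).
* **Egg chambers**: a follicle-epithelium ring with a thin, bright
  subapical band at its inner rim — the band is the structure the DoG
  pipeline should map.
* **Clathrin pits**: thin annuli near the resolution limit (below).
* **STED series**: blob structures decaying as `2^(−t/halflife)` with
  independent per-frame noise; the same renderer serves cultured-cell and
  egg-chamber movie emulation, since the ROI-mean analysis is geometry
  agnostic.

Brightness variability uses a truncated Gaussian with a coefficient of
variation chosen per scene kind: 0.2 *between cells* in HeLa fields
(matching the broad per-cell intensity distributions such experiments
show) and 0.1 *between images/movies* for tissue stills and time series,
the scale of staining and acquisition variability between repeats of an
endogenously tagged line. In efficiency scenes, cells drawn as "labeled"
are placed above the detection limit by construction (amplitude floored at
40% of the condition mean, blobs of radius 5–7 px), so
`labeled_fraction_above_limit` means what it says; the complementary
fraction renders no specific dye signal at all.

**Apparent vs physical ring diameter.** A flat annulus of diameter 100 nm
convolved with a 60-nm-FWHM PSF does *not* produce peaks 100 nm apart: the
rim curvature pulls both peaks inward by roughly σ²/R plus cross-talk from
the opposite rim, and the measured separation lands near 80 nm. What a
STED measurement of a pit reports — and what published "≈100 nm donut"
figures describe — is the *apparent* peak-to-peak diameter. The generator
therefore treats `ring_diameter_nm` as the apparent diameter: using the
closed form for a circle convolved with an isotropic Gaussian,
`f(r) ∝ exp(−(r² + R²)/2σ²)·I₀(rR/σ²)`, it solves for the physical rim
radius whose post-PSF peak sits at the requested radius (≈57 nm rim radius
for a 100-nm apparent diameter under a 60-nm PSF). When no donut-shaped
solution exists — the PSF is too wide and the structure images as a filled
spot, as under a 250-nm confocal PSF — the rim is rendered at the nominal
radius; it is unresolved either way, which is the behavior the analysis
must detect.

What the generator does **not** emulate: vectorial or depth-dependent
PSFs, depletion-beam photophysics, drift, autofluorescence textures,
anatomically realistic tissue, or touching/overlapping cells. Passing
recovery tests on these scenes therefore demonstrates that the *analysis
chain* is correct and unbiased under the stated noise model — not that it
is robust to every artifact of real microscopy data.

# Problem sizes and numerical choices

The validation suite and the acceptance script run, per quantity: 12
egg-chamber images per condition at 512×512 (ground-truth ratio 4.5);
HeLa fields totalling ≈300 transfected cells per condition (ratio 2.8);
≈740 reporter-positive cells at 93% above-limit fraction; 4 STED movies
per condition of 40 frames at 256×256 (ratio 3); 4 vs 6 movies at
19.53-nm pixels with 5-frame summing (ratio 2.5); and single-pit profiles
at 10-nm pixels. These sizes mirror the replication the original analyses
used; the package itself has no size limits. With 4 movies per condition
and ~10% per-movie brightness variability, the fold estimator's CV is
about 7% — small designs are intrinsically noisy, and recovery bands in
the tests reflect that.

Other numerics: Gaussian kernels are truncated at 4σ and renormalized;
histograms use 256 bins over the filtered image's [min, max]; Poisson
draws switch to the matching normal approximation above 2³⁰ expected
electrons to stay within integer range; nonlinear fits use
Levenberg–Marquardt (`minpack.lm`) with data-driven starts (half-maximum
crossings for peaks, half-decay time for bleaching) and bounded
parameters; the bootstrap and every generator draw are seeded, and paired
conditions use disjoint seed offsets so their noise is independent.

# Interfaces

The scene writers emit multi-page TIFF (frame-major, reporter page before
marker), a ground-truth CSV, and a YAML config sidecar;
`read_image_stack()` round-trips them. `run_comparison()` is the
end-to-end entry point (simulate → quantify → compare) and writes a
summary CSV, a per-unit CSV and a JSON report embedding the seed and a
configuration hash, so reports are reproducible byte for byte. R functions
and `scripts/acceptance.R` are the intended entry points; there is no
separate shell executable.
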