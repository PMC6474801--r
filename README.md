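# tagbright

Quantification of how much brighter one self-labeling protein tag is than
another in fluorescence microscopy.

HaloTag and SNAP-tag both attach organic fluorophores to fusion proteins in
live cells, but the tag itself changes the photophysics of the dye sitting
on it: far-red rhodamines (SiR, JF646) can be several-fold brighter on
HaloTag than on SNAP-tag, with direct consequences for confocal image
quality and for how long a STED movie stays usable. `tagbright` is an R
package for making that comparison quantitative, aimed at microscopists and
image analysts who need reproducible brightness, labeling-efficiency and
resolution statistics rather than visual impressions.

## What it computes

**Tissue segmentation** — the semi-automated quantifier for tissue stills
(e.g. *Drosophila* egg chambers expressing a double-tagged protein): a
difference-of-Gaussians band-pass `G(σ) − G(kσ)` (σ = 4 px, k = 1.4), an
automatic threshold by the Rényi-entropy method on a 256-bin histogram,
compositing of all 8-connected regions ≥ 500 px, and the
background-corrected mean

```
corrected_signal = mean(image | mask) − mean(image | outside mask)
```

measured on the raw image.

**Per-cell statistics** — detection of reporter-positive (GFP⁺) cells,
a k·σ co-labeling classifier (`marker_corrected > k·sd(background)`,
k = 3), labeling efficiency (% of reporter⁺ cells co-labeled), Gaussian
fits of intensity distributions, Halo:SNAP fold ratios of condition means
with bootstrap 95% CIs, and two-tailed unpaired t-tests with the usual
significance stars.

**STED time series** — summing of raw frames (4 or 5 per block),
kymographs along a line, background-corrected intensity-over-time curves
with a mono-exponential bleach fit `I(t) = offset + I0·2^(−t/halflife)`,
and initial-intensity estimation.

**Line profiles** — Gaussian FWHM fits for resolution readout and
equal-width double-Gaussian fits that report the peak-to-peak separation
of donut-shaped structures (clathrin-coated pits, apparent diameter
≈ 100 nm in STED), with an explicit "unresolved" flag when the profile has
no real hollow center.

**Photophysics** — Beer–Lambert arithmetic (`A = ε·c·l`): stock
concentrations, conjugate extinction coefficients, 3-vs-6-equivalent
saturation checks, and ε / ε·Φ brightness folds between conjugates.

**Synthetic microscopy** — a seeded generator for all four scene families
(HeLa fields with a transfected subset, egg-chamber epithelia with a bright
subapical band, clathrin-pit rings near the resolution limit, bleaching
STED series) under Poisson + Gaussian read noise, with exact ground truth;
every analysis above is validated by parameter recovery on these scenes.

## Worked example

Simulate twelve egg-chamber images per labeling condition with a
ground-truth Halo:SNAP brightness ratio of 4.5, run the full
segmentation-and-statistics pipeline, and compare:

```r
library(tagbright)

cfg <- scene_config("egg_chamber", tag_ratio = 4.5, seed = 1)
rep <- run_comparison(cfg, n_per_condition = 12)
print(rep)
#> ComparisonReport
#>   condition  n      mean        sd
#> 1      halo 12 139.63261 12.136976
#> 2      snap 12  31.09504  2.543479
#>   fold (halo/snap): 4.491  [95% CI 4.215, 4.791]  (truth 4.5)
#>   t = 30.3, p = 1.93e-19 [****]
#>   seed 1, config 86d3d30c2d25ebe04f1334dc7cc306ce
```

The `mean` column is the background-corrected signal per condition in
detector counts; the pipeline recovers the configured 4.5-fold difference
as 4.49 with a bootstrap CI covering the truth, and the t-test calls the
difference at the **** level. Rerunning with the same seed reproduces the
report byte for byte.

Photophysics works directly from measured extinction coefficients:

```r
halo <- conjugate_record("SiR", "halo", 130200)   # Halo–SiR, M⁻¹cm⁻¹
snap <- conjugate_record("SiR", "snap", 43200)    # SNAP–SiR
brightness_fold(halo, snap)$epsilon_fold
#> [1] 3.013889
```

i.e. a ~3-fold extinction-coefficient difference between the two SiR
conjugates. Quantum yields are user-supplied inputs; when both are given,
`brightness_fold()` also returns the ε·Φ brightness fold.

See `vignettes/tagbright-methods.Rmd` for the models, assumptions and
design decisions (including why the clathrin-ring generator parameterizes
the *apparent* donut diameter).

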