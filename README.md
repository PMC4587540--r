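# squareT1

Surface quadrupolar relaxation (SQUARE) T1 analysis for hyperpolarized
^83^Kr lung MRI, with a digital phantom and acquisition simulator.

## The problem

Gas-phase ^83^Kr relaxes fast near surfaces: transient adsorption couples
its quadrupolar nucleus to the surface and rapid exchange carries the
depolarization into the gas, so the longitudinal relaxation time scales
with the gas volume per unit surface, **T1 = κ·V/S**. In a healthy rat
lung the high surface-to-volume alveoli give T1 ≈ 1 s while conducting
airways relax more slowly; emphysema enlarges alveoli (mean alveolar area,
MAA, rises), lowers S/V and lengthens the alveolar T1. Pixel-wise T1 maps
from T1-weighted images acquired at several post-inhalation delays
therefore carry a microstructural biomarker: the T1 histogram of a lung
decomposes into a fast (alveolar) and a slow (airway) Gaussian mode, each
summarized by its expected value EV(T1) and full width at half maximum
FWHM(T1), and the EV values separate control from elastase-induced
emphysema groups under a Student's t-test at α = 0.05.

The package is for imaging scientists who want to reproduce, test or
extend this analysis chain without access to the original raw data. It
implements, as tested S4 components:

- `makePhantom()` / `simulateDelaySeries()` — a 2-D coronal digital lung
  phantom whose T1 field encodes S/V, and a single-inhalation
  variable-flip-angle FLASH simulator (TE 1.8 ms, TR 12.6 ms, 64 × 32
  matrix, delays 0.2–2.2 s, flip angles θ_j = arctan(1/√(n−j)), complex
  k-space noise, optional timing jitter, ventilation defects, intra-scan
  decay);
- `reconstructSeries()` — sine-bell squared apodization, centred zero
  filling to 64 × 64 and unitary inverse FFT to magnitude images
  (0.795 × 0.635 mm pixels at the 50.9 × 40.7 mm field of view);
- `buildT1Map()` — per-pixel fits of S(τ) = S0·exp(−τ/T1) with the
  physical-range filter 0 < T1 ≤ 6 s and a lung-contour ROI from the
  first image;
- `binT1()` / `fitBimodal()` — 200 bins × 0.03 s histograms and the
  two-Gaussian decomposition with automated peak picking;
- `compareGroups()` — group means ± SD and pooled-variance t-tests on the
  four biomarkers, with the published per-lung values shipped as
  `lungBiomarkerTable()`;
- `runExperiment()` — the full simulated cohort study, deterministic under
  a seed.

## Worked example

Simulate one control lung, reconstruct, map T1 and decompose the
histogram:

```r
library(squareT1)
gt    <- makePhantom(phantomSpec("control", seed = 7))
ks    <- simulateDelaySeries(gt, acquisitionParams(), seed = 7)
imgs  <- reconstructSeries(ks, truncateTo = c(32L, NA))
t1map <- buildT1Map(imgs)
t1map
#> T1Map: 64 x 64 px, 1647 in ROI, 1647 valid (0 < T1 <= 6 s)
#>   masked T1: median 1.071 s, IQR 1.023 - 1.192 s
fitBimodal(binT1(t1map))
#> BimodalFit
#>   fast: EV 1.0359 s, FWHM 0.0984 s, amplitude 258.6
#>   slow: EV 1.2041 s, FWHM 0.3957 s, amplitude 52.2
#>   RMS residual 4.96 counts
```

The fast mode (alveolar gas, EV ≈ 1.04 s) and slow mode (airway gas,
EV ≈ 1.20 s) recover the phantom's control-lung presets up to the
partial-volume mixing of the reconstruction point-spread function.

Group statistics on the shipped per-lung biomarker table (the atypical
elastase lung is excluded by default, as published):

```r
compareGroups(lungBiomarkerTable())
#>      metric mean_control sd_control mean_elastase sd_elastase statistic df  p_value reject
#> 1   ev_fast       1.0062   0.009168        1.2536     0.08795   -4.7364  5 0.005167   TRUE
#> 2 fwhm_fast       0.1458   0.052598        0.2336     0.07926   -1.6472  5 0.160434  FALSE
#> 3   ev_slow       1.2699   0.074641        1.7009     0.24926   -2.8389  5 0.036295   TRUE
#> 4 fwhm_slow       0.4401   0.124420        0.5514     0.16736   -0.9606  5 0.380856  FALSE
```

The expected values reject the null hypothesis of no group difference at
α = 0.05; the widths do not — EV(T1) is the useful biomarker for this
emphysema model.

A full simulated cohort (3 control + 4 elastase lungs) with per-lung
fits, group comparison and provenance output:

```r
res <- runExperiment(seed = 1, outDir = "square-run")
res$comparison
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --seed 1 --out square-run`.

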