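---
title: "SQUARE T1 mapping of hyperpolarized 83Kr lung MRI: models and methods"
author: "squareT1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SQUARE T1 mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squareT1)
```

## The contrast mechanism

Gas-phase ^83^Kr has a quadrupolar nucleus (spin 9/2). Far from any
surface its longitudinal relaxation time T~1~ is minutes, but transient
adsorption on a surface distorts the electron cloud, relaxes the nucleus,
and rapid exchange carries the depolarization back into the gas. This
surface quadrupolar relaxation (SQUARE) makes the gas-phase T~1~ scale with
the available gas volume per unit surface,

$$T_1 = \kappa \, \frac{V}{S},$$

so the high surface-to-volume (S/V) alveolar airspaces of a healthy lung
relax fast (T~1~ near 1 s in the rat) while the conducting airways relax
slowly. Emphysema enlarges alveoli — the mean alveolar area (MAA) measured
by histology grows — lowering S/V and lengthening the alveolar T~1~. The
package treats the alveolar linear scale as $\sqrt{MAA}$, so
$T_1 \propto MAA^{e}$ with the exponent $e = 0.5$ by default
(`svExponent`, configurable because the exact MAA-to-S/V map in tissue is
not quantitatively established; see `t1FromSV()` and `svFromMAA()`).

Because hyperpolarized magnetization is non-renewable, every image in a
delay series comes from a fresh inhalation: after a programmed
post-inhalation delay $\tau_d$ the remaining longitudinal magnetization is
$m_0 e^{-\tau_d/T_1}$, and varying $\tau_d$ (0.2, 0.7, 1.2, 1.7, 2.2 s by
default; a 0.5–2.0 s four-point scheme is also supported) encodes T~1~ in
the image intensities.

## The digital phantom and acquisition simulator

`makePhantom()` builds a stylized 2-D coronal lung on a 64 × 64 grid over a
50.9 × 40.7 mm field of view: a trachea (about 3.5 mm across), two
main-stem bronchi and one lobar branch per side over two elliptical lung
fields. Airway pixels draw T~1~ from the slow mode, parenchymal pixels from
the fast mode; the modes are Gaussians whose centres (EV) and full widths
at half maximum (FWHM) default to the group-average values of the
biomarker table shipped with the package (`modePresets()`): control
1.0062 s / 0.1458 s (fast) and 1.2699 s / 0.4401 s (slow); elastase
1.2536 s / 0.2336 s and 1.7009 s / 0.5514 s.

The per-pixel T~1~ deviations form a Gaussian random field with a spatial
correlation length of 3 pixels (exact unit marginal variance by
construction). Two reasons: disease-related T~1~ change is regional, not
pixel-to-pixel white noise; and a spatially white T~1~ field would be
averaged away by the reconstruction point-spread function, leaving
histograms far narrower than any real lung produces.

`simulateDelaySeries()` models the single-inhalation variable-flip-angle
(VFA) FLASH acquisition (TE 1.8 ms, TR 12.6 ms, 64 read × 32 phase-encode
matrix). The VFA schedule $\theta_j = \arctan(1/\sqrt{n-j})$ consumes equal
fractions of the remaining magnetization, so each of the $n$ k-space lines
yields the constant transverse signal $m_z/\sqrt{n}$ (`vfaSchedule()`; the
constancy is asserted to 10^-12^ in the tests). The image-domain signal —
apparent polarization × $m_0 e^{-\tau_d/T_1}/\sqrt{n}$ — is Fourier
transformed (unitary, DC at the grid centre) and the central
`nRead × nPhase` block is kept. Complex Gaussian noise in k-space produces
Rician magnitude noise; its scale `noiseSigma` is expressed relative to the
peak signal of the shortest-delay frame, and the default 0.02 (peak SNR
50) was chosen so that the fitted-T1 scatter it adds stays well below the
ground-truth mode widths, which the published between-lung table already
fixes. The protocol tolerated a roughly ±0.2 s manual-inhalation timing
error; `timingJitter` reproduces it as zero-mean uniform shifts of the
realised delays while the analysis always uses the nominal ones.

Jitter is **off** in the default cohort conditions, deliberately.
Independent ±0.2 s shifts of five delays spanning 2 s perturb the slope of
the decay regression by up to tens of percent, i.e. they shift a whole
lung's fitted-T1 map by up to ±0.4 s. The published per-lung biomarkers
vary between lungs by only 0.009–0.249 s (standard deviations), and the
cohort generator already draws each lung's mode parameters from those
observed between-lung spreads — which subsume whatever timing error
contributed in reality. Simulating the full jitter on top would
double-count that variance and produce cohorts visibly unlike the
published ones. The switch remains available for sensitivity studies, as
does optional intra-scan T~1~ decay across the phase-encode train (off by
default; the 0.4 s readout was designed to make it negligible).

## Reconstruction

`reconstructFrame()` reproduces the published processing chain: the raw
frame (optionally truncated to its central 32-point read block, matching
the processing actually applied to the 64-point read acquisitions) is
apodized with the separable sine-bell squared window
$w(k) = \sin^2\!\big(\pi (k + \tfrac12)/N\big)$, zero filled to 64 points
per dimension with the DC sample kept at the grid centre, inverse Fourier
transformed (unitary) and taken to magnitude. The half-sample window
offset makes $w$ exactly symmetric with no zeroed edge sample; the unitary
normalization makes Parseval checks exact; centred zero filling is the
standard MRI convention. The 50.9 × 40.7 mm field of view over 64 points
gives 0.795 × 0.636 mm pixels.

## T1 mapping and its filters

`buildT1Map()` fits $S(\tau_d) = S_0 e^{-\tau_d/T_1}$ per pixel by
nonlinear least squares (Levenberg–Marquardt) initialised from the
log-linear regression of $\log S$ on $\tau_d$ — exact on clean data,
robust at low SNR. The model has no offset term, so the Rician noise floor
is ignored; at the default SNR this biases only near-empty pixels, which
the region filters remove. Fits use magnitude data and nominal delays.
Three filters define the valid mask: the fit must converge to positive
estimates; T~1~ must lie in the physically meaningful window
$0 < T_1 \le 6$ s (inclusive upper bound, with a 10^-9^ relative epsilon so
estimates sitting numerically on the bound are kept); and the pixel must
lie in the lung-contour region of interest. The ROI comes from the
shortest-delay image: threshold at 0.4 of the 99th-percentile intensity,
remove components under 9 pixels, close interior holes. The threshold was
calibrated once on noise-free phantoms (Dice ≈ 0.98 against the
ground-truth ventilated mask); on real data a threshold this high could
drop poorly ventilated regions, which is the accepted behaviour of an
intensity-based lung contour.

## Histogram decomposition

Masked T~1~ values are binned into 200 intervals of 0.03 s — exactly the
0–6 s acceptance window, with on-edge values assigned to the lower bin so
that T~1~ = 6 s lands in the last bin. `fitBimodal()` models the bin-centre
counts as two Gaussians (alveolar fast mode, airway slow mode) by
unweighted least squares and reports EV = μ and FWHM = $2\sqrt{2\ln 2}\,σ$
per mode, ordered fast < slow.

Automated peak picking initialises the fit: counts are smoothed with a
5-bin moving average; the two tallest local maxima at least 3 bins apart
seed the centres; if only one free-standing maximum exists, local minima
of the second difference (strong negative curvature) are searched for a
merged shoulder — necessary because a broad slow mode often rides on the
fast peak's flank rather than forming its own maximum, and this is how
vendor multipeak auto-detection finds partially merged components.
Initial widths come from local half-height widths (capped at the peak
separation), amplitudes from peak heights. After convergence a fit is
declared degenerate — and refitted as a single Gaussian, never silently
forced bimodal — if a component's FWHM exceeds 2 s (a pseudo-baseline), the
centres collapse within 3 bins, or one amplitude falls under 2% of the
other. Unweighted bin-centre fitting with a zero baseline mirrors generic
multipeak behaviour; weighting schemes were not used.

## Group statistics

`compareGroups()` summarises each biomarker as mean ± sample standard
deviation per group and applies the two-sided pooled-variance Student's
t-test at α = 0.05 (Welch's variant behind `varEqual = FALSE`; the
equal-variance form is the published choice). No multiple-testing
correction is applied across the four biomarkers — decisions are
per-metric, a documented limitation. The shipped `lungBiomarkerTable()`
excludes by default the one elastase lung whose disease developed in a
single lobe only, matching the published analysis; it can be restored with
`includeExcluded = TRUE`.

A note on cross-checking with an exact permutation test: with groups of 3
and 4 lungs there are only 35 distinct assignments, so the smallest
achievable two-sided permutation p-value is 1/35 ≈ 0.029 and the next is
2/35 ≈ 0.057. For the slow-mode EV the observed split is the second most
extreme, so the permutation p (0.057) sits just above α = 0.05 while
Student's t rejects (p = 0.036). That is discreteness of the exact test at
tiny n, not a contradiction; the permutation oracle agrees with the
t-decisions for the other three biomarkers and the test suite records
both facts.

## What the simulator does and does not establish

The generator reproduces: the bimodal T~1~ structure with published mode
parameters and between-lung spread, the exponential delay encoding, the
VFA signal budget, k-space truncation/apodization/zero-filling artefacts,
Rician noise, ventilation defects (zero-signal regions) and the MAA
coupling of the alveolar mode. It does not reproduce: real anatomy (the
geometry is stylized; SQUARE contrast depends only on the T~1~ and m~0~
fields), gas-flow and ventilation mechanics, diffusion, B~1~ or flip-angle
miscalibration, or the Rician noise floor's interaction with very long
delays. Passing tests therefore validate the analysis chain and its
filters, not the physiology: per-lung EV/FWHM values from the real study
cannot be regenerated without the raw data, and the cohort-level checks
are property-based (group ordering and overlap) rather than numeric
reproductions.

Partial-volume mixing is a real and intended effect: the reconstruction
PSF averages thin airways with surrounding parenchyma, pulling the fitted
slow mode below its ground-truth centre and occasionally leaving it
undetectable in a small lung (a degenerate fit). Exact ground-truth
recovery is only claimed — and tested to 10^-6^ relative — where it is
mathematically exact: on a spatially uniform (flat) T~1~ phantom the delay
dependence is a global positive scalar, so the linear reconstruction
distorts every frame identically and per-pixel intensity ratios are
preserved through the full apodized chain. The same distortion-free
round trip underlies `makeFixtures()`, which stores its 16 × 16 series
without apodization so the stored frames fit back to the stored truth
exactly.

## Problem sizes and tolerances

The shipped tests run the full pipeline at the study's native sizes
(64 × 64 grid, 64 × 32 acquisition, 5 delays, 3 + 4 lungs) for the
cohort-level checks, and smaller 16–32 pixel grids for unit-level round
trips; Monte-Carlo checks use 200–1000 replicates at 1% noise. Optimizer
tolerances are minpack defaults with 100 (pixel fits) and 500 (histogram
fits) iteration caps; noise-free recoveries are asserted at 10^-6^
relative, analytic identities at 10^-8^–10^-12^.
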