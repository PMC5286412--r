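---
title: "Quantifying adipose tissue browning from optical measurements"
author: "adipoptics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipose tissue browning from optical measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoptics)
```

## The measurement problem

White adipose tissue (WAT) stores lipid in large unilocular droplets;
brown adipose tissue (BAT) is packed with mitochondria and burns energy.
Under beta3-adrenergic stimulation (e.g. CL 316,243), a subpopulation of
white adipocytes "browns": it turns UCP1-positive and acquires BAT-like
morphology. Browning is classically quantified by qPCR and
immunohistochemistry, which are slow and destructive. Diffuse reflectance
spectroscopy (DRS) and multispectral imaging (MSI) offer a fast optical
read-out: browning tissue gains hemoglobin and mitochondrial pigments
that absorb strongly around 550 nm (the hemoglobin Q-bands), while near
680 nm all adipose classes reflect similarly.

`adipoptics` implements the full quantification chain for three assays —
DRS, MSI and qPCR — plus a calibrated phantom generator so the pipeline
can be validated end to end with known ground truth.

## The DRS model

A spectrometer acquisition session yields three spectra on a common
wavelength grid (450–700 nm, 1 nm steps by default): a dark spectrum $D$
(lamp off), a reference spectrum $W$ from a diffuse reflectance standard,
and the tissue spectrum $S$. Diffuse reflectance is

$$R(\lambda) = \frac{S(\lambda) - D(\lambda)}{W(\lambda) - D(\lambda)},$$

with grid points where $W - D \le \varepsilon$ masked as unreliable
($\varepsilon = 10^{-6}\max(W-D)$ by default). Two indices summarize
browning:

* **Intensity ratio** $R(680)/R(550)$, computed as the ratio of mean
  reflectance in $\pm 2$ nm bands around the two wavelengths. Band means
  (not single pixels) are used for noise robustness; the half-width is
  configurable. The ratio is invariant to global rescaling of $R$, so it
  is computed on the unnormalized reflectance.
* **Band slope**: the ordinary least-squares slope of the
  680 nm-normalized reflectance against wavelength over 570–630 nm,
  reported per 100 nm. Normalizing at 680 nm first makes the slope
  illumination-invariant; on this scale the control-WAT to control-BAT
  range is roughly 0.19–0.44. An optional post-hoc rescaling by the
  control-WAT group mean is provided (off by default, because the
  headline values are on the per-100 nm scale, not relative to control
  WAT).

Indices are computed per probe location, then averaged per sample
(unweighted mean); the per-location values are retained as a
within-sample dispersion diagnostic. For noise-free data this choice is
indistinguishable from computing indices on the mean spectrum; for noisy
data it additionally yields a QC signal, which is why it was chosen.
Masked points inside the slope window are dropped from the fit rather
than interpolated.

## The MSI model

Band-pass images at 550, 600 and 680 nm are quantified by the arithmetic
mean pixel intensity over one fixed region of interest (ROI) shared by
all images in a run. Raw 8-bit ROI means are reported by default; the
550 nm group levels of interest run from about 48 (control WAT) down to
about 20 (control BAT). Normalization of each sample to the control-WAT
group mean at the same band is available but off by default: reporting
the control class at 1.0 would discard the absolute scale that the raw
levels carry. RGB frames collapse to grayscale by the unweighted channel
mean (under narrow band-pass illumination the camera's color response is
uninformative); Rec. 601 luma weights are available.

## The qPCR model

Relative expression uses the standard Livak $2^{-\Delta\Delta C_t}$
method: $\Delta C_t = C_t^{\text{target}} - C_t^{\text{reference}}$
per sample (reference gene beta-actin), $\Delta\Delta C_t$ relative to
the mean control $\Delta C_t$ of the same tissue and day, and the
reported fold is the geometric mean of $2^{-\Delta\Delta C_t}$ over the
group — folds are log-scale quantities, so uncertainty is propagated in
log2 space and reported both as `se_log2` and as a delta-method linear
`se_fold`. Technical replicates are averaged (arithmetic mean of
$C_t$) before analysis. No amplification-efficiency correction is
applied (no efficiencies are modelled). The control group's fold is 1 by
construction.

## Group statistics

All assays are summarized as mean ± SE per (group, tissue, day) cell,
with pooled control cells (day "4+7") for control WAT and BAT — the
convention under which control tissue is reported. Omnibus comparison is
a classical one-way fixed-effects ANOVA (Welch is deliberately not the
default), with Tukey HSD pairwise correction by default and Bonferroni by
flag; the correction used is recorded in the output rather than asserted
to match any particular historical analysis. Stars follow the
figure convention: `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.

## What the phantom generator emulates

The generator replaces mouse tissue with phantoms whose ground truth is
the set of published-scale group statistics, one template per class:

| class | ratio | slope (/100 nm) | 550 nm ROI level |
|---|---|---|---|
| C_WAT | 1.08 | 0.19 | 48 |
| TrWAT_d4 | 1.17 | 0.30 | 33 |
| TrWAT_d7 | 1.33 | 0.36 | 23 |
| C_BAT (= TrBAT) | 2.36 | 0.44 | 20 |

Each spectral template is built from anchors $T(680)=T(700)=1$,
$T(550)=1/\rho$, $T(570)=\min(1/\rho,\,1-0.6s)-0.05$,
$T(630)=T(570)+0.6s$, $T(450)=0.9\,T(550)$, joined by monotone Hermite
interpolation. Three numerical choices make the calibration *exact*
rather than approximate: short plateaus at 548–552 and 678–682 nm so the
±2 nm band means equal the anchor values; an exactly linear 570–630 nm
segment so the least-squares slope equals $s$; and the dip below
$1/\rho$ near 570 nm, which mimics the hemoglobin Q-band absorption that
shapes real adipose spectra. Slope units are normalized reflectance per
100 nm — the scale on which the 0.19–0.44 range is plausible for
680-normalized spectra.

Raw acquisitions are synthesized as $D = d$, $W = d + g\,L(\lambda)$
with a smooth broadband lamp profile $L$ (a broad quartic peaking near
600 nm; its shape divides out in the correction), and
$S = D + (W-D)\,T(\lambda)(1+\varepsilon_m) + \varepsilon_a$ with
per-point multiplicative noise of coefficient of variation `cv` and
optional additive detector noise. With zero noise the corrected
reflectance reproduces the template exactly, which is the basis of the
exactness tests.

MSI levels are *independent* generator parameters, not derived from the
spectral templates: the published-scale ROI means and intensity ratios
are not mutually consistent under any single illumination gain, and the
generator does not force a consistency the data do not claim. At 680 nm
all classes share one level (50), at 600 nm levels interpolate linearly
in wavelength. Ct tables place the reference gene at 18 cycles, control
targets at 26, and shift treated targets down by $\log_2(\text{fold})$.

Defaults — 8 mice per class, 5 probe locations per sample, `cv = 0.02`,
`ct_sd = 0.15` cycles, `texture_sd = 3` (8-bit units), 64×64 ROI —
reproduce group SEs of the same order as the study's error bars with
n = 4–8 per group. All randomness derives from one master seed via
documented stream splitting (`derive_seed`), so identical seeds give
bitwise-identical datasets and byte-identical report CSVs.

**What passing on phantoms does not show.** The phantoms have exactly
the published spectral shape family, homogeneous ROIs, Gaussian noise
and no specular reflection, probe-pressure, hydration or depth effects.
Recovery on phantoms validates the *computation* — correction, indices,
ROI means, ddCt, statistics — not the biology or the instrument; real
tissue adds variability the generator deliberately does not model
(no radiative-transfer or photon-transport physics, no camera color
response).

## Degenerate inputs and edge policies

* Spectra never extrapolate: a grid point outside the measured range is
  an error, not a silent clip.
* A reference that nowhere exceeds dark is a degenerate-input error; a
  masked or non-positive 680 nm point blocks normalization.
* Fewer than 3 unmasked points in the slope window is an error.
* Zero within-group variance with unequal means is flagged `degenerate`
  in the ANOVA result (F reported as infinite, p as 0).
* Singleton groups report `se = NA` rather than 0.

## Worked example

```{r example, eval = FALSE}
cfg <- list(n_mice = 8, n_locations = 5, cv = 0.02, seed = 1,
            out_dir = "browning-report")
res <- run_pipeline(cfg)
subset(res$drs_summary, metric == "ratio" & day %in% c("4+7", "4", "7"))
res$qpcr[res$qpcr$group == "Tr", c("gene", "day", "fold", "se_fold")]
```

The validation suite exercises this pipeline at the same problem sizes
(8 samples × 5 locations per class; 64×64 ROI images; n = 8 Ct tables),
which keeps every check well under a minute while leaving group-mean
Monte-Carlo error far below the tolerances being tested. No empirical
number is quoted here that the tests and `scripts/acceptance.R` do not
recompute.

## Known limitations

* The intensity ratio and the MSI levels are calibrated independently;
  the package makes no attempt to reconcile the two modalities.
* Classical (not Welch) ANOVA is the default; with strongly unequal
  variances use `correction = "bonferroni"` on Welch-style judgement or
  treat pairwise p values with care.
* The ddCt model assumes equal amplification efficiency across genes.
* Error bars on folds are reported in both log2 and linear scales; which
  scale a given publication plots is often unstated, so both are kept.
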