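---
title: "Quantifying membrane cholesterol from GP and FLIM readouts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane cholesterol from GP and FLIM readouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvchol)
```

## The measurement problem

Cholesterol content is a first-order determinant of lipid-membrane packing,
but in giant unilamellar vesicles (GUVs) made by emulsion-based methods it
cannot be read off the stock lipid composition: cholesterol partitions into
the oil phase and is incorporated poorly. Delivering cholesterol after
vesicle formation with methyl-β-cyclodextrin carriers works, but then the
amount actually incorporated must be measured *in situ*. Two environment-
sensitive probes make this possible without destroying the vesicles:

* **NR12A**, a solvatochromic Nile-Red derivative whose emission spectrum
  blue-shifts as the membrane becomes more ordered and less hydrated. The
  spectral position is summarized by the generalized polarization
  $$\mathrm{GP} = \frac{I_B - I_R}{I_B + I_R},$$
  with $I_B$ and $I_R$ the intensities at a blue (570 nm) and red (640 nm)
  analysis wavelength. Higher GP means a more ordered membrane.
* **Flipper-TR**, a mechanosensitive probe whose fluorescence lifetime
  lengthens with lateral packing pressure. Decays are biexponential; the
  reported quantity is the intensity-weighted mean lifetime
  $$\tau_{m,\mathrm{int}} = \frac{\sum_k I_k \tau_k}{\sum_k I_k}, \qquad k = 1, 2.$$

Both readouts increase roughly linearly with mol% cholesterol over the
0--40 mol% range, so a linear calibration $y = c + m x$ fitted to reference
GUVs of known composition (made by gel-assisted swelling, which incorporates
cholesterol faithfully) can be inverted, $\hat x = (y - c)/m$, to estimate
the cholesterol content of unknown vesicles.

This package implements the complete chain -- spectral-stack GP analysis,
TCSPC reconvolution fitting and phasor analysis, calibration fitting,
inversion and error propagation -- together with a synthetic phantom
generator that emulates the microscope well enough to validate every stage
against known ground truth.

## Spectral GP pipeline

`run_gp_pipeline()` composes the stages in a fixed order, mirroring how
spectral stacks of equatorial GUV sections are commonly processed:

1. **Channel registration** (`register_stack()`): each of the 14 spectral
   channels is aligned to the brightest channel by FFT cross-correlation,
   and the integer part of the estimated translation is applied as a
   circular shift, which preserves photon counts exactly. We use plain
   (mean-subtracted) cross-correlation rather than spectrally whitened
   phase correlation: the channels share structure but carry independent
   Poisson noise, which whitening amplifies to the point of off-by-one peak
   errors on dim channels. Subpixel estimates (parabolic interpolation of
   the correlation peak) are reported but not applied, since interpolation
   would redistribute counts. Shifts above a 16 px cap are refused with a
   warning -- a structureless channel can produce an arbitrary peak.
2. **Maximum-intensity projection** across channels.
3. **Bright-outlier exclusion**: saturated pixels or bright debris are
   flagged either above an absolute count or above an upper quantile of the
   nonzero pixels (default: 99.9th percentile). Both modes exist because
   acquisition pipelines differ in whether saturation has a known count
   value; excluding more than half of the nonzero pixels is treated as a
   configuration error.
4. **Contrast stretch** to $[0,1]$ between the 1st and 99th intensity
   percentiles (defaults; the stretch is monotone, so it changes no
   ordering, only conditions the histogram for thresholding).
5. **Otsu segmentation** on a 256-bin histogram (via `EBImage::otsu`),
   minus the exclusion mask. If the mask has several connected components
   (several vesicles in the field), the largest is kept and the count is
   reported -- the pipeline assumes one vesicle per record.
6. **Pixel-wise GP** between the channels nearest 570 and 640 nm. On the
   565, 575, ..., 695 nm band-centre grid both analysis wavelengths are
   exactly equidistant between two channels; ties break toward the shorter
   wavelength (565 and 635 nm), and the channels actually used are logged.
   Pixels with $I_B + I_R < 10$ counts are dropped from the mask: the
   ratio-of-counts estimator is strongly biased at low counts, and the
   floor, together with its count, is recorded.
7. **Vesicle mean**: the unweighted mean over defined GP pixels.

Linearly polarized excitation makes ring arcs parallel to the polarization
axis brighter than perpendicular ones (photoselection). Because the
modulation is wavelength-independent, per-pixel GP is unaffected in
expectation; averaging over the whole ring smooths the artifact out of the
per-vesicle mean. Bright arcs do contribute more above-floor pixels, so the
pixel mean weights them slightly more -- accepted here, since ring-angle
averaging is precisely what the per-vesicle mean is meant to do.

## TCSPC reconvolution fitting

`fit_reconvolution()` maximizes the Poisson likelihood of
$$\mu_j = \Big[\mathrm{IRF} \circledast \sum_k I_k e^{-t/\tau_k}\Big]_j + b/n,$$
over the fit window (default 0.2--45 ns of a 50 ns period), where
$\circledast$ is circular convolution on the period. Poisson likelihood is
the correct objective for counting data; least-squares alternatives
underweight the decay tail. Implementation choices that matter:

* The exponential kernel uses the exact geometric-sum closed form of the
  periodically wrapped decay, integrated over each bin, so there is no
  truncation error from summing a finite number of preceding periods.
* The IRF enters as measured bin masses; convolution aligns IRF bin centres
  with kernel bin intervals, making the forward model exact for an IRF
  concentrated at bin centres. On 256 bins (0.195 ns) the residual
  discretisation error is well below the 0.1% recovery target for
  noise-free data.
* Parameters (component intensities, lifetimes, uniform background) are
  optimized on the log scale with `optim(method = "L-BFGS-B")` from three
  deterministic starts derived from a method-of-moments lifetime guess
  (mean arrival time minus IRF centroid, split ×0.5/×2); no randomness
  enters the fit. The background is free because photon-counting detectors
  still have dark counts.
* Components are reported sorted by lifetime; a component below $10^{-3}$
  of the total intensity is collapsed, so monoexponential truth degrades
  gracefully. A uniform histogram (no decay) is fitted as background plus,
  possibly, components at lifetimes far beyond the period -- which are also
  uniform; tests assert flatness of the model rather than a particular
  allocation between the two, since they are not identifiable.
* Parameter covariance comes from the observed information (numerical
  Hessian of the negative log-likelihood on the log scale, delta-transformed
  back); fits with fewer than 500 photons in the window are refused.

`run_flim_pipeline()` fits one aggregate decay per vesicle, matching the
one-lifetime-per-GUV reporting convention; per-pixel analysis is reserved
for the phasor route.

## Phasor analysis

`phasor_transform()` maps a decay to
$g = \sum c_i \cos(\omega t_i)/\sum c_i$,
$s = \sum c_i \sin(\omega t_i)/\sum c_i$ at the repetition frequency, and
divides the complex phasor by the IRF's phasor, which removes the
instrument phase delay and modulation loss. Monoexponentials then satisfy
$g^2 + s^2 = g$ (the universal semicircle); mixtures lie on chords inside
it, and the transform is linear in photons.

A numerical caveat documented here because tests rely on it: the discrete
bin-centred phasor of an $n$-bin histogram sits off the semicircle by
$O((\omega\Delta t)^2/8)$ -- about $7\times10^{-5}$ at 256 bins. This is a
property of binning, not of the transform, so the $10^{-6}$ semicircle
identity is asserted on finely binned (4096-bin) noise-free decays, where
the discretisation term is below $5\times10^{-7}$. Analyses of real 256-bin
histograms carry the (entirely negligible for lifetime contrast) 256-bin
version of this bias.

For phase-separated vesicles, `phasor_image()` computes per-pixel phasors,
`denoise_phasor()` median-filters the $g$ and $s$ images (3×3 at strength
1), and `select_phasor_cloud()` collects pixels inside a circle in phasor
space and reports the phase lifetime of the photon-weighted mean phasor,
$\tau_\phi = \bar s/(\omega \bar g)$. The median filter is an explicit,
documented stand-in for proprietary "wavelet" denoising found in vendor
FLIM software, whose algorithm is unpublished; likewise the selection
radius is specified in $(g, s)$ units (default 0.02) because vendor
"screen-unit" radii have no published conversion.

## Calibration, inversion and error propagation

`fit_calibration()` fits $y = c + mx$ to per-condition mean readouts by
weighted least squares with weights $1/\mathrm{SD}^2$ (default) or equal
weights. Inverse-variance weighting of condition means is the default
because it reproduces published fit parameters for this kind of data where
unweighted fitting of the means does not. Standard errors follow the
`stats::lm` convention (scaled by residual reduced $\chi^2$), which is also
what common fitting software reports. The unscaled, known-variance
covariance $(X^\top W X)^{-1}$ is the appropriate reference when the
weights are true inverse variances, and the parameter-recovery test uses it
for coverage checking.

`propagate_error()` applies the delta method to $\hat x = (y - c)/m$ with
$\sigma_y = \mathrm{SD}/\sqrt{n}$ (SEM of the condition mean):
$$\sigma_x^2 = \frac{\sigma_y^2 + \mathrm{se}_c^2}{m^2}
 + \frac{\hat x^2\,\mathrm{se}_m^2}{m^2}
 + \frac{2\hat x\,\mathrm{cov}(c,m)}{m^2}.$$
The covariance cross-term carries a plus sign -- both partial derivatives
$\partial \hat x/\partial c$ and $\partial \hat x/\partial m$ are negative
-- and since $\mathrm{cov}(c,m)$ is itself negative for positive mean
abscissa, the term usually shrinks the variance. SEM (not per-vesicle SD)
enters because the quantity being inverted is a condition mean; a
covariance-free mode is provided for comparison with propagation from
quoted parameter errors alone. `estimate_conditions()` assembles
per-condition and per-vesicle estimates, runs a Kruskal--Wallis test of the
condition effect per modality (χ² approximation -- standard at ≥50
vesicles per group; no post-hoc pairwise testing), and, when both probes
are analysed, compares the two methods' sets of per-condition estimates
with a Kruskal--Wallis test. The method comparison deliberately operates on
condition-level estimates: the two probes have very different per-vesicle
scatter in cholesterol units (the GP route divides an SD of ~0.1 GP by a
slope of ~0.01 GP/mol%), so a per-vesicle rank test between methods within
one condition would mostly measure that scatter difference rather than
method agreement.

## The phantom generator

`simulate_spectral_stack()` and `simulate_decay()` generate data with known
ground truth under the acquisition geometry the pipelines expect: 14
spectral channels (560--700 nm in 10 nm bands) on a 256×256 px field, and
256-bin TCSPC histograms over a 50 ns period (20 MHz repetition) with a
Gaussian IRF (FWHM 0.2 ns, centred at 2 ns -- a standard desk substitute
for an uncharacterized measured IRF).

Design choices, fixed once:

* **Spectrum**: each membrane pixel emits a mixture of two Gaussian bands
  at 580 and 635 nm with FWHM 35 nm; the mixture weight is solved per
  phantom so the intensity ratio at the analysis channels equals
  $(1+\mathrm{GP})/(1-\mathrm{GP})$ exactly. Only the two analysis channels
  matter to GP; intermediate channels only need to be smooth. The 35 nm
  width is interpreted as FWHM because that choice makes nearly the whole
  $(-1, 1)$ GP range representable with nonnegative intensities, so
  condition draws from realistic statistics can never leave the model's
  gamut.
* **Ring**: radial Gaussian of $\sigma = \mathrm{width}/2.355$ around the
  circle -- a diffraction-limited membrane cross-section.
* **Photoselection**: multiplicative $(1-d) + d\cos^2(\theta-\theta_0)$
  with default depth $d = 0.6$, reproducing the bright-parallel /
  dim-perpendicular pattern without polarization physics.
* **Brightness**: 600 expected photons (summed over channels) at the
  brightest membrane pixel and 2 background counts per pixel -- photon-
  counting-mode scales at which the pipeline's GP bias is well under 0.02.
* **Decays**: intensity fractions and lifetimes are exact inputs; counts
  are ideal Poisson draws. Pile-up is deliberately not simulated: the
  acquisition regime being emulated keeps rates below 0.5 photons per
  pulse precisely so that pile-up is negligible.
* **Condition batches** (`simulate_condition_batch()`): per-vesicle true
  readouts are drawn from Normal(mean, SD) with GP clamped to $(-1,1)$ and
  lifetimes kept positive; geometry (radius 40--75 px, centre jitter, ring
  width 3--5 px) is randomized per vesicle. A drawn lifetime truth is
  realised as a biexponential with intensity fractions (0.35, 0.65) and
  component lifetimes (0.5, 1.2692)×τ, which emulates the probe's
  biexponential character while keeping the intensity-weighted mean exactly
  at the drawn truth. Per-vesicle seeds derive from the batch seed by a
  counter scheme, so vesicle $i$ is reproducible independently of batch
  size or order.

What the phantoms do **not** emulate -- and hence what passing recovery
tests do not establish about real data: optical blur beyond the ring
profile (no PSF), detector afterpulsing and pile-up, spectral bleed of a
real probe outside the two-band shape, chromatic misregistration beyond
pure translation, membrane undulations, multi-vesicle clutter and debris,
and any systematic difference between gel-swelling calibration membranes
and emulsion-made membranes (residual oil). The recovery experiments
validate the estimators under the stated noise model, not the microscope.

## Problem sizes and runtime

The shipped tests and the acceptance script use the study-scale condition
size of 50 vesicles per condition, full 256×256 px spectral phantoms, and
$10^5$-photon decays; the biexponential accuracy benchmark runs 100
replicates. The full suite completes in roughly three minutes on one core;
the acceptance script in about one.

## Known limitations

* The calibration is linear and bounded to 0--40 mol% cholesterol; near the
  ~60 mol% solubility limit the readout--composition relation is not linear
  and lateral heterogeneity invalidates a single-number estimate.
* Phase-separated vesicles violate the single-phase assumption of the
  calibration inversion; the phasor tooling separates domains but no
  domain-resolved cholesterol estimation is attempted.
* The reconvolution fitter is limited to two components, matching the
  reporting convention for this probe; systems needing three or more
  components need a different tool.
* Registration is translation-only; rotational or scaling drift between
  spectral channels is outside its model.
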