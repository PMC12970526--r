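# guvchol

Quantify cholesterol incorporation in the membranes of giant unilamellar
vesicles (GUVs) from two complementary fluorescence microscopy readouts,
and validate the whole analysis chain on synthetic phantoms with known
ground truth.

Emulsion-based GUV production methods (such as eDICE) incorporate
cholesterol poorly, so cholesterol is delivered to preformed vesicles with
methyl-β-cyclodextrin carriers — and the amount actually reaching the
membrane must then be measured *in situ*. Two environment-sensitive probes
report on it:

* **NR12A** (solvatochromic): its emission spectrum blue-shifts as packing
  increases, summarized by the generalized polarization
  `GP = (I_B − I_R)/(I_B + I_R)` between 570 nm and 640 nm emission.
* **Flipper-TR** (mechanosensitive): its fluorescence lifetime lengthens
  with lateral packing pressure, summarized by the intensity-weighted mean
  lifetime `τ_m,int = Σ I_k τ_k / Σ I_k` of a biexponential reconvolution
  fit to the TCSPC decay.

Both readouts grow linearly with mol% cholesterol over 0–40 mol%, so a
weighted linear calibration `y = c + m·x` fitted to reference GUVs of known
composition can be inverted, `x̂ = (y − c)/m`, with delta-method error
propagation, to estimate membrane cholesterol in mol%.

The package implements, per module:

| Stage | Functions |
|---|---|
| Spectral GP pipeline | `register_stack()`, `max_projection()`, `exclude_bright_outliers()`, `contrast_stretch()`, `otsu_mask()`, `compute_gp()`, `vesicle_mean_gp()`, `run_gp_pipeline()` |
| FLIM | `fit_reconvolution()`, `tau_m_int()`, `run_flim_pipeline()`, `phasor_transform()`, `phasor_image()`, `denoise_phasor()`, `select_phasor_cloud()` |
| Calibration | `fit_calibration()`, `invert_calibration()`, `propagate_error()`, `kruskal_wallis()`, `estimate_conditions()` |
| Phantoms | `simulate_spectral_stack()`, `simulate_decay()`, `simulate_condition_batch()`, `simulate_two_domain_vesicle()` |
| I/O + orchestration | `save_stack()`/`load_stack()`, `save_decay()`/`load_decay()`, `save_table()`/`load_table()`, `experiment_config()`, `run_experiment()` |

Reference measurement tables (calibration series and per-condition
statistics) ship in `inst/extdata/` and load via `guv_reference_table()`.

## Worked example

```r
library(guvchol)

# calibration lines from the bundled gel-swelling reference series
m_gp <- fit_calibration(calibration_points("GP"))
m_lt <- fit_calibration(calibration_points("lifetime"))
m_gp
#> <calibration_model> readout = -0.5395 (+/- 0.015) + 0.01041 (+/- 0.00091) * mol%  [invvar weights, n = 4]
m_lt
#> <calibration_model> readout = 2.921 (+/- 0.019) + 0.03758 (+/- 0.002) * mol%  [invvar weights, n = 4]

# a synthetic GUV with true GP -0.44, analysed by the full spectral pipeline
ph  <- simulate_spectral_stack(spectral_phantom_spec(gp_true = -0.44, seed = 42))
res <- run_gp_pipeline(ph$stack)
res$record
#>   vesicle_id condition modality      value n_pixels replicate
#> 1          1      <NA>       GP -0.4417811     1816        NA

# invert a condition mean (GP -0.44, SD 0.08 over 50 vesicles) to mol%
propagate_error(m_gp, -0.44, 0.08, 50)
#> <cholesterol_estimate> 9.56 +/- 1.56 mol%

# lifetime route: fit a simulated Flipper-TR decay (true tau_m,int 3.41 ns)
d <- simulate_decay(decay_phantom_spec(component_fractions = c(0.35, 0.65),
       component_lifetimes = c(0.5, 1.2692) * 3.41, seed = 42))
fit_reconvolution(d$hist)
#> <lifetime_fit> tau_m,int = 3.387 ns; components: 1.673 ns (33%), 4.250 ns (67%); reduced chi2 = 1.011
```

Reading the numbers: the pipeline recovers the phantom's true GP of −0.44
to 0.002 from 1816 ring pixels; inverting that condition mean through the
GP calibration places the membrane at 9.6 ± 1.6 mol% cholesterol; and the
reconvolution fit recovers the 3.41 ns intensity-weighted lifetime to 0.7%
from a 10⁵-photon decay with a reduced χ² of 1.01.

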