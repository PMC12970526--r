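# Shared fixture builders: tiny deterministic stacks and decays assembled in
# code so tests stay self-contained.

# noise-free spectral stack from a phantom spec (expected counts, no Poisson)
noise_free_stack <- function(spec) {
  ex <- guvchol:::expected_spectral_cube(spec)
  spectral_stack(ex$cube, spec$channel_centers)
}

# small phantom spec used across the spectral tests (64 px field keeps the
# pipeline fast while leaving ~500 ring pixels)
small_spectral_spec <- function(gp_true = -0.3, seed = 1L, ...) {
  spectral_phantom_spec(
    geometry = guv_geometry(center = c(32.5, 32.5), radius = 18,
                            ring_width = 4, image_size = c(64L, 64L)),
    gp_true = gp_true, seed = seed, ...)
}

# noise-free decay histogram for given components (expected counts as data)
noise_free_decay <- function(fractions, lifetimes, photon_budget = 1e5,
                             background_fraction = 0.01, n_bins = 256L,
                             irf_center = 2, irf_fwhm = 0.2, rep_period = 50) {
  spec <- decay_phantom_spec(component_fractions = fractions,
                             component_lifetimes = lifetimes,
                             photon_budget = photon_budget,
                             background_fraction = background_fraction,
                             n_bins = n_bins, irf_center = irf_center,
                             irf_fwhm = irf_fwhm, rep_period = rep_period)
  ex <- guvchol:::expected_decay_counts(spec)
  decay_histogram(seq(0, rep_period, length.out = n_bins + 1),
                  ex$expected, ex$irf_mass * 1e4, rep_period)
}

# finely binned noise-free monoexponential with a near-delta IRF: at 4096
# bins the discrete phasor satisfies the semicircle identity to better than
# 1e-6 (bin-width discretisation error ~3e-7)
mono_decay_fine <- function(tau, n_bins = 4096L, rep_period = 50,
                            background_fraction = 0) {
  noise_free_decay(1, tau, photon_budget = 1e6,
                   background_fraction = background_fraction,
                   n_bins = n_bins, irf_center = 1e-4, irf_fwhm = 1e-6,
                   rep_period = rep_period)
}

# fresh scratch directory per call (cleaned with the session tempdir)
withr_tempdir <- function() {
  d <- tempfile("guvchol_test_")
  dir.create(d)
  d
}

# hand-built calibration model (for propagation tests with quoted errors)
manual_calibration_model <- function(intercept, slope, se_intercept, se_slope,
                                     cov_cm = 0) {
  V <- matrix(c(se_intercept^2, cov_cm, cov_cm, se_slope^2), 2, 2)
  structure(list(intercept = intercept, slope = slope,
                 se_intercept = se_intercept, se_slope = se_slope,
                 cov = V, weighting = "invvar", sigma = NA_real_,
                 n_points = NA_integer_, modality = NA_character_),
            class = "calibration_model")
}
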