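# Phantom generators: expected-value structure, determinism, Poisson
# statistics, and condition-batch draws.

test_that("expected spectral cube encodes the requested GP at the analysis channels", {
  centers <- default_channel_centers()
  iB <- guvchol:::nearest_channel(centers, 570)
  iR <- guvchol:::nearest_channel(centers, 640)

  # symmetric case: equal expected counts in the two analysis channels
  sp0 <- small_spectral_spec(gp_true = 0, background_rate = 0)
  ex0 <- guvchol:::expected_spectral_cube(sp0)
  expect_equal(ex0$cube[iB, , ], ex0$cube[iR, , ], tolerance = 1e-12)

  # pure-DOPC-scale disorder: I570/I640 = (1 - 0.51)/(1 + 0.51) at every
  # membrane pixel
  sp <- small_spectral_spec(gp_true = -0.51, background_rate = 0)
  ex <- guvchol:::expected_spectral_cube(sp)
  on_ring <- ex$membrane_mask
  ratio <- ex$cube[iB, , ][on_ring] / ex$cube[iR, , ][on_ring]
  expect_equal(ratio, rep(0.49 / 1.51, sum(on_ring)), tolerance = 1e-10)

  # GP of the expected band intensities equals gp_true regardless of the
  # photoselection angle (modulation is wavelength independent)
  for (g in c(-0.8, -0.25, 0.4)) {
    spg <- small_spectral_spec(gp_true = g, background_rate = 0,
                               polarization_axis_deg = 37)
    exg <- guvchol:::expected_spectral_cube(spg)
    IB <- exg$cube[iB, , ][exg$membrane_mask]
    IR <- exg$cube[iR, , ][exg$membrane_mask]
    expect_equal((IB - IR) / (IB + IR), rep(g, length(IB)), tolerance = 1e-10)
  }
})

test_that("photoselection modulation behaves as specified", {
  # depth 0: intensity depends on radius only, so the expected projection is
  # symmetric under x/y exchange about the (symmetric) centre; with
  # modulation switched on it is not
  sp <- small_spectral_spec(photoselection_depth = 0, background_rate = 0)
  ex <- guvchol:::expected_spectral_cube(sp)
  proj <- apply(ex$cube, c(2, 3), sum)
  expect_equal(proj, t(proj), tolerance = 1e-12)
  r <- sp$geometry$radius

  # depth 0.6: parallel arcs brighter than perpendicular by the stated factor
  sp2 <- small_spectral_spec(photoselection_depth = 0.6, background_rate = 0,
                             polarization_axis_deg = 0)
  ex2 <- guvchol:::expected_spectral_cube(sp2)
  proj2 <- apply(ex2$cube, c(2, 3), sum)
  par_px <- proj2[round(32.5), round(32.5 + r)]    # theta = 0
  perp_px <- proj2[round(32.5 + r), round(32.5)]   # theta = 90 deg
  expect_equal(perp_px / par_px, 0.4, tolerance = 0.02)
})

test_that("spectral phantom rejects invalid specs and is deterministic", {
  expect_error(spectral_phantom_spec(gp_true = 1), "undefined")
  expect_error(guv_geometry(center = c(5, 5), radius = 60), "outside")
  expect_error(guv_geometry(radius = 1, ring_width = 4), "ring_width")
  expect_error(small_spectral_spec(photoselection_depth = 1.5), "photoselection")

  sp <- small_spectral_spec(seed = 99)
  a <- simulate_spectral_stack(sp)
  b <- simulate_spectral_stack(sp)
  expect_identical(a$stack$data, b$stack$data)
  # and a different seed changes the draw
  sp2 <- small_spectral_spec(seed = 100)
  expect_false(identical(simulate_spectral_stack(sp2)$stack$data, a$stack$data))
})

test_that("expected decay histogram normalizes to the photon budget", {
  spec <- decay_phantom_spec(photon_budget = 12345)
  ex <- guvchol:::expected_decay_counts(spec)
  expect_equal(sum(ex$expected), 12345, tolerance = 1e-9)
})

test_that("near-delta IRF decay follows the closed-form bin integral", {
  # single component, no background, IRF collapsed into the first bin:
  # expected counts must match the wrapped-exponential bin integrals
  # computed independently from the geometric-sum closed form
  tau <- 3; n <- 64L; T <- 50
  spec <- decay_phantom_spec(component_fractions = 1, component_lifetimes = tau,
                             irf_center = 1e-4, irf_fwhm = 1e-6, n_bins = n,
                             photon_budget = 1e6, background_fraction = 0)
  ex <- guvchol:::expected_decay_counts(spec)$expected
  # oracle: integral of sum_p exp(-(t + pT)/tau) over each bin, bins taken
  # relative to the centre of bin 1 where the IRF sits
  dt <- T / n
  edges_rel <- seq(0, T, length.out = n + 1) - dt / 2
  cdf <- function(t) {
    neg <- t < 0
    t[neg] <- t[neg] + T
    p <- (1 - exp(-t / tau)) / (1 - exp(-T / tau))
    p[neg] <- p[neg] - 1
    p
  }
  oracle <- 1e6 * (cdf(edges_rel[-1]) - cdf(edges_rel[-(n + 1)]))
  expect_equal(ex, oracle, tolerance = 1e-9)
  # and away from the wrap the shape is a plain exponential
  mid <- 5:40
  expect_equal(diff(log(ex[mid])), rep(-dt / tau, length(mid) - 1),
               tolerance = 1e-3)
})

test_that("two identical lifetimes are indistinguishable from one component", {
  a <- guvchol:::expected_decay_counts(
    decay_phantom_spec(component_fractions = c(0.5, 0.5),
                       component_lifetimes = c(4, 4)))$expected
  b <- guvchol:::expected_decay_counts(
    decay_phantom_spec(component_fractions = 1,
                       component_lifetimes = 4))$expected
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("decay phantom validates inputs", {
  expect_error(decay_phantom_spec(component_fractions = c(0.5, 0.4)), "sum to 1")
  expect_error(decay_phantom_spec(n_bins = 3), "at least 4")
  expect_error(decay_phantom_spec(component_lifetimes = c(-1, 2),
                                  component_fractions = c(0.5, 0.5)), "> 0")
  expect_warning(decay_phantom_spec(component_fractions = 1,
                                    component_lifetimes = 600), "tail")
})

test_that("Poisson draws match the expected histogram in distribution", {
  # chi-squared test on per-bin totals over many independent draws
  spec <- decay_phantom_spec(n_bins = 16L, photon_budget = 2000, irf_fwhm = 0.5)
  reps <- 10000
  tot <- numeric(16)
  for (i in seq_len(reps)) {
    s <- spec; s$seed <- i
    tot <- tot + simulate_decay(s)$hist$counts
  }
  ex <- guvchol:::expected_decay_counts(spec)$expected
  chi <- sum((tot - reps * ex)^2 / (reps * ex))
  expect_gt(pchisq(chi, df = 16, lower.tail = FALSE), 0.01)
})

test_that("condition batches draw, clamp and reproduce as specified", {
  # sd = 0: every vesicle shares the same true readout
  b0 <- simulate_condition_batch(5, -0.3, 0, modality = "GP", seed = 4)
  expect_equal(b0$truth$true_readout, rep(-0.3, 5))

  # CLT bound at the untreated-DOPC statistics (mean -0.51, SD 0.05, n 50)
  b <- simulate_condition_batch(50, -0.51, 0.05, modality = "GP", seed = 5)
  expect_lt(abs(mean(b$truth$true_readout) + 0.51), 3 * 0.05 / sqrt(50))

  # determinism: same seed, same batch
  b2 <- simulate_condition_batch(50, -0.51, 0.05, modality = "GP", seed = 5)
  expect_identical(b$truth, b2$truth)

  # lifetime batches keep the drawn truth as the intensity-weighted mean of
  # the biexponential actually simulated
  bl <- simulate_condition_batch(10, 3.4, 0.1, modality = "lifetime", seed = 6)
  tm <- vapply(bl$specs, function(sp)
    sum(sp$component_fractions * sp$component_lifetimes), numeric(1))
  expect_equal(tm, bl$truth$true_readout, tolerance = 1e-12)

  expect_error(simulate_condition_batch(5, 0, -1, modality = "GP"), "sd")
  expect_error(simulate_condition_batch(0, 0, 1, modality = "GP"), "n_vesicles")
})
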