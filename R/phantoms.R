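# Synthetic GUV phantoms: spectral ring images and TCSPC decay histograms
# with known ground truth, emulating equatorial confocal sections of probe-
# labelled vesicles under photon-counting detection.

#' GUV ring geometry for spectral phantoms
#'
#' @param center numeric length-2, (x, y) pixel coordinates of the vesicle
#'   centre (1-based, x = column, y = row).
#' @param radius ring radius in pixels.
#' @param ring_width full width of the membrane annulus in pixels.
#' @param image_size integer length-2, image size in pixels (rows, columns).
#' @return an object of class `guv_geometry`.
#' @export
guv_geometry <- function(center = c(128.5, 128.5), radius = 60,
                         ring_width = 4, image_size = c(256L, 256L)) {
  stopifnot(length(center) == 2, length(image_size) == 2)
  if (!(radius > ring_width / 2 && ring_width > 0))
    stop("require radius > ring_width/2 > 0")
  if (center[1] - radius - ring_width / 2 < 1 ||
      center[1] + radius + ring_width / 2 > image_size[2] ||
      center[2] - radius - ring_width / 2 < 1 ||
      center[2] + radius + ring_width / 2 > image_size[1])
    stop("ring extends outside the image bounds")
  structure(list(center = as.numeric(center), radius = radius,
                 ring_width = ring_width,
                 image_size = as.integer(image_size)),
            class = "guv_geometry")
}

#' Default spectral channel grid
#'
#' Band centres for a lambda scan covering 560-700 nm in 10 nm steps:
#' 14 contiguous 10 nm bands centred at 565, 575, ..., 695 nm.
#' @return numeric vector of 14 channel centres (nm).
#' @export
default_channel_centers <- function() seq(565, 695, by = 10)

# Two-band emission model for the solvatochromic probe: Gaussian bands at
# 580 nm (ordered/blue) and 635 nm (disordered/red), FWHM 35 nm.  The mixture
# weight is solved per phantom so that the intensity ratio at the analysis
# channels reproduces the requested GP exactly.
.band_centers <- c(580, 635)
.band_fwhm <- 35

# Channel nearest to a target wavelength; ties break toward the shorter
# wavelength (the 565.../695 grid makes 570 and 640 nm exactly equidistant
# between two bands).
nearest_channel <- function(channel_centers, lambda) {
  which.min(abs(channel_centers - lambda))
}

# Per-channel spectrum (summing to 1) with GP = gp_true measured between the
# channels nearest 570 and 640 nm.
spectral_shape <- function(gp_true, channel_centers) {
  sigma <- .band_fwhm / (2 * sqrt(2 * log(2)))
  b1 <- exp(-(channel_centers - .band_centers[1])^2 / (2 * sigma^2))
  b2 <- exp(-(channel_centers - .band_centers[2])^2 / (2 * sigma^2))
  b1 <- b1 / sum(b1); b2 <- b2 / sum(b2)
  iB <- nearest_channel(channel_centers, 570)
  iR <- nearest_channel(channel_centers, 640)
  r <- (1 + gp_true) / (1 - gp_true)   # target I_B / I_R
  # solve w*b1 + (1-w)*b2 for w s.t. s[iB]/s[iR] = r
  w <- (r * b2[iR] - b2[iB]) / (b1[iB] - b2[iB] - r * (b1[iR] - b2[iR]))
  s <- w * b1 + (1 - w) * b2
  if (any(s < 0))
    stop("gp_true = ", signif(gp_true, 3),
         " is outside the range representable by the two-band spectral model")
  s / sum(s)
}

#' Specification of a spectral GUV phantom
#'
#' @param geometry a [guv_geometry()].
#' @param gp_true true generalized polarization of the membrane, in (-1, 1).
#' @param total_photons_per_pixel expected photon count (summed over channels)
#'   at the brightest membrane pixel.
#' @param photoselection_depth amplitude in `[0, 1]` of the cos^2 intensity
#'   modulation around the ring caused by polarized excitation.
#' @param polarization_axis_deg orientation of the excitation polarization
#'   (degrees).
#' @param background_rate expected background counts per pixel, summed over
#'   channels.
#' @param channel_centers emission channel centres in nm, strictly increasing.
#' @param seed integer seed making the Poisson draw reproducible.
#' @return an object of class `spectral_phantom_spec`.
#' @export
spectral_phantom_spec <- function(geometry = guv_geometry(), gp_true = -0.5,
                                  total_photons_per_pixel = 600,
                                  photoselection_depth = 0.6,
                                  polarization_axis_deg = 0,
                                  background_rate = 2,
                                  channel_centers = default_channel_centers(),
                                  seed = 1L) {
  stopifnot(inherits(geometry, "guv_geometry"))
  if (abs(gp_true) >= 1)
    stop("gp_true must lie strictly inside (-1, 1): the band ratio (1+GP)/(1-GP) ",
         "is undefined at GP = +/-1 with nonzero counts in both bands")
  if (photoselection_depth < 0 || photoselection_depth > 1)
    stop("photoselection_depth must be in [0, 1]")
  if (any(diff(channel_centers) <= 0))
    stop("channel_centers must be strictly increasing")
  if (total_photons_per_pixel < 0 || background_rate < 0)
    stop("expected counts must be nonnegative")
  structure(list(geometry = geometry, gp_true = gp_true,
                 total_photons_per_pixel = total_photons_per_pixel,
                 photoselection_depth = photoselection_depth,
                 polarization_axis_deg = polarization_axis_deg,
                 background_rate = background_rate,
                 channel_centers = channel_centers, seed = as.integer(seed)),
            class = "spectral_phantom_spec")
}

# Noise-free expected photon-count cube (channel x row x col) plus geometry
# maps, shared by the simulator and by tests that need the expectation.
expected_spectral_cube <- function(spec) {
  g <- spec$geometry
  nr <- g$image_size[1]; nc <- g$image_size[2]
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  dx <- x - g$center[1]; dy <- y - g$center[2]
  d <- sqrt(dx^2 + dy^2)
  sigma <- g$ring_width / 2.355
  ring <- exp(-(d - g$radius)^2 / (2 * sigma^2))
  theta <- atan2(dy, dx)
  ax <- spec$polarization_axis_deg * pi / 180
  psel <- (1 - spec$photoselection_depth) +
    spec$photoselection_depth * cos(theta - ax)^2
  spatial <- ring * psel
  spatial <- spatial * (spec$total_photons_per_pixel / max(spatial))
  s <- spectral_shape(spec$gp_true, spec$channel_centers)
  nchan <- length(s)
  cube <- array(0, dim = c(nchan, nr, nc))
  bg <- spec$background_rate / nchan
  for (k in seq_len(nchan)) cube[k, , ] <- spatial * s[k] + bg
  list(cube = cube, membrane_mask = abs(d - g$radius) <= g$ring_width / 2)
}

#' Simulate a spectral GUV image stack
#'
#' Draws a photon-count cube (channel x row x col) for a single equatorial
#' GUV section.  The expected per-pixel spectrum is a smooth two-band profile
#' whose intensities at the channels nearest 570 and 640 nm satisfy
#' I_B/I_R = (1 + GP)/(1 - GP); the ring intensity is modulated as
#' (1 - depth) + depth * cos^2(theta - axis) to emulate photoselection; counts
#' are independent Poisson draws, deterministic given the spec's seed.
#'
#' @param spec a [spectral_phantom_spec()].
#' @return list with elements `stack` (a [spectral_stack()]) and
#'   `ground_truth` (spec, true GP, true membrane mask, seed).
#' @export
simulate_spectral_stack <- function(spec) {
  stopifnot(inherits(spec, "spectral_phantom_spec"))
  ex <- expected_spectral_cube(spec)
  counts <- array(
    withr_seed(spec$seed, rpois(length(ex$cube), lambda = ex$cube)),
    dim = dim(ex$cube))
  stack <- spectral_stack(counts, spec$channel_centers,
                          meta = list(phantom = TRUE, seed = spec$seed))
  gt <- structure(list(spec = spec, gp_true = spec$gp_true,
                       membrane_mask = ex$membrane_mask, seed = spec$seed),
                  class = "phantom_ground_truth")
  list(stack = stack, ground_truth = gt)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Specification of a TCSPC decay phantom
#'
#' @param component_fractions intensity fractions of the exponential
#'   components (nonnegative, summing to 1).
#' @param component_lifetimes component lifetimes in ns (positive).
#' @param rep_period laser repetition period in ns (50 ns = 20 MHz).
#' @param irf_center,irf_fwhm Gaussian instrument-response centre and FWHM, ns.
#' @param n_bins number of TCSPC time bins over one period.
#' @param photon_budget expected total photon count of the histogram.
#' @param background_fraction fraction of photons from a uniform background.
#' @param seed integer seed for the Poisson draw.
#' @return an object of class `decay_phantom_spec`.
#' @export
decay_phantom_spec <- function(component_fractions = c(0.6, 0.4),
                               component_lifetimes = c(2, 5),
                               rep_period = 50, irf_center = 2,
                               irf_fwhm = 0.2, n_bins = 256L,
                               photon_budget = 1e5,
                               background_fraction = 0.01, seed = 1L) {
  if (any(component_fractions < 0) ||
      abs(sum(component_fractions) - 1) > 1e-8)
    stop("component_fractions must be nonnegative and sum to 1")
  if (any(component_lifetimes <= 0)) stop("component_lifetimes must be > 0")
  if (rep_period <= 0) stop("rep_period must be > 0")
  if (photon_budget < 0) stop("photon_budget must be >= 0")
  if (n_bins < 4) stop("n_bins must be at least 4")
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0, 1]")
  if (any(component_lifetimes >= rep_period * 10))
    warning("a component lifetime exceeds 10x the repetition period; ",
            "its decay tail cannot be resolved")
  structure(list(component_fractions = component_fractions,
                 component_lifetimes = component_lifetimes,
                 rep_period = rep_period, irf_center = irf_center,
                 irf_fwhm = irf_fwhm, n_bins = as.integer(n_bins),
                 photon_budget = photon_budget,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "decay_phantom_spec")
}

# Noise-free expected counts per bin for a decay phantom.
expected_decay_counts <- function(spec) {
  irf <- gaussian_irf_mass(spec$irf_center, spec$irf_fwhm,
                           spec$rep_period, spec$n_bins)
  p <- decay_expected_probs(spec$component_fractions,
                            spec$component_lifetimes, irf,
                            spec$rep_period, spec$background_fraction)
  list(expected = spec$photon_budget * p, irf_mass = irf)
}

#' Simulate a TCSPC decay histogram
#'
#' Expected counts are the periodic wrap of the multi-exponential decay
#' convolved with a Gaussian IRF plus a uniform background, scaled to the
#' photon budget; observed counts are independent Poisson draws,
#' deterministic given the spec's seed.  The recorded IRF is the exact
#' (noise-free) binned Gaussian.
#'
#' @param spec a [decay_phantom_spec()].
#' @return list with elements `hist` (a [decay_histogram()]) and
#'   `ground_truth` (spec, true intensity-weighted mean lifetime, seed).
#' @export
simulate_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_phantom_spec"))
  ex <- expected_decay_counts(spec)
  counts <- withr_seed(spec$seed, rpois(spec$n_bins, lambda = ex$expected))
  h <- decay_histogram(
    bin_edges = seq(0, spec$rep_period, length.out = spec$n_bins + 1),
    counts = counts,
    irf_counts = ex$irf_mass * 1e4,
    rep_period = spec$rep_period)
  gt <- structure(
    list(spec = spec,
         tau_m_int = sum(spec$component_fractions * spec$component_lifetimes),
         seed = spec$seed),
    class = "phantom_ground_truth")
  list(hist = h, ground_truth = gt)
}

#' Generate phantom specifications for one experimental condition
#'
#' Draws per-vesicle true readouts from Normal(mean, sd) -- GP values clamped
#' to (-1, 1), lifetimes to > 0.05 ns -- and emits one phantom spec per
#' vesicle with randomized ring geometry.  Per-vesicle seeds derive from the
#' batch seed by a counter scheme, so vesicle i is reproducible independently
#' of batch size or order.
#'
#' For the lifetime modality each drawn true tau_m,int is realised as a
#' biexponential with intensity fractions (0.35, 0.65) and component
#' lifetimes (0.5, 1.2692) * tau_m,int, which keeps the intensity-weighted
#' mean exactly at the drawn truth.
#'
#' @param n_vesicles number of vesicles (>= 1).
#' @param readout_mean,readout_sd generating mean and SD of the per-vesicle
#'   true readout (GP, dimensionless; or lifetime, ns).
#' @param modality `"GP"` or `"lifetime"`.
#' @param seed integer batch seed.
#' @param ... overrides passed to [spectral_phantom_spec()] or
#'   [decay_phantom_spec()] (e.g. `total_photons_per_pixel`, `photon_budget`).
#' @return list with `specs` (list of phantom specs) and `truth`
#'   (data.frame of per-vesicle true readouts and seeds).
#' @export
simulate_condition_batch <- function(n_vesicles, readout_mean, readout_sd,
                                     modality = c("GP", "lifetime"),
                                     seed = 1L, ...) {
  modality <- match.arg(modality)
  if (n_vesicles < 1) stop("n_vesicles must be >= 1")
  if (readout_sd < 0) stop("readout_sd must be >= 0")
  truths <- withr_seed(seed, rnorm(n_vesicles, readout_mean, readout_sd))
  vseed <- (as.integer(seed) + 7919L * seq_len(n_vesicles)) %% 2147483629L
  geom_par <- withr_seed(seed + 1L, data.frame(
    radius = runif(n_vesicles, 40, 75),
    cx = runif(n_vesicles, 120, 136),
    cy = runif(n_vesicles, 120, 136),
    ring_width = runif(n_vesicles, 3, 5)))
  dots <- list(...)
  specs <- vector("list", n_vesicles)
  if (modality == "GP") {
    truths <- pmin(pmax(truths, -0.999), 0.999)
    for (i in seq_len(n_vesicles)) {
      geom <- guv_geometry(center = c(geom_par$cx[i], geom_par$cy[i]),
                           radius = geom_par$radius[i],
                           ring_width = geom_par$ring_width[i])
      args <- modifyList(list(geometry = geom, gp_true = truths[i],
                              seed = vseed[i]), dots)
      specs[[i]] <- do.call(spectral_phantom_spec, args)
    }
  } else {
    truths <- pmax(truths, 0.05)
    for (i in seq_len(n_vesicles)) {
      args <- modifyList(list(component_fractions = c(0.35, 0.65),
                              component_lifetimes = c(0.5, (1 - 0.35 * 0.5) / 0.65) * truths[i],
                              seed = vseed[i]), dots)
      specs[[i]] <- do.call(decay_phantom_spec, args)
    }
  }
  list(specs = specs,
       truth = data.frame(vesicle_id = seq_len(n_vesicles),
                          true_readout = truths, seed = vseed,
                          modality = modality))
}

#' Simulate a phase-separated vesicle as per-pixel TCSPC decays
#'
#' Builds a ring of membrane pixels whose upper angular half decays with the
#' liquid-ordered (L_o) lifetime and lower half with the liquid-disordered
#' (L_d) lifetime (monoexponential per domain), each pixel an independent
#' Poisson draw.  Used to exercise phasor-based domain separation.
#'
#' @param tau_lo,tau_ld domain lifetimes in ns (L_o > L_d for a packed domain).
#' @param geometry a [guv_geometry()]; pixel grid for the ring mask.
#' @param photons_per_pixel expected photons in each pixel decay.
#' @param rep_period,n_bins,irf_center,irf_fwhm as in [decay_phantom_spec()].
#' @param background_fraction uniform background fraction per pixel.
#' @param seed integer seed.
#' @return list with `decays` (pixels x bins count matrix), `pixel_domain`
#'   (factor `"Lo"`/`"Ld"` per pixel), `pixel_index` (row/col of each pixel),
#'   `irf_mass`, `rep_period`, `bin_edges`, and the true lifetimes.
#' @export
simulate_two_domain_vesicle <- function(tau_lo = 4.87, tau_ld = 3.88,
                                        geometry = guv_geometry(
                                          center = c(64.5, 64.5), radius = 40,
                                          ring_width = 4,
                                          image_size = c(128L, 128L)),
                                        photons_per_pixel = 1500,
                                        rep_period = 50, n_bins = 256L,
                                        irf_center = 2, irf_fwhm = 0.2,
                                        background_fraction = 0.01,
                                        seed = 1L) {
  g <- geometry
  nr <- g$image_size[1]; nc <- g$image_size[2]
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  d <- sqrt((x - g$center[1])^2 + (y - g$center[2])^2)
  in_ring <- abs(d - g$radius) <= g$ring_width / 2
  idx <- which(in_ring, arr.ind = TRUE)
  upper <- (y - g$center[2])[in_ring] < 0
  domain <- factor(ifelse(upper, "Lo", "Ld"), levels = c("Lo", "Ld"))
  irf <- gaussian_irf_mass(irf_center, irf_fwhm, rep_period, n_bins)
  p_lo <- decay_expected_probs(1, tau_lo, irf, rep_period, background_fraction)
  p_ld <- decay_expected_probs(1, tau_ld, irf, rep_period, background_fraction)
  npix <- nrow(idx)
  lam <- matrix(0, npix, n_bins)
  lam[domain == "Lo", ] <- matrix(photons_per_pixel * p_lo,
                                  sum(domain == "Lo"), n_bins, byrow = TRUE)
  lam[domain == "Ld", ] <- matrix(photons_per_pixel * p_ld,
                                  sum(domain == "Ld"), n_bins, byrow = TRUE)
  counts <- matrix(withr_seed(seed, rpois(length(lam), lam)), npix, n_bins)
  list(decays = counts, pixel_domain = domain, pixel_index = idx,
       irf_mass = irf, rep_period = rep_period,
       bin_edges = seq(0, rep_period, length.out = n_bins + 1),
       tau_lo = tau_lo, tau_ld = tau_ld, image_size = g$image_size)
}
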