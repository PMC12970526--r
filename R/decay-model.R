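# Shared forward model for TCSPC decays: multi-exponential kernels wrapped on
# the laser period, circularly convolved with a binned IRF. Used both by the
# phantom generator (with a Gaussian IRF) and by the reconvolution fitter
# (with whatever IRF the histogram carries).

# Bin masses of a single-exponential decay wrapped on period T, on n equal
# bins, evaluated on intervals shifted by -dt/2 so that convolution with IRF
# masses placed at bin centres lines up with the bin grid (a photon arriving
# at IRF-bin centre u with delay d falls in bin j iff d is in
# [(j-i-0.5)dt, (j-i+0.5)dt)).  Sums to 1 over one period.
wrapped_exp_kernel <- function(tau, rep_period, n_bins) {
  dt <- rep_period / n_bins
  # CDF of the wrapped exponential on [0, T], extended periodically below 0
  wexp_cdf <- function(t) {
    neg <- t < 0
    t[neg] <- t[neg] + rep_period
    p <- (1 - exp(-t / tau)) / (1 - exp(-rep_period / tau))
    p[neg] <- p[neg] - 1
    p
  }
  m <- seq_len(n_bins) - 1L
  wexp_cdf((m + 0.5) * dt) - wexp_cdf((m - 0.5) * dt)
}

# Circular convolution of IRF bin masses with a kernel, via FFT.  `irf_fft`
# may be precomputed with stats::fft(irf_mass) to avoid recomputation inside
# optimizer loops.
convolve_circular <- function(irf_fft, kernel) {
  n <- length(kernel)
  out <- Re(fft(irf_fft * fft(kernel), inverse = TRUE)) / n
  pmax(out, 0)
}

# Expected per-bin photon probabilities for a (possibly multi-component)
# decay: sum_k frac[k] * (IRF (*) wrapped-exp(tau[k])) + uniform background.
decay_expected_probs <- function(fractions, lifetimes, irf_mass, rep_period,
                                 background_fraction = 0) {
  n <- length(irf_mass)
  irf_fft <- fft(irf_mass)
  sig <- numeric(n)
  for (k in seq_along(fractions)) {
    sig <- sig + fractions[k] *
      convolve_circular(irf_fft, wrapped_exp_kernel(lifetimes[k], rep_period, n))
  }
  (1 - background_fraction) * sig / sum(sig) + background_fraction / n
}

# Bin masses of a Gaussian IRF (centre, FWHM in ns) on the histogram grid,
# normalized to unit total.  The Gaussian is assumed to lie well inside the
# period (true for any realistic instrument response).
gaussian_irf_mass <- function(center, fwhm, rep_period, n_bins) {
  edges <- seq(0, rep_period, length.out = n_bins + 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  m <- diff(pnorm(edges, mean = center, sd = sigma))
  if (sum(m) <= 0) stop("IRF has no mass inside the acquisition period")
  m / sum(m)
}
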