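# Phasor analysis of fluorescence lifetimes: each decay is mapped to its
# first-harmonic Fourier coordinates (g, s) at the laser repetition
# frequency; monoexponential decays lie on the universal semicircle
# g^2 + s^2 = g, mixtures fall inside it on the chord between their
# component phasors.

# complex phasor of a counts vector at angular frequency omega (rad/ns),
# bins centred at tc
.complex_phasor <- function(counts, tc, omega) {
  tot <- sum(counts)
  if (tot <= 0) stop("cannot compute the phasor of an empty histogram")
  sum(counts * exp(1i * omega * tc)) / tot
}

#' Phasor transform of a decay histogram
#'
#' Computes g = sum(c_i cos(w t_i))/sum(c_i) and
#' s = sum(c_i sin(w t_i))/sum(c_i) at w = 2*pi*harmonic/rep_period, and
#' corrects for the instrument response by dividing the complex data phasor
#' by the IRF phasor (removing the IRF's phase delay and modulation loss).
#'
#' @param hist a [decay_histogram()].
#' @param harmonic harmonic number (1 = repetition frequency).
#' @return an object of class `phasor_point`: list with `g`, `s`, `omega`
#'   (rad/ns) and `photons`.
#' @export
phasor_transform <- function(hist, harmonic = 1) {
  stopifnot(inherits(hist, "decay_histogram"))
  omega <- 2 * pi * harmonic / hist$rep_period
  tc <- bin_centers(hist)
  z <- .complex_phasor(hist$counts, tc, omega) /
    .complex_phasor(hist$irf_counts, tc, omega)
  structure(list(g = Re(z), s = Im(z), omega = omega,
                 photons = sum(hist$counts)),
            class = "phasor_point")
}

#' Per-pixel phasor image
#'
#' Phasor transform applied to a matrix of per-pixel decays (pixels in rows,
#' time bins in columns), IRF-corrected as in [phasor_transform()].
#'
#' @param decays numeric matrix, pixels x time bins.
#' @param irf_mass IRF bin masses on the same grid.
#' @param rep_period repetition period in ns.
#' @param harmonic harmonic number.
#' @return data.frame with one row per pixel: `pixel_id`, `g`, `s`,
#'   `photons`; the angular frequency is attached as attribute `omega`.
#' @export
phasor_image <- function(decays, irf_mass, rep_period = 50, harmonic = 1) {
  n <- ncol(decays)
  omega <- 2 * pi * harmonic / rep_period
  tc <- (seq_len(n) - 0.5) * rep_period / n
  tot <- rowSums(decays)
  z <- (decays %*% exp(1i * omega * tc))[, 1] / tot
  z <- z / .complex_phasor(irf_mass, tc, omega)
  out <- data.frame(pixel_id = seq_len(nrow(decays)), g = Re(z), s = Im(z),
                    photons = tot)
  attr(out, "omega") <- omega
  out
}

#' Median-filter a per-pixel phasor image
#'
#' Smooths the g and s coordinate images with a square median filter of
#' half-width `strength` (a 3x3 kernel at strength 1), sharpening photon
#' clouds in the phasor plot before cloud selection.  Per-pixel photon
#' totals are left untouched.
#'
#' @param points a [phasor_image()] result.
#' @param pixel_index integer matrix (row, col) giving each pixel's image
#'   position (e.g. from [simulate_two_domain_vesicle()]).
#' @param image_size image dimensions (rows, columns).
#' @param strength kernel half-width in pixels.
#' @return `points` with filtered `g` and `s`.
#' @export
denoise_phasor <- function(points, pixel_index, image_size, strength = 1) {
  if (strength < 1) return(points)
  filt_one <- function(v) {
    img <- matrix(NA_real_, image_size[1], image_size[2])
    img[pixel_index] <- v
    out <- img
    k <- as.integer(strength)
    for (p in seq_len(nrow(pixel_index))) {
      i <- pixel_index[p, 1]; j <- pixel_index[p, 2]
      nb <- img[max(1, i - k):min(image_size[1], i + k),
                max(1, j - k):min(image_size[2], j + k)]
      out[i, j] <- median(nb, na.rm = TRUE)
    }
    out[pixel_index]
  }
  points$g <- filt_one(points$g)
  points$s <- filt_one(points$s)
  points
}

#' Select a photon cloud on the phasor plot
#'
#' Collects all pixels within a circle of the given radius (in phasor units)
#' around a centre, and reports the phase lifetime of the photon-weighted
#' mean phasor, tau_phi = s_bar / (omega * g_bar).
#'
#' @param points a [phasor_image()] result (optionally denoised).
#' @param center numeric length-2, (g, s) centre of the selection.
#' @param radius selection radius in phasor units.
#' @param omega angular frequency in rad/ns; taken from
#'   `attr(points, "omega")` if absent.
#' @return an object of class `phasor_cloud`: centre, radius, member pixel
#'   ids, photon-weighted mean phasor and the cloud's phase lifetime (ns).
#' @export
select_phasor_cloud <- function(points, center, radius = 0.02, omega = NULL) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(omega)) omega <- attr(points, "omega")
  if (is.null(omega)) stop("omega not supplied and not attached to points")
  d <- sqrt((points$g - center[1])^2 + (points$s - center[2])^2)
  member <- which(d <= radius)
  if (length(member) == 0)
    stop("no phasor points fall within the selection circle")
  w <- points$photons[member]
  gbar <- sum(w * points$g[member]) / sum(w)
  sbar <- sum(w * points$s[member]) / sum(w)
  structure(list(center = c(g = center[1], s = center[2]), radius = radius,
                 member_pixels = points$pixel_id[member],
                 n_members = length(member),
                 g_mean = gbar, s_mean = sbar,
                 lifetime = sbar / (omega * gbar)),
            class = "phasor_cloud")
}
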