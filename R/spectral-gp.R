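# Generalized polarization (GP) analysis of spectral image stacks:
# channel registration, masking and pixel-wise GP = (I_B - I_R)/(I_B + I_R)
# between the channels nearest 570 nm (blue) and 640 nm (red), averaged per
# vesicle.

#' Spectral image stack
#'
#' @param data numeric array, channel x row x column photon counts.
#' @param channel_centers emission channel centres in nm, strictly
#'   increasing, one per channel.
#' @param pixel_size optional pixel size in micrometres.
#' @param meta free-form acquisition metadata (list).
#' @return an object of class `spectral_stack`.
#' @export
spectral_stack <- function(data, channel_centers, pixel_size = NULL,
                           meta = list()) {
  if (length(dim(data)) != 3) stop("data must be a channel x row x col array")
  if (dim(data)[1] < 2) stop("need at least 2 spectral channels")
  if (length(channel_centers) != dim(data)[1])
    stop("one channel centre per channel required")
  if (any(diff(channel_centers) <= 0))
    stop("channel_centers must be strictly increasing")
  if (any(data < 0)) stop("photon counts must be nonnegative")
  structure(list(data = data, channel_centers = channel_centers,
                 pixel_size = pixel_size, meta = meta),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<spectral_stack> ", d[1], " channels (",
      min(x$channel_centers), "-", max(x$channel_centers), " nm), ",
      d[2], "x", d[3], " px, ", sum(x$data), " photons\n", sep = "")
  invisible(x)
}

# integer circular shift of a matrix by (dy, dx)
roll_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  if (dy %% nr != 0) m <- m[((seq_len(nr) - 1 - dy) %% nr) + 1, , drop = FALSE]
  if (dx %% nc != 0) m <- m[, ((seq_len(nc) - 1 - dx) %% nc) + 1, drop = FALSE]
  m
}

# FFT cross-correlation shift estimate of `moving` relative to `ref`:
# returns the (dy, dx) that aligns moving onto ref, with a subpixel
# parabolic refinement around the correlation peak.  Plain (unwhitened)
# cross-correlation: spectral channels share structure but carry
# independent counting noise, which spectral whitening amplifies.
phase_correlation_shift <- function(ref, moving, eps = 1e-12) {
  fa <- fft(ref - mean(ref)); fb <- fft(moving - mean(moving))
  r <- Re(fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  nr <- nrow(r); nc <- ncol(r)
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  # parabolic subpixel refinement along each axis
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < eps) 0 else 0.5 * (vm - vp) / den
  }
  ym <- ((pk[1] - 2) %% nr) + 1; yp <- (pk[1] %% nr) + 1
  xm <- ((pk[2] - 2) %% nc) + 1; xp <- (pk[2] %% nc) + 1
  list(shift = c(dy = dy, dx = dx),
       subpixel = c(dy = dy + refine(r[ym, pk[2]], r[pk[1], pk[2]], r[yp, pk[2]]),
                    dx = dx + refine(r[pk[1], xm], r[pk[1], pk[2]], r[pk[1], xp])))
}

#' Register spectral channels by phase correlation
#'
#' Estimates the translation of each channel relative to the brightest
#' channel by phase correlation and applies the integer part of the shift
#' (circular roll, so photon counts are preserved exactly).  Subpixel
#' estimates are reported but not applied.  Channels with shifts exceeding
#' `max_shift` are left in place with a warning (degenerate, structureless
#' channels can produce arbitrary correlation peaks); all-zero channels are
#' skipped with a warning.
#'
#' @param stack a [spectral_stack()].
#' @param max_shift cap on the applied shift magnitude, pixels.
#' @return the registered `spectral_stack`; per-channel shifts are stored in
#'   `$meta$registration` (applied integer and estimated subpixel shifts).
#' @export
register_stack <- function(stack, max_shift = 16) {
  stopifnot(inherits(stack, "spectral_stack"))
  nchan <- dim(stack$data)[1]
  totals <- apply(stack$data, 1, sum)
  ref_i <- which.max(totals)
  ref <- stack$data[ref_i, , ]
  shifts <- data.frame(channel = seq_len(nchan), dy = 0, dx = 0,
                       dy_subpixel = 0, dx_subpixel = 0, applied = TRUE)
  out <- stack$data
  for (k in seq_len(nchan)) {
    if (k == ref_i) next
    if (totals[k] == 0) {
      warning("channel ", k, " is empty; skipped during registration")
      shifts$applied[k] <- FALSE
      next
    }
    est <- phase_correlation_shift(ref, stack$data[k, , ])
    shifts[k, c("dy", "dx")] <- est$shift
    shifts[k, c("dy_subpixel", "dx_subpixel")] <- est$subpixel
    if (any(abs(est$shift) > max_shift)) {
      warning("channel ", k, ": estimated shift (", est$shift[1], ", ",
              est$shift[2], ") exceeds the ", max_shift,
              " px cap; channel left unshifted")
      shifts$applied[k] <- FALSE
      shifts[k, c("dy", "dx")] <- c(0, 0)
      next
    }
    out[k, , ] <- roll_matrix(stack$data[k, , ], est$shift[1], est$shift[2])
  }
  stack$data <- out
  stack$meta$registration <- list(reference_channel = ref_i, shifts = shifts)
  stack
}

#' Maximum intensity projection across channels
#'
#' @param stack a [spectral_stack()].
#' @return numeric matrix, pixel-wise maximum over channels.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "spectral_stack"))
  apply(stack$data, c(2, 3), max)
}

#' Flag high-intensity outlier pixels
#'
#' Pixels above a brightness threshold (saturated pixels, bright debris) are
#' flagged for exclusion from the segmentation mask.
#'
#' @param image nonnegative numeric matrix (typically a max projection).
#' @param threshold_mode `"quantile"` (default: flag pixels above the
#'   `quantile_pct` percentile of nonzero pixels) or `"absolute"`.
#' @param quantile_pct percentile in (0, 100) for quantile mode.
#' @param absolute_threshold count threshold for absolute mode.
#' @return logical matrix, `TRUE` where the pixel is excluded.
#' @export
exclude_bright_outliers <- function(image,
                                    threshold_mode = c("quantile", "absolute"),
                                    quantile_pct = 99.9,
                                    absolute_threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (any(image < 0)) stop("image must be nonnegative")
  thr <- if (threshold_mode == "quantile") {
    nz <- image[image > 0]
    if (length(nz) == 0) Inf else quantile(nz, quantile_pct / 100, names = FALSE)
  } else {
    if (is.null(absolute_threshold))
      stop("absolute_threshold required for absolute mode")
    absolute_threshold
  }
  excl <- image > thr
  nnz <- sum(image > 0)
  if (nnz > 0 && sum(excl) > 0.5 * nnz)
    stop("brightness threshold excludes more than half of the nonzero pixels; ",
         "check the threshold mode and value")
  excl
}

#' Percentile-based contrast stretch
#'
#' Linearly rescales an image to `[0, 1]`, clamping below the `low_pct` and
#' above the `high_pct` intensity percentiles.  Monotone and order
#' preserving.
#'
#' @param image numeric matrix.
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return rescaled matrix in `[0, 1]`.
#' @export
contrast_stretch <- function(image, low_pct = 1, high_pct = 99) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("require 0 <= low_pct < high_pct <= 100")
  lo <- quantile(image, low_pct / 100, names = FALSE)
  hi <- quantile(image, high_pct / 100, names = FALSE)
  if (hi <= lo) {
    warning("degenerate image (no intensity spread between percentiles); ",
            "returning the image unchanged")
    return(image)
  }
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

#' Otsu segmentation mask
#'
#' Thresholds an image at the level maximizing between-class variance on a
#' 256-bin histogram (Otsu's method, via `EBImage::otsu`) and removes
#' excluded outlier pixels.
#'
#' @param image numeric matrix, typically contrast-stretched to `[0, 1]`.
#' @param exclusion optional logical matrix of pixels to drop from the mask.
#' @return logical matrix, `TRUE` on above-threshold (foreground) pixels.
#' @export
otsu_mask <- function(image, exclusion = NULL) {
  rng <- range(image)
  if (diff(rng) == 0)
    stop("cannot Otsu-threshold a single-valued image")
  thr <- EBImage::otsu(image, range = rng, levels = 256)
  mask <- image > thr
  if (!is.null(exclusion)) mask <- mask & !exclusion
  attr(mask, "threshold") <- thr
  mask
}

#' Pixel-wise generalized polarization image
#'
#' For every masked pixel computes GP = (I_B - I_R)/(I_B + I_R), where I_B
#' and I_R are the counts in the channels nearest `lambda_blue` and
#' `lambda_red` (ties break toward the shorter wavelength).  Pixels whose
#' summed intensity I_B + I_R falls below `min_counts` are dropped from the
#' mask (the ratio estimator is strongly biased at low counts); the number
#' dropped is recorded.
#'
#' @param stack a [spectral_stack()].
#' @param mask logical matrix selecting membrane pixels.
#' @param lambda_blue,lambda_red analysis wavelengths in nm.
#' @param min_counts minimum I_B + I_R for a pixel to be evaluated.
#' @return an object of class `gp_image`: list with `gp` (matrix, `NA`
#'   outside the evaluated mask), `mask`, `lambda_blue`/`lambda_red` (the
#'   channel centres actually used), and `n_dropped_low_counts`.
#' @export
compute_gp <- function(stack, mask, lambda_blue = 570, lambda_red = 640,
                       min_counts = 10) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (!any(mask)) stop("mask is empty")
  iB <- nearest_channel(stack$channel_centers, lambda_blue)
  iR <- nearest_channel(stack$channel_centers, lambda_red)
  if (iB == iR) stop("blue and red wavelengths resolve to the same channel")
  IB <- stack$data[iB, , ]
  IR <- stack$data[iR, , ]
  tot <- IB + IR
  if (all(tot[mask] == 0))
    stop("I_B + I_R is zero on every masked pixel")
  keep <- mask & tot >= min_counts
  gp <- matrix(NA_real_, nrow(IB), ncol(IB))
  gp[keep] <- (IB[keep] - IR[keep]) / tot[keep]
  structure(list(gp = gp, mask = keep,
                 lambda_blue = stack$channel_centers[iB],
                 lambda_red = stack$channel_centers[iR],
                 min_counts = min_counts,
                 n_dropped_low_counts = sum(mask) - sum(keep)),
            class = "gp_image")
}

#' Mean GP of one vesicle
#'
#' Unweighted mean over all defined GP pixels; averaging over the whole ring
#' smooths out the orientation-dependent photoselection artifact.
#'
#' @param gp_image a [compute_gp()] result.
#' @param vesicle_id,condition,replicate labels carried into the record.
#' @return one-row data.frame (`vesicle_id`, `condition`, `modality`,
#'   `value`, `n_pixels`, `replicate`).
#' @export
vesicle_mean_gp <- function(gp_image, vesicle_id = 1L, condition = NA_character_,
                            replicate = NA_integer_) {
  stopifnot(inherits(gp_image, "gp_image"))
  vals <- gp_image$gp[!is.na(gp_image$gp)]
  if (length(vals) == 0) stop("no defined GP pixels to average")
  data.frame(vesicle_id = vesicle_id, condition = condition,
             modality = "GP", value = mean(vals), n_pixels = length(vals),
             replicate = replicate)
}

#' Full spectral GP pipeline for one field of view
#'
#' Composition of the analysis stages in order: channel registration,
#' maximum intensity projection, brightness-outlier exclusion, percentile
#' contrast stretch, Otsu segmentation (largest connected component kept if
#' several vesicles are present), pixel-wise GP, per-vesicle mean.
#'
#' @param stack a [spectral_stack()].
#' @param lambda_blue,lambda_red GP analysis wavelengths, nm.
#' @param low_pct,high_pct contrast-stretch percentiles.
#' @param min_counts minimum-count floor for GP pixels.
#' @param register whether to run channel registration first.
#' @param outlier_mode,outlier_quantile_pct,outlier_absolute brightness
#'   outlier handling, see [exclude_bright_outliers()].
#' @param vesicle_id,condition,replicate labels for the record.
#' @return list with `record` (one-row data.frame), `gp_image`, `mask`, and
#'   `log` (every threshold and channel actually used).
#' @export
run_gp_pipeline <- function(stack, lambda_blue = 570, lambda_red = 640,
                            low_pct = 1, high_pct = 99, min_counts = 10,
                            register = TRUE,
                            outlier_mode = "quantile",
                            outlier_quantile_pct = 99.9,
                            outlier_absolute = NULL,
                            vesicle_id = 1L, condition = NA_character_,
                            replicate = NA_integer_) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (register) stack <- register_stack(stack)
  proj <- max_projection(stack)
  excl <- exclude_bright_outliers(proj, threshold_mode = outlier_mode,
                                  quantile_pct = outlier_quantile_pct,
                                  absolute_threshold = outlier_absolute)
  stretched <- contrast_stretch(proj, low_pct, high_pct)
  mask <- otsu_mask(stretched, exclusion = excl)
  otsu_thr <- attr(mask, "threshold")
  n_components <- NA_integer_
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    n_components <- max(lab)
    if (n_components > 1) {
      sizes <- tabulate(lab[lab > 0])
      mask <- lab == which.max(sizes)
    }
  }
  gp_img <- compute_gp(stack, mask, lambda_blue, lambda_red, min_counts)
  rec <- vesicle_mean_gp(gp_img, vesicle_id = vesicle_id,
                         condition = condition, replicate = replicate)
  list(record = rec, gp_image = gp_img, mask = mask,
       log = list(otsu_threshold = otsu_thr,
                  outlier_mode = outlier_mode,
                  outlier_quantile_pct = outlier_quantile_pct,
                  outlier_absolute = outlier_absolute,
                  contrast_percentiles = c(low_pct, high_pct),
                  min_counts = min_counts,
                  lambda_blue_channel = gp_img$lambda_blue,
                  lambda_red_channel = gp_img$lambda_red,
                  n_connected_components = n_components,
                  n_dropped_low_counts = gp_img$n_dropped_low_counts,
                  registration = stack$meta$registration))
}
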