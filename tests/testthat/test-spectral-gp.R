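# Spectral GP analysis: registration, masking, pixel-wise GP and the
# composed per-vesicle pipeline.

test_that("registration recovers constructed shifts and respects degenerate input", {
  sp <- small_spectral_spec(seed = 21)
  stack <- simulate_spectral_stack(sp)$stack

  # identical channels: zero shifts, output equals input
  arr_same <- array(0, dim = c(3, 64, 64))
  for (k in 1:3) arr_same[k, , ] <- stack$data[8, , ]
  same <- spectral_stack(arr_same, c(565, 575, 585))
  reg <- register_stack(same)
  expect_identical(reg$data, same$data)
  expect_true(all(reg$meta$registration$shifts[, c("dy", "dx")] == 0))

  # a bright (non-reference) channel rolled by (3, -2) is rolled back
  # exactly; the reported shift is the one applied to restore alignment
  ch <- order(apply(stack$data, 1, sum), decreasing = TRUE)[2]
  shifted <- stack
  shifted$data[ch, , ] <- guvchol:::roll_matrix(stack$data[ch, , ], 3, -2)
  reg2 <- suppressWarnings(register_stack(shifted))
  expect_equal(reg2$data[ch, , ], stack$data[ch, , ])
  expect_equal(unlist(reg2$meta$registration$shifts[ch, c("dy", "dx")]),
               c(dy = -3, dx = 2), ignore_attr = TRUE)
  # counts preserved by the circular shift
  expect_equal(sum(reg2$data), sum(shifted$data))

  # structureless noise channel: shift capped, warning emitted, left in place
  noisy <- stack
  noisy$data[14, , ] <- matrix(guvchol:::withr_seed(1, rpois(64 * 64, 0.2)), 64, 64)
  expect_warning(reg3 <- register_stack(noisy, max_shift = 2), "cap")

  # all-zero channel skipped with warning
  zero <- stack
  zero$data[14, , ] <- 0
  expect_warning(register_stack(zero), "empty")
})

test_that("max projection is the pixel-wise channel maximum", {
  arr <- array(0, dim = c(2, 8, 8))
  arr[2, , ] <- 5
  st <- spectral_stack(arr, c(565, 575))
  expect_equal(max_projection(st), matrix(5, 8, 8))

  # disjoint bright structures: union survives
  a <- matrix(0, 8, 8); a[2, ] <- 10
  b <- matrix(0, 8, 8); b[, 7] <- 8
  arr2 <- array(0, dim = c(2, 8, 8))
  arr2[1, , ] <- a; arr2[2, , ] <- b
  st2 <- spectral_stack(arr2, c(565, 575))
  expect_equal(max_projection(st2), pmax(a, b))
})

test_that("bright-outlier exclusion flags exactly the offending pixels", {
  img <- matrix(100, 16, 16)
  expect_equal(sum(exclude_bright_outliers(img, "absolute",
                                           absolute_threshold = 200)), 0)

  img[5, 7] <- 60000   # one saturated pixel
  excl <- exclude_bright_outliers(img, "absolute", absolute_threshold = 5000)
  expect_equal(which(excl), which(img == 60000))

  # constant image, quantile mode: nothing above the quantile of itself
  flat <- matrix(7, 16, 16)
  expect_lte(sum(exclude_bright_outliers(flat, "quantile")), 0.001 * 256)

  # excluding most of the image is refused
  expect_error(exclude_bright_outliers(img, "absolute", absolute_threshold = 50),
               "half")
})

test_that("contrast stretch is a clamped monotone rescale", {
  img <- matrix(runif(400, 10, 50), 20, 20)
  s <- contrast_stretch(img, 0, 100)
  expect_equal(s, (img - min(img)) / (max(img) - min(img)))

  # linear ramp with (1, 99): tails clamp to 0 and 1
  ramp <- matrix(seq(0, 1, length.out = 1e4), 100, 100)
  s2 <- contrast_stretch(ramp, 1, 99)
  q <- quantile(ramp, c(0.01, 0.99))
  expect_true(all(s2[ramp <= q[1]] == 0))
  expect_true(all(s2[ramp >= q[2]] == 1))
  # order preserved in between
  expect_true(all(diff(s2[, 50]) >= 0))

  expect_warning(contrast_stretch(matrix(3, 5, 5)), "degenerate")
  expect_error(contrast_stretch(img, 99, 1))
})

test_that("Otsu mask separates two-level images exactly and survives noise", {
  ring <- matrix(10, 32, 32)
  ring[10:20, 10:20] <- 100
  m <- otsu_mask(ring)
  expect_equal(unname(m), ring == 100, ignore_attr = TRUE)

  # inversion selects the complementary class
  m_inv <- otsu_mask(max(ring) + min(ring) - ring)
  expect_equal(unname(m_inv), ring == 10, ignore_attr = TRUE)

  expect_error(otsu_mask(matrix(1, 4, 4)), "single-valued")

  # Poisson phantom at default brightness and field size: mask recovers the
  # true ring
  sim <- simulate_spectral_stack(spectral_phantom_spec(seed = 31))
  proj <- max_projection(sim$stack)
  mask <- otsu_mask(contrast_stretch(proj, 1, 99))
  truth <- sim$ground_truth$membrane_mask
  expect_gte(sum(mask & truth) / sum(truth), 0.95)
  expect_lte(sum(mask & !truth) / sum(!truth), 0.01)
})

test_that("pixel-wise GP follows the ratiometric definition", {
  d <- array(0, dim = c(2, 4, 4))
  d[1, , ] <- 90; d[2, , ] <- 30
  st <- spectral_stack(d, c(565, 635))
  mask <- matrix(TRUE, 4, 4)
  g <- compute_gp(st, mask, min_counts = 0)
  expect_equal(unique(as.vector(g$gp)), 0.5)

  # I_B = I_R: GP = 0
  d2 <- d; d2[2, , ] <- 90
  expect_equal(unique(as.vector(
    compute_gp(spectral_stack(d2, c(565, 635)), mask, min_counts = 0)$gp)), 0)

  # swapping blue and red negates GP pixel-wise
  g_swap <- compute_gp(st, mask, lambda_blue = 640, lambda_red = 570,
                       min_counts = 0)
  expect_equal(g_swap$gp, -g$gp)

  # low-count pixels drop out of the mask and are counted
  d3 <- d; d3[, 1, 1] <- 2
  g3 <- compute_gp(spectral_stack(d3, c(565, 635)), mask, min_counts = 10)
  expect_true(is.na(g3$gp[1, 1]))
  expect_equal(g3$n_dropped_low_counts, 1)

  # all-zero on mask errors
  expect_error(compute_gp(spectral_stack(array(0, dim = c(2, 4, 4)),
                                         c(565, 635)), mask), "zero")
})

test_that("vesicle mean GP averages defined pixels only", {
  gp <- matrix(NA_real_, 6, 6)
  gp[2, 1:3] <- -0.4
  gp[4, 1:3] <- -0.2
  img <- structure(list(gp = gp, mask = !is.na(gp), lambda_blue = 565,
                        lambda_red = 635, min_counts = 0,
                        n_dropped_low_counts = 0), class = "gp_image")
  rec <- vesicle_mean_gp(img, vesicle_id = 3L, condition = "mix")
  expect_equal(rec$value, -0.3)
  expect_equal(rec$n_pixels, 6)
  expect_equal(rec$condition, "mix")

  empty <- img; empty$gp[] <- NA_real_
  expect_error(vesicle_mean_gp(empty), "no defined")
})

test_that("noise-free pipeline returns the true GP exactly and scales invariantly", {
  sp <- small_spectral_spec(gp_true = -0.37, background_rate = 0)
  st <- noise_free_stack(sp)
  res <- run_gp_pipeline(st, register = FALSE)
  expect_equal(res$record$value, -0.37, tolerance = 1e-10)

  # multiplying the stack by c > 0 leaves noise-free GP unchanged
  st2 <- st; st2$data <- st$data * 7.3
  res2 <- run_gp_pipeline(st2, register = FALSE)
  expect_equal(res2$record$value, res$record$value, tolerance = 1e-10)

  # every reported pixel GP within [-1, 1] on noisy phantoms
  sim <- simulate_spectral_stack(small_spectral_spec(gp_true = -0.9, seed = 8))
  out <- suppressWarnings(run_gp_pipeline(sim$stack))
  vals <- out$gp_image$gp[!is.na(out$gp_image$gp)]
  expect_true(all(vals >= -1 & vals <= 1))
  expect_true(res$record$value >= -1 && res$record$value <= 1)

  # all-zero stack fails at the masking stage with a clean error
  zeros <- spectral_stack(array(0, dim = c(3, 16, 16)), c(565, 575, 585))
  expect_error(suppressWarnings(run_gp_pipeline(zeros)))
})

test_that("pipeline mean GP is unbiased at the default photon budget", {
  recovered <- vapply(1:20, function(i) {
    sim <- simulate_spectral_stack(small_spectral_spec(gp_true = -0.3, seed = 300 + i))
    suppressWarnings(run_gp_pipeline(sim$stack)$record$value)
  }, numeric(1))
  expect_lt(abs(mean(recovered) + 0.3), 0.02)
})

test_that("multi-vesicle fields keep the largest connected component", {
  # two rings in one field: build by summing two noise-free phantoms
  g1 <- guv_geometry(center = c(20, 20), radius = 12, ring_width = 4,
                     image_size = c(64L, 64L))
  g2 <- guv_geometry(center = c(48, 48), radius = 8, ring_width = 4,
                     image_size = c(64L, 64L))
  s1 <- noise_free_stack(spectral_phantom_spec(g1, gp_true = -0.4,
                                               background_rate = 0))
  s2 <- noise_free_stack(spectral_phantom_spec(g2, gp_true = 0.2,
                                               background_rate = 0))
  both <- s1; both$data <- s1$data + s2$data
  res <- run_gp_pipeline(both, register = FALSE)
  expect_gt(res$log$n_connected_components, 1)
  # the larger ring dominates: mean GP reflects its truth
  expect_equal(res$record$value, -0.4, tolerance = 1e-6)
})
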