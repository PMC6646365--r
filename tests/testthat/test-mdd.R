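test_that("MDD profiles are normalized to unit area and guard degenerate input", {
  set.seed(41)
  v <- as_grey8(array(rnorm(40^3, 120, 15), c(40, 40, 40)))
  prof <- compute_mdd(v)
  area <- sum(diff(prof$density_axis) *
                (prof$frequency[-256] + prof$frequency[-1]) / 2)
  expect_lt(abs(area - 1), 1e-9)
  expect_equal(sum(prof$mass), 1, tolerance = 1e-12)

  expect_warning(pc <- compute_mdd(as_grey8(array(80, c(12, 12, 12)))),
                 "degenerate")
  expect_true(pc$degenerate)
  expect_error(compute_mdd(v, tissue_mask = array(FALSE, c(40, 40, 40))),
               "too small")
})

test_that("the profile of a two-Gaussian phantom matches the generating mixture", {
  tc <- two_class_volume(c(60, 60, 60), frac = 0.4, mu = c(90, 170),
                         sd = c(12, 12), seed = 43)
  prof <- compute_mdd(tc$volume)
  x <- 0:255
  target <- 0.6 * dnorm(x, 90, 12) + 0.4 * dnorm(x, 170, 12)
  expect_lt(max(abs(prof$frequency - target)), 6 / sqrt(60^3))
})

test_that("smoothing interpolates at zero, preserves area, finds the mode", {
  set.seed(47)
  v <- as_grey8(array(rnorm(50^3, 120, 15), c(50, 50, 50)))
  prof <- compute_mdd(v)
  p0 <- smooth_profile(prof, smoothing = 0)
  at_bins <- approx(p0$smooth$x, p0$smooth$y, xout = prof$density_axis)$y
  # interpolation up to the post-clipping re-normalization factor
  expect_lt(max(abs(at_bins - prof$frequency)), 1e-4)

  ps <- smooth_profile(prof)
  fine_area <- sum(diff(ps$smooth$x) *
                     (ps$smooth$y[-length(ps$smooth$y)] + ps$smooth$y[-1]) / 2)
  expect_lt(abs(fine_area - 1), 1e-6)
  expect_lt(abs(ps$smooth$x[which.max(ps$smooth$y)] - 120), 1)
})

test_that("reference ranges are the P and 1-P quantiles of the pooled distribution", {
  set.seed(53)
  v <- as_grey8(array(rnorm(40^3, 110, 12), c(40, 40, 40)))
  prof <- compute_mdd(v)
  ref <- compute_reference_range(list(prof), P = 0.005)
  # brute-force quantiles of the voxel sample itself
  q <- quantile(as.vector(v$voxels), c(0.005, 0.995), names = FALSE, type = 7)
  expect_lt(abs(ref$low_cut - q[1]), 1)
  expect_lt(abs(ref$high_cut - q[2]), 1)

  # pooling two profiles equals quantiles of the concatenated samples
  v2 <- as_grey8(array(rnorm(40^3, 130, 12), c(40, 40, 40)))
  prof2 <- compute_mdd(v2)
  ref2 <- compute_reference_range(list(prof, prof2), P = 0.05)
  qq <- quantile(c(as.vector(v$voxels), as.vector(v2$voxels)),
                 c(0.05, 0.95), names = FALSE, type = 7)
  expect_lt(abs(ref2$low_cut - qq[1]), 1)
  expect_lt(abs(ref2$high_cut - qq[2]), 1)

  # symmetric profile -> cuts symmetric about the centre
  expect_lt(abs((ref$low_cut + ref$high_cut) / 2 - mean(v$voxels)), 1)
  expect_error(compute_reference_range(list()), "empty")
})

test_that("Gaussian grey volumes reproduce the closed-form descriptors", {
  set.seed(59)
  v <- as_grey8(array(rnorm(80^3, 120, 15), c(80, 80, 80)))
  prof <- smooth_profile(compute_mdd(v))
  ref <- compute_reference_range(list(prof), P = 0.005)
  pars <- extract_mdd_parameters(prof, ref)
  expect_lt(abs(pars$peak - 120), 1)
  expect_lt(abs(pars$mean - 120), 0.5)
  expect_lt(abs(pars$fwhm - 2 * sqrt(2 * log(2)) * 15), 1.5)
  # a profile scored against its own reference leaves P mass in each tail
  expect_lt(abs(pars$low - 0.5), 0.2)
  expect_lt(abs(pars$high - 0.5), 0.2)
  expect_false(pars$multimodal)
  expect_lte(pars$low + pars$high, 100)
})

test_that("mean exceeds peak for right-skewed profiles and coincides for symmetric", {
  set.seed(61)
  sym <- as_grey8(array(rnorm(40^3, 120, 10), c(40, 40, 40)))
  psym <- smooth_profile(compute_mdd(sym))
  ref <- compute_reference_range(list(psym))
  parsym <- extract_mdd_parameters(psym, ref)
  expect_lt(abs(parsym$mean - parsym$peak), 1)

  skewed <- as_grey8(array(100 + rexp(40^3, 1 / 20), c(40, 40, 40)))
  pskew <- smooth_profile(compute_mdd(skewed))
  parskew <- extract_mdd_parameters(pskew, ref)
  expect_gt(parskew$mean, parskew$peak + 1)
})

test_that("high-density contamination raises the high tail monotonically", {
  set.seed(67)
  base <- array(rnorm(40^3, 110, 12), c(40, 40, 40))
  ref <- compute_reference_range(list(compute_mdd(as_grey8(base))), 0.005)
  highs <- vapply(c(0, 0.02, 0.05, 0.1), function(q) {
    contaminated <- base
    n <- length(base)
    pick <- sample(n, round(q * n))
    contaminated[pick] <- runif(length(pick), 180, 240)
    p <- smooth_profile(compute_mdd(as_grey8(contaminated)))
    extract_mdd_parameters(p, ref)$high
  }, numeric(1))
  expect_true(all(diff(highs) > 0))
  # contamination mass lies almost entirely beyond the cut
  expect_lt(abs(highs[4] - (0.5 + 10)) , 1.5)
})

test_that("descriptors are stable under re-binning of a float volume", {
  set.seed(71)
  vals <- array(rnorm(50^3, 120, 15), c(50, 50, 50))
  v <- volume_image(vals, 1, "retrieved_float")
  p256 <- smooth_profile(compute_mdd(v, bins = 256, range = c(0, 255)))
  p512 <- smooth_profile(compute_mdd(v, bins = 512, range = c(0, 255)))
  ref256 <- compute_reference_range(list(p256), 0.005)
  ref512 <- compute_reference_range(list(p512), 0.005)
  a <- extract_mdd_parameters(p256, ref256)
  b <- extract_mdd_parameters(p512, ref512)
  expect_lt(abs(a$peak - b$peak), 1)
  expect_lt(abs(a$mean - b$mean), 0.5)
  expect_lt(abs(a$fwhm - b$fwhm), 1.5)
  expect_lt(abs(a$low - b$low), 0.2)
  expect_lt(abs(a$high - b$high), 0.2)
})

test_that("fibrotic phantoms widen the distribution relative to their controls", {
  ctr <- generate_fiber_phantom(phantom_spec(
    shape_um = c(150, 150, 100), voxel_size_um = 2.5,
    target_coll_fraction = 0.05, bundle_radius_um = c(6, 1.5),
    bright_spot_rate = 0, seed = 73))
  lei <- generate_fiber_phantom(phantom_spec(
    shape_um = c(150, 150, 100), voxel_size_um = 2.5,
    target_coll_fraction = 0.40, bundle_radius_um = c(15, 3),
    bright_spot_rate = 0, seed = 73))
  pc <- smooth_profile(compute_mdd(ctr$volume))
  pl <- smooth_profile(compute_mdd(lei$volume))
  ref <- compute_reference_range(list(pc), 0.005)
  parc <- extract_mdd_parameters(pc, ref)
  parl <- extract_mdd_parameters(pl, ref)
  expect_gt(parl$fwhm, parc$fwhm)
  expect_gt(parl$high, parc$high)
})
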