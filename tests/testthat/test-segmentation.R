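test_that("histograms are exact integer counts that conserve mass", {
  v <- as_grey8(array(7, c(10, 10, 10)))
  h <- compute_histogram(v)
  expect_identical(h$counts[8], 1000L)
  expect_identical(sum(h$counts), 1000L)

  set.seed(2)
  v2 <- as_grey8(array(runif(4000, 0, 255), c(20, 20, 10)))
  h2 <- compute_histogram(v2)
  expect_identical(h2$total, 4000L)
  expect_identical(sum(h2$counts), 4000L)

  region <- array(FALSE, c(20, 20, 10))
  expect_error(compute_histogram(v2, region), "empty region")
  region[1:5, , ] <- TRUE
  expect_identical(compute_histogram(v2, region)$total, 1000L)
})

test_that("the histogram of a two-class phantom matches the generating mixture", {
  tc <- two_class_volume(c(60, 60, 60), frac = 0.4, seed = 11)
  h <- compute_histogram(tc$volume)
  x <- 0:255
  expected <- (0.6 * dnorm(x, 80, 10) + 0.4 * dnorm(x, 180, 10)) * h$total
  keep <- expected > 5
  chi2 <- sum((h$counts[keep] - expected[keep])^2 / expected[keep])
  # multinomial sampling: chi2 ~ df; allow a generous band
  expect_lt(chi2, 2.5 * sum(keep))
})

test_that("gaussian_intersection solves symmetric, general and degenerate cases", {
  expect_equal(gaussian_intersection(list(mean = 50, sd = 10, weight = .5),
                                     list(mean = 150, sd = 10, weight = .5)),
               100)
  # unequal-sd crossing against a dense numeric scan of the weighted pdfs
  a <- list(mean = 80, sd = 10, weight = 0.5)
  b <- list(mean = 180, sd = 20, weight = 0.5)
  x <- gaussian_intersection(a, b)
  xs <- seq(80, 180, by = 1e-4)
  dens <- function(c_, x_) c_$weight * dnorm(x_, c_$mean, c_$sd)
  grid <- xs[which.min(abs(dens(a, xs) - dens(b, xs)))]
  expect_lt(abs(x - grid), 1e-3)
  # unequal weights shift the equal-sd threshold by s^2 log(w1/w2)/dm
  aw <- list(mean = 100, sd = 8, weight = 0.8)
  bw <- list(mean = 140, sd = 8, weight = 0.2)
  expect_equal(gaussian_intersection(aw, bw),
               120 + 64 * log(0.8 / 0.2) / 40, tolerance = 1e-9)

  expect_error(gaussian_intersection(list(mean = 50, sd = 5, weight = .5),
                                     list(mean = 50, sd = 5, weight = .5)),
               "mean")
  expect_warning(
    t_ <- gaussian_intersection(list(mean = 100, sd = 1, weight = 1e-9),
                                list(mean = 104, sd = 1, weight = 1 - 1e-9)),
    "boundary")
  expect_gte(t_, 100); expect_lte(t_, 104)
})

test_that("the split-search mixture fit recovers well-separated components", {
  h <- mixture_histogram(1e6, 0.5, 80, 10, 180, 10)
  fit <- fit_two_gaussians(h)
  expect_lt(abs(fit$threshold - 130), 2)
  expect_lt(abs(fit$muscle$mean - 80), 1)
  expect_lt(abs(fit$collagen$mean - 180), 1)
  expect_true(fit$muscle$mean <= fit$threshold &&
              fit$threshold <= fit$collagen$mean)
  expect_equal(fit$muscle$weight + fit$collagen$weight, 1)

  # optimality: the selected split's SSE is minimal among all candidates
  sse_at_split <- function(s) {
    n <- h$counts; N <- h$total; x <- 0:255
    li <- 1:s; ri <- (s + 1):256
    nl <- sum(n[li]); nr <- N - nl
    ml <- sum(n[li] * x[li]) / nl; sl <- sqrt(sum(n[li] * x[li]^2) / nl - ml^2)
    mr <- sum(n[ri] * x[ri]) / nr; sr <- sqrt(sum(n[ri] * x[ri]^2) / nr - mr^2)
    mix <- (nl / N) * dnorm(x, ml, sl) + (nr / N) * dnorm(x, mr, sr)
    sum((mix - n / N)^2)
  }
  others <- vapply(c(60, 100, 130, 160, 200), sse_at_split, numeric(1))
  expect_true(all(fit$fit_error <= others + 1e-15))

  # EM comparison route lands on the same components
  fit_em <- fit_two_gaussians(h, method = "em")
  expect_lt(abs(fit_em$threshold - fit$threshold), 2)
})

test_that("a unimodal histogram triggers the overlap warning", {
  h <- mixture_histogram(1e5, 0.5, 118, 15, 122, 15)
  expect_warning(fit_two_gaussians(h), "unimodal")
  expect_error(fit_two_gaussians(
    structure(list(counts = c(5L, 5L, rep(0L, 254)), total = 10L),
              class = "grey_histogram")), "3 distinct")
})

test_that("threshold recovery on a voxel phantom is within 2 grey levels", {
  tc <- two_class_volume(c(60, 60, 60), frac = 0.5, seed = 13)
  fit <- fit_two_gaussians(compute_histogram(tc$volume))
  expect_lt(abs(fit$threshold - 130), 2)
  # misclassification at the recovered threshold matches the analytic overlap
  mask <- apply_threshold(tc$volume, round(fit$threshold))
  mis <- mean(mask$voxels != tc$class)
  overlap <- 0.5 * pnorm(130, 180, 10) + 0.5 * pnorm(130, 80, 10,
                                                     lower.tail = FALSE)
  expect_lt(abs(mis - overlap), 0.002)
})

test_that("slice-averaged thresholds behave under homogeneity and drift", {
  tc <- two_class_volume(c(40, 40, 24), frac = 0.5, seed = 17)
  t_all <- fit_two_gaussians(compute_histogram(tc$volume))$threshold
  t_avg <- slice_averaged_threshold(tc$volume, 12)
  expect_lte(abs(t_avg - t_all), 1.5)

  t_one <- slice_averaged_threshold(tc$volume, 1)
  h1 <- compute_histogram(
    volume_image(tc$volume$voxels[, , 1, drop = FALSE], 1, "grey8"))
  expect_identical(t_one,
                   as.integer(round(fit_two_gaussians(h1)$threshold)),
                   ignore_attr = TRUE)

  # z-gradient phantom: averaged threshold lies between per-slice extremes
  set.seed(19)
  nz <- 12
  arr <- array(0, c(40, 40, nz))
  for (k in seq_len(nz)) {
    drift <- 2 * k
    cls <- runif(1600) < 0.5
    g <- ifelse(cls, rnorm(1600, 170 + drift, 10), rnorm(1600, 70 + drift, 10))
    arr[, , k] <- g
  }
  v <- as_grey8(arr)
  t_avg2 <- slice_averaged_threshold(v, nz)
  per <- attr(t_avg2, "per_slice")
  expect_gte(t_avg2, min(per, na.rm = TRUE) - 0.5)
  expect_lte(t_avg2, max(per, na.rm = TRUE) + 0.5)
})

test_that("mask cleaning removes specks and pinholes but keeps structure", {
  # a solid slab with pinholes, plus isolated specks in the background
  m <- array(FALSE, c(40, 40, 21))
  m[, , 8:14] <- TRUE
  set.seed(29)
  holes <- cbind(sample(3:38, 30, TRUE), sample(3:38, 30, TRUE),
                 sample(9:13, 30, TRUE))
  m[holes] <- FALSE
  specks <- cbind(sample(3:38, 20, TRUE), sample(3:38, 20, TRUE),
                  sample(c(2:5, 17:20), 20, TRUE))
  m[specks] <- TRUE
  dirty <- collagen_mask(m, 1)
  clean <- clean_mask(dirty)
  expect_true(all(clean$voxels[, , 8:14]))       # holes filled
  expect_false(any(clean$voxels[, , c(1:7, 15:21)]))  # specks removed
  # pinholes would otherwise collapse the local thickness
  expect_lt(abs(local_thickness(clean)$mean_um - 7), 0.5)

  # background connected to the border is never filled
  tube <- array(FALSE, c(15, 15, 15))
  tube[4:12, 4:12, 4:12] <- TRUE
  tube[8, 8, ] <- FALSE          # open channel through the block
  cleaned <- clean_mask(collagen_mask(tube, 1))
  expect_false(any(cleaned$voxels[8, 8, ]))
})

test_that("thresholding is strict and monotone in t", {
  tc <- two_class_volume(c(20, 20, 20), frac = 0.5, seed = 23)
  expect_false(any(apply_threshold(tc$volume, 255)$voxels))
  fr <- vapply(seq(0, 255, by = 15),
               function(t) mean(apply_threshold(tc$volume, t)$voxels),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  # voxels equal to t go to muscle
  v <- as_grey8(array(c(109, 110, 111), c(3, 1, 1)))
  expect_identical(as.vector(apply_threshold(v, 110)$voxels),
                   c(FALSE, FALSE, TRUE))
})
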