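#' Grey-level histogram of an 8-bit volume
#'
#' Exact integer counts over the 256 grey bins, optionally restricted to a
#' region mask.
#'
#' @param volume a grey8 [volume_image()].
#' @param region optional logical array or [collagen_mask()] selecting the
#'   voxels to count.
#' @return An object of class `grey_histogram`: list with `counts` (length
#'   256, bin i+1 holds grey value i) and `total`.
#' @export
compute_histogram <- function(volume, region = NULL) {
  stopifnot_volume(volume, "grey8")
  v <- volume$voxels
  if (!is.null(region)) {
    if (inherits(region, "collagen_mask")) region <- region$voxels
    v <- v[region]
    if (length(v) == 0L) stop("empty region")
  }
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "grey_histogram")
}

#' @export
print.grey_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<grey_histogram> %d voxels, grey range [%d, %d]\n",
              x$total, min(nz) - 1L, max(nz) - 1L))
  invisible(x)
}

#' Intersection of two weighted Gaussians
#'
#' Solves `w_a N(x; mu_a, sd_a) = w_b N(x; mu_b, sd_b)` for the crossing
#' between the two means - the mixture-model threshold. With equal standard
#' deviations the solution is the closed linear form; otherwise the
#' quadratic is solved and the root inside `[mu_a, mu_b]` returned. If no
#' root falls between the means (extreme weight imbalance) the
#' error-minimizing boundary on a fine grid is returned with a warning.
#'
#' @param a,b lists with elements `mean`, `sd`, `weight` (the two mixture
#'   components, `a$mean < b$mean`).
#' @return The threshold grey value (numeric scalar).
#' @export
gaussian_intersection <- function(a, b) {
  if (!(a$mean < b$mean)) stop("requires a$mean < b$mean")
  s1 <- a$sd; s2 <- b$sd; m1 <- a$mean; m2 <- b$mean
  lw <- log((a$weight / s1) / (b$weight / s2))
  if (abs(s1 - s2) < 1e-9) {
    # linear case: (x-m1)^2 - (x-m2)^2 = 2 s^2 lw
    x <- (m1 + m2) / 2 + s1^2 * lw / (m2 - m1)
    if (x >= m1 && x <= m2) return(x)
  } else {
    A <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
    B <- m2 / s2^2 - m1 / s1^2
    C <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - lw
    disc <- B^2 - 4 * A * C
    if (disc >= 0) {
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      inside <- roots[roots >= m1 & roots <= m2]
      if (length(inside) == 1L) return(inside)
      if (length(inside) == 2L) return(min(inside))
    }
  }
  warning("no Gaussian crossing between the means; using error-minimizing boundary")
  xs <- seq(m1, m2, length.out = 2048L)
  # total misclassification if thresholding at x
  err <- a$weight * pnorm(xs, m1, s1, lower.tail = FALSE) +
    b$weight * pnorm(xs, m2, s2)
  xs[which.min(err)]
}

#' Two-Gaussian mixture fit of a grey histogram
#'
#' Histogram-based mixture modelling: for every candidate split
#' `s in [1, 254]` the two sub-histograms (grey < s and grey >= s) are
#' summarized by moment-matched Gaussians (weight, mean, sd), the implied
#' two-Gaussian mixture density is compared to the empirical histogram by
#' summed squared error, and the best-scoring split's components are kept.
#' The reported threshold is the [gaussian_intersection()] of the selected
#' pair - the muscle component is the left (lower-mean) Gaussian, the
#' collagen component the right one.
#'
#' A warning is issued when the two components overlap so heavily that the
#' histogram is effectively unimodal (component means closer than one
#' pooled standard deviation).
#'
#' @param hist a `grey_histogram` from [compute_histogram()].
#' @param method `"split"` (exhaustive split search with moment matching,
#'   default, mirroring the classic histogram-plugin behaviour) or `"em"`
#'   (expectation-maximization on binned data, for comparison).
#' @return An object of class `mixture_fit`: components `muscle` and
#'   `collagen` (each `mean`, `sd`, `weight`), `threshold`, `fit_error`
#'   (summed squared difference between implied mixture and empirical
#'   frequencies), and `split`.
#' @export
fit_two_gaussians <- function(hist, method = c("split", "em")) {
  method <- match.arg(method)
  if (!inherits(hist, "grey_histogram")) stop("expected a `grey_histogram`")
  n <- hist$counts
  N <- hist$total
  if (sum(n > 0) < 3L) stop("histogram needs mass in at least 3 distinct bins")
  x <- 0:255
  p <- n / N
  if (method == "em") {
    fit <- em_two_gaussians(x, n)
  } else {
    cs_n <- cumsum(n)
    cs_x <- cumsum(n * x)
    cs_x2 <- cumsum(n * x^2)
    best <- NULL
    for (s in 1:254) {
      nl <- cs_n[s]                 # bins 0 .. s-1
      nr <- N - nl
      if (nl < 2 || nr < 2) next
      ml <- cs_x[s] / nl
      vl <- cs_x2[s] / nl - ml^2
      mr <- (cs_x[256] - cs_x[s]) / nr
      vr <- (cs_x2[256] - cs_x2[s]) / nr - mr^2
      if (vl <= 0 || vr <= 0) next
      sl <- sqrt(vl); sr <- sqrt(vr)
      mix <- (nl / N) * dnorm(x, ml, sl) + (nr / N) * dnorm(x, mr, sr)
      sse <- sum((mix - p)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(sse = sse, s = s, wl = nl / N, ml = ml, sl = sl,
                     wr = nr / N, mr = mr, sr = sr)
    }
    if (is.null(best))
      stop("mixture fit failed: all candidate splits degenerate")
    fit <- best
  }
  muscle <- list(mean = fit$ml, sd = fit$sl, weight = fit$wl)
  collagen <- list(mean = fit$mr, sd = fit$sr, weight = fit$wr)
  thr <- suppressWarnings(gaussian_intersection(muscle, collagen))
  # model-misfit detection: a genuinely bimodal mixture dips between the
  # component means; if the empirical histogram shows no dip at the
  # threshold the two-Gaussian model is questionable
  peaks <- p[pmin(256, pmax(1, round(c(muscle$mean, collagen$mean)) + 1))]
  at_thr <- p[pmin(256, pmax(1, round(thr) + 1))]
  if (min(peaks) > 0 && at_thr > 0.8 * min(peaks))
    warning("no clear dip between components: histogram may be unimodal (two-Gaussian fit unreliable)")
  structure(list(muscle = muscle, collagen = collagen,
                 threshold = thr, fit_error = fit$sse,
                 split = if (!is.null(fit$s)) fit$s else NA_integer_),
            class = "mixture_fit")
}

# binned EM for two Gaussian components (comparison route)
em_two_gaussians <- function(x, n, max_iter = 500, tol = 1e-10) {
  N <- sum(n)
  p <- n / N
  m <- sum(p * x); s <- sqrt(sum(p * x^2) - m^2)
  th <- list(wl = 0.5, ml = m - s, sl = s / 2, wr = 0.5, mr = m + s, sr = s / 2)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dl <- th$wl * dnorm(x, th$ml, th$sl)
    dr <- th$wr * dnorm(x, th$mr, th$sr)
    tot <- dl + dr
    tot[tot == 0] <- .Machine$double.xmin
    g <- dl / tot
    ll <- sum(n * log(tot))
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
    wl <- sum(n * g) / N
    ml <- sum(n * g * x) / sum(n * g)
    sl <- sqrt(sum(n * g * (x - ml)^2) / sum(n * g))
    wr <- 1 - wl
    mr <- sum(n * (1 - g) * x) / sum(n * (1 - g))
    sr <- sqrt(sum(n * (1 - g) * (x - mr)^2) / sum(n * (1 - g)))
    th <- list(wl = wl, ml = ml, sl = max(sl, 0.25),
               wr = wr, mr = mr, sr = max(sr, 0.25))
  }
  if (th$ml > th$mr)
    th <- list(wl = th$wr, ml = th$mr, sl = th$sr,
               wr = th$wl, mr = th$ml, sr = th$sl)
  mix <- th$wl * dnorm(x, th$ml, th$sl) + th$wr * dnorm(x, th$mr, th$sr)
  c(th, list(sse = sum((mix - p)^2), s = NA_integer_))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> threshold %.2f\n",
                     "  muscle:   N(%.2f, %.2f), w = %.3f\n",
                     "  collagen: N(%.2f, %.2f), w = %.3f\n",
                     "  fit error (SSE): %.3g\n"),
              x$threshold, x$muscle$mean, x$muscle$sd, x$muscle$weight,
              x$collagen$mean, x$collagen$sd, x$collagen$weight, x$fit_error))
  invisible(x)
}

#' Slice-averaged mixture-model threshold
#'
#' Fits the two-Gaussian mixture on `n_slices` axial slices at uniformly
#' spaced z positions and returns the arithmetic mean of the per-slice
#' thresholds, rounded to the nearest integer grey level. Slices whose fit
#' fails are skipped with a message; the call errors only if every slice
#' fails.
#'
#' @param volume a grey8 [volume_image()].
#' @param n_slices number of slices to average; default 12.
#' @param method passed to [fit_two_gaussians()].
#' @return Integer threshold, with attribute `per_slice` (the per-slice
#'   thresholds, NA where skipped).
#' @export
slice_averaged_threshold <- function(volume, n_slices = 12,
                                     method = "split") {
  stopifnot_volume(volume, "grey8")
  nz <- dim(volume$voxels)[3]
  if (n_slices < 1 || n_slices > nz)
    stop("n_slices must lie between 1 and the z extent")
  zs <- unique(round(seq(1, nz, length.out = n_slices)))
  th <- rep(NA_real_, length(zs))
  for (i in seq_along(zs)) {
    slice <- volume$voxels[, , zs[i], drop = FALSE]
    h <- structure(list(counts = tabulate(as.vector(slice) + 1L, 256L),
                        total = length(slice)),
                   class = "grey_histogram")
    fit <- tryCatch(suppressWarnings(fit_two_gaussians(h, method = method)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      message(sprintf("slice z = %d skipped: mixture fit failed", zs[i]))
    } else {
      th[i] <- fit$threshold
    }
  }
  if (all(is.na(th))) stop("mixture fit failed on every slice")
  out <- as.integer(round(mean(th, na.rm = TRUE)))
  attr(out, "per_slice") <- th
  out
}

#' Threshold a grey volume into a collagen mask
#'
#' Foreground (collagen) is every voxel with grey value strictly greater
#' than `t`; voxels equal to `t` are assigned to muscle. The strict
#' inequality is fixed so that segmentations are bit-reproducible.
#'
#' @param volume a grey8 [volume_image()].
#' @param t threshold grey value in \[0, 255\].
#' @return A [collagen_mask()].
#' @export
apply_threshold <- function(volume, t) {
  stopifnot_volume(volume, "grey8")
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  collagen_mask(volume$voxels > t, volume$voxel_size_um)
}
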