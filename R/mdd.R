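#' Relative mass-density distribution (MDDr) profile
#'
#' The normalized grey-level frequency distribution of the overall tissue
#' domain. Because grey levels of a phase-retrieved reconstruction are
#' proportional to mass density up to an unknown factor, the distribution is
#' a *relative* density distribution: all descriptors derived from it
#' compare samples to each other, never to absolute density.
#'
#' The profile stores bin centres (`density_axis`), the frequency
#' normalized to unit area under the trapezoid rule (`frequency`), and the
#' per-bin probability masses (`mass`, summing to 1) used for quantile and
#' tail-area computations.
#'
#' @param volume a grey8 [volume_image()], or a `retrieved_float` volume if
#'   `bins`/`range` are given explicitly.
#' @param tissue_mask optional logical array or [collagen_mask()]
#'   restricting the tissue domain.
#' @param bins number of histogram bins (default 256).
#' @param range value range covered by the bins; default `c(0, 255)`.
#' @param min_voxels minimum voxels required (default 1000).
#' @return An object of class `mdd_profile`.
#' @export
compute_mdd <- function(volume, tissue_mask = NULL, bins = 256,
                        range = c(0, 255), min_voxels = 1000) {
  stopifnot_volume(volume)
  v <- as.vector(volume$voxels)
  if (!is.null(tissue_mask)) {
    if (inherits(tissue_mask, "collagen_mask")) tissue_mask <- tissue_mask$voxels
    v <- v[as.vector(tissue_mask)]
  }
  if (length(v) < min_voxels)
    stop(sprintf("tissue domain too small: %d voxels (need >= %d)",
                 length(v), min_voxels))
  width <- (range[2] - range[1]) / bins
  centers <- range[1] + (seq_len(bins) - 0.5) * width
  if (volume$scale == "grey8" && bins == 256 &&
      identical(range, c(0, 255))) {
    # exact integer binning: bin i+1 <-> grey value i
    counts <- tabulate(v + 1L, nbins = 256L)
    centers <- 0:255
    width <- 1
  } else {
    idx <- pmin(bins, pmax(1, floor((v - range[1]) / width) + 1))
    counts <- tabulate(idx, nbins = bins)
  }
  mass <- counts / sum(counts)
  freq <- mass / width
  area <- trapz_area(centers, freq)
  if (area <= 0) stop("degenerate profile")
  freq <- freq / area
  degenerate <- sum(counts > 0) == 1L
  if (degenerate)
    warning("degenerate single-bin profile (constant volume)")
  structure(list(density_axis = centers, frequency = freq, mass = mass,
                 smooth = NULL, degenerate = degenerate),
            class = "mdd_profile")
}

trapz_area <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' @export
print.mdd_profile <- function(x, ...) {
  cat(sprintf("<mdd_profile> %d bins over [%g, %g]%s%s\n",
              length(x$density_axis), min(x$density_axis),
              max(x$density_axis),
              if (is.null(x$smooth)) "" else ", smoothed",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' @export
plot.mdd_profile <- function(x, ...) {
  plot(x$density_axis, x$frequency, type = "h", col = "grey70",
       xlab = "relative density (grey level)", ylab = "normalized frequency",
       ...)
  if (!is.null(x$smooth))
    lines(x$smooth$x, x$smooth$y, col = "red3", lwd = 2)
  invisible(x)
}

#' Smooth an MDDr profile
#'
#' Fits a cubic smoothing spline to the normalized histogram and evaluates
#' it on a ten-fold finer grid; negative values are clipped to zero and the
#' curve re-normalized to unit area. With `smoothing = 0` the histogram
#' points are interpolated exactly (natural cubic spline). With
#' `smoothing = NULL` (default) the spline's smoothness is chosen by
#' generalized cross-validation.
#'
#' @param profile an `mdd_profile`.
#' @param smoothing `NULL` (GCV), 0 (interpolation), or a positive `spar`
#'   value in (0, 1\] passed to [stats::smooth.spline()].
#' @return The profile with its `smooth` field set (list `x`, `y`).
#' @export
smooth_profile <- function(profile, smoothing = NULL) {
  if (!inherits(profile, "mdd_profile")) stop("expected an `mdd_profile`")
  if (isTRUE(profile$degenerate)) stop("cannot smooth a degenerate profile")
  x <- profile$density_axis
  y <- profile$frequency
  fine <- seq(min(x), max(x), length.out = 10L * length(x))
  if (!is.null(smoothing) && smoothing == 0) {
    ys <- splinefun(x, y, method = "natural")(fine)
  } else {
    fit <- if (is.null(smoothing)) smooth.spline(x, y, cv = FALSE)
           else smooth.spline(x, y, spar = smoothing)
    ys <- predict(fit, fine)$y
  }
  ys[ys < 0] <- 0
  area <- trapz_area(fine, ys)
  if (area <= 0) stop("smoothing removed all structure")
  ys <- ys / area
  if (max(ys) < 2 * mean(ys))
    warning("smoothed profile is nearly flat: oversmoothing?")
  profile$smooth <- list(x = fine, y = ys)
  profile
}

# piecewise-constant-density quantile of a binned distribution: each bin's
# mass is spread uniformly over [center - w/2, center + w/2]
binned_quantile <- function(centers, mass, p) {
  w <- if (length(centers) > 1) centers[2] - centers[1] else 1
  cdf <- cumsum(mass)
  vapply(p, function(pp) {
    i <- which(cdf >= pp - 1e-15)[1]
    prev <- if (i == 1) 0 else cdf[i - 1]
    frac <- if (mass[i] > 0) (pp - prev) / mass[i] else 0
    centers[i] - w / 2 + frac * w
  }, numeric(1))
}

# mass beyond a cut, with linear interpolation inside the cut bin
binned_tail <- function(centers, mass, cut, upper = FALSE) {
  w <- if (length(centers) > 1) centers[2] - centers[1] else 1
  lo <- centers - w / 2
  hi <- centers + w / 2
  below <- sum(mass[hi <= cut])
  part <- which(lo < cut & hi > cut)
  if (length(part)) below <- below + mass[part] * (cut - lo[part]) / w
  if (upper) 1 - below else below
}

#' Reference range from control profiles
#'
#' Pools a set of control (healthy-tissue) MDDr profiles by averaging their
#' normalized frequencies, then places the low/high cuts at the `P` and
#' `1 - P` quantiles of the pooled distribution (linear interpolation
#' within bins). Samples are later scored by how much of their own
#' distribution falls outside these cuts.
#'
#' @param control_profiles list of `mdd_profile` objects on a common axis.
#' @param P tail probability; default 0.005 (0.5th/99.5th percentiles).
#' @return An object of class `reference_range`: `low_cut`, `high_cut`,
#'   `P`, `pooled_mass`, `density_axis`, `n_controls`.
#' @export
compute_reference_range <- function(control_profiles, P = 0.005) {
  if (length(control_profiles) == 0L) stop("empty control set")
  if (P <= 0 || P >= 0.5) stop("P must lie in (0, 0.5)")
  axis <- control_profiles[[1]]$density_axis
  for (pr in control_profiles)
    if (!isTRUE(all.equal(pr$density_axis, axis)))
      stop("control profiles must share a common density axis")
  pooled <- Reduce(`+`, lapply(control_profiles, `[[`, "mass")) /
    length(control_profiles)
  cuts <- binned_quantile(axis, pooled, c(P, 1 - P))
  structure(list(low_cut = cuts[1], high_cut = cuts[2], P = P,
                 pooled_mass = pooled, density_axis = axis,
                 n_controls = length(control_profiles)),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range> P = %g: cuts [%.2f, %.2f] (%d control profile%s)\n",
              x$P, x$low_cut, x$high_cut, x$n_controls,
              if (x$n_controls == 1) "" else "s"))
  invisible(x)
}

#' Roschger-style descriptors of an MDDr profile
#'
#' Extracts the five summary parameters: `peak` (density at the maximum of
#' the smoothed profile), `mean` (trapezoidal integral of `x f(x)` of the
#' normalized histogram), `fwhm` (distance between the outermost crossings
#' of half the smoothed maximum), and `low`/`high` (percentage of the
#' sample's distribution below/above the reference-range cuts). When the
#' smoothed profile is multimodal the outermost half-maximum crossings are
#' used and the result is flagged.
#'
#' @param profile a smoothed `mdd_profile` (see [smooth_profile()]).
#' @param ref a `reference_range` from [compute_reference_range()].
#' @return An object of class `mdd_parameters`: `peak`, `mean`, `fwhm`,
#'   `low`, `high` (percent), and `multimodal` flag.
#' @export
extract_mdd_parameters <- function(profile, ref) {
  if (!inherits(profile, "mdd_profile")) stop("expected an `mdd_profile`")
  if (is.null(profile$smooth))
    stop("profile must be smoothed first (see smooth_profile)")
  if (!inherits(ref, "reference_range")) stop("expected a `reference_range`")
  sx <- profile$smooth$x
  sy <- profile$smooth$y
  imax <- which.max(sy)
  peak <- sx[imax]
  half <- sy[imax] / 2
  above <- sy >= half
  # outermost half-maximum crossings, linearly interpolated
  first <- which(above)[1]
  last <- rev(which(above))[1]
  xl <- if (first == 1) sx[1] else {
    i <- first
    sx[i - 1] + (half - sy[i - 1]) / (sy[i] - sy[i - 1]) * (sx[i] - sx[i - 1])
  }
  xr <- if (last == length(sx)) sx[length(sx)] else {
    i <- last
    sx[i] + (sy[i] - half) / (sy[i] - sy[i + 1]) * (sx[i + 1] - sx[i])
  }
  fwhm <- xr - xl
  # multimodality: interior dips below half between the outer crossings
  multimodal <- any(!above[first:last])
  mu <- trapz_area(profile$density_axis,
                   profile$density_axis * profile$frequency)
  low <- 100 * binned_tail(profile$density_axis, profile$mass, ref$low_cut)
  high <- 100 * binned_tail(profile$density_axis, profile$mass,
                            ref$high_cut, upper = TRUE)
  structure(list(peak = peak, mean = mu, fwhm = fwhm, low = low,
                 high = high, multimodal = multimodal),
            class = "mdd_parameters")
}

#' @export
print.mdd_parameters <- function(x, ...) {
  cat(sprintf(paste0("<mdd_parameters> peak %.2f, mean %.2f, fwhm %.2f, ",
                     "low %.3f%%, high %.3f%%%s\n"),
              x$peak, x$mean, x$fwhm, x$low, x$high,
              if (isTRUE(x$multimodal)) " [multimodal]" else ""))
  invisible(x)
}

mdd_param_names <- c("mdd_peak", "mdd_mean", "mdd_fwhm", "mdd_low", "mdd_high")
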