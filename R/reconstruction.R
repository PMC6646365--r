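#' Projection sets
#'
#' Containers for flat/dark-corrected projection stacks (`projection_set`,
#' relative intensities I/I0) and phase-retrieved stacks
#' (`retrieved_projection_set`, projected thickness maps). Arrays are stored
#' as `(u, v, angle)` with `u` the in-slice detector axis and `v` the
#' vertical (axial) axis; there is one projection per angle of the attached
#' [scan_geometry()].
#'
#' @param projections 3D array `(u, v, angle)` of positive intensities I/I0.
#' @param geometry a [scan_geometry()].
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(projections, geometry) {
  if (!is.array(projections) || length(dim(projections)) != 3L)
    stop("`projections` must be a 3D array (u, v, angle)")
  if (!inherits(geometry, "scan_geometry")) stop("expected a `scan_geometry`")
  if (dim(projections)[3] != length(geometry$angles_deg))
    stop("need exactly one projection per angle")
  if (min(projections) <= 0)
    stop("corrected intensities must be strictly positive")
  structure(list(projections = projections, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("<projection_set> %d x %d detector, %d angles\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Flat- and dark-field correction
#'
#' Converts raw detector counts to relative intensities
#' `I/I0 = (raw - dark) / (flat - dark)`, clipped below at a small positive
#' floor so downstream logarithms stay defined.
#'
#' @param raw 3D array `(u, v, angle)` of raw counts.
#' @param flat,dark 2D images `(u, v)`; `flat - dark` must be strictly
#'   positive everywhere.
#' @param geometry a [scan_geometry()].
#' @param floor lower clip value; default `1e-6`.
#' @return A [projection_set()].
#' @export
flat_dark_correct <- function(raw, flat, dark, geometry, floor = 1e-6) {
  if (any(flat - dark <= 0))
    stop("calibration error: flat <= dark somewhere")
  denom <- flat - dark
  corr <- sweep(sweep(raw, 1:2, dark, "-"), 1:2, denom, "/")
  corr[corr < floor] <- floor
  projection_set(corr, geometry)
}

paganin_alpha_um2 <- function(geometry, params) {
  lambda_um <- geometry$wavelength_nm * 1e-3
  D_um <- geometry$distance_mm * 1e3
  params$delta_beta * D_um * lambda_um / (4 * pi)
}

# mirror-pad a matrix to (mx, my)
pad_symmetric <- function(M, mx, my) {
  n1 <- nrow(M); n2 <- ncol(M)
  ix <- c(seq_len(n1), rev(seq_len(n1)))[((seq_len(mx) - 1) %% (2 * n1)) + 1]
  iy <- c(seq_len(n2), rev(seq_len(n2)))[((seq_len(my) - 1) %% (2 * n2)) + 1]
  M[ix, iy, drop = FALSE]
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# squared angular spatial frequency grid (rad^2/um^2) for an (mx, my) FFT
# with sample spacing `px` um
k2_grid <- function(mx, my, px) {
  fx <- (((seq_len(mx) - 1) + mx %/% 2) %% mx - mx %/% 2) / (mx * px)
  fy <- (((seq_len(my) - 1) + my %/% 2) %% my - my %/% 2) / (my * px)
  (2 * pi)^2 * outer(fx^2, fy^2, "+")
}

#' Single-distance Paganin phase retrieval
#'
#' Applies the homogeneous-object low-pass filter to each flat-corrected
#' projection and converts to projected thickness:
#' `T = -(1/mu) * ln( F^-1[ F(I/I0) / (1 + (D * delta/mu) |k|^2) ] )`
#' with `mu = 4*pi*beta/lambda`. The filter coefficient only requires the
#' delta/beta ratio (`D * delta/mu = (delta/beta) * D * lambda / (4*pi)`);
#' `mu` itself is needed only to express the result in micrometres. When
#' `mu` is unset the retrieved maps are `-ln(.)` of the filtered intensity,
#' i.e. thickness-proportional arbitrary units.
#'
#' @param projections a [projection_set()].
#' @param params a [paganin_params()].
#' @param pad `"symmetric"` (mirror padding to at least twice the extent;
#'   default, appropriate for measured data) or `"none"` (periodic FFT grid,
#'   the exact algebraic inverse of [forward_project()]).
#' @return An object of class `retrieved_projection_set` with element
#'   `thickness_maps` shaped like the input projections.
#' @export
paganin_retrieve <- function(projections, params = paganin_params(),
                             pad = c("symmetric", "none")) {
  pad <- match.arg(pad)
  if (!inherits(projections, "projection_set"))
    stop("expected a `projection_set`")
  if (!inherits(params, "paganin_params")) stop("expected `paganin_params`")
  P <- projections$projections
  d <- dim(P)
  if (d[1] < 2 || d[2] < 2) stop("projections must be at least 2 x 2")
  if (min(P) <= 0) stop("non-positive intensities: cannot take log")
  alpha <- paganin_alpha_um2(projections$geometry, params)
  px <- projections$geometry$pixel_size_um
  if (pad == "symmetric") {
    mx <- next_pow2(2 * d[1]); my <- next_pow2(2 * d[2])
  } else {
    mx <- d[1]; my <- d[2]
  }
  H <- 1 / (1 + alpha * k2_grid(mx, my, px))
  out <- array(0, dim = d)
  for (a in seq_len(d[3])) {
    M <- P[, , a]
    Mp <- if (pad == "symmetric") pad_symmetric(M, mx, my) else M
    filt <- Re(fft(fft(Mp) * H, inverse = TRUE)) / (mx * my)
    filt <- filt[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
    filt[filt < 1e-12] <- 1e-12
    out[, , a] <- -log(filt)
  }
  if (!is.null(params$mu_um_inv)) out <- out / params$mu_um_inv
  structure(list(thickness_maps = out, geometry = projections$geometry,
                 params = params),
            class = "retrieved_projection_set")
}

#' @export
print.retrieved_projection_set <- function(x, ...) {
  d <- dim(x$thickness_maps)
  cat(sprintf("<retrieved_projection_set> %d x %d maps, %d angles, units: %s\n",
              d[1], d[2], d[3],
              if (is.null(x$params$mu_um_inv)) "arbitrary (optical depth)" else "um"))
  invisible(x)
}

#' Forward-project thickness maps under the homogeneous-object model
#'
#' The physically consistent inverse of [paganin_retrieve()]: each contact
#' image `C = exp(-mu * T)` is propagated with the linearized
#' single-material transfer function
#' `I/I0 = F^-1[ (1 + (D * delta/mu) |k|^2) * F(C) ]`,
#' which is the exact algebraic inverse of the Paganin filter on the same
#' FFT grid. With `pad = "none"` (default) the model is defined on the
#' periodic grid and `paganin_retrieve(..., pad = "none")` recovers the
#' input thickness maps to machine precision. Optional Poisson noise
#' emulates finite photon counts.
#'
#' @param thickness_maps 3D array `(u, v, angle)` of non-negative projected
#'   thickness (um when `mu` is set, optical-depth units otherwise).
#' @param geometry a [scan_geometry()]; `dim(thickness_maps)[3]` must equal
#'   the number of angles.
#' @param params a [paganin_params()].
#' @param pad `"none"` (periodic model grid) or `"symmetric"`.
#' @param counts optional mean photon counts per pixel for Poisson noise.
#' @return A [projection_set()].
#' @export
forward_project <- function(thickness_maps, geometry,
                            params = paganin_params(),
                            pad = c("none", "symmetric"), counts = NULL) {
  pad <- match.arg(pad)
  if (min(thickness_maps) < 0) stop("thickness maps must be non-negative")
  d <- dim(thickness_maps)
  if (d[3] != length(geometry$angles_deg))
    stop("need one thickness map per angle")
  mu <- if (is.null(params$mu_um_inv)) 1 else params$mu_um_inv
  alpha <- paganin_alpha_um2(geometry, params)
  px <- geometry$pixel_size_um
  if (pad == "symmetric") {
    mx <- next_pow2(2 * d[1]); my <- next_pow2(2 * d[2])
  } else {
    mx <- d[1]; my <- d[2]
  }
  H <- 1 + alpha * k2_grid(mx, my, px)
  out <- array(0, dim = d)
  for (a in seq_len(d[3])) {
    C <- exp(-mu * thickness_maps[, , a])
    Cp <- if (pad == "symmetric") pad_symmetric(C, mx, my) else C
    I <- Re(fft(fft(Cp) * H, inverse = TRUE)) / (mx * my)
    out[, , a] <- I[seq_len(d[1]), seq_len(d[2])]
  }
  if (!is.null(counts)) {
    out[out < 0] <- 0
    out[] <- rpois(length(out), counts * out) / counts
  }
  out[out < 1e-9] <- 1e-9
  projection_set(out, geometry)
}

# Ram-Lak (ramp) filter frequency response of length m, built from the
# band-limited spatial kernel so the DC term is handled correctly
ramp_response <- function(m, window = c("none", "cosine")) {
  window <- match.arg(window)
  h <- numeric(m)
  h[1] <- 0.25
  k <- seq_len(m %/% 2)
  odd <- k[k %% 2 == 1]
  h[odd + 1] <- -1 / (pi^2 * odd^2)
  h[m - odd + 1] <- -1 / (pi^2 * odd^2)
  H <- Re(fft(h))
  if (window == "cosine") {
    f <- (((seq_len(m) - 1) + m %/% 2) %% m - m %/% 2) / m
    H <- H * cos(pi * f)
  }
  H
}

fbp_slice <- function(sino, angles_rad, n_out, window = "none",
                      center_offset = 0) {
  nu <- nrow(sino); na <- ncol(sino)
  m <- next_pow2(2 * nu)
  H <- ramp_response(m, window)
  filt <- matrix(0, nu, na)
  for (a in seq_len(na)) {
    p <- c(sino[, a], numeric(m - nu))
    q <- Re(fft(fft(p) * H, inverse = TRUE)) / m
    filt[, a] <- q[seq_len(nu)]
  }
  cu <- (nu - 1) / 2 + 1 + center_offset   # 1-based detector centre
  cg <- (n_out - 1) / 2
  xg <- seq_len(n_out) - 1 - cg
  X <- matrix(xg, n_out, n_out)
  Y <- matrix(xg, n_out, n_out, byrow = TRUE)
  rec <- matrix(0, n_out, n_out)
  for (a in seq_len(na)) {
    u <- -X * sin(angles_rad[a]) + Y * cos(angles_rad[a]) + cu
    i0 <- floor(u)
    w <- u - i0
    ok <- i0 >= 1 & i0 < nu
    vals <- numeric(length(u))
    idx <- i0[ok]
    vals[ok] <- filt[idx, a] * (1 - w[ok]) + filt[idx + 1, a] * w[ok]
    rec <- rec + matrix(vals, n_out, n_out)
  }
  rec * pi / na
}

#' Filtered back-projection reconstruction
#'
#' Slice-by-slice parallel-beam FBP with a ramp (Ram-Lak) filter and linear
#' interpolation during back-projection. Projections are zero-padded to the
#' next power of two of at least twice the detector extent before
#' filtering. The reconstructed voxel size equals the detector pixel size;
#' values are per-unit-length densities of whatever quantity the retrieved
#' maps integrate (dimensionless for optical-depth maps).
#'
#' @param retrieved a `retrieved_projection_set` from [paganin_retrieve()],
#'   or a [projection_set()] whose intensities are first converted with
#'   `-log`.
#' @param n_out reconstruction grid side length; defaults to the detector
#'   width.
#' @param window `"none"` (plain ramp, default) or `"cosine"` apodization.
#' @param center_offset manual rotation-centre offset in pixels.
#' @return A `retrieved_float` [volume_image()] of dim `(n_out, n_out, nv)`.
#' @export
fbp_reconstruct <- function(retrieved, n_out = NULL, window = "none",
                            center_offset = 0) {
  if (inherits(retrieved, "projection_set")) {
    maps <- -log(retrieved$projections)
    geometry <- retrieved$geometry
  } else if (inherits(retrieved, "retrieved_projection_set")) {
    maps <- retrieved$thickness_maps
    geometry <- retrieved$geometry
  } else stop("expected a projection set")
  d <- dim(maps)
  if (d[3] < 2) stop("reconstruction needs at least 2 angles")
  if (is.null(n_out)) n_out <- d[1]
  angles_rad <- geometry$angles_deg * pi / 180
  px <- geometry$pixel_size_um
  vol <- array(0, dim = c(n_out, n_out, d[2]))
  for (v in seq_len(d[2])) {
    vol[, , v] <- fbp_slice(maps[, v, , drop = TRUE], angles_rad, n_out,
                            window, center_offset) / px
  }
  volume_image(vol, px, "retrieved_float")
}
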