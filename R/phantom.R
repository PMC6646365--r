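#' Specification of a synthetic two-phase tissue phantom
#'
#' Describes the ground-truth-known phantoms used to exercise the pipeline:
#' a smooth-muscle background with collagen bundles modelled as a union of
#' straight capsules (random centre lines, von Mises-Fisher distributed
#' directions, Gaussian-distributed radii), class-conditionally Gaussian grey
#' levels, sparse saturated "blood clot" spots and optional additive noise.
#'
#' Defaults emulate a fibrotic (leiomyoma-like) sample: 40% collagen volume
#' fraction with thick bundles; a healthy-myometrium-like phantom is obtained
#' by lowering `target_coll_fraction` (to about 0.05) and the bundle radius.
#'
#' @param shape_um length-3 numeric, volume extent (x, y, z) in um.
#' @param voxel_size_um isotropic voxel size in um.
#' @param target_coll_fraction desired collagen volume fraction in \[0, 1).
#' @param bundle_radius_um `c(mean, sd)` of the capsule radius in um.
#' @param orientation_axis unit vector, preferred bundle direction.
#' @param orientation_kappa von Mises-Fisher concentration; 0 = isotropic.
#' @param muscle_grey,collagen_grey `c(mean, sd)` of the class-conditional
#'   grey level (8-bit scale); the collagen mean must exceed the muscle mean.
#' @param bright_spot_rate expected saturated spots per mm^3.
#' @param bright_spot_radius_um `c(mean, sd)` of spot radius in um.
#' @param noise_sd additional additive grey noise (sd, grey levels).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_um = c(300, 300, 200), voxel_size_um = 2.5,
                         target_coll_fraction = 0.40,
                         bundle_radius_um = c(15, 3),
                         orientation_axis = c(0, 0, 1),
                         orientation_kappa = 0,
                         muscle_grey = c(90, 12), collagen_grey = c(140, 14),
                         bright_spot_rate = 50,
                         bright_spot_radius_um = c(3, 1),
                         noise_sd = 0, seed = 1L) {
  if (target_coll_fraction < 0 || target_coll_fraction >= 1)
    stop("target_coll_fraction must lie in [0, 1)")
  if (orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  if (collagen_grey[1] <= muscle_grey[1])
    stop("collagen grey mean must exceed muscle grey mean")
  if (any(c(muscle_grey[1], collagen_grey[1]) < 0) ||
      any(c(muscle_grey[1], collagen_grey[1]) > 255))
    stop("grey means must lie in [0, 255]")
  axis <- orientation_axis / sqrt(sum(orientation_axis^2))
  structure(list(shape_um = shape_um, voxel_size_um = voxel_size_um,
                 target_coll_fraction = target_coll_fraction,
                 bundle_radius_um = bundle_radius_um,
                 orientation_axis = axis,
                 orientation_kappa = orientation_kappa,
                 muscle_grey = muscle_grey, collagen_grey = collagen_grey,
                 bright_spot_rate = bright_spot_rate,
                 bright_spot_radius_um = bright_spot_radius_um,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# sample n directions from a von Mises-Fisher distribution on the sphere
rvmf <- function(n, axis, kappa) {
  if (kappa <= 0) {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    return(cbind(s * cos(phi), s * sin(phi), z))
  }
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(phi), s * sin(phi), w)
  # rotate the local +z frame onto the requested axis
  z <- c(0, 0, 1)
  if (sum((axis - z)^2) < 1e-12) return(local)
  if (sum((axis + z)^2) < 1e-12) return(local %*% diag(c(1, -1, -1)))
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  cth <- sum(z * axis)
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  Rm <- diag(3) + vx + vx %*% vx / (1 + cth)
  local %*% t(Rm)
}

#' Generate a two-phase fiber phantom with known ground truth
#'
#' Builds the collagen phase as a union of straight capsules added until the
#' realized volume fraction falls within 0.01 of the target, assigns
#' class-conditional Gaussian grey values (clipped to \[0, 255\]), adds
#' saturated spherical bright spots at the requested rate, and returns both
#' the grey volume and the exact ground truth (collagen mask, realized
#' fraction, mean bundle radius, generating grey parameters, bright-spot
#' mask).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a grey8 [volume_image()]) and
#'   `truth` (class `phantom_ground_truth`).
#' @export
generate_fiber_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a `phantom_spec`")
  set.seed(spec$seed)
  d <- as.integer(round(spec$shape_um / spec$voxel_size_um))
  if (any(d < 4L)) stop("phantom too small")
  n <- prod(d)
  mask <- array(FALSE, dim = d)
  span <- sqrt(sum(d^2))
  target <- spec$target_coll_fraction
  radii_used <- numeric(0)
  count <- 0
  if (target > 0) {
    max_iter <- 10000L
    iter <- 0L
    repeat {
      frac <- count / n
      deficit <- target - frac
      if (deficit <= 0.005) break
      iter <- iter + 1L
      if (iter > max_iter)
        stop("could not reach target collagen fraction within iteration cap")
      r_um <- max(spec$voxel_size_um / 2,
                  rnorm(1, spec$bundle_radius_um[1], spec$bundle_radius_um[2]))
      r <- r_um / spec$voxel_size_um
      dirv <- drop(rvmf(1, spec$orientation_axis, spec$orientation_kappa))
      ctr <- runif(3) * (d - 1)
      # shrink capsules as the target nears so the realized fraction cannot
      # overshoot the +/- 0.01 band
      halflen <- span / 2
      expected_gain <- pi * r^2 * 2 * halflen / n
      if (expected_gain > deficit) {
        halflen <- max(2, halflen * deficit / expected_gain)
      }
      p0 <- ctr - halflen * dirv
      p1 <- ctr + halflen * dirv
      mask <- cpp_add_capsule(as.vector(mask), d, p0, p1, r)
      added <- attr(mask, "added")
      mask <- array(mask, dim = d)
      if (added > 0) {
        count <- count + added
        radii_used <- c(radii_used, r_um)
      }
      if (count / n > target + 0.01)
        stop("overshot target collagen fraction")
    }
  }

  grey <- array(0, dim = d)
  nfg <- sum(mask)
  grey[!mask] <- rnorm(n - nfg, spec$muscle_grey[1], spec$muscle_grey[2])
  if (nfg > 0)
    grey[mask] <- rnorm(nfg, spec$collagen_grey[1], spec$collagen_grey[2])
  if (spec$noise_sd > 0) grey <- grey + rnorm(n, 0, spec$noise_sd)

  # bright spots: small saturated spheres, recorded separately
  vol_mm3 <- prod(spec$shape_um) / 1e9
  nspots <- rpois(1, spec$bright_spot_rate * vol_mm3)
  bright <- array(FALSE, dim = d)
  if (nspots > 0) {
    for (i in seq_len(nspots)) {
      r_um <- max(spec$voxel_size_um,
                  rnorm(1, spec$bright_spot_radius_um[1],
                        spec$bright_spot_radius_um[2]))
      r <- r_um / spec$voxel_size_um
      ctr <- runif(3) * (d - 1)
      bright <- cpp_add_capsule(as.vector(bright), d, ctr, ctr, r)
      bright <- array(bright, dim = d)
    }
    grey[bright] <- 255
  }
  g8 <- array(as.integer(pmin(255, pmax(0, round(grey)))), dim = d)

  truth <- structure(list(
    mask = collagen_mask(mask, spec$voxel_size_um),
    true_coll_fraction = nfg / n,
    true_mean_radius_um = if (length(radii_used)) mean(radii_used) else NA_real_,
    orientation_axis = spec$orientation_axis,
    orientation_kappa = spec$orientation_kappa,
    muscle_grey = spec$muscle_grey,
    collagen_grey = spec$collagen_grey,
    bright_mask = bright,
    n_bundles = length(radii_used),
    # straight-capsule closed form, ignoring overlap: S/V = 2/r
    approx_specific_surface_per_mm =
      if (length(radii_used)) 2000 / mean(radii_used) else NA_real_),
    class = "phantom_ground_truth")

  list(volume = volume_image(g8, spec$voxel_size_um, "grey8"), truth = truth)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_ground_truth> collagen fraction %.4f, ",
                     "%d bundles, mean radius %.3g um\n"),
              x$true_coll_fraction, x$n_bundles, x$true_mean_radius_um))
  invisible(x)
}

#' Voxelize an analytic solid
#'
#' Generates binary masks of simple solids with closed-form volume, surface,
#' thickness and topology, used as oracles for the morphometric indices.
#' Voxels are included when their centre lies inside the solid. The solid
#' must keep a margin of at least 2 voxels from the volume boundary so that
#' surface and connectivity estimates are not truncated.
#'
#' @param kind one of `"sphere"`, `"slab"`, `"cylinder"`, `"torus"`,
#'   `"two_tori"`.
#' @param dim_vox length-3 integer, volume dimensions in voxels.
#' @param voxel_size_um voxel size in um (default 1).
#' @param r radius in voxels (sphere, cylinder; minor radius for tori).
#' @param R_major major radius in voxels (tori).
#' @param thickness slab thickness in voxels.
#' @return A [collagen_mask()].
#' @export
generate_geometric_solid <- function(kind = c("sphere", "slab", "cylinder",
                                              "torus", "two_tori"),
                                     dim_vox, voxel_size_um = 1,
                                     r = NULL, R_major = NULL,
                                     thickness = NULL) {
  kind <- match.arg(kind)
  d <- as.integer(dim_vox)
  # centre on a voxel centre so digitized radii are not biased by a
  # half-voxel grid offset
  c0 <- floor((d - 1) / 2)
  x <- seq_len(d[1]) - 1; y <- seq_len(d[2]) - 1; z <- seq_len(d[3]) - 1
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  margin_err <- function() stop("solid touches the volume boundary (needs >= 2 voxel margin)")
  mask <- switch(kind,
    sphere = {
      if (is.null(r)) stop("sphere needs `r`")
      if (r + 2 > min(c0, d - 1 - c0)) margin_err()
      (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= r^2
    },
    slab = {
      if (is.null(thickness)) stop("slab needs `thickness`")
      if (thickness + 4 > d[3]) margin_err()
      lo <- floor(c0[3]) - floor((thickness - 1) / 2)
      abs(Z - lo - (thickness - 1) / 2) <= (thickness - 1) / 2 + 1e-9
    },
    cylinder = {
      if (is.null(r)) stop("cylinder needs `r`")
      if (r + 2 > min(c0[1], c0[2])) margin_err()
      (X - c0[1])^2 + (Y - c0[2])^2 <= r^2
    },
    torus = {
      if (is.null(r) || is.null(R_major)) stop("torus needs `r` and `R_major`")
      if (R_major + r + 2 > min(c0[1], c0[2]) || r + 2 > c0[3]) margin_err()
      (sqrt((X - c0[1])^2 + (Y - c0[2])^2) - R_major)^2 + (Z - c0[3])^2 <= r^2
    },
    two_tori = {
      if (is.null(r) || is.null(R_major)) stop("two_tori needs `r` and `R_major`")
      cx1 <- c0[1] / 2; cx2 <- 3 * c0[1] / 2
      if (R_major + r + 2 > min(cx1, c0[2] / 1) || r + 2 > c0[3]) margin_err()
      t1 <- (sqrt((X - cx1)^2 + (Y - c0[2])^2) - R_major)^2 + (Z - c0[3])^2 <= r^2
      t2 <- (sqrt((X - cx2)^2 + (Y - c0[2])^2) - R_major)^2 + (Z - c0[3])^2 <= r^2
      t1 | t2
    })
  collagen_mask(mask, voxel_size_um)
}

#' Project a volume to per-angle thickness maps
#'
#' Computes parallel-beam line integrals of a volume (rotation about the z
#' axis) on a 1D detector per axial slice, returning per-angle projected
#' maps in physical units (value x um). Applied to a binary mask this gives
#' projected thickness in um; applied to a density volume it gives projected
#' density-length.
#'
#' @param volume a [volume_image()] or [collagen_mask()].
#' @param angles_deg projection angles in degrees.
#' @param n_detector number of detector bins; default covers the diagonal.
#' @return 3D array `(u, z, angle)` with attribute `pixel_size_um`.
#' @export
project_thickness <- function(volume, angles_deg, n_detector = NULL) {
  vox <- volume$voxels
  d <- as.integer(dim(vox))
  if (is.null(n_detector)) n_detector <- 2L * ceiling(sqrt(d[1]^2 + d[2]^2) / 2) + 1L
  sino <- cpp_radon(as.double(vox), d, angles_deg * pi / 180, as.integer(n_detector))
  out <- array(sino, dim = c(n_detector, d[3], length(angles_deg))) *
    volume$voxel_size_um
  attr(out, "pixel_size_um") <- volume$voxel_size_um
  out
}
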