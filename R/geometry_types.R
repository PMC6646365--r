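#' Scan geometry for propagation-based imaging
#'
#' Describes a parallel-beam synchrotron scan: photon energy, sample-detector
#' propagation distance, detector pixel size and the projection angles. The
#' X-ray wavelength is derived from the energy (`lambda[nm] = 1.239842 / E[keV]`).
#' Shipped defaults match a typical propagation-based soft-tissue protocol:
#' 19 keV, 100 mm propagation distance, 1 um pixels.
#'
#' @param energy_keV photon energy in keV.
#' @param distance_mm sample-detector distance in mm.
#' @param pixel_size_um detector pixel size in micrometres.
#' @param angles_deg strictly increasing projection angles in degrees,
#'   spanning less than 180.
#' @param wavelength_nm optional; if supplied it must agree with the energy
#'   to 1e-6 relative precision.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(energy_keV = 19, distance_mm = 100,
                          pixel_size_um = 1,
                          angles_deg = seq(0, 180, length.out = 181)[-181],
                          wavelength_nm = NULL) {
  if (energy_keV <= 0 || distance_mm <= 0 || pixel_size_um <= 0)
    stop("energy, distance and pixel size must be positive")
  lam <- 1.239842 / energy_keV
  if (!is.null(wavelength_nm) &&
      abs(wavelength_nm - lam) > 1e-6 * lam)
    stop("wavelength_nm inconsistent with energy_keV")
  if (length(angles_deg) > 1L) {
    if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
    if (max(angles_deg) - min(angles_deg) >= 180)
      stop("angle range must span less than 180 degrees")
  }
  structure(list(energy_keV = energy_keV, wavelength_nm = lam,
                 distance_mm = distance_mm, pixel_size_um = pixel_size_um,
                 angles_deg = angles_deg),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(paste0("<scan_geometry> %g keV (lambda %.5g nm), D = %g mm, ",
                     "pixel %g um, %d angles over [%g, %g] deg\n"),
              x$energy_keV, x$wavelength_nm, x$distance_mm, x$pixel_size_um,
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Paganin phase-retrieval parameters
#'
#' Single-distance phase retrieval under the homogeneous-object assumption
#' (refractive index `n = 1 - delta + i*beta` with a fixed `delta/beta`
#' ratio). When the linear attenuation coefficient `mu = 4*pi*beta/lambda`
#' is supplied (per um), retrieved maps are projected thickness in um;
#' otherwise they are reported in arbitrary thickness-proportional (optical
#' depth) units, consistent with relative-only density analysis.
#'
#' @param delta_beta the delta/beta ratio; default 100.
#' @param mu_um_inv optional linear attenuation coefficient in 1/um.
#' @return An object of class `paganin_params`.
#' @export
paganin_params <- function(delta_beta = 100, mu_um_inv = NULL) {
  if (delta_beta <= 0) stop("delta_beta must be positive")
  if (!is.null(mu_um_inv) && mu_um_inv <= 0) stop("mu_um_inv must be positive")
  structure(list(delta_beta = delta_beta, mu_um_inv = mu_um_inv),
            class = "paganin_params")
}

#' @export
print.paganin_params <- function(x, ...) {
  cat(sprintf("<paganin_params> delta/beta = %g, mu = %s\n", x$delta_beta,
              if (is.null(x$mu_um_inv)) "unset (arbitrary units)"
              else sprintf("%g /um", x$mu_um_inv)))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the quantitative pipeline.
#'
#' @param subvolume_size_um physical subvolume extent (x, y, z) in um;
#'   default `c(600, 600, 400)`.
#' @param n_threshold_slices number of axial slices averaged for the
#'   segmentation threshold; default 12 ("a dozen").
#' @param mdd_reference_P tail probability defining the reference range
#'   cuts; default 0.005 (0.5th / 99.5th percentiles).
#' @param da_convention `"paper"` (1 = perfect isotropy) or `"complement"`
#'   (1 - eigenvalue ratio, the common fabric-tensor software convention).
#' @param bins histogram bin count for grey8 data; default 256.
#' @param seed integer seed controlling all randomized steps.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(subvolume_size_um = c(600, 600, 400),
                            n_threshold_slices = 12,
                            mdd_reference_P = 0.005,
                            da_convention = c("paper", "complement"),
                            bins = 256, seed = 1L) {
  da_convention <- match.arg(da_convention)
  if (mdd_reference_P <= 0 || mdd_reference_P >= 0.5)
    stop("mdd_reference_P must lie in (0, 0.5)")
  if (n_threshold_slices < 1) stop("n_threshold_slices must be >= 1")
  structure(list(subvolume_size_um = subvolume_size_um,
                 n_threshold_slices = as.integer(n_threshold_slices),
                 mdd_reference_P = mdd_reference_P,
                 da_convention = da_convention,
                 bins = as.integer(bins), seed = as.integer(seed)),
            class = "analysis_config")
}
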