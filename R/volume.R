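#' Volume images
#'
#' A `volume_image` is the central data container of the pipeline: a 3D voxel
#' grid with isotropic voxel size in micrometres and a value-scale tag. The
#' voxel array has `dim = c(nx, ny, nz)`; the third index is the axial (z)
#' direction, so `volume$voxels[, , k]` is the k-th axial slice.
#'
#' Two scales are used: `"retrieved_float"` for reconstructed
#' phase-proportional values (arbitrary units, any real range) and `"grey8"`
#' for 8-bit grey volumes with integer values in \[0, 255\], on which
#' histograms, thresholds and density distributions are defined.
#'
#' @param voxels numeric or integer 3D array, `dim = c(nx, ny, nz)`.
#' @param voxel_size_um positive scalar, isotropic voxel size in micrometres.
#' @param scale `"retrieved_float"` or `"grey8"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size_um,
                         scale = c("retrieved_float", "grey8")) {
  scale <- match.arg(scale)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (scale == "grey8") {
    v <- as.vector(voxels)
    if (anyNA(v) || min(v) < 0 || max(v) > 255 || any(v != round(v)))
      stop("grey8 volumes must hold integers in [0, 255]")
    storage.mode(voxels) <- "integer"
  } else {
    storage.mode(voxels) <- "double"
  }
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 scale = scale),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels, %.3g um/voxel, scale: %s\n",
              d[1], d[2], d[3], x$voxel_size_um, x$scale))
  cat(sprintf("  extent: %.0f x %.0f x %.0f um, value range [%.4g, %.4g]\n",
              d[1] * x$voxel_size_um, d[2] * x$voxel_size_um,
              d[3] * x$voxel_size_um, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

is_grey8 <- function(volume) {
  inherits(volume, "volume_image") && volume$scale == "grey8"
}

stopifnot_volume <- function(volume, scale = NULL) {
  if (!inherits(volume, "volume_image"))
    stop("expected a `volume_image` object")
  if (!is.null(scale) && volume$scale != scale)
    stop(sprintf("expected a %s volume, got %s", scale, volume$scale))
  invisible(volume)
}

#' Read a volume from a TIFF stack
#'
#' Reads either a directory of single-page TIFF files (slices ordered by file
#' name) or one multi-page TIFF file (slices ordered by page index). The
#' stored bit depth decides the scale: 8-bit files become `grey8` volumes;
#' 32-bit float files become `retrieved_float` volumes. Float stacks written
#' by [write_volume_stack()] carry a plain-text `.scale` sidecar with the
#' affine mapping used to fit arbitrary values into the unit range of the
#' TIFF float convention; it is applied transparently on read.
#'
#' @param path directory containing `.tif`/`.tiff` files, or a single
#'   multi-page TIFF file.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @return A [volume_image()].
#' @export
read_volume_stack <- function(path, voxel_size_um) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, all = FALSE))
    sidecar <- file.path(path, "stack.scale")
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".scale")
  } else {
    stop("path does not exist: ", path)
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("slices have mismatched shapes")
  # readTIFF returns matrices [row, col] in [0,1]; rows map to y, cols to x
  nx <- shapes[2, 1]; ny <- shapes[1, 1]; nz <- length(pages)
  vox <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
  if (file.exists(sidecar)) {
    sc <- scan(sidecar, quiet = TRUE)
    vox <- vox * (sc[2] - sc[1]) + sc[1]
    volume_image(vox, voxel_size_um, "retrieved_float")
  } else {
    g <- round(vox * 255)
    if (max(abs(vox * 255 - g)) < 1e-6) {
      volume_image(g, voxel_size_um, "grey8")
    } else {
      volume_image(vox, voxel_size_um, "retrieved_float")
    }
  }
}

#' Write a volume as a TIFF stack
#'
#' `grey8` volumes are written losslessly as 8-bit pages. `retrieved_float`
#' volumes are written as 32-bit float pages after an affine map onto
#' \[0, 1\] (the TIFF float convention of the writer); the mapping is stored
#' in a plain-text `.scale` sidecar so that the round trip is exact to
#' 32-bit float precision.
#'
#' @param volume a [volume_image()].
#' @param path output file name (multi-page TIFF). If `path` is an existing
#'   directory, one file per slice (`slice_0001.tif`, ...) is written there.
#' @return `path`, invisibly.
#' @export
write_volume_stack <- function(volume, path) {
  stopifnot_volume(volume)
  d <- dim(volume$voxels)
  if (any(d < 1L)) stop("empty volume")
  as_pages <- function(arr) lapply(seq_len(d[3]), function(k) t(arr[, , k]))
  if (volume$scale == "grey8") {
    pages <- as_pages(volume$voxels / 255)
    bits <- 8L
    sidecar <- NULL
  } else {
    lo <- min(volume$voxels); hi <- max(volume$voxels)
    if (hi == lo) hi <- lo + 1
    pages <- as_pages((volume$voxels - lo) / (hi - lo))
    bits <- 32L
    sidecar <- c(lo, hi)
  }
  if (dir.exists(path)) {
    for (k in seq_len(d[3])) {
      tiff::writeTIFF(pages[[k]],
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = bits, compression = "none",
                      reduce = FALSE)
    }
    if (!is.null(sidecar))
      cat(sprintf("%.17g %.17g\n", sidecar[1], sidecar[2]),
          file = file.path(path, "stack.scale"))
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE)
    if (!is.null(sidecar))
      cat(sprintf("%.17g %.17g\n", sidecar[1], sidecar[2]),
          file = paste0(path, ".scale"))
  }
  invisible(path)
}

#' Rescale a retrieved volume to the 8-bit grey scale
#'
#' Maps the value interval between two percentiles of the voxel distribution
#' linearly onto \[0, 255\], clipping outside. Percentile clipping (rather
#' than min-max) keeps sparse hyperdense voxels - e.g. residual blood-clot
#' spots - from compressing the tissue grey range.
#'
#' The mapping used is attached to the result (attribute `grey8_mapping`)
#' and can be passed back via `mapping` to rescale a whole batch of volumes
#' with one shared mapping. A shared mapping is what makes thresholds and
#' density-distribution descriptors comparable across independently
#' reconstructed samples.
#'
#' @param volume a `retrieved_float` [volume_image()].
#' @param low_clip,high_clip percentiles (in \[0, 100\]) delimiting the value
#'   window; defaults 0.01 and 99.99.
#' @param mapping optional `grey8_mapping` object from a previous call.
#' @return A `grey8` [volume_image()] with attribute `grey8_mapping`.
#' @export
rescale_to_grey8 <- function(volume, low_clip = 0.01, high_clip = 99.99,
                             mapping = NULL) {
  stopifnot_volume(volume, "retrieved_float")
  if (is.null(mapping)) {
    if (low_clip >= high_clip) stop("low_clip must be < high_clip")
    qq <- quantile(volume$voxels, c(low_clip, high_clip) / 100,
                   names = FALSE, type = 7)
    if (qq[2] <= qq[1])
      stop("degenerate value range: volume is (nearly) constant")
    mapping <- structure(list(lo = qq[1], hi = qq[2]), class = "grey8_mapping")
  }
  v <- (volume$voxels - mapping$lo) / (mapping$hi - mapping$lo)
  g <- array(as.integer(round(255 * pmin(1, pmax(0, v)))), dim = dim(v))
  out <- volume_image(g, volume$voxel_size_um, "grey8")
  attr(out, "grey8_mapping") <- mapping
  out
}

#' @export
print.grey8_mapping <- function(x, ...) {
  cat(sprintf("<grey8_mapping> [%.6g, %.6g] -> [0, 255]\n", x$lo, x$hi))
  invisible(x)
}

#' Tile a volume into subvolumes
#'
#' Cuts the volume into a non-overlapping grid of equally sized subvolumes
#' anchored at the volume origin. Partial tiles at the far edges are
#' discarded so that every analyzed subvolume is fully included in the
#' sample bulk.
#'
#' @param volume a [volume_image()].
#' @param subvolume_size_um length-3 numeric, physical tile extent in um
#'   (x, y, z); default `c(600, 600, 400)`.
#' @return A list of [volume_image()] tiles, with attribute `grid` giving the
#'   tile counts per axis.
#' @export
extract_subvolumes <- function(volume, subvolume_size_um = c(600, 600, 400)) {
  stopifnot_volume(volume)
  if (length(subvolume_size_um) == 1L)
    subvolume_size_um <- rep(subvolume_size_um, 3L)
  tile <- round(subvolume_size_um / volume$voxel_size_um)
  d <- dim(volume$voxels)
  if (any(tile < 1L)) stop("subvolume smaller than one voxel")
  if (any(tile > d)) stop("subvolume larger than volume")
  ntile <- d %/% tile
  out <- vector("list", prod(ntile))
  i <- 0L
  for (kz in seq_len(ntile[3])) for (ky in seq_len(ntile[2]))
    for (kx in seq_len(ntile[1])) {
      i <- i + 1L
      xs <- ((kx - 1L) * tile[1] + 1L):(kx * tile[1])
      ys <- ((ky - 1L) * tile[2] + 1L):(ky * tile[2])
      zs <- ((kz - 1L) * tile[3] + 1L):(kz * tile[3])
      out[[i]] <- volume_image(volume$voxels[xs, ys, zs, drop = FALSE],
                               volume$voxel_size_um, volume$scale)
      attr(out[[i]], "origin_voxel") <- c(xs[1], ys[1], zs[1])
    }
  attr(out, "grid") <- ntile
  out
}
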