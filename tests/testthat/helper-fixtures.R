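# Shared fixture builders. Everything is generated in code at test time.

# grey8 volume from a numeric array (values clipped/rounded to [0, 255])
as_grey8 <- function(arr, voxel_size_um = 1) {
  volume_image(array(as.integer(pmin(255, pmax(0, round(arr)))),
                     dim = dim(arr)),
               voxel_size_um, "grey8")
}

# two-class grey volume drawn directly from the generating mixture, with the
# class assignment returned alongside (independent of the fiber generator)
two_class_volume <- function(n_vox, frac, mu = c(80, 180), sd = c(10, 10),
                             seed = 1) {
  set.seed(seed)
  d <- c(n_vox[1], n_vox[2], n_vox[3])
  cls <- array(runif(prod(d)) < frac, dim = d)
  g <- array(0, dim = d)
  g[!cls] <- rnorm(sum(!cls), mu[1], sd[1])
  g[cls] <- rnorm(sum(cls), mu[2], sd[2])
  list(volume = as_grey8(g), class = cls)
}

# jittered dense packing of equal spheres (isotropic fabric oracle)
sphere_packing_mask <- function(d = c(80, 80, 80), r = 6, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim = d)
  step <- 2 * r + 3
  centers <- expand.grid(x = seq(r + 2, d[1] - r - 2, by = step),
                         y = seq(r + 2, d[2] - r - 2, by = step),
                         z = seq(r + 2, d[3] - r - 2, by = step))
  centers <- centers + matrix(runif(3 * nrow(centers), -1, 1),
                              ncol = 3)
  x <- seq_len(d[1]) - 1; y <- seq_len(d[2]) - 1; z <- seq_len(d[3]) - 1
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    xs <- which(abs(x - cx) <= r); ys <- which(abs(y - cy) <= r)
    zs <- which(abs(z - cz) <= r)
    sub <- outer(outer((x[xs] - cx)^2, (y[ys] - cy)^2, "+"), (z[zs] - cz)^2,
                 "+") <= r^2
    m[xs, ys, zs] <- m[xs, ys, zs] | sub
  }
  collagen_mask(m, 1)
}

# straight parallel fibers along +z (anisotropic fabric oracle)
parallel_fiber_mask <- function(d = c(64, 64, 64), r = 3, n_fibers = 30,
                                seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim = d)
  x <- seq_len(d[1]) - 1; y <- seq_len(d[2]) - 1
  for (i in seq_len(n_fibers)) {
    cx <- runif(1, r, d[1] - 1 - r); cy <- runif(1, r, d[2] - 1 - r)
    disk <- outer((x - cx)^2, (y - cy)^2, "+") <= r^2
    m <- m | array(rep(disk, d[3]), dim = d)
  }
  collagen_mask(m, 1)
}

# alternating full-width slabs along z: `a` foreground layers, `b` gap
# layers, repeated; pattern starts and ends with a gap block
periodic_slab_mask <- function(a = 5, b = 7, periods = 4, side = 32) {
  nz <- periods * (a + b) + b
  zfg <- logical(nz)
  z0 <- b
  for (p in seq_len(periods)) {
    zfg[(z0 + 1):(z0 + a)] <- TRUE
    z0 <- z0 + a + b
  }
  m <- array(rep(zfg, each = side * side), dim = c(side, side, nz))
  collagen_mask(m, 1)
}

# analytic parallel-beam sinogram of a centred uniform disk
disk_sinogram <- function(nu, n_angles, r) {
  u <- (seq_len(nu) - 1) - (nu - 1) / 2
  ch <- r^2 - u^2
  prof <- ifelse(ch > 0, 2 * sqrt(pmax(ch, 0)), 0)
  array(rep(prof, n_angles), dim = c(nu, 1, n_angles))
}

make_retrieved <- function(maps, geometry) {
  structure(list(thickness_maps = maps, geometry = geometry,
                 params = paganin_params(100)),
            class = "retrieved_projection_set")
}

fbp_angles <- function(n) seq(0, 180, length.out = n + 1)[-(n + 1)]

# deterministic histogram with counts proportional to a two-Gaussian mixture
mixture_histogram <- function(N, w1, m1, s1, m2, s2) {
  x <- 0:255
  p <- w1 * dnorm(x, m1, s1) + (1 - w1) * dnorm(x, m2, s2)
  counts <- round(N * p / sum(p))
  structure(list(counts = counts, total = sum(counts)),
            class = "grey_histogram")
}
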