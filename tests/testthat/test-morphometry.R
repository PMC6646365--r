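test_that("volume fraction is exact on trivial and analytic masks", {
  full <- collagen_mask(array(TRUE, c(4, 4, 4)), 1)
  expect_identical(volume_fraction(full), 100)
  ch <- array(FALSE, c(6, 6, 6))
  for (z in 1:6) for (y in 1:6) for (x in 1:6)
    ch[x, y, z] <- (x + y + z) %% 2 == 0
  expect_identical(volume_fraction(collagen_mask(ch, 1)), 50)
  sph <- generate_geometric_solid("sphere", c(128, 128, 128), r = 25)
  expect_lt(abs(volume_fraction(sph) - 100 * (4 / 3) * pi * 25^3 / 128^3) /
              (100 * (4 / 3) * pi * 25^3 / 128^3), 0.01)
})

test_that("isosurface area matches closed forms for sphere and slab", {
  sph <- generate_geometric_solid("sphere", c(64, 64, 64), r = 25)
  a <- surface_area(sph)   # mm^2 at 1 um voxels
  expect_lt(abs(a / (4 * pi * 25^2 * 1e-6) - 1), 0.03)
  expect_false(attr(a, "truncated"))

  slab <- generate_geometric_solid("slab", c(64, 64, 32), thickness = 7)
  as_ <- surface_area(slab)
  expect_lt(abs(as.numeric(as_) / (2 * 63^2 * 1e-6) - 1), 0.03)
  expect_true(attr(as_, "truncated"))

  empty <- collagen_mask(array(FALSE, c(8, 8, 8)), 1)
  expect_identical(as.numeric(surface_area(empty)), 0)
})

test_that("specific surface matches 3/r, 2/t, 2/r and is intensive", {
  sph <- generate_geometric_solid("sphere", c(64, 64, 64), r = 25)
  expect_lt(abs(specific_surface(sph) / (3 / 25 * 1000) - 1), 0.05)

  slab <- generate_geometric_solid("slab", c(64, 64, 32), thickness = 7)
  expect_lt(abs(specific_surface(slab) / (2 / 7 * 1000) - 1), 0.05)

  cyl <- generate_geometric_solid("cylinder", c(48, 48, 60), r = 10)
  expect_lt(abs(specific_surface(cyl) / (2 / 10 * 1000) - 1), 0.05)

  # two disjoint spheres have the same S/V as one (intensive quantity)
  one <- generate_geometric_solid("sphere", c(40, 40, 40), r = 10)
  two <- array(FALSE, c(80, 40, 40))
  two[1:40, , ] <- one$voxels
  two[41:80, , ] <- one$voxels
  expect_lt(abs(specific_surface(collagen_mask(two, 1)) /
                  specific_surface(one) - 1), 1e-9)
})

test_that("local thickness matches slab, cylinder, sphere and single voxel", {
  slab <- generate_geometric_solid("slab", c(64, 64, 32), thickness = 7)
  expect_lt(abs(local_thickness(slab)$mean_um - 7), 0.5)

  cyl <- generate_geometric_solid("cylinder", c(48, 48, 60), r = 10)
  expect_lt(abs(local_thickness(cyl)$mean_um - 20), 1)

  sph <- generate_geometric_solid("sphere", c(64, 64, 64), r = 25)
  expect_lt(abs(local_thickness(sph)$mean_um / 50 - 1), 0.05)

  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_identical(local_thickness(collagen_mask(one, 1))$mean_um, 1)

  expect_error(local_thickness(collagen_mask(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
})

test_that("spacing is the thickness of the gap phase", {
  # two parallel slabs with a 9-voxel gap
  m <- array(FALSE, c(32, 32, 25))
  m[, , 3:7] <- TRUE    # slab 1
  m[, , 17:21] <- TRUE  # slab 2
  sp <- mean_spacing(collagen_mask(m, 1))
  gapvals <- sp$map[, , 8:16]
  expect_lt(abs(mean(gapvals) - 9), 0.5)

  empty <- collagen_mask(array(FALSE, c(12, 20, 30)), 2)
  expect_identical(mean_spacing(empty)$mean_um, 24)
  full <- collagen_mask(array(TRUE, c(4, 4, 4)), 1)
  expect_error(mean_spacing(full), "background")
})

test_that("structure number follows the rod model and the periodic oracle", {
  expect_equal(bundle_number(35.4, 13.9), 1000 / 49.3, tolerance = 1e-12)
  expect_lt(bundle_number(1e7, 1e7), 1e-3)          # Nr -> 0 limit
  expect_equal(bundle_number(10, 40, coll_v_over_tv = 20, model = "plate"),
               20)

  # alternating slabs of period p = a + b -> Nr = 1000/p; averages are taken
  # over the central periods to emulate the infinite periodic medium (gaps
  # touching the z boundary are open and would bias Sp upward)
  pm <- periodic_slab_mask(a = 5, b = 7, periods = 6, side = 24)
  thmap <- local_thickness(pm)$map
  spmap <- mean_spacing(pm)$map
  core <- 13:(dim(thmap)[3] - 12)
  th <- mean(thmap[, , core][pm$voxels[, , core]])
  sp <- mean(spmap[, , core][!pm$voxels[, , core]])
  expect_lt(abs(th - 5), 0.5)
  expect_lt(abs(sp - 7), 0.5)
  expect_lt(abs(bundle_number(th, sp) - 1000 / 12) / (1000 / 12), 0.05)
})

test_that("MIL anisotropy separates isotropic and aligned fabrics deterministically", {
  iso <- sphere_packing_mask(c(80, 80, 80), r = 6, seed = 2)
  da_iso <- degree_of_anisotropy(iso, seed = 3)
  expect_gte(da_iso, 0.8)

  fib <- parallel_fiber_mask(c(64, 64, 64), r = 3, n_fibers = 30, seed = 2)
  da_fib <- degree_of_anisotropy(fib, seed = 3)
  expect_lte(da_fib, 0.3)
  expect_lt(da_fib, da_iso)

  expect_identical(as.numeric(degree_of_anisotropy(fib, seed = 7)),
                   as.numeric(degree_of_anisotropy(fib, seed = 7)))
  expect_equal(as.numeric(degree_of_anisotropy(fib, seed = 7,
                                               convention = "complement")),
               1 - as.numeric(degree_of_anisotropy(fib, seed = 7)),
               tolerance = 1e-12)
  expect_error(degree_of_anisotropy(
    collagen_mask(array(TRUE, c(4, 4, 4)), 1)), "both phases")
})

test_that("connectivity density counts handles through the Euler characteristic", {
  ball <- generate_geometric_solid("sphere", c(32, 32, 32), r = 10)
  expect_identical(attr(connectivity_density(ball), "beta1"), 0)

  tor <- generate_geometric_solid("torus", c(48, 48, 24), r = 5, R_major = 12)
  cd <- connectivity_density(tor)
  expect_identical(attr(cd, "beta1"), 1)
  expect_equal(as.numeric(cd), 1 / prod(48, 48, 24))

  two <- generate_geometric_solid("two_tori", c(96, 48, 24), r = 5,
                                  R_major = 10)
  # purge keeps the largest component only: a single torus remains
  expect_identical(attr(connectivity_density(two), "beta1"), 1)

  # hollow sphere: the enclosed cavity is filled, leaving a ball
  shell <- array(FALSE, c(40, 40, 40))
  x <- seq_len(40) - 1
  r2 <- outer(outer((x - 19)^2, (x - 19)^2, "+"), (x - 19)^2, "+")
  shell[r2 <= 15^2 & r2 >= 10^2] <- TRUE
  expect_identical(attr(connectivity_density(collagen_mask(shell, 1)),
                        "beta1"), 0)

  # strut lattice: beta1 equals the cycle rank E - V + 1 of the strut graph
  d <- c(40, 40, 40)
  m <- array(FALSE, dim = d)
  nodes <- c(8, 20, 32)
  for (a in nodes) for (b in nodes) { m[, a, b] <- TRUE; m[a, , b] <- TRUE
    m[a, b, ] <- TRUE }
  cdl <- connectivity_density(collagen_mask(m, 1))
  expect_identical(attr(cdl, "beta1"), 54 - 27 + 1)
})

test_that("both Euler routes agree exactly on exhaustive and random volumes", {
  # all 256 two-by-two-by-two binary volumes, exhaustively
  for (code in 0:255) {
    m <- array(bitwAnd(code, bitwShiftL(1L, 0:7)) != 0L, c(2, 2, 2))
    expect_identical(euler_characteristic(m, "complex"),
                     euler_characteristic(m, "inclusion_exclusion"))
  }
  set.seed(31)
  for (i in 1:300) {
    d <- sample(2:5, 3, replace = TRUE)
    m <- array(runif(prod(d)) < runif(1, 0.2, 0.8), dim = d)
    expect_identical(euler_characteristic(m, "complex"),
                     euler_characteristic(m, "inclusion_exclusion"))
  }
})

test_that("subvolume reports aggregate correctly and bracket global fractions", {
  sph <- generate_geometric_solid("sphere", c(32, 32, 32), r = 9)
  rep3 <- analyze_subvolumes(list(sph, sph, sph))
  expect_true(all(rep3$aggregate$sd == 0))
  expect_equal(rep3$aggregate$mean[rep3$aggregate$index == "coll_v_over_tv"],
               volume_fraction(sph))
  expect_equal(rep3$aggregate$mean,
               vapply(rep3$aggregate$index, function(ix)
                 mean(rep3$per_subvolume[[ix]]), numeric(1)),
               ignore_attr = TRUE)

  # spatially varying fraction: per-subvolume fractions bracket the global
  spec <- phantom_spec(shape_um = c(160, 160, 80), voxel_size_um = 2.5,
                       target_coll_fraction = 0.25,
                       bundle_radius_um = c(8, 2), bright_spot_rate = 0,
                       seed = 6)
  ph <- generate_fiber_phantom(spec)
  tiles <- extract_subvolumes(ph$volume, c(80, 80, 80))
  fracs <- vapply(tiles, function(t)
    mean(ph$truth$mask$voxels[
      attr(t, "origin_voxel")[1]:(attr(t, "origin_voxel")[1] + 31),
      attr(t, "origin_voxel")[2]:(attr(t, "origin_voxel")[2] + 31),
      ]), numeric(1))
  gl <- ph$truth$true_coll_fraction
  expect_gte(gl, min(fracs)); expect_lte(gl, max(fracs))
})

test_that("indices are intensive under structure duplication", {
  tor <- generate_geometric_solid("torus", c(48, 48, 24), r = 5, R_major = 12)
  dup <- array(FALSE, c(96, 48, 24))
  dup[1:48, , ] <- tor$voxels
  dup[49:96, , ] <- tor$voxels
  dm <- collagen_mask(dup, 1)
  expect_equal(volume_fraction(dm), volume_fraction(tor), tolerance = 1e-12)
  expect_equal(specific_surface(dm), specific_surface(tor), tolerance = 0.02)
  expect_equal(local_thickness(dm)$mean_um, local_thickness(tor)$mean_um,
               tolerance = 0.02)
  # without purging, handles and ROI volume both double: density unchanged
  expect_equal(as.numeric(connectivity_density(dm, purge = FALSE)),
               as.numeric(connectivity_density(tor, purge = FALSE)),
               tolerance = 1e-12)
  expect_identical(attr(connectivity_density(dm, purge = FALSE), "beta1"), 2)
  # the default purge keeps the largest connected component only
  expect_identical(attr(connectivity_density(dm), "beta1"), 1)
})

test_that("sphere S/V and thickness errors shrink with resolution", {
  errs_sv <- errs_th <- numeric(3)
  radii <- c(8, 16, 32)
  for (i in 1:3) {
    r <- radii[i]
    side <- as.integer(2 * r + 8)
    sph <- generate_geometric_solid("sphere", rep(side, 3), r = r,
                                    voxel_size_um = 32 / r)
    r_um <- r * 32 / r
    errs_sv[i] <- abs(specific_surface(sph) - 3 / r_um * 1000) /
      (3 / r_um * 1000)
    errs_th[i] <- abs(local_thickness(sph)$mean_um - 2 * r_um) / (2 * r_um)
  }
  expect_true(all(diff(errs_sv) <= 0.005))
  expect_true(all(diff(errs_th) <= 0.005))
})
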