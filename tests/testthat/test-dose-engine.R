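test_that("WEPL in water and slab geometries matches closed forms", {
  wp <- make_water_phantom(c(40, 40, 40), c(1, 1, 1))
  g <- wp$grid
  ## 100 mm of water -> 100 mm WEPL; here a 30 mm-deep point
  expect_equal(wepl(g, c(1, 0, 0), c(30, 20, 20)), 30.5, tolerance = 1e-9)
  ## 20 mm water + 15.5 mm of density 2.0
  g2 <- g; g2$voxels[21:40, , ] <- 2
  expect_equal(wepl(g2, c(1, 0, 0), c(35, 20, 20)), 20 + 15.5 * 2,
               tolerance = 1e-9)
  ## bolus offset at zero geometric depth (entry face)
  expect_equal(wepl(g, c(1, 0, 0), c(-0.5, 20, 20), bolus_mm = 20), 20,
               tolerance = 1e-9)
  expect_error(wepl(g, c(1, 0, 0), c(-5, 20, 20)), "outside")
})

test_that("per-beam WEPL maps agree with the pointwise tracer", {
  wp <- make_water_phantom(c(20, 20, 20), c(1, 1, 1))
  g <- wp$grid
  g$voxels[8:13, 1:10, ] <- 1.7
  ctr <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  for (dir in list(c(1, 0, 0), c(0, -1, 0), pbsrobust:::unitize(c(1, .4, .3)))) {
    b <- beam_setup(dir, "carbon", bolus_mm = 5)
    wm <- pbsrobust:::wepl_map(g, b)
    wv <- wepl(g, dir, ctr, bolus_mm = 5)
    expect_lt(max(abs(as.numeric(wm) - wv)), 0.35)
  }
})

test_that("depth dose is normalized at the peak with a plateau and steep falloff", {
  for (sp in c("carbon", "proton")) {
    expect_equal(depth_dose(100, 100, sp), 1.0)
    sz <- pbsrobust:::species_defaults(sp)$sigma_z
    expect_lt(depth_dose(100, 100 + 5 * sz, sp), 0.01)
    pl <- depth_dose(100, 0, sp)
    expect_gt(pl, 0.2); expect_lt(pl, 0.5)
  }
  ## frozen regression value of the chosen parameterization
  expect_equal(depth_dose(100, 0, "carbon"), 0.2545455, tolerance = 1e-6)
  ## the curve rises from the plateau into the peak region and never
  ## exceeds the peak by more than the parameterization's small overshoot
  z <- seq(0, 110, by = 0.5)
  dd <- depth_dose(100, z, "carbon")
  expect_true(all(dd[z >= 90 & z <= 100] > depth_dose(100, 50, "carbon")))
  expect_lt(max(dd), 1.05)
  expect_equal(z[which.max(dd)], 100, tolerance = 3)
})

test_that("spot FWHM interpolates the species endpoints monotonically", {
  expect_equal(spot_fwhm(20, "carbon"), 7.5)
  expect_equal(spot_fwhm(300, "carbon"), 5.0)
  expect_equal(spot_fwhm(20, "proton"), 11.0)
  expect_equal(spot_fwhm(300, "proton"), 5.5)
  r <- seq(20, 300, length.out = 30)
  for (sp in c("carbon", "proton"))
    expect_true(all(diff(spot_fwhm(r, sp)) <= 0))
  expect_error(spot_fwhm(10, "carbon"), "machine limits")
  expect_error(spot_fwhm(400, "proton"), "machine limits")
})

test_that("the lateral profile halves at FWHM/2 off axis", {
  sig <- pbsrobust:::fwhm_to_sigma(6)
  expect_equal(exp(-(6 / 2)^2 / (2 * sig^2)), 0.5, tolerance = 1e-12)
})

test_that("spot placement follows the species raster parameters", {
  wp <- tiny_water_case()
  ptv <- wp$structures$masks$PTV
  bc <- beam_setup(c(1, 0, 0), "carbon", bolus_mm = 20)
  sc <- place_spots(ptv, wp$grid, bc)
  expect_equal(unique(diff(sort(unique(sc$range)))), 3)
  expect_equal(unique(diff(sort(unique(sc$u)))), 2)  # carbon pitch
  bp <- beam_setup(c(1, 0, 0), "proton", bolus_mm = 20)
  sp <- place_spots(ptv, wp$grid, bp)
  expect_equal(unique(diff(sort(unique(sp$range)))), 2)
  expect_equal(unique(diff(sort(unique(sp$u)))), 3)  # proton pitch
  ## every target voxel has a bracketing layer
  wm <- pbsrobust:::wepl_map(wp$grid, bc)
  tw <- wm[ptv]
  expect_true(all(vapply(tw, function(w)
    any(abs(sc$range - w) <= bc$depth_step), TRUE)))
  ## lattice dilation is monotone in the tolerance
  s0 <- place_spots(ptv, wp$grid,
                    beam_setup(c(1, 0, 0), "carbon", tolerance = 0,
                               bolus_mm = 20))
  s1 <- place_spots(ptv, wp$grid,
                    beam_setup(c(1, 0, 0), "carbon", tolerance = 1,
                               bolus_mm = 20))
  expect_gt(nrow(s1), nrow(s0))
})

test_that("too-shallow targets are rejected unless a bolus is added", {
  wp <- tiny_water_case()
  b <- beam_setup(c(1, 0, 0), "carbon")
  expect_error(place_spots(wp$structures$masks$PTV, wp$grid, b), "bolus")
  b20 <- beam_setup(c(1, 0, 0), "carbon", bolus_mm = 20)
  expect_silent(place_spots(wp$structures$masks$PTV, wp$grid, b20))
  expect_error(place_spots(array(FALSE, dim = dim(wp$grid$voxels)),
                           wp$grid, b20), "empty")
})

test_that("superposition is linear and places the peak at the right depth", {
  wp <- make_water_phantom(c(40, 40, 40), c(1, 1, 1))
  b <- beam_setup(c(1, 0, 0), "carbon", bolus_mm = 20)
  spot <- data.frame(beam = 1L, layer = 1L, range = 50, u = 20, v = 20,
                     fwhm = spot_fwhm(50, beam = b), weight = 1)
  d0 <- compute_dose(wp$grid, b, spot, weights = 0)
  expect_true(all(d0$absorbed == 0) && all(d0$weighted == 0))
  d1 <- compute_dose(wp$grid, b, spot, weights = 1)
  d2 <- compute_dose(wp$grid, b, spot, weights = 2)
  expect_equal(d2$absorbed, 2 * d1$absorbed)
  ## axial maximum at geometric depth = range - bolus
  ax <- d1$absorbed[, 21, 21]
  expect_equal(which.max(ax) - 1 + 0.0, 30, tolerance = 1)
  expect_error(compute_dose(wp$grid, b, spot, weights = -1), "negative")
  expect_error(compute_dose(wp$grid, b, spot, weights = c(1, 1)), "number of spots")
})

test_that("the engine matches a brute-force per-voxel superposition", {
  ## axis-aligned in water: exact separable evaluation, machine precision
  wp <- make_water_phantom(c(24, 24, 24), c(1, 1, 1))
  b <- beam_setup(c(1, 0, 0), "carbon", bolus_mm = 15)
  set.seed(3)
  spots <- data.frame(beam = 1L, layer = rep(1:2, each = 4),
                      range = rep(c(30, 33), each = 4),
                      u = runif(8, 6, 18), v = runif(8, 6, 18),
                      fwhm = rep(spot_fwhm(c(30, 33), beam = b), each = 4),
                      weight = runif(8, 0.5, 2))
  eng_w <- compute_dose(wp$grid, b, spots)
  ora_w <- oracle_dose(wp$grid, b, spots, spots$weight)
  expect_lt(max(abs(eng_w$absorbed - ora_w)), 1e-10 * max(ora_w))
  ## heterogeneous channel: the oracle integrates the interpolated density
  ## with a fixed 0.5 mm step, the aligned engine integrates the voxel
  ## profile exactly; they agree to a fraction of a percent
  g <- wp$grid
  g$voxels[10:14, 1:12, ] <- 1.6
  eng_h <- compute_dose(g, b, spots)
  ora_h <- oracle_dose(g, b, spots, spots$weight)
  expect_lt(max(abs(eng_h$absorbed - ora_h)), 0.01 * max(ora_h))
  ## oblique: shared 0.5 mm tracing on a 1 mm grid, lateral fluence map
  ## interpolation leaves a few percent
  bo <- beam_setup(pbsrobust:::unitize(c(1, 0.35, 0.25)), "proton",
                   bolus_mm = 15)
  spots_o <- spots
  spots_o$fwhm <- rep(spot_fwhm(c(30, 33), beam = bo), each = 4)
  eng_o <- compute_dose(g, bo, spots_o)
  ora_o <- oracle_dose(g, bo, spots_o, spots_o$weight)
  expect_lt(max(abs(eng_o$absorbed - ora_o)), 0.05 * max(ora_o))
})

test_that("lateral translation of all spots translates the dose in water", {
  wp <- make_water_phantom(c(24, 24, 24), c(2, 2, 2))
  b <- beam_setup(c(1, 0, 0), "carbon", bolus_mm = 20)
  spots <- place_spots(wp$structures$masks$CTV, wp$grid, b)
  d0 <- compute_dose(wp$grid, b, spots)
  spots2 <- spots; spots2$u <- spots2$u + 2  # one voxel along +y
  d2 <- compute_dose(wp$grid, b, spots2)
  expect_equal(d2$absorbed[, 2:24, ], d0$absorbed[, 1:23, ], tolerance = 1e-12)
})

test_that("RBE weighting: fixed 1.1 for protons, monotone surrogate for carbon", {
  wp <- tiny_water_case()
  bp <- lateral_opposed_beams("proton", bolus_mm = 20)
  sp <- do.call(rbind, lapply(1:2, function(i) {
    s <- place_spots(wp$structures$masks$PTV, wp$grid, bp[[i]])
    s$beam <- i
    s
  }))
  dg <- compute_dose(wp$grid, bp, sp)
  nz <- dg$absorbed > 0
  expect_equal(dg$weighted[nz] / dg$absorbed[nz], rep(1.1, sum(nz)))
  ## apply_rbe on an explicit grid
  dg2 <- apply_rbe(dg, "proton")
  expect_equal(dg2$weighted, 1.1 * dg$absorbed)
  expect_true(all(dg$weighted[dg$absorbed == 0] == 0))
  ## carbon factor: >= 1 everywhere, larger near end of range
  f <- pbsrobust:::carbon_rbe_factor(c(0, 5, 20, 80, 200, -3))
  expect_true(all(f >= 1))
  expect_true(all(diff(f[1:5]) < 0))
  expect_equal(f[6], f[1])  # clipped beyond the peak
  expect_error(apply_rbe(dg, "helium"), "unknown species")
  expect_error(apply_rbe(dg, "carbon"), "residual")
  ## weighted dose dominates absorbed for both species
  bc <- lateral_opposed_beams("carbon", bolus_mm = 20)
  sc <- do.call(rbind, lapply(1:2, function(i) {
    s <- place_spots(wp$structures$masks$PTV, wp$grid, bc[[i]])
    s$beam <- i
    s
  }))
  dc <- compute_dose(wp$grid, bc, sc)
  expect_true(all(dc$weighted >= dc$absorbed))
})
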