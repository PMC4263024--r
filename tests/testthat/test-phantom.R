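test_that("water phantom is exactly water with a centred interior target", {
  wp <- make_water_phantom(c(20, 20, 16), spacing = c(1, 1, 2.5))
  expect_true(all(wp$grid$voxels == 1.0))
  expect_equal(wp$grid$spacing, c(1, 1, 2.5))
  ctv <- wp$structures$masks$CTV
  expect_gt(sum(ctv), 0)
  idx <- which(ctv, arr.ind = TRUE)
  expect_true(all(idx > 1) && all(t(idx) < dim(ctv)))
  expect_true(all(wp$structures$masks$PTV[ctv]))
})

test_that("skull-base phantoms respect the configured CTV volume range and geometry invariants", {
  for (s in 1:3) {
    ph <- make_skullbase_phantom(phantom_spec(seed = s))
    m <- ph$structures$masks
    vol <- mask_volume_cm3(m$CTV, ph$grid)
    expect_gte(vol, 15.6)
    expect_lte(vol, 90.7)
    expect_true(all(m$PTV[m$CTV]))
    ## all structures inside the external contour, air outside it
    for (nm in setdiff(names(m), "external"))
      expect_true(all(m$external[m[[nm]]]), label = nm)
    expect_true(all(ph$grid$voxels[!m$external] == 0.001))
    ## CTV disjoint from every OAR
    expect_false(any(m$CTV & (m$brainstem | m$chiasm | m$optic_ipsi |
                                m$optic_contra)))
  }
})

test_that("phantom generation is a pure function of spec and seed", {
  a <- make_skullbase_phantom(phantom_spec(seed = 11))
  b <- make_skullbase_phantom(phantom_spec(seed = 11))
  expect_identical(a$grid$voxels, b$grid$voxels)
  expect_identical(a$structures$masks, b$structures$masks)
  c <- make_skullbase_phantom(phantom_spec(seed = 12))
  expect_false(identical(a$grid$voxels, c$grid$voxels))
})

test_that("brainstem abuts the PTV when requested and stands off otherwise", {
  ph <- make_skullbase_phantom(phantom_spec(seed = 2, abut_brainstem = TRUE))
  m <- ph$structures$masks
  expect_false(any(m$brainstem & m$PTV))
  ## zero surface distance: a one-voxel isotropic expansion of the PTV
  ## already overlaps the brainstem
  touch <- expand_margin(m$PTV, ph$grid$spacing, ph$grid$spacing[1],
                         ph$grid$spacing[2], ph$grid$spacing[3])
  expect_true(any(touch & m$brainstem))
  ph2 <- make_skullbase_phantom(phantom_spec(seed = 2, abut_brainstem = FALSE))
  m2 <- ph2$structures$masks
  touch2 <- expand_margin(m2$PTV, ph2$grid$spacing, ph2$grid$spacing[1],
                          ph2$grid$spacing[2], ph2$grid$spacing[3])
  expect_false(any(touch2 & m2$brainstem))
})

test_that("a density interface crosses the mediolateral entrance channel", {
  ph <- make_skullbase_phantom(phantom_spec(seed = 1))
  b <- beam_setup(c(1, 0, 0), "carbon")
  wm <- pbsrobust:::wepl_map(ph$grid, b)
  spread <- diff(range(wm[ph$structures$masks$CTV]))
  ## well beyond what target depth extent alone could explain
  expect_gt(spread, 20)
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(phantom_spec(shape = c(20, 20, 20), spacing = c(1, 1, 1),
                            ctv_volume_range = c(80, 90.7)),
               "infeasible")
  expect_error(phantom_spec(ctv_volume_range = c(50, 20)), "increasing")
})

test_that("margin expansion matches the anisotropic-distance definition", {
  ## single voxel on a 1 mm grid, margins (2,2,3): bounding box 5 x 5 x 7
  m <- array(FALSE, dim = c(11, 11, 11))
  m[6, 6, 6] <- TRUE
  e <- expand_margin(m, c(1, 1, 1), 2, 2, 3)
  bb <- apply(which(e, arr.ind = TRUE), 2, range)
  expect_equal(bb[2, ] - bb[1, ] + 1, c(5, 5, 7), ignore_attr = TRUE)
  expect_identical(e, oracle_expand_margin(m, c(1, 1, 1), c(2, 2, 3)))

  ## exhaustive oracle on random masks, anisotropic spacing
  set.seed(42)
  for (rep in 1:3) {
    d <- c(9, 8, 7)
    mask <- array(runif(prod(d)) < 0.08, dim = d)
    if (!any(mask)) mask[5, 4, 3] <- TRUE
    sp <- c(1, 1.5, 2)
    mg <- c(2, 2, 3)
    expect_identical(expand_margin(mask, sp, mg[1], mg[2], mg[3]),
                     oracle_expand_margin(mask, sp, mg))
  }
})

test_that("margin expansion edge behaviour: identity, containment, equivariance", {
  set.seed(7)
  mask <- array(runif(12^3) < 0.05, dim = c(12, 12, 12))
  mask[6, 6, 6] <- TRUE
  expect_identical(expand_margin(mask, c(1, 1, 1), 0, 0, 0), mask)
  e <- expand_margin(mask, c(1, 1, 1), 2, 2, 3)
  expect_true(all(e[mask]))
  ## translation equivariance (away from the boundary)
  m1 <- array(FALSE, dim = c(15, 15, 15)); m1[6, 7, 8] <- TRUE
  m2 <- array(FALSE, dim = c(15, 15, 15)); m2[7, 8, 9] <- TRUE
  e1 <- expand_margin(m1, c(1, 1, 1), 2, 2, 3)
  e2 <- expand_margin(m2, c(1, 1, 1), 2, 2, 3)
  expect_identical(e1[2:13, 3:13, 3:12], e2[3:14, 4:14, 4:13])
  expect_error(expand_margin(mask, c(1, 1, 1), -1, 0, 0), ">= 0")
})

test_that("external override sets air outside and preserves inside", {
  g <- density_grid(array(1, dim = c(6, 6, 6)), c(1, 1, 1))
  half <- array(FALSE, dim = c(6, 6, 6)); half[1:3, , ] <- TRUE
  o <- apply_external_override(g, half)
  expect_true(all(o$voxels[4:6, , ] == 0.001))
  expect_true(all(o$voxels[1:3, , ] == 1))
  full <- array(TRUE, dim = c(6, 6, 6))
  expect_identical(apply_external_override(g, full)$voxels, g$voxels)
  none <- array(FALSE, dim = c(6, 6, 6))
  expect_true(all(apply_external_override(g, none)$voxels == 0.001))
  expect_error(apply_external_override(g, array(TRUE, dim = c(5, 6, 6))),
               "shape")
})

test_that("NIfTI round trip preserves voxels and spacing", {
  ph <- make_water_phantom(c(8, 8, 8), c(1, 1, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_grid_nifti(ph$grid, f)
  g <- read_grid_nifti(f)
  expect_equal(g$voxels, ph$grid$voxels, ignore_attr = TRUE)
  expect_equal(g$spacing, ph$grid$spacing, tolerance = 1e-6)
  dir <- tempfile()
  paths <- write_structures_nifti(ph$structures, ph$grid, dir)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[["CTV"]])
  expect_equal(array(as.integer(back), dim = dim(back)),
               array(as.integer(ph$structures$masks$CTV), dim = c(8, 8, 8)))
})
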