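test_that("cumulative DVH matches brute-force voxel counting", {
  ## hand cases
  m4 <- array(TRUE, dim = c(4, 1, 1))
  dvh4 <- cumulative_dvh(array(c(1, 2, 3, 4), dim = c(4, 1, 1)), m4,
                         prescription = 4)
  expect_equal(v_at(dvh4, 2.5), 50)
  expect_equal(v_at(dvh4, 0), 100)
  expect_equal(d_at(dvh4, 100), 1)
  u <- cumulative_dvh(array(7, dim = c(3, 3, 3)),
                      array(TRUE, dim = c(3, 3, 3)), prescription = 7)
  expect_equal(v_at(u, c(0, 6.9, 7)), c(100, 100, 100))
  expect_equal(v_at(u, 7.01), 0)
  ## random cases vs counting and the curve's invariants
  set.seed(5)
  for (rep in 1:4) {
    d <- array(rexp(16^3, 1 / 50), dim = c(16, 16, 16))
    mask <- array(runif(16^3) < 0.3, dim = c(16, 16, 16))
    if (!any(mask)) mask[1] <- TRUE
    dvh <- cumulative_dvh(d, mask, prescription = 60)
    lv <- runif(6, 0, max(d))
    expect_equal(v_at(dvh, lv), vapply(lv, function(l)
      oracle_v_at(d[mask], l), 1))
    expect_true(all(diff(dvh$volume) <= 0))
    expect_equal(dvh$volume[1], 100)
    expect_equal(dvh$volume[length(dvh$volume)], 0)
  }
  expect_error(cumulative_dvh(array(1, dim = c(2, 2, 2)),
                              array(FALSE, dim = c(2, 2, 2))), "empty")
})

test_that("dose-at-volume interpolates the quantile function", {
  set.seed(9)
  doses <- rexp(500, 1 / 40)
  dvh <- cumulative_dvh(array(doses, dim = c(500, 1, 1)),
                        array(TRUE, dim = c(500, 1, 1)))
  for (q in c(1, 2, 25, 50, 98, 100))
    expect_equal(d_at(dvh, q), oracle_d_at(doses, q))
  ## round trip: at least q percent receive d_at(q)
  for (q in c(5, 50, 95)) expect_gte(v_at(dvh, d_at(dvh, q)), q)
  expect_error(d_at(dvh, 0), "in \\(0, 100\\]")
})

test_that("homogeneity index in percentage points of prescription", {
  u <- cumulative_dvh(array(60, dim = c(50, 1, 1)),
                      array(TRUE, dim = c(50, 1, 1)), prescription = 60)
  expect_equal(homogeneity_index(u), 0)
  ## half the voxels at 95%, half at 105% of a 60 Gy(RBE) prescription
  d <- array(rep(c(57, 63), each = 500), dim = c(1000, 1, 1))
  dvh <- cumulative_dvh(d, array(TRUE, dim = c(1000, 1, 1)),
                        prescription = 60)
  expect_equal(homogeneity_index(dvh), 10)
  set.seed(2)
  r <- cumulative_dvh(array(runif(200, 50, 70), dim = c(200, 1, 1)),
                      array(TRUE, dim = c(200, 1, 1)), prescription = 60)
  expect_gte(homogeneity_index(r), 0)
})

test_that("conformity index follows the conformation-number formula", {
  d <- array(0, dim = c(10, 10, 10))
  ptv <- array(FALSE, dim = c(10, 10, 10)); ptv[3:6, 3:6, 3:6] <- TRUE
  d[ptv] <- 60
  expect_equal(conformity_index(d, ptv, 57), 1)
  ## isodose covers the PTV plus as much again: CN = 0.5
  d2 <- d
  d2[7:10, 3:6, 3:6] <- 60  # same volume again outside
  expect_equal(conformity_index(d2, ptv, 57), 0.5)
  d3 <- array(0, dim = c(10, 10, 10)); d3[8:9, 8:9, 8:9] <- 60
  expect_equal(conformity_index(d3, ptv, 57), 0)
  expect_equal(conformity_index(array(0, dim = c(10, 10, 10)), ptv, 57), 0)
})

test_that("maximum and near-maximum doses", {
  u <- array(42, dim = c(5, 5, 5))
  dm <- dmax_and_near_max(u, array(TRUE, dim = c(5, 5, 5)))
  expect_equal(unname(dm), c(42, 42))
  ## 200 voxels, one hot voxel (0.5% of the volume): Dmax sees it, the 1%
  ## near-max percentile does not
  d <- array(c(100, rep(10, 199)), dim = c(200, 1, 1))
  dm2 <- dmax_and_near_max(d, array(TRUE, dim = c(200, 1, 1)))
  expect_equal(dm2[["dmax"]], 100)
  expect_equal(dm2[["d_near_max"]], oracle_d_at(as.numeric(d), 1))
  ## with the hot region at exactly 1% of the volume the percentile
  ## interpolates between the two dose levels
  d3 <- array(c(rep(100, 2), rep(10, 198)), dim = c(200, 1, 1))
  dm3b <- dmax_and_near_max(d3, array(TRUE, dim = c(200, 1, 1)))
  expect_equal(dm3b[["d_near_max"]], oracle_d_at(as.numeric(d3), 1))
  expect_gt(dm3b[["d_near_max"]], 10); expect_lt(dm3b[["d_near_max"]], 100)
  set.seed(8)
  r <- array(rexp(300), dim = c(300, 1, 1))
  dm3 <- dmax_and_near_max(r, array(TRUE, dim = c(300, 1, 1)))
  expect_gte(dm3[["dmax"]], dm3[["d_near_max"]])
  expect_error(dmax_and_near_max(u, array(FALSE, dim = c(5, 5, 5))), "empty")
})

test_that("indices depend only on the dose multiset and scale correctly", {
  set.seed(4)
  d <- runif(400, 30, 70)
  arr <- function(x) array(x, dim = c(400, 1, 1))
  msk <- array(TRUE, dim = c(400, 1, 1))
  a <- cumulative_dvh(arr(d), msk, 60)
  b <- cumulative_dvh(arr(sample(d)), msk, 60)
  expect_equal(d_at(a, c(1, 2, 50, 98)), d_at(b, c(1, 2, 50, 98)))
  expect_equal(v_at(a, 57), v_at(b, 57))
  ## scaling all doses by s scales percentile doses and preserves V at the
  ## scaled level
  s <- 1.7
  cs <- cumulative_dvh(arr(s * d), msk, 60 * s)
  expect_equal(d_at(cs, c(2, 98)), s * d_at(a, c(2, 98)))
  expect_equal(v_at(cs, s * 57), v_at(a, 57))
})

test_that("compute_indices assembles the evaluation index set", {
  ph <- make_water_phantom(c(12, 12, 12), c(2, 2, 2), oar = TRUE)
  d <- array(0, dim = c(12, 12, 12))
  d[ph$structures$masks$PTV] <- 60
  dg <- structure(list(absorbed = d, weighted = d, spacing = c(2, 2, 2),
                       origin = c(0, 0, 0), species = "proton"),
                  class = "dose_grid")
  idx <- compute_indices(dg, ph$structures, 60)
  expect_equal(idx$ptv_v95, 100)
  expect_equal(idx$ctv_v95, 100)
  expect_equal(idx$ptv_hi, 0)
  expect_equal(idx$ci, 1)
  expect_equal(idx$dmax_oar, 0)
})
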