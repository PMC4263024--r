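test_that("objective is zero at the prescription and quadratic in OAR excess", {
  d <- c(2, 1, 1)
  grid <- density_grid(array(1, dim = d), c(1, 1, 1))
  ptv <- array(c(TRUE, FALSE), dim = d)
  oar <- array(c(FALSE, TRUE), dim = d)
  st <- structure_set(list(CTV = ptv, PTV = ptv, oar = oar), grid)
  pres <- prescription(60)
  con <- list(oar_constraint("oar", 54))
  mk <- function(v) array(v, dim = d)
  expect_equal(objective_value(mk(c(60, 0)), st, pres, con), 0)
  expect_equal(objective_value(mk(c(60, 54)), st, pres, con), 0)
  ## hand-computed two-voxel fixture: PTV at 58, OAR at 57
  f <- objective_value(mk(c(58, 57)), st, pres, con, oar_weight = 50)
  expect_equal(f, (58 - 60)^2 / 60^2 + 50 * (57 - 54)^2 / 54^2)
  ## doubling the OAR excess quadruples its penalty term
  f1 <- objective_value(mk(c(60, 57)), st, pres, con, oar_weight = 50)
  f2 <- objective_value(mk(c(60, 60)), st, pres, con, oar_weight = 50)
  expect_equal(f2 / f1, 4)
  ## ridge term
  expect_equal(objective_value(mk(c(60, 0)), st, pres, con,
                               weights = c(2, 1), weights_penalty = 0.1),
               0.1 * 5)
})

test_that("unconstrained planning reaches the coverage objective on water", {
  plan <- tiny_plan("carbon", "uc")
  expect_gte(plan$indices$ptv_v95, 95)
  expect_gte(plan$indices$ctv_v95, 98)
  expect_true(all(plan$spots$weight >= 0))
  expect_s3_class(plan, "ion_plan")
})

test_that("optimization is deterministic", {
  wp <- tiny_water_case()
  beams <- lateral_opposed_beams("carbon", bolus_mm = 20)
  p1 <- suppressWarnings(optimize_plan(wp$grid, wp$structures, beams,
                                       prescription(60), mode = "uc",
                                       control = list(maxit = 60)))
  p2 <- suppressWarnings(optimize_plan(wp$grid, wp$structures, beams,
                                       prescription(60), mode = "uc",
                                       control = list(maxit = 60)))
  expect_identical(p1$spots$weight, p2$spots$weight)
  expect_identical(p1$dose$weighted, p2$dose$weighted)
})

test_that("OAR maximum-dose constraints are met within solver tolerance", {
  plan <- tiny_plan("carbon", "mc", oar = TRUE)
  expect_gte(plan$indices$ptv_v95, 95)
  expect_lte(plan$indices$dmax_oar, 55)
  expect_equal(dose_modulation(plan), plan$indices$dmax_oar / 60)
})

test_that("single-field mode delivers per-field uniform target doses", {
  plan <- tiny_plan("carbon", "sc", oar = TRUE)
  expect_gte(plan$indices$ptv_v95, 95)
  ptv <- plan$structures$masks$PTV
  for (b in 1:2) {
    sel <- plan$spots$beam == b
    db <- compute_dose(plan$grid, plan$beams, plan$spots[sel, ],
                       plan$spots$weight[sel], caches = plan$caches)
    fd <- db$weighted[ptv]
    half <- plan$prescription$dose / 2
    dvh <- cumulative_dvh(array(fd, dim = c(length(fd), 1, 1)),
                          array(TRUE, dim = c(length(fd), 1, 1)), half)
    expect_lt(homogeneity_index(dvh, half), 12)  # pp of the per-field dose
    expect_equal(mean(fd), half, tolerance = 0.05)
  }
})

test_that("removing constraints cannot worsen the target-only optimum", {
  uc <- tiny_plan("carbon", "uc", oar = TRUE)
  mc <- tiny_plan("carbon", "mc", oar = TRUE)
  f_uc <- objective_value(uc$dose, uc$structures, uc$prescription)
  f_mc <- objective_value(mc$dose, mc$structures, mc$prescription)
  expect_lte(f_uc, f_mc + 1e-6)
})

test_that("dose modulation ratio arithmetic", {
  d <- c(2, 1, 1)
  grid <- density_grid(array(1, dim = d), c(1, 1, 1))
  ptv <- array(c(TRUE, FALSE), dim = d)
  oar <- array(c(FALSE, TRUE), dim = d)
  st <- structure_set(list(CTV = ptv, PTV = ptv, oar = oar), grid)
  con <- list(oar_constraint("oar", 54))
  mk <- function(v) array(v, dim = d)
  expect_equal(dose_modulation(mk(c(60, 54)), st, con, 60), 0.9)
  expect_equal(dose_modulation(mk(c(60, 0)), st, con, 60), 0)
  expect_equal(dose_modulation(mk(c(60, 60)), st, con, 60), 1)
  expect_error(dose_modulation(mk(c(60, 60)), st, list(), 60),
               "no OAR constraints")
})

test_that("plans serialize to JSON + spot CSV + dose NIfTI and read back", {
  plan <- tiny_plan("carbon", "uc")
  dir <- tempfile()
  paths <- write_plan(plan, dir)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["plan"]], simplifyVector = TRUE)
  expect_equal(meta$species, "carbon")
  expect_equal(meta$mode, "uc")
  expect_equal(length(meta$beams$name), 2)
  sp <- read.csv(paths[["spots"]])
  expect_equal(nrow(sp), nrow(plan$spots))
  expect_equal(sp$weight, plan$spots$weight)
  back <- read_grid_nifti(paths[["dose"]])
  expect_equal(back$voxels, plan$dose$weighted, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("plan methods expose weights, residuals and simulated shifts", {
  plan <- tiny_plan("carbon", "uc")
  expect_identical(coef(plan), plan$spots$weight)
  r <- residuals(plan)
  expect_length(r, sum(plan$structures$masks$PTV))
  expect_lt(mean(abs(r)), 3)  # close to prescription across the PTV
  out <- utils::capture.output(print(plan))
  expect_true(any(grepl("ion_plan", out)))
  s <- summary(plan)
  expect_s3_class(s, "summary.ion_plan")
  sim <- simulate(plan, nsim = 2, seed = 4)
  expect_equal(nrow(sim), 2)
  expect_true(all(c("d_ptv_v95", "d_ctv_v95") %in% names(sim)))
})
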