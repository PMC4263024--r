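## Independent brute-force oracles, deliberately written as plain loops over
## voxels so they share no code with the production paths they check.

## Anisotropic margin expansion by exhaustive per-voxel distance checking.
oracle_expand_margin <- function(mask, spacing, margins) {
  d <- dim(mask)
  inp <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    for (r in seq_len(nrow(inp))) {
      dd <- (c(i, j, k) - inp[r, ]) * spacing
      s <- 0
      ok <- TRUE
      for (ax in 1:3) {
        if (margins[ax] == 0) {
          if (dd[ax] != 0) { ok <- FALSE; break }
        } else s <- s + (dd[ax] / margins[ax])^2
      }
      if (ok && s <= 1) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}

## Exact volume-at-dose by counting.
oracle_v_at <- function(doses, level) 100 * sum(doses >= level) / length(doses)

## Linear-interpolation quantile (type 7), written out from the definition.
oracle_d_at <- function(doses, volume_percent) {
  s <- sort(doses)
  n <- length(s)
  p <- 1 - volume_percent / 100
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

## Brute-force pencil-beam superposition: per-voxel, per-spot triple sum
## using the pointwise WEPL tracer.
oracle_dose <- function(grid, beam, spots, weights) {
  fr <- pbsrobust:::beam_frame(beam$direction)
  d <- dim(grid$voxels)
  ctr <- as.matrix(expand.grid(
    pbsrobust:::axis_coords(grid, 1),
    pbsrobust:::axis_coords(grid, 2),
    pbsrobust:::axis_coords(grid, 3)))
  wv <- wepl(grid, beam$direction, ctr, bolus_mm = beam$bolus_mm)
  u <- as.numeric(ctr %*% fr$eu)
  v <- as.numeric(ctr %*% fr$ev)
  out <- numeric(nrow(ctr))
  for (i in seq_len(nrow(spots))) {
    sig <- spots$fwhm[i] / (2 * sqrt(2 * log(2)))
    dd <- depth_dose(spots$range[i], wv, beam$species,
                     sigma_z = beam$sigma_z)
    lat <- exp(-((u - spots$u[i])^2 + (v - spots$v[i])^2) / (2 * sig^2))
    out <- out + weights[i] * dd * lat
  }
  array(out, dim = d)
}

## Two-sided exact binomial sign-test p-value from the tail definition.
oracle_sign_p <- function(k, n) {
  pk <- function(j) choose(n, j) / 2^n
  lower <- sum(vapply(0:min(k, n - k), pk, 1))
  upper <- sum(vapply(max(k, n - k):n, pk, 1))
  min(1, lower + upper)
}

## Small shared fixtures ----------------------------------------------------

## Water phantom with a centred cubic target; bolus keeps the target deeper
## than the minimum machine range.
tiny_water_case <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                            ctv_side_mm = 16, oar = FALSE) {
  make_water_phantom(shape, spacing, ctv_side_mm = ctv_side_mm, oar = oar)
}

## One small optimized plan, built once per test session and reused.
.fixture_env <- new.env(parent = emptyenv())

tiny_plan <- function(species = "carbon", mode = "uc", oar = FALSE,
                      maxit = 150) {
  key <- paste(species, mode, oar, maxit)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  wp <- tiny_water_case(oar = oar)
  beams <- lateral_opposed_beams(species, bolus_mm = 20)
  cons <- if (oar) list(oar_constraint("oar", 54)) else list()
  plan <- suppressWarnings(
    optimize_plan(wp$grid, wp$structures, beams, prescription(60, 20),
                  constraints = cons, mode = mode,
                  control = list(maxit = maxit)))
  .fixture_env[[key]] <- plan
  plan
}
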