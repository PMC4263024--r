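## Inverse optimization of pencil-beam spot weights.
##
## The planning problem is a convex quadratic: a PTV under/overdose penalty
## pulling every PTV voxel to the prescription, plus one-sided quadratic
## organ-at-risk overdose penalties, minimized over non-negative spot weights
## by a spectral projected-gradient method. Three modes mirror clinical
## practice: `uc` (unconstrained: target terms only), `mc` (multiple-field
## modulation: all fields' weights optimized jointly under the constraints)
## and `sc` (single-field modulation: each field optimized separately to a
## uniform fraction of the target dose with proportionally scaled
## constraints, then summed).

#' Define a prescription
#'
#' @param dose Prescribed dose in Gy(RBE) (> 0).
#' @param fractions Number of fractions (>= 1); carried for bookkeeping.
#' @param ptv_v95,ctv_v95 Planning objectives: minimum percent volume of
#'   PTV/CTV to receive 95% of the prescription (clinical goals of 95%
#'   and 98%).
#' @return An object of class `prescription`.
#' @export
prescription <- function(dose = 60, fractions = 20, ptv_v95 = 95,
                         ctv_v95 = 98) {
  check_numeric(dose, "dose", 1, positive = TRUE)
  check_numeric(fractions, "fractions", 1, positive = TRUE)
  if (fractions < 1) stopf("fractions must be >= 1")
  structure(list(dose = dose, fractions = fractions, ptv_v95 = ptv_v95,
                 ctv_v95 = ctv_v95), class = "prescription")
}

#' Define an organ-at-risk constraint
#'
#' @param structure Structure name in the structure set.
#' @param limit Maximum-dose limit in Gy(RBE) (> 0).
#' @param type `"max"` (limit applies to every voxel) or `"near_max"` (the
#'   structure surface abutting the PTV — voxels within `abut_margin_mm` of
#'   the PTV — may receive up to `relaxed_limit`; the strict limit applies to
#'   the rest).
#' @param relaxed_limit Relaxed surface limit for `near_max` (> `limit`).
#' @param abut_margin_mm Width of the abutting-surface region (mm).
#' @return An object of class `oar_constraint`.
#' @export
oar_constraint <- function(structure, limit, type = c("max", "near_max"),
                           relaxed_limit = NULL, abut_margin_mm = 3) {
  type <- match.arg(type)
  check_numeric(limit, "limit", 1, positive = TRUE)
  if (type == "near_max") {
    relaxed_limit <- relaxed_limit %||% limit
    check_numeric(relaxed_limit, "relaxed_limit", 1, positive = TRUE)
  }
  structure(list(structure = structure, limit = limit, type = type,
                 relaxed_limit = relaxed_limit,
                 abut_margin_mm = abut_margin_mm), class = "oar_constraint")
}

#' Clinical organ-at-risk constraint sets per species
#'
#' Carbon: 54 Gy(RBE) maximum dose to optic nerves and chiasm; brainstem
#' near-maximum 54 Gy(RBE) with the PTV-abutting surface allowed up to
#' 60 Gy(RBE). Protons: 60 and 63 Gy(RBE) respectively.
#'
#' @param species Ion species.
#' @return List of `oar_constraint` objects.
#' @export
default_constraints <- function(species = c("carbon", "proton")) {
  species <- match.arg(species)
  lim <- if (species == "carbon") c(54, 60) else c(60, 63)
  list(oar_constraint("chiasm", lim[1]),
       oar_constraint("optic_ipsi", lim[1]),
       oar_constraint("optic_contra", lim[1]),
       oar_constraint("brainstem", lim[1], type = "near_max",
                      relaxed_limit = lim[2]))
}

## --------------------------------------------------------------------------
## Objective

## Penalty terms as (index vector into eval rows, target/limit, factor,
## one_sided flag); shared between objective_value() and the solver.
.build_terms <- function(structures, prescription, constraints, oar_weight,
                         eval_idx = NULL) {
  m <- structures$masks
  dp <- prescription$dose
  pick <- function(mask) {
    w <- which(mask)
    if (is.null(eval_idx)) w else match(w, eval_idx)
  }
  terms <- list(list(idx = pick(m$PTV), limit = dp, one_sided = FALSE,
                     factor = 1 / (sum(m$PTV) * dp^2)))
  for (con in constraints) {
    mask <- m[[con$structure]]
    if (is.null(mask) || !any(mask))
      stopf("constraint references missing structure '%s'", con$structure)
    if (con$type == "max") {
      terms <- c(terms, list(list(idx = pick(mask), limit = con$limit,
                                  one_sided = TRUE,
                                  factor = oar_weight / (sum(mask) * con$limit^2))))
    } else {
      near <- expand_margin(m$PTV, structures$spacing, con$abut_margin_mm,
                            con$abut_margin_mm, con$abut_margin_mm)
      strict <- mask & !near
      relaxed <- mask
      if (any(strict))
        terms <- c(terms, list(list(idx = pick(strict), limit = con$limit,
                                    one_sided = TRUE,
                                    factor = oar_weight / (sum(strict) * con$limit^2))))
      terms <- c(terms, list(list(idx = pick(relaxed),
                                  limit = con$relaxed_limit, one_sided = TRUE,
                                  factor = oar_weight / (sum(relaxed) * con$relaxed_limit^2))))
    }
  }
  terms
}

#' Planning objective value of a dose distribution
#'
#' Quadratic PTV under/overdose penalty (mean squared deviation from the
#' prescription over PTV voxels, normalized by the prescription squared) plus
#' one-sided quadratic OAR overdose penalties (normalized by each limit
#' squared and scaled by `oar_weight`), plus an optional ridge on the spot
#' weights. The objective is zero iff every PTV voxel is exactly at the
#' prescription and no OAR voxel exceeds its limit.
#'
#' @param dose_grid A `dose_grid` (RBE-weighted component used).
#' @param structures `structure_set` with a `PTV` mask.
#' @param prescription A `prescription` (or dose in Gy(RBE)).
#' @param constraints List of `oar_constraint`s.
#' @param weights Optional spot weights for the ridge term.
#' @param weights_penalty Ridge coefficient (default 0).
#' @param oar_weight Relative weight of the OAR terms (default 50).
#' @return Non-negative scalar.
#' @export
objective_value <- function(dose_grid, structures, prescription,
                            constraints = list(), weights = NULL,
                            weights_penalty = 0, oar_weight = 50) {
  if (!inherits(prescription, "prescription"))
    prescription <- prescription(dose = prescription)
  dose <- if (inherits(dose_grid, "dose_grid")) dose_grid$weighted else dose_grid
  terms <- .build_terms(structures, prescription, constraints, oar_weight)
  f <- 0
  for (tm in terms) {
    r <- dose[tm$idx] - tm$limit
    if (tm$one_sided) r <- pmax(r, 0)
    f <- f + tm$factor * sum(r^2)
  }
  if (weights_penalty > 0 && !is.null(weights))
    f <- f + weights_penalty * sum(weights^2)
  f
}

## --------------------------------------------------------------------------
## Influence matrix (RBE-weighted dose per unit spot weight, on eval voxels)

.influence_matrix <- function(cache, spots_b, eval_idx, grid) {
  fr <- cache$frame
  idx3 <- arrayInd(eval_idx, cache$dim)
  pts <- cbind(grid$origin[1] + (idx3[, 1] - 1) * grid$spacing[1],
               grid$origin[2] + (idx3[, 2] - 1) * grid$spacing[2],
               grid$origin[3] + (idx3[, 3] - 1) * grid$spacing[3])
  ue <- as.numeric(pts %*% fr$eu)
  ve <- as.numeric(pts %*% fr$ev)
  we <- cache$wepl[eval_idx]
  fe <- if (cache$beam$species == "proton") rep(1.1, length(eval_idx))
        else cache$rbe[eval_idx]
  A <- matrix(0, nrow = length(eval_idx), ncol = nrow(spots_b))
  for (l in unique(spots_b$layer)) {
    cols <- which(spots_b$layer == l)
    sig <- fwhm_to_sigma(spots_b$fwhm[cols][1])
    dd <- depth_dose(spots_b$range[cols][1], we, cache$beam$species,
                     sigma_z = cache$beam$sigma_z) * fe
    G <- exp(-(outer(ue, spots_b$u[cols], "-")^2 +
               outer(ve, spots_b$v[cols], "-")^2) / (2 * sig^2))
    A[, cols] <- dd * G
  }
  A
}

## --------------------------------------------------------------------------
## Spectral projected gradient on the non-negative orthant

.spg_solve <- function(A, terms, w0, maxit = 500, tol = 1e-6,
                       weights_penalty = 0, fmin = 1e-7) {
  n <- nrow(A)
  fg <- function(w) {
    r <- as.numeric(A %*% w)
    f <- 0
    z <- numeric(n)
    for (tm in terms) {
      e <- r[tm$idx] - tm$limit
      if (tm$one_sided) e <- pmax(e, 0)
      f <- f + tm$factor * sum(e^2)
      z[tm$idx] <- z[tm$idx] + 2 * tm$factor * e
    }
    g <- as.numeric(crossprod(A, z))
    if (weights_penalty > 0) {
      f <- f + weights_penalty * sum(w^2)
      g <- g + 2 * weights_penalty * w
    }
    list(f = f, g = g)
  }
  w <- pmax(w0, 0)
  st <- fg(w)
  fhist <- rep(st$f, 10)
  ## deterministic initial step from a curvature probe along the gradient
  dir0 <- pmax(w - st$g, 0) - w
  if (sqrt(sum(dir0^2)) < 1e-300) return(list(w = w, f = st$f, iters = 0L,
                                              converged = TRUE))
  alpha <- 1
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(maxit)) {
    iters <- it
    d <- pmax(w - alpha * st$g, 0) - w
    gd <- sum(st$g * d)
    if (sqrt(sum(d^2)) < 1e-14 * max(1, sqrt(sum(w^2)))) {
      converged <- TRUE
      break
    }
    lam <- 1
    fref <- max(fhist)
    repeat {
      wn <- w + lam * d
      stn <- fg(wn)
      if (stn$f <= fref + 1e-4 * lam * gd || lam < 1e-10) break
      lam <- lam / 2
    }
    s <- wn - w
    y <- stn$g - st$g
    sy <- sum(s * y)
    alpha <- if (sy > 1e-300) min(max(sum(s * s) / sy, 1e-10), 1e10) else 1
    fprev <- st$f
    w <- wn; st <- stn
    fhist <- c(fhist[-1], st$f)
    ## stop on a stalled objective or once the (normalized) objective is
    ## negligible — the planning goals are then met to well below a tenth
    ## of a percent RMS
    if (st$f <= fmin || abs(fprev - st$f) <= tol * max(fprev, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(w = w, f = st$f, iters = iters, converged = converged)
}

## --------------------------------------------------------------------------
## The fitting function

#' Optimize spot weights of a scanned ion-beam plan
#'
#' Places raster spots over the PTV for each beam (unless given), builds the
#' RBE-weighted dose-influence matrix on the PTV and constrained OAR voxels,
#' and minimizes the planning objective over non-negative spot weights with a
#' spectral projected-gradient method (weights are non-negative by
#' projection). Modes: `"uc"` ignores the OAR constraints, `"mc"` optimizes
#' all fields jointly, `"sc"` optimizes each field separately to a uniform
#' `1/n_fields` share of the prescription with proportionally scaled OAR
#' limits, then sums the fields.
#'
#' @param grid A `density_grid`.
#' @param structures A `structure_set` with `CTV` and `PTV`.
#' @param beams List of `beam_setup`s (same species).
#' @param prescription A `prescription`.
#' @param constraints List of `oar_constraint`s (ignored in `uc` mode).
#' @param mode Optimization mode: `"mc"`, `"sc"` or `"uc"`.
#' @param spots Optional pre-placed spot data.frame.
#' @param control List: `maxit` (500), `tol` (1e-6 relative objective
#'   change), `oar_weight` (50), `weights_penalty` (0).
#' @return An object of class `ion_plan`.
#' @export
optimize_plan <- function(grid, structures, beams, prescription,
                          constraints = list(), mode = c("mc", "sc", "uc"),
                          spots = NULL, control = list()) {
  mode <- match.arg(mode)
  if (inherits(beams, "beam_setup")) beams <- list(beams)
  if (!inherits(prescription, "prescription"))
    prescription <- prescription(dose = prescription)
  species <- unique(vapply(beams, `[[`, "", "species"))
  if (length(species) != 1) stopf("all beams must share one species")
  ctrl <- modifyList(list(maxit = 500, tol = 1e-6, fmin = 1e-7, oar_weight = 50,
                          weights_penalty = 0), control)
  cons <- if (mode == "uc") list() else constraints
  m <- structures$masks
  if (is.null(m$PTV) || !any(m$PTV)) stopf("structures must contain a PTV")

  ## per-beam WEPL, spot placement, caches
  caches <- vector("list", length(beams))
  if (is.null(spots)) {
    sp_list <- vector("list", length(beams))
    for (b in seq_along(beams)) {
      warr <- wepl_map(grid, beams[[b]],
                       step = max(0.5, min(grid$spacing) / 2))
      sp <- place_spots(m$PTV, grid, beams[[b]], wepl_arr = warr)
      sp$beam <- b
      sp_list[[b]] <- sp
      caches[[b]] <- beam_cache(grid, beams[[b]], sp, wepl_arr = warr)
    }
    spots <- do.call(rbind, sp_list)
  } else {
    for (b in seq_along(beams))
      caches[[b]] <- beam_cache(grid, beams[[b]],
                                spots[spots$beam == b, , drop = FALSE])
  }

  ## evaluation voxels: PTV plus all constrained structures
  eval_mask <- m$PTV
  for (con in cons) {
    if (is.null(m[[con$structure]]))
      stopf("constraint references missing structure '%s'", con$structure)
    eval_mask <- eval_mask | m[[con$structure]]
  }
  eval_idx <- which(eval_mask)

  A <- matrix(0, nrow = length(eval_idx), ncol = nrow(spots))
  for (b in seq_along(beams)) {
    cols <- which(spots$beam == b)
    if (!length(cols)) next
    A[, cols] <- .influence_matrix(caches[[b]],
                                   spots[cols, , drop = FALSE], eval_idx, grid)
  }

  nf <- length(beams)
  weights <- numeric(nrow(spots))
  info <- list()
  if (mode == "sc" && nf > 1) {
    for (b in seq_along(beams)) {
      cols <- which(spots$beam == b)
      presb <- prescription
      presb$dose <- prescription$dose / nf
      consb <- lapply(cons, function(con) {
        con$limit <- con$limit / nf
        if (!is.null(con$relaxed_limit)) con$relaxed_limit <- con$relaxed_limit / nf
        con
      })
      terms <- .build_terms(structures, presb, consb, ctrl$oar_weight, eval_idx)
      Ab <- A[, cols, drop = FALSE]
      w0 <- .uniform_start(Ab, terms[[1]]$idx, presb$dose)
      sol <- .spg_solve(Ab, terms, w0, ctrl$maxit, ctrl$tol, ctrl$weights_penalty, ctrl$fmin)
      weights[cols] <- sol$w
      info[[b]] <- sol[c("f", "iters", "converged")]
    }
    converged <- all(vapply(info, `[[`, TRUE, "converged"))
    iters <- max(vapply(info, `[[`, 0L, "iters"))
  } else {
    terms <- .build_terms(structures, prescription, cons, ctrl$oar_weight,
                          eval_idx)
    w0 <- .uniform_start(A, terms[[1]]$idx, prescription$dose)
    sol <- .spg_solve(A, terms, w0, ctrl$maxit, ctrl$tol, ctrl$weights_penalty, ctrl$fmin)
    weights <- sol$w
    converged <- sol$converged
    iters <- sol$iters
  }
  if (!converged)
    warning("optimizer did not converge within the iteration cap; ",
            "returning the best iterate", call. = FALSE)

  spots$weight <- weights
  dose <- compute_dose(grid, beams, spots, weights, caches = caches)
  indices <- compute_indices(dose, structures, prescription)
  obj <- objective_value(dose, structures, prescription, cons,
                         weights = weights,
                         weights_penalty = ctrl$weights_penalty,
                         oar_weight = ctrl$oar_weight)
  structure(list(grid = grid, structures = structures, beams = beams,
                 spots = spots, prescription = prescription,
                 constraints = cons, mode = mode, species = species,
                 dose = dose, indices = indices, objective = obj,
                 converged = converged, iterations = iters,
                 control = ctrl, caches = caches),
            class = "ion_plan")
}

.uniform_start <- function(A, ptv_rows, dp) {
  md <- mean(A[ptv_rows, , drop = FALSE] %*% rep(1, ncol(A)))
  rep(if (md > 0) dp / md else 1, ncol(A))
}

#' Dose modulation ratio of a plan
#'
#' Ratio between the maximum RBE-weighted dose over all constrained OAR
#' voxels and the prescription dose.
#'
#' @param plan An `ion_plan` with at least one OAR constraint, or a
#'   `dose_grid` (then `structures`, `constraints` and `prescription` must be
#'   given).
#' @param structures,constraints,prescription Used when `plan` is a
#'   `dose_grid`.
#' @return Dimensionless ratio.
#' @export
dose_modulation <- function(plan, structures = NULL, constraints = NULL,
                            prescription = NULL) {
  if (inherits(plan, "ion_plan")) {
    structures <- plan$structures
    constraints <- plan$constraints
    prescription <- plan$prescription
    dose <- plan$dose$weighted
  } else {
    dose <- if (inherits(plan, "dose_grid")) plan$weighted else plan
  }
  if (inherits(prescription, "prescription")) prescription <- prescription$dose
  if (length(constraints) == 0) stopf("no OAR constraints defined")
  mx <- 0
  for (con in constraints) {
    mask <- structures$masks[[con$structure]]
    if (is.null(mask) || !any(mask)) stopf("no OAR voxels for '%s'", con$structure)
    mx <- max(mx, max(dose[mask]))
  }
  mx / prescription
}
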