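## Robust beam-setup selection.
##
## The clinical practice this module operationalizes is choosing beam
## directions whose entrance channels avoid strong density interfaces. A
## candidate direction is scored by how much the WEPL to the target voxels
## changes under small transverse probe shifts: in laterally homogeneous
## media the score is exactly zero, and it grows with the lateral WEPL
## gradients that make a plan vulnerable to setup errors.

#' Candidate beam directions on a yaw/inclination grid
#'
#' Directions start from a mediolateral beam and are tilted by a cranial
#' couch yaw and an inclination about the longitudinal (SI) axis, on both
#' patient sides.
#'
#' @param yaw Vector of cranial yaw angles (degrees, >= 0).
#' @param inclination Vector of inclinations about the SI axis (degrees).
#' @param sides `+1` (beam entering from the low-LR side), `-1`, or both.
#' @param max_yaw,max_inclination Mechanical feasibility limits (degrees).
#' @return Data.frame with `yaw`, `inclination`, `side`, direction components
#'   `dx`, `dy`, `dz` and a `feasible` flag.
#' @export
candidate_directions <- function(yaw = seq(0, 60, by = 15),
                                 inclination = seq(-30, 30, by = 15),
                                 sides = c(1, -1),
                                 max_yaw = 60, max_inclination = 45) {
  g <- expand.grid(side = sides, inclination = inclination, yaw = yaw)
  th <- g$yaw * pi / 180; ph <- g$inclination * pi / 180
  ## base beam along +/- LR, yawed toward cranial (entering from superior),
  ## then inclined about the SI axis
  dx <- g$side * cos(th) * cos(ph)
  dy <- cos(th) * sin(ph)
  dz <- -sin(th)
  data.frame(yaw = g$yaw, inclination = g$inclination, side = g$side,
             dx = dx, dy = dy, dz = dz,
             feasible = g$yaw <= max_yaw & abs(g$inclination) <= max_inclination)
}

#' Entrance-channel heterogeneity score of a beam direction
#'
#' Mean over target voxels of the spread (max - min, or standard deviation)
#' of the WEPL to the voxel across small transverse probe shifts. Zero for
#' laterally homogeneous media; large when the entrance channel crosses
#' density interfaces that turn setup shifts into range errors.
#'
#' @param grid A `density_grid`.
#' @param target_mask Logical array (typically the CTV or PTV).
#' @param direction Length-3 beam direction.
#' @param probe_shifts Matrix of probe shifts (rows, mm, patient frame);
#'   default: the transverse projections of the 1 mm members of the
#'   enumerated shift set, deduplicated.
#' @param spread Per-voxel spread statistic: `"range"` (max - min, default)
#'   or `"sd"`.
#' @param aggregate How per-voxel spreads are pooled over the target:
#'   `"mean"` (default) or `"max"` (worst voxel).
#' @param max_target_voxels Deterministic decimation cap on target voxels.
#' @param step Ray-tracing step (mm).
#' @return Non-negative scalar (mm).
#' @export
heterogeneity_score <- function(grid, target_mask, direction,
                                probe_shifts = NULL,
                                spread = c("range", "sd"),
                                aggregate = c("mean", "max"),
                                max_target_voxels = 300, step = 1) {
  spread <- match.arg(spread)
  aggregate <- match.arg(aggregate)
  direction <- unitize(as.numeric(direction))
  if (!any(target_mask)) stopf("empty target")
  if (is.null(probe_shifts)) {
    s <- enumerate_shifts(1)
    probe_shifts <- as.matrix(s[, c("x", "y", "z")])
  }
  ## transverse projections, deduplicated, nonzero
  pr <- probe_shifts - (probe_shifts %*% direction) %*% t(direction)
  pr <- pr[sqrt(rowSums(pr^2)) > 1e-9, , drop = FALSE]
  pr <- unique(round(pr, 6))
  if (nrow(pr) < 2) stopf("need at least two distinct transverse probes")
  pts <- mask_points(grid, target_mask)
  if (nrow(pts) > max_target_voxels) {
    idx <- round(seq(1, nrow(pts), length.out = max_target_voxels))
    pts <- pts[idx, , drop = FALSE]
  }
  n <- nrow(pts); np <- nrow(pr)
  all_pts <- pts[rep(seq_len(n), times = np), , drop = FALSE] +
    pr[rep(seq_len(np), each = n), , drop = FALSE]
  ## target voxels interior to the grid: probe points may poke outside by a
  ## millimetre near the boundary, which the batched tracer treats as air
  w <- .wepl_points(grid, direction, all_pts, step = step)
  wm <- matrix(w, nrow = n, ncol = np)
  sp <- if (spread == "range") {
    apply(wm, 1, max) - apply(wm, 1, min)
  } else {
    apply(wm, 1, stats::sd)
  }
  if (aggregate == "mean") mean(sp) else max(sp)
}

#' Select a robust beam setup by heterogeneity ranking
#'
#' Scores every feasible candidate direction and returns the `n_beams`
#' combination with the lowest total score subject to a minimum pairwise
#' angular separation; ties are broken by candidate enumeration order.
#'
#' @param grid A `density_grid`.
#' @param target Logical target mask.
#' @param candidates Data.frame from [candidate_directions()].
#' @param n_beams Number of beams (2 typical; exhaustive search for
#'   `n_beams <= 2`, greedy beyond).
#' @param min_separation_deg Minimum pairwise angle (degrees).
#' @param scores Optional precomputed score vector (one per candidate row).
#' @param ... Passed to [heterogeneity_score()].
#' @return The selected candidate rows with a `score` column, ordered by
#'   enumeration order.
#' @export
select_robust_setup <- function(grid, target, candidates, n_beams = 2,
                                min_separation_deg = 30, scores = NULL, ...) {
  feas <- which(candidates$feasible)
  if (length(feas) < n_beams) stopf("fewer than %d feasible candidates", n_beams)
  dirs <- as.matrix(candidates[, c("dx", "dy", "dz")])
  if (is.null(scores)) {
    scores <- rep(NA_real_, nrow(candidates))
    for (i in feas)
      scores[i] <- heterogeneity_score(grid, target, dirs[i, ], ...)
  }
  sep_ok <- function(set) {
    if (length(set) < 2) return(TRUE)
    pairs <- utils::combn(set, 2)
    all(apply(pairs, 2, function(p) angle_deg(dirs[p[1], ], dirs[p[2], ]) >=
                min_separation_deg - 1e-9))
  }
  if (n_beams <= 2) {
    combos <- if (n_beams == 1) matrix(feas, nrow = 1)
              else utils::combn(feas, 2)
    best <- NULL; best_s <- Inf
    for (j in seq_len(ncol(combos))) {
      set <- combos[, j]
      if (!sep_ok(set)) next
      s <- sum(scores[set])
      if (s < best_s - 1e-12) { best <- set; best_s <- s }
    }
    if (is.null(best)) stopf("no candidate combination satisfies the separation")
  } else {
    ord <- feas[order(scores[feas])]
    best <- ord[1]
    for (i in ord[-1]) {
      if (length(best) == n_beams) break
      if (sep_ok(c(best, i))) best <- c(best, i)
    }
    if (length(best) < n_beams) stopf("no candidate combination satisfies the separation")
    best <- sort(best)
  }
  out <- candidates[best, , drop = FALSE]
  out$score <- scores[best]
  out
}

#' Beam setups from selected candidate directions
#'
#' @param candidates Rows of [candidate_directions()] output (e.g. from
#'   [select_robust_setup()]).
#' @param species Ion species.
#' @param ... Passed to [beam_setup()].
#' @return List of `beam_setup` objects.
#' @export
beams_from_candidates <- function(candidates, species, ...) {
  lapply(seq_len(nrow(candidates)), function(i)
    beam_setup(c(candidates$dx[i], candidates$dy[i], candidates$dz[i]),
               species,
               name = sprintf("%s_yaw%g_incl%g_s%d", species,
                              candidates$yaw[i], candidates$inclination[i],
                              candidates$side[i]), ...))
}
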