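## S3 methods for fitted plans.

#' @export
print.ion_plan <- function(x, ...) {
  cat(sprintf("<ion_plan> %s, mode %s, %d beam(s), %d spots\n",
              x$species, x$mode, length(x$beams), nrow(x$spots)))
  cat(sprintf("  prescription %g Gy(RBE) x %d fractions; objective %.3g (%s, %d iter)\n",
              x$prescription$dose, x$prescription$fractions, x$objective,
              if (x$converged) "converged" else "not converged", x$iterations))
  cat(sprintf("  PTV V95 %.1f%%  CTV V95 %.1f%%  PTV HI %.1f pp  CI %.2f\n",
              x$indices$ptv_v95, x$indices$ctv_v95, x$indices$ptv_hi,
              x$indices$ci))
  invisible(x)
}

#' @export
summary.ion_plan <- function(object, ...) {
  out <- list(indices = object$indices, mode = object$mode,
              species = object$species, objective = object$objective,
              converged = object$converged,
              weights = summary(object$spots$weight),
              constraints = lapply(object$constraints, function(con) {
                mask <- object$structures$masks[[con$structure]]
                dn <- dmax_and_near_max(object$dose, mask)
                data.frame(structure = con$structure, type = con$type,
                           limit = con$limit, dmax = dn[["dmax"]],
                           d_near_max = dn[["d_near_max"]])
              }))
  class(out) <- "summary.ion_plan"
  out
}

#' @export
print.summary.ion_plan <- function(x, ...) {
  cat(sprintf("Ion plan (%s, mode %s): objective %.3g, %s\n", x$species,
              x$mode, x$objective,
              if (x$converged) "converged" else "not converged"))
  cat("Indices:\n")
  print(round(x$indices, 2), row.names = FALSE)
  if (length(x$constraints)) {
    cat("Constraints:\n")
    print(do.call(rbind, x$constraints), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ion_plan <- function(object, ...) object$spots$weight

#' Recompute the dose of a fitted plan, optionally under a setup shift
#'
#' Reapplies the frozen, optimized spot weights with all irradiation fields
#' rigidly translated by `shift` relative to the density grid (the anatomy
#' and the structure masks stay fixed). A zero shift reproduces the planned
#' dose bit-exactly; in the parallel-beam model a shift along a beam's axis
#' does not perturb that beam's dose.
#'
#' @param object An `ion_plan`.
#' @param shift Length-3 shift in mm, patient frame (LR, AP, SI).
#' @param type `"dose"` returns the `dose_grid`; `"indices"` the index set of
#'   the shifted dose.
#' @param ... Unused.
#' @export
predict.ion_plan <- function(object, shift = c(0, 0, 0),
                             type = c("dose", "indices"), ...) {
  type <- match.arg(type)
  dose <- compute_dose(object$grid, object$beams, object$spots,
                       object$spots$weight, shift = shift,
                       caches = object$caches)
  if (type == "dose") dose
  else compute_indices(dose, object$structures, object$prescription)
}

#' @export
residuals.ion_plan <- function(object, ...) {
  object$dose$weighted[object$structures$masks$PTV] - object$prescription$dose
}

#' Plot DVH curves of a fitted plan
#'
#' @param x An `ion_plan`.
#' @param structures Structure names to draw (default CTV, PTV and all
#'   constrained OARs).
#' @param ... Passed to the first `plot()` call.
#' @export
plot.ion_plan <- function(x, structures = NULL, ...) {
  nms <- structures %||%
    unique(c("CTV", "PTV", vapply(x$constraints, `[[`, "", "structure")))
  nms <- intersect(nms, names(x$structures$masks))
  cols <- seq_along(nms)
  first <- TRUE
  for (i in seq_along(nms)) {
    dvh <- cumulative_dvh(x$dose, x$structures$masks[[nms[i]]],
                          x$prescription$dose, structure = nms[i])
    plot(dvh, add = !first, col = cols[i], ...)
    first <- FALSE
  }
  abline(v = 0.95 * x$prescription$dose, lty = 3)
  legend("bottomleft", legend = nms, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Serialize a fitted plan to disk
#'
#' Writes `plan.json` (species, mode, prescription, beams and constraints),
#' `spots.csv` (layer, lateral raster coordinates, range, FWHM, optimized
#' weight per beam) and the planned RBE-weighted dose as NIfTI.
#'
#' @param plan An `ion_plan`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_plan <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plan = file.path(dir, "plan.json"),
             spots = file.path(dir, "spots.csv"),
             dose = file.path(dir, "dose.nii.gz"))
  meta <- list(
    species = plan$species, mode = plan$mode,
    prescription = unclass(plan$prescription),
    objective = plan$objective, converged = plan$converged,
    beams = lapply(plan$beams, function(b)
      list(name = b$name, direction = b$direction, pitch = b$pitch,
           depth_step = b$depth_step, tolerance = b$tolerance,
           bolus_mm = b$bolus_mm, fwhm = b$fwhm)),
    constraints = lapply(plan$constraints, unclass))
  jsonlite::write_json(meta, paths[["plan"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(plan$spots[, c("beam", "layer", "u", "v", "range",
                                  "fwhm", "weight")],
                   paths[["spots"]], row.names = FALSE)
  write_grid_nifti(density_grid(plan$dose$weighted, plan$dose$spacing,
                                plan$dose$origin),
                   paths[["dose"]])
  invisible(paths)
}

#' Simulate setup errors for a fitted plan
#'
#' Draws `nsim` shifts uniformly from the enumerated shift set at the given
#' magnitudes, recomputes the plan under each and returns the per-shift
#' index changes.
#'
#' @param object An `ion_plan`.
#' @param nsim Number of simulated setup errors.
#' @param seed Optional seed.
#' @param magnitudes Shift magnitudes in mm.
#' @param ... Unused.
#' @return A data.frame of `DeltaRecord`s (see [delta_indices()]).
#' @export
simulate.ion_plan <- function(object, nsim = 1, seed = NULL,
                              magnitudes = c(1, 2), ...) {
  shifts <- enumerate_shifts(magnitudes)
  pick <- if (is.null(seed)) sample.int(nrow(shifts), nsim, replace = TRUE)
          else with_seed(seed, sample.int(nrow(shifts), nsim, replace = TRUE))
  shift_battery(object, shifts[pick, , drop = FALSE])
}
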