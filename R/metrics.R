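## DVH construction and dosimetric indices.
##
## All indices are functions of the multiset of voxel doses within a mask.
## Percentile-type doses (D2%, D98%, D1%) use linear interpolation of the
## empirical quantile function, which is stable across DVH bin widths.

#' Cumulative dose-volume histogram
#'
#' `V(d) = 100 * |{v in mask : dose(v) >= d}| / |mask|`. The exported curve is
#' tabulated on a regular dose axis (default bin width 0.1% of the
#' prescription, when given); the raw voxel doses are retained so that
#' `v_at()`/`d_at()` are exact.
#'
#' @param dose_grid A `dose_grid` (the RBE-weighted component is used) or a
#'   numeric array.
#' @param mask Non-empty logical array.
#' @param prescription Prescription dose (Gy(RBE)); sets the default bin width
#'   and the reference for V95%.
#' @param bin_width Dose bin width; default `0.001 * prescription` (or of the
#'   maximum dose if no prescription is given).
#' @param structure Optional structure name carried along.
#' @return An object of class `dvh_curve` with fields `dose`, `volume` (%),
#'   `structure`.
#' @export
cumulative_dvh <- function(dose_grid, mask, prescription = NULL,
                           bin_width = NULL, structure = NULL) {
  dose <- if (inherits(dose_grid, "dose_grid")) dose_grid$weighted else dose_grid
  if (!any(mask)) stopf("empty mask")
  dv <- sort(as.numeric(dose[mask]))
  ref <- prescription %||% max(dv)
  bw <- bin_width %||% max(0.001 * ref, 1e-9)
  axis <- seq(0, max(dv) + bw, by = bw)
  n <- length(dv)
  ## |{dose >= d}| via the sorted vector
  vol <- 100 * (n - findInterval(axis - 1e-12, dv)) / n
  structure(list(dose = axis, volume = vol, doses = dv,
                 prescription = prescription, structure = structure),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve>%s %d voxels, dose range [%.2f, %.2f]\n",
              if (is.null(x$structure)) "" else paste0(" ", x$structure),
              length(x$doses), min(x$doses), max(x$doses)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, add = FALSE, xlab = "Dose [Gy(RBE)]",
                           ylab = "Volume [%]", type = "l", ...) {
  if (add) lines(x$dose, x$volume, ...)
  else plot(x$dose, x$volume, type = type, xlab = xlab, ylab = ylab,
            ylim = c(0, 100), ...)
  invisible(x)
}

#' Volume at dose / dose at volume
#'
#' `v_at(dvh, d)` is the exact percent volume receiving at least `d`.
#' `d_at(dvh, q)` is the dose exceeded by `q`% of the volume, by linear
#' interpolation of the empirical quantile function (so D2% of `n` voxels
#' interpolates between the two hottest-tail order statistics).
#'
#' @param dvh A `dvh_curve`.
#' @param dose_level Dose level(s) (same units as the curve), >= 0.
#' @param volume_percent Volume level(s) in (0, 100].
#' @return Percent volume / dose.
#' @export
v_at <- function(dvh, dose_level) {
  check_numeric(dose_level, "dose_level", nonneg = TRUE)
  n <- length(dvh$doses)
  100 * (n - findInterval(dose_level - 1e-12, dvh$doses)) / n
}

#' @rdname v_at
#' @export
d_at <- function(dvh, volume_percent) {
  check_numeric(volume_percent, "volume_percent")
  if (any(volume_percent <= 0 | volume_percent > 100))
    stopf("volume_percent must be in (0, 100]")
  as.numeric(quantile(dvh$doses, probs = 1 - volume_percent / 100,
                      type = 7, names = FALSE))
}

#' Homogeneity index
#'
#' `HI = D2% - D98%`, reported in percentage points of the prescription dose
#' when one is known (otherwise in dose units).
#'
#' @param dvh A `dvh_curve`.
#' @param prescription Prescription dose; defaults to the one stored in the
#'   curve. If `NULL`, the raw dose difference is returned.
#' @return HI (pp of prescription, or Gy(RBE)).
#' @export
homogeneity_index <- function(dvh, prescription = dvh$prescription) {
  hi <- d_at(dvh, 2) - d_at(dvh, 98)
  if (is.null(prescription)) hi else 100 * hi / prescription
}

#' Conformity of the prescription isodose to the PTV
#'
#' Van't Riet conformation number
#' `CN = (TV_PIV / TV) * (TV_PIV / PIV)`, where `TV` is the PTV volume, `PIV`
#' the volume enclosed by the isodose at `level`, and `TV_PIV` their
#' intersection; 1 means perfect conformity, 0 no overlap (or an empty PIV).
#'
#' @param dose_grid `dose_grid` or array.
#' @param ptv_mask Logical array.
#' @param level Isodose level in dose units (typically 95% of prescription).
#' @return CN in `[0, 1]`.
#' @export
conformity_index <- function(dose_grid, ptv_mask, level) {
  dose <- if (inherits(dose_grid, "dose_grid")) dose_grid$weighted else dose_grid
  if (!any(ptv_mask)) stopf("empty PTV mask")
  check_numeric(level, "level", 1, positive = TRUE)
  piv <- dose >= level
  npiv <- sum(piv)
  if (npiv == 0) return(0)
  ntv <- sum(ptv_mask)
  ninter <- sum(piv & ptv_mask)
  (ninter / ntv) * (ninter / npiv)
}

#' Maximum and near-maximum dose of a structure
#'
#' `Dmax` is the hottest voxel; `D_near_max` is the dose exceeded by the
#' hottest 1% of the structure's volume (`d_at(1)`).
#'
#' @param dose_grid `dose_grid` or array.
#' @param mask Non-empty logical array.
#' @return Named vector `c(dmax = ..., d_near_max = ...)`.
#' @export
dmax_and_near_max <- function(dose_grid, mask) {
  dose <- if (inherits(dose_grid, "dose_grid")) dose_grid$weighted else dose_grid
  if (!any(mask)) stopf("empty mask")
  dvh <- cumulative_dvh(dose, mask)
  c(dmax = max(dvh$doses), d_near_max = d_at(dvh, 1))
}

## Structures whose Dmax is constrained/reported
OPTIC_STRUCTURES <- c("chiasm", "optic_ipsi", "optic_contra")

#' All dosimetric indices of a plan dose distribution
#'
#' Computes the index set used for plan evaluation: PTV and CTV V95% (% of
#' volume receiving >= 95% of prescription), PTV and CTV HI (pp of
#' prescription), the PTV conformity number at the 95% isodose, Dmax of each
#' optic structure present and the brainstem near-maximum dose at 1% volume.
#'
#' @param dose_grid A `dose_grid`.
#' @param structures A `structure_set` containing at least `CTV` and `PTV`.
#' @param prescription Prescription dose in Gy(RBE) (or a `prescription`
#'   object).
#' @return One-row data.frame.
#' @export
compute_indices <- function(dose_grid, structures, prescription) {
  if (inherits(prescription, "prescription")) prescription <- prescription$dose
  check_numeric(prescription, "prescription", 1, positive = TRUE)
  m <- structures$masks
  if (is.null(m$PTV) || is.null(m$CTV)) stopf("structures must contain CTV and PTV")
  lev <- 0.95 * prescription
  dvh_ptv <- cumulative_dvh(dose_grid, m$PTV, prescription)
  dvh_ctv <- cumulative_dvh(dose_grid, m$CTV, prescription)
  out <- data.frame(
    ptv_v95 = v_at(dvh_ptv, lev),
    ctv_v95 = v_at(dvh_ctv, lev),
    ptv_hi = homogeneity_index(dvh_ptv, prescription),
    ctv_hi = homogeneity_index(dvh_ctv, prescription),
    ci = conformity_index(dose_grid, m$PTV, lev))
  for (nm in intersect(OPTIC_STRUCTURES, names(m)))
    if (any(m[[nm]]))
      out[[paste0("dmax_", nm)]] <- dmax_and_near_max(dose_grid, m[[nm]])[["dmax"]]
  if (!is.null(m$brainstem) && any(m$brainstem))
    out$dnearmax_brainstem <-
      dmax_and_near_max(dose_grid, m$brainstem)[["d_near_max"]]
  if (!is.null(m$oar) && any(m$oar))
    out$dmax_oar <- dmax_and_near_max(dose_grid, m$oar)[["dmax"]]
  out
}
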