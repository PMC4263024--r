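## Setup-error robustness: enumerated rigid-shift sets, dose recomputation at
## frozen spot weights, per-shift index deltas and population statistics.

#' Enumerate the complete rigid-shift set
#'
#' All vectors `(x, y, z)` whose components are each `0` or `+/-c` for a
#' single `c > 0`, with 3-D magnitude in `magnitudes` — for each magnitude
#' `m`: 6 one-axis shifts (`c = m`), 12 two-axis shifts (`c = m/sqrt(2)`)
#' and 8 three-axis shifts (`c = m/sqrt(3)`), 26 in total; the null vector is
#' excluded. Magnitudes `{1, 2}` give the canonical 52-shift battery.
#'
#' @param magnitudes Finite set of positive shift magnitudes (mm).
#' @return Data.frame with columns `x`, `y`, `z` (mm, patient frame
#'   LR/AP/SI), `magnitude` and a sign-pattern `label` such as `"2(0,+,-)"`.
#' @export
enumerate_shifts <- function(magnitudes) {
  if (length(magnitudes) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      magnitude = numeric(0), label = character(0)))
  check_numeric(magnitudes, "magnitudes", positive = TRUE)
  magnitudes <- sort(unique(magnitudes))
  signs <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  signs <- signs[rowSums(signs != 0) > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(magnitudes, function(m) {
    k <- rowSums(signs != 0)
    c_ <- m / sqrt(k)
    data.frame(x = signs[, 1] * c_, y = signs[, 2] * c_, z = signs[, 3] * c_,
               magnitude = m,
               label = sprintf("%g(%s,%s,%s)", m,
                               c("-", "0", "+")[signs[, 1] + 2],
                               c("-", "0", "+")[signs[, 2] + 2],
                               c("-", "0", "+")[signs[, 3] + 2]))
  }))
  rownames(out) <- NULL
  out
}

#' Recompute a plan's dose under a rigid setup shift
#'
#' Translates all irradiation fields by `shift` relative to the CT data and
#' re-superposes the dose with the plan's frozen spot weights; structure
#' masks stay fixed, so indices are evaluated against the unshifted anatomy.
#'
#' @param plan An `ion_plan`.
#' @param shift Length-3 numeric (mm) or one row of [enumerate_shifts()].
#' @return A `dose_grid`.
#' @export
recompute_with_shift <- function(plan, shift) {
  if (is.data.frame(shift)) shift <- c(shift$x[1], shift$y[1], shift$z[1])
  predict(plan, shift = shift)
}

#' Change in dosimetric indices between a shifted and the initial plan
#'
#' Componentwise `shifted - initial`, so that a coverage loss appears as a
#' negative delta (e.g. V95 99.8 -> 96.3 gives -3.5 pp).
#'
#' @param initial,shifted One-row index data.frames from [compute_indices()]
#'   with identical columns.
#' @return One-row data.frame of deltas, columns prefixed `d_`.
#' @export
delta_indices <- function(initial, shifted) {
  if (!identical(sort(names(initial)), sort(names(shifted))))
    stopf("index sets do not share the same structures")
  d <- shifted[names(initial)] - initial
  names(d) <- paste0("d_", names(initial))
  d
}

#' Run a plan against a battery of shifts
#'
#' @param plan An `ion_plan`.
#' @param shifts Data.frame from [enumerate_shifts()] (or with columns
#'   `x`, `y`, `z`).
#' @return Tidy data.frame: one row per shift with the shift columns and the
#'   signed index deltas.
#' @export
shift_battery <- function(plan, shifts) {
  init <- plan$indices
  rows <- lapply(seq_len(nrow(shifts)), function(i) {
    dose <- predict(plan, shift = c(shifts$x[i], shifts$y[i], shifts$z[i]))
    delta_indices(init, compute_indices(dose, plan$structures,
                                        plan$prescription))
  })
  cbind(shifts, do.call(rbind, rows))
}

#' Aggregate per-shift index changes over a population
#'
#' For every delta column: median, 1st/3rd quartiles, minimum and maximum,
#' plus the fraction of records with `|delta|` below the applicable
#' threshold (1 pp for V95 and HI deltas, 2 Gy(RBE) for dose deltas, by
#' default).
#'
#' @param records Data.frame with `d_*` delta columns (rows = case x shift).
#' @param thresholds Named vector: `v95`, `hi` (pp) and `dose` (Gy(RBE)).
#' @return An object of class `robustness_summary`: data.frame with one row
#'   per index.
#' @export
aggregate_population <- function(records, thresholds = c(v95 = 1, hi = 1,
                                                         dose = 2)) {
  if (nrow(records) == 0) stopf("no records to aggregate")
  dcols <- grep("^d_", names(records), value = TRUE)
  if (!length(dcols)) stopf("no delta columns found")
  out <- do.call(rbind, lapply(dcols, function(cl) {
    v <- records[[cl]]
    thr <- if (grepl("v95", cl)) thresholds[["v95"]]
           else if (grepl("(^|_)hi$", cl)) thresholds[["hi"]]
           else thresholds[["dose"]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(index = cl, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v), threshold = thr,
               frac_within = mean(abs(v) < thr))
  }))
  rownames(out) <- NULL
  class(out) <- c("robustness_summary", "data.frame")
  out
}

#' Exact paired-sample sign test
#'
#' Two-sided exact binomial test on the signs of the paired differences
#' `a - b`; ties (zero differences) are dropped before testing.
#'
#' @param paired_deltas_a,paired_deltas_b Equal-length numeric vectors,
#'   matched pairwise (by case and shift). If `paired_deltas_b` is omitted,
#'   `paired_deltas_a` is taken as the differences.
#' @return List with `p_value`, `n` (pairs after tie removal), `n_positive`
#'   and `significant` (at 0.05).
#' @export
sign_test <- function(paired_deltas_a, paired_deltas_b = NULL) {
  d <- if (is.null(paired_deltas_b)) paired_deltas_a
       else {
         if (length(paired_deltas_a) != length(paired_deltas_b))
           stopf("paired samples must have equal length")
         paired_deltas_a - paired_deltas_b
       }
  d <- d[d != 0]
  if (length(d) == 0)
    stopf("sign test undefined: all pairs are tied (zero differences)")
  k <- sum(d > 0)
  p <- binom.test(k, length(d), p = 0.5)$p.value
  list(p_value = p, n = length(d), n_positive = k, significant = p < 0.05)
}
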