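#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median binom.test rnorm runif pnorm setNames
#' @importFrom utils write.csv read.csv modifyList head tail
#' @importFrom graphics lines legend abline
NULL

## Relative water-equivalent density assigned to air. Kept strictly positive so
## that ray tracing through air-overridden regions stays well defined.
AIR_DENSITY <- 0.001

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so that seeded generators are pure functions of their
#' arguments and do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric <- function(x, name, len = NULL, positive = FALSE,
                          nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stopf("'%s' must be numeric without NAs", name)
  if (!is.null(len) && length(x) != len)
    stopf("'%s' must have length %d", name, len)
  if (positive && any(x <= 0)) stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0)) stopf("'%s' must be >= 0", name)
  invisible(x)
}

## Unit vector helpers -------------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stopf("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle between two unit vectors, degrees.
angle_deg <- function(a, b) {
  d <- sum(a * b)
  acos(min(1, max(-1, d))) * 180 / pi
}
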