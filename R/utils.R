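#' @importFrom methods new is validObject show
#' @importFrom stats rnorm rlnorm ks.test sd setNames
NULL

.TERRITORIES <- c("ACA", "supMCA", "infMCA", "PCA", "PICA")

#' Names of the five brain-artery territories
#'
#' The classification targets: anterior cerebral artery (ACA), superior and
#' inferior divisions of the middle cerebral artery (supMCA, infMCA),
#' posterior cerebral artery (PCA) and posterior inferior cerebellar artery
#' (PICA), in canonical order.
#'
#' @return Character vector of length five.
#' @export
territoryNames <- function() .TERRITORIES

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# population (divisor n) standard deviation
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length axis vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return 2|a&b| / (|a|+|b|); \code{NaN} when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
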