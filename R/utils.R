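#' @keywords internal
"_PACKAGE"

## depths are stored in mm everywhere; physics happens in m
MM_PER_M <- 1000
SECONDS_PER_DAY <- 86400

mm_to_m <- function(z_mm) z_mm / MM_PER_M

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores the global RNG state so generators are deterministic
#' for a given seed without disturbing the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Trapezoidal integral
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Overlap length of interval [a1, a2] with [b1, b2]
#' @noRd
overlap_len <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Format a ratio as the conventional "n-fold" string
#'
#' @param x a positive ratio, e.g. from [fold_change()]
#' @return character, the ratio rounded to the nearest integer with a
#'   "-fold" suffix (e.g. `"9-fold"`).
#' @export
#' @examples
#' fold_format(17.7) # "18-fold"
fold_format <- function(x) {
  sprintf("%d-fold", as.integer(round(x)))
}
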