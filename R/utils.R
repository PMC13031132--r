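# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generator calls are
#' deterministic without touching the caller's RNG state.
#' @noRd
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Condition helpers: validation errors carry class "zn_validation_error" so the
# command-line wrapper can map them to exit code 2 (vs 3 for numerical failures).
zn_stop <- function(msg, class = "zn_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "zn_error")))
}

#' Signed area of a polygon (shoelace formula)
#'
#' @param v numeric matrix with columns x, y; vertices in order, not closed.
#' @return signed area in squared pixels (positive for counter-clockwise in a
#'   y-down coordinate frame the sign flips; callers use `abs()`).
#' @noRd
polygon_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(v) abs(polygon_signed_area(v))

#' Polygon centroid by first moments
#' @noRd
polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) zn_stop("degenerate polygon: zero area")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
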