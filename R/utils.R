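# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a vector to unit length
#' @param v numeric vector
#' @param tol vectors with norm <= tol are considered degenerate
#' @return unit vector, or NULL if degenerate
#' @keywords internal
unit_vector <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n <= tol) return(NULL)
  v / n
}

#' Draw a uniformly distributed random unit vector on the sphere
#'
#' Uses the current R RNG stream (Marsaglia's normal-deviate method).
#' @return length-3 unit vector
#' @keywords internal
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
}
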