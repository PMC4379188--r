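# Shape and trajectory metrics: Cell Morphological Index (membrane area
# ratio), elongation, Random Index (mean cosine alignment), steady-state
# window detection and the equilibrium-plane (IEP) estimate.

#' Cell Morphological Index
#'
#' Current membrane area relative to the initial (spherical) membrane
#' area; 1 at the start, grows as the cell spreads or elongates.
#'
#' @param S current membrane area (um^2)
#' @param S_in initial membrane area (um^2)
#' @return dimensionless index
#' @export
cmi <- function(S, S_in) {
  if (any(S_in <= 0)) stop("S_in must be > 0")
  S / S_in
}

#' Cell elongation
#'
#' One minus the geometric mean of the two shorter principal dimensions
#' over the longest: 0 for a sphere, approaching 1 for a filament.
#'
#' @param l_max,l_med,l_min principal dimensions,
#'   \code{l_max >= l_med >= l_min > 0}
#' @return value in [0, 1)
#' @export
#' @examples
#' elongation(40, 10, 10)  # 0.75
elongation <- function(l_max, l_med, l_min) {
  if (any(l_max <= 0)) stop("l_max must be > 0")
  if (any(l_min <= 0)) stop("l_min must be > 0")
  if (any(l_max < l_med) || any(l_med < l_min))
    stop("need l_max >= l_med >= l_min")
  1 - sqrt(l_min * l_med) / l_max
}

#' Random Index of a trajectory
#'
#' Mean cosine of the angle between the cell polarization and the cue
#' axis over the steady-state window; +1 means perfect alignment.
#'
#' @param thetas angles (rad) between polarization and cue axis
#' @return value in [-1, 1]
#' @export
random_index <- function(thetas) {
  if (length(thetas) == 0L) stop("empty steady-state window")
  mean(cos(thetas))
}

#' Steady-state window of a centroid coordinate series
#'
#' The window starts at the first step from which the coordinate stays
#' within \code{frac} of the substrate length of its final value for at
#' least \code{k} consecutive steps, and extends to the end of the run.
#'
#' @param x centroid coordinate series (um)
#' @param L substrate length (um)
#' @param frac tolerance as a fraction of \code{L}
#' @param k required number of consecutive in-band steps
#' @return integer indices of the window, or NULL if no steady state
#' @export
steady_window <- function(x, L, frac = 0.05, k = 20L) {
  n <- length(x)
  if (n < k) return(NULL)
  inband <- abs(x - x[n]) <= frac * L
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (inband[i]) run + 1L else 0L
    if (run == k) {
      start <- i - k + 1L
      if (all(inband[start:n])) return(start:n)
      run <- 0L
    }
  }
  NULL
}

#' Equilibrium-plane (IEP) estimate over repeated runs
#'
#' Per run, the tail mean of the centroid x-coordinate over its
#' steady-state window; across runs, mean and standard deviation. Runs
#' that never reach steady state are excluded with a warning.
#'
#' @param x_series list of centroid x series (one per run)
#' @param L substrate length (um)
#' @param frac,k steady-state criteria, see \code{\link{steady_window}}
#' @return list: \code{mean}, \code{sd} (um; \code{sd} is 0 for a single
#'   run), per-run tail means \code{per_run}, and the number of excluded
#'   runs
#' @export
iep_estimate <- function(x_series, L, frac = 0.05, k = 20L) {
  if (!is.list(x_series)) x_series <- list(x_series)
  tails <- vapply(x_series, function(x) {
    w <- steady_window(x, L, frac = frac, k = k)
    if (is.null(w)) NA_real_ else mean(x[w])
  }, numeric(1))
  bad <- sum(is.na(tails))
  if (bad > 0)
    warning(bad, " run(s) never reached steady state and were excluded")
  ok <- tails[!is.na(tails)]
  if (length(ok) == 0L) stop("no run reached steady state")
  list(mean = mean(ok), sd = if (length(ok) > 1) stats::sd(ok) else 0,
       per_run = tails, excluded = bad)
}
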