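#' Description of the extracellular stimuli
#'
#' Collects the guidance fields imposed on the substrate: a linear-in-x
#' stiffness profile (always present; it drives mechanotaxis), optional
#' linear temperature and chemoattractant profiles, and an optional uniform
#' direct-current electric field (dcEF). Gradient fields are stored by
#' their end values at \code{x = 0} and \code{x = Lx}; the abstraction also
#' accepts an arbitrary vectorized function of x for the stiffness.
#'
#' @param Lx substrate length along the gradient axis (um)
#' @param stiffness either \code{c(at_x0, at_xL)} in kPa or a vectorized
#'   function of x returning kPa (must be strictly positive)
#' @param temperature optional \code{c(at_x0, at_xL)} in degrees C
#' @param chemo optional \code{c(at_x0, at_xL)} chemoattractant
#'   concentration in M
#' @param ef_strength optional dcEF strength in mV/mm (numerically equal to
#'   V/m); \code{NULL} or 0 disables the electric force
#' @param ef_direction unit vector pointing from anode to cathode
#' @param ef_polarity \code{"cathode"} for cathode-seeking cells (the force
#'   acts along \code{ef_direction}), \code{"anode"} for anode-seeking
#' @param eta_min substrate viscosity at the minimum stiffness (Pa s)
#' @param lambda proportionality of viscosity on local stiffness
#'   (Pa s per kPa); default 0, i.e. uniform viscosity \code{eta_min}
#' @param omega_satur saturation surface charge density of the cell (C/m^2)
#' @param e_satur dcEF strength at which the surface charge saturates (mV/mm)
#' @param ef_gain scale mapping the physical electric force (nN) into the
#'   model's traction force units; \code{NULL} means "calibrate at start-up"
#'   (see \code{\link{run_simulation}})
#' @param ef_velocity_saturation if TRUE, the product E * Omega(E) is
#'   clamped at its saturation value for E > e_satur so the migration
#'   velocity saturates with field strength; default FALSE (literal
#'   quadratic growth below saturation, linear above)
#' @param min_thermo_gradient minimum temperature difference across the
#'   substrate (degrees C) for the thermotactic cue to be sensed; below it
#'   the cue is inactive
#' @return object of class \code{stimulus_field}
#' @export
stimulus_field <- function(Lx,
                           stiffness = c(1, 100),
                           temperature = NULL,
                           chemo = NULL,
                           ef_strength = NULL,
                           ef_direction = c(1, 0, 0),
                           ef_polarity = c("cathode", "anode"),
                           eta_min = 1000,
                           lambda = 0,
                           omega_satur = 1e-4,
                           e_satur = 100,
                           ef_gain = NULL,
                           ef_velocity_saturation = FALSE,
                           min_thermo_gradient = 0.2) {
  ef_polarity <- match.arg(ef_polarity)
  if (Lx <= 0) stop("Lx must be > 0")
  if (is.function(stiffness)) {
    probe <- stiffness(seq(0, Lx, length.out = 101))
    if (any(!is.finite(probe)) || any(probe <= 0))
      stop("stiffness must be strictly positive over the domain")
  } else {
    stopifnot(length(stiffness) == 2)
    if (any(stiffness <= 0)) stop("stiffness must be strictly positive")
  }
  if (e_satur <= 0) stop("e_satur must be > 0")
  if (omega_satur < 0) stop("omega_satur must be >= 0")
  ef <- NULL
  if (!is.null(ef_strength) && ef_strength > 0) {
    d <- unit_vector(ef_direction)
    if (is.null(d)) stop("ef_direction must be a non-zero vector")
    ef <- list(strength = ef_strength, direction = d, polarity = ef_polarity)
  }
  structure(list(Lx = Lx, stiffness = stiffness, temperature = temperature,
                 chemo = chemo, ef = ef, eta_min = eta_min, lambda = lambda,
                 omega_satur = omega_satur, e_satur = e_satur,
                 ef_gain = ef_gain,
                 ef_velocity_saturation = isTRUE(ef_velocity_saturation),
                 min_thermo_gradient = min_thermo_gradient),
            class = "stimulus_field")
}

#' Substrate stiffness at position x
#' @param field a \code{\link{stimulus_field}}
#' @param x position(s) along the gradient axis (um)
#' @return Young's modulus in kPa
#' @export
stiffness_at <- function(field, x) {
  s <- field$stiffness
  if (is.function(s)) s(x)
  else s[1] + (s[2] - s[1]) * x / field$Lx
}

#' Effective substrate viscosity
#'
#' Linear dependence of the medium viscosity on local stiffness:
#' \code{eta = eta_min + lambda * E_sub}.
#'
#' @param E_sub local substrate stiffness (kPa)
#' @param eta_min viscosity at minimum stiffness (Pa s)
#' @param lambda proportionality coefficient (Pa s / kPa)
#' @return viscosity in Pa s
#' @export
effective_viscosity <- function(E_sub, eta_min, lambda = 0) {
  if (any(E_sub <= 0)) stop("E_sub must be > 0")
  eta_min + lambda * E_sub
}

#' Unit vector of a gradient cue
#'
#' Direction of the chemoattractant or temperature gradient. The fields
#' used here are linear in x, so the cue vector is the (signed) x axis.
#' Returns NULL when the cue is absent or its gradient is zero (for the
#' thermal cue, also when the end-to-end difference is below the sensing
#' threshold); the caller redistributes the cue's weight (see
#' \code{\link{resolve_weights}}).
#'
#' @param field a \code{\link{stimulus_field}}
#' @param which \code{"chemo"} or \code{"temperature"}
#' @return length-3 unit vector or NULL if the cue is inactive
#' @export
cue_unit_vector <- function(field, which = c("chemo", "temperature")) {
  which <- match.arg(which)
  ends <- field[[which]]
  if (is.null(ends)) return(NULL)
  d <- ends[2] - ends[1]
  if (d == 0) return(NULL)
  if (which == "temperature" && abs(d) < field$min_thermo_gradient) return(NULL)
  c(sign(d), 0, 0)
}

#' Cell surface charge density under a dcEF
#'
#' Linear in the field strength up to saturation:
#' \code{Omega = omega_satur * E / e_satur} for \code{E <= e_satur}, then
#' constant at \code{omega_satur}.
#'
#' @param E dcEF strength (mV/mm), >= 0
#' @param omega_satur saturation charge density (C/m^2)
#' @param e_satur saturating field strength (mV/mm)
#' @return surface charge density (C/m^2)
#' @export
surface_charge <- function(E, omega_satur, e_satur) {
  if (any(E < 0)) stop("E must be >= 0")
  pmin(E / e_satur, 1) * omega_satur
}

#' Electric force on the cell
#'
#' Physical force magnitude \code{E * Omega(E) * S} (with E in V/m =
#' mV/mm, Omega in C/m^2 and the membrane area S converted from um^2 to
#' m^2), expressed in nN and scaled by \code{gain} into the model's
#' traction-force units. Directed along the dcEF axis towards the cathode
#' or anode according to the configured polarity.
#'
#' @param E dcEF strength (mV/mm)
#' @param S current cell membrane area (um^2)
#' @param field a \code{\link{stimulus_field}} with an active \code{ef}
#' @param gain model-unit scale factor (defaults to the field's
#'   \code{ef_gain}, or 1 if unset)
#' @return length-3 force vector (zero when no EF is active)
#' @export
#' @examples
#' f <- stimulus_field(400, ef_strength = 100)
#' # physical magnitude at saturation strength, gain = 1:
#' vn <- sqrt(sum(electric_force(100, 4 * pi * 20^2, f, gain = 1)^2))
electric_force <- function(E, S, field, gain = NULL) {
  if (is.null(field$ef) || is.null(E) || E <= 0) return(c(0, 0, 0))
  if (S <= 0) stop("membrane area must be > 0")
  gain <- gain %||% field$ef_gain %||% 1
  EOm <- E * surface_charge(E, field$omega_satur, field$e_satur)
  if (field$ef_velocity_saturation)
    EOm <- min(EOm, field$e_satur * field$omega_satur)
  # mV/mm == V/m; um^2 -> m^2 is 1e-12; N -> nN is 1e9
  mag_nN <- EOm * S * 1e-12 * 1e9
  dir <- field$ef$direction
  if (field$ef$polarity == "anode") dir <- -dir
  gain * mag_nN * dir
}

#' Effective weights of the guidance cues
#'
#' The mechanotactic, chemotactic and thermotactic contributions to the
#' effective force are convex weights: each in [0, 1] and summing to 1.
#'
#' @param mu_mech,mu_ch,mu_th effective factors
#' @return object of class \code{stimulus_weights}
#' @export
stimulus_weights <- function(mu_mech = 1 - mu_ch - mu_th, mu_ch = 0, mu_th = 0) {
  w <- c(mu_mech = mu_mech, mu_ch = mu_ch, mu_th = mu_th)
  stopifnot_finite(w, "stimulus weights")
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    stop("each effective factor must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("mu_mech + mu_ch + mu_th must equal 1")
  structure(as.list(pmin(pmax(w, 0), 1)), class = "stimulus_weights")
}

#' Redistribute the weights of inactive cues
#'
#' A cue with no gradient (or an unset field) cannot steer the cell; its
#' effective factor is folded into the mechanotactic weight, keeping the
#' convex-sum constraint. Mechanotaxis is the baseline driver and is always
#' active.
#'
#' @param w a \code{\link{stimulus_weights}} object
#' @param ch_active,th_active logical, is the cue active?
#' @return a \code{stimulus_weights} object with inactive weights zeroed
#' @export
resolve_weights <- function(w, ch_active, th_active) {
  mu_ch <- if (ch_active) w$mu_ch else 0
  mu_th <- if (th_active) w$mu_th else 0
  stimulus_weights(mu_mech = 1 - mu_ch - mu_th, mu_ch = mu_ch, mu_th = mu_th)
}
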