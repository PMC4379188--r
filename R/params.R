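#' Mechanical parameters of the migrating cell
#'
#' Bundles the constitutive and adhesion constants of the cell: the passive
#' (microtubule/membrane) and active (acto-myosin) stiffness moduli, the
#' strain bounds of the contractile machinery, the maximum contractile
#' stress, the integrin binding constants and receptor/ligand numbers that
#' define adhesivity, and the nominal cell radius.
#'
#' Defaults are the reference parameter set used throughout the package for
#' a generic eukaryotic cell in a collagen-like matrix.
#'
#' @param K_pas stiffness of the passive cellular elements (kPa)
#' @param K_act stiffness of the active cellular elements (kPa)
#' @param sigma_max maximum contractile stress of the acto-myosin machinery (kPa)
#' @param eps_min,eps_max minimum / maximum strain of the active machinery
#'   (dimensionless, \code{eps_min < 0 < eps_max})
#' @param k_f,k_b integrin binding constant at the front / rear (mol^-1)
#' @param n_f,n_b number of available receptors at the front / rear
#' @param psi ligand concentration (mol)
#' @param r nominal (spherical) cell radius (um)
#'
#' @return an object of class \code{cell_params}; the derived quantity
#'   \code{eps_tilde = sigma_max / K_act} (the strain at which the active
#'   stress peaks) is included.
#' @export
#' @examples
#' p <- cell_params()
#' p$eps_tilde  # 0.05 with default values
cell_params <- function(K_pas = 2.8, K_act = 2, sigma_max = 0.1,
                        eps_min = -0.09, eps_max = 0.09,
                        k_f = 1e8, k_b = 1e8, n_f = 1e5, n_b = 1e5,
                        psi = 1e-5, r = 20) {
  vals <- c(K_pas = K_pas, K_act = K_act, sigma_max = sigma_max,
            eps_min = eps_min, eps_max = eps_max,
            k_f = k_f, k_b = k_b, n_f = n_f, n_b = n_b, psi = psi, r = r)
  stopifnot_finite(vals, "cell parameters")
  if (!(eps_min < 0 && 0 < eps_max)) stop("need eps_min < 0 < eps_max")
  if (sigma_max <= 0) stop("sigma_max must be > 0")
  if (K_act <= 0) stop("K_act must be > 0")
  if (K_pas < 0) stop("K_pas must be >= 0")
  if (r <= 0) stop("cell radius must be > 0")
  if (any(c(k_f, k_b, n_f, n_b, psi) < 0)) stop("adhesion factors must be >= 0")
  eps_tilde <- sigma_max / K_act
  if (eps_tilde < eps_min || eps_tilde > eps_max)
    stop("sigma_max / K_act must lie within [eps_min, eps_max]")
  structure(list(K_pas = K_pas, K_act = K_act, sigma_max = sigma_max,
                 eps_min = eps_min, eps_max = eps_max, eps_tilde = eps_tilde,
                 k_f = k_f, k_b = k_b, n_f = n_f, n_b = n_b,
                 psi = psi, r = r),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell mechanical parameters\n")
  cat(sprintf("  K_pas = %g kPa, K_act = %g kPa, sigma_max = %g kPa\n",
              x$K_pas, x$K_act, x$sigma_max))
  cat(sprintf("  strain range [%g, %g], eps_tilde = %g\n",
              x$eps_min, x$eps_max, x$eps_tilde))
  cat(sprintf("  adhesivity front/rear = %g / %g, r = %g um\n",
              adhesivity(x$k_f, x$n_f, x$psi),
              adhesivity(x$k_b, x$n_b, x$psi), x$r))
  invisible(x)
}
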