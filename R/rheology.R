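#' Carreau-Yasuda blood rheology parameters
#'
#' Five-parameter shear-thinning viscosity law interpolating between a
#' zero-shear plateau `mu_0` and an infinite-shear plateau `mu_inf`. The
#' defaults are the standard whole-blood parameter set used in pulsatile
#' aortic CFD.
#'
#' @param mu_inf viscosity at infinite shear rate (Pa s).
#' @param mu_0 zero-shear viscosity (Pa s).
#' @param lambda relaxation time (s).
#' @param a Yasuda exponent (dimensionless).
#' @param n power-law index (dimensionless); `n < 1` gives shear thinning.
#' @return object of class `rheology_params`.
#' @export
rheology_params <- function(mu_inf = 0.00345, mu_0 = 0.056,
                            lambda = 1.902, a = 1.25, n = 0.22) {
  if (!(mu_0 > mu_inf && mu_inf > 0)) stop("need mu_0 > mu_inf > 0")
  if (lambda <= 0) stop("lambda must be positive")
  if (a <= 0) stop("Yasuda exponent a must be positive")
  if (!(n > 0 && n < 1)) stop("power index n must lie in (0, 1) for shear thinning")
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, lambda = lambda, a = a, n = n),
            class = "rheology_params")
}

#' Carreau-Yasuda apparent viscosity
#'
#' Evaluates
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
#'   \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' at one or more shear rates. The zero-shear limit is `mu_0`; for
#' `n < 1` the viscosity decreases monotonically towards `mu_inf`.
#'
#' @param gamma_dot shear rate(s), 1/s, nonnegative.
#' @param params a [rheology_params()] object.
#' @return viscosity in Pa s, same length as `gamma_dot`.
#' @examples
#' carreau_yasuda_viscosity(0)            # zero-shear plateau
#' carreau_yasuda_viscosity(c(1, 100, 1e6))
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, params = rheology_params()) {
  if (!inherits(params, "rheology_params")) stop("params must be rheology_params")
  gamma_dot <- as.numeric(gamma_dot)
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0)) {
    stop("shear rate must be finite and nonnegative")
  }
  params$mu_inf + (params$mu_0 - params$mu_inf) *
    (1 + (params$lambda * gamma_dot)^params$a)^((params$n - 1) / params$a)
}
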