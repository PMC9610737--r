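#' Parameter set for the stochastic delayed SVIR model
#'
#' Bundles every constant of the model: demographic and epidemiological
#' rates, the two immunity-period delays, the saturation factors of the
#' two incidence functions, the multiplicative noise intensities, and the
#' split-step weight used by both integrators.
#'
#' The model tracks susceptible (S), vaccinated-in-process (V) and
#' infected (I) densities.  Infection-induced immunity wanes after
#' `tau1` time units (survivors return to S at rate
#' `gamma1 * exp(-mu * tau1)`), vaccination-induced immunity after `tau2`
#' (survivors re-enter V at rate `gamma2 * exp(-mu * tau2)`).  The
#' recovered compartment decouples and is not simulated.
#'
#' Transmission follows general saturated incidence
#' `beta1 * S * I / (1 + lambda1*S + lambda2*I + lambda3*S*I)` between S
#' and I, and the analogous form with `beta2` and `eta1..eta3` between V
#' and I.  Setting the saturation factors to zero recovers bilinear
#' incidence; `lambda3 = 0` gives Beddington-DeAngelis and
#' `lambda3 = lambda1 * lambda2` Crowley-Martin.
#'
#' @param mu Recruitment rate, equal to the natural death rate (1/time).
#' @param alpha Vaccination uptake rate of susceptibles (1/time).
#' @param beta1,beta2 Transmission coefficients for S-I and V-I contacts.
#'   Partial immunity during the vaccination process motivates
#'   `beta2 < beta1`; the reverse ordering is accepted with a warning.
#' @param gamma1 Recovery rate of infected individuals (1/time).
#' @param gamma2 Rate at which vaccinees acquire immunity (1/time).
#' @param tau1,tau2 Immunity periods (time units), strictly positive.
#' @param lambda1,lambda2,lambda3 Nonnegative saturation factors of the
#'   S-I incidence function.
#' @param eta1,eta2,eta3 Nonnegative saturation factors of the V-I
#'   incidence function.
#' @param sigma1,sigma2,sigma3 Nonnegative intensities of the
#'   multiplicative Brownian perturbations on S, V and I.
#' @param theta Split-step weight in \[0, 1\] used when interpolating the
#'   delayed states.
#'
#' @return A validated object of class `svir_params`.
#' @seealso [derived_constants()], [load_preset()]
#' @examples
#' p <- svir_params(beta1 = 10.5, beta2 = 5.5)
#' derived_constants(p)$R0s
#' @export
svir_params <- function(mu = 1, alpha = 10, beta1 = 10.5, beta2 = 5.5,
                        gamma1 = 1.5, gamma2 = 2.4,
                        tau1 = 1, tau2 = 2,
                        lambda1 = 0.2, lambda2 = 0.3, lambda3 = 0.4,
                        eta1 = 0.4, eta2 = 0.2, eta3 = 0.1,
                        sigma1 = 0.1, sigma2 = 0.02, sigma3 = 0.05,
                        theta = 0.5) {
  p <- structure(
    list(mu = mu, alpha = alpha, beta1 = beta1, beta2 = beta2,
         gamma1 = gamma1, gamma2 = gamma2, tau1 = tau1, tau2 = tau2,
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         eta1 = eta1, eta2 = eta2, eta3 = eta3,
         sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3,
         theta = theta),
    class = "svir_params")
  validate_params(p)
}

#' Validate an SVIR parameter set
#'
#' Checks finiteness, positivity of the rates and delays, nonnegativity
#' of the saturation factors and noise intensities, and `theta` in
#' \[0, 1\].  The modelling assumption `beta2 < beta1` (partial immunity
#' of vaccinees) is soft: its violation warns but does not reject.
#'
#' @param p An object of class `svir_params`.
#' @return `p`, unchanged, if all invariants hold.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "svir_params"))
  num <- unlist(p)
  if (!all(is.finite(num)))
    stop("non-finite parameter value(s): ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  pos <- c("mu", "alpha", "gamma1", "gamma2", "tau1", "tau2")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  nneg <- c("beta1", "beta2", "lambda1", "lambda2", "lambda3",
            "eta1", "eta2", "eta3", "sigma1", "sigma2", "sigma3")
  bad <- nneg[vapply(nneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be nonnegative: ", paste(bad, collapse = ", "))
  if (p$theta < 0 || p$theta > 1)
    stop("theta must lie in [0, 1], got ", p$theta)
  if (p$beta2 > p$beta1)
    warning("beta2 > beta1: vaccinees more susceptible than unvaccinated ",
            "contradicts the partial-immunity assumption (accepted anyway)")
  p
}

#' @export
print.svir_params <- function(x, ...) {
  cat("Stochastic delayed SVIR parameter set\n")
  cat(sprintf("  rates:      mu=%g alpha=%g beta1=%g beta2=%g gamma1=%g gamma2=%g\n",
              x$mu, x$alpha, x$beta1, x$beta2, x$gamma1, x$gamma2))
  cat(sprintf("  delays:     tau1=%g tau2=%g\n", x$tau1, x$tau2))
  cat(sprintf("  saturation: lambda=(%g, %g, %g)  eta=(%g, %g, %g)\n",
              x$lambda1, x$lambda2, x$lambda3, x$eta1, x$eta2, x$eta3))
  cat(sprintf("  noise:      sigma=(%g, %g, %g)   theta=%g\n",
              x$sigma1, x$sigma2, x$sigma3, x$theta))
  invisible(x)
}
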