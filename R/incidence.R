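#' General saturated incidence rates
#'
#' The force of new infections from susceptible-infected contacts,
#' `incidence_si()`, is `beta1 * S * I / (1 + lambda1*S + lambda2*I +
#' lambda3*S*I)`; `incidence_vi()` is the analogous rate for contacts of
#' in-process vaccinees with the infected, using `beta2` and
#' `eta1..eta3`.  Both are Hattaf-type general incidence functions:
#' special parameter choices recover the bilinear, saturated,
#' Beddington-DeAngelis and Crowley-Martin forms.
#'
#' For nonnegative arguments the denominator is at least 1, the rate is
#' nonnegative, vanishes when either argument is zero, and is dominated
#' by the bilinear rate (`incidence_si <= beta1*S*I`).
#'
#' @param p An `svir_params` object.
#' @param S,V,I Nonnegative state values (vectorized).
#' @return Nonnegative incidence rate(s).
#' @examples
#' p <- svir_params()
#' incidence_si(p, S = 0.3, I = 0.2)
#' @export
incidence_si <- function(p, S, I) {
  if (any(S < 0) || any(I < 0)) stop("S and I must be nonnegative")
  p$beta1 * S * I / (1 + p$lambda1 * S + p$lambda2 * I + p$lambda3 * S * I)
}

#' @rdname incidence_si
#' @export
incidence_vi <- function(p, V, I) {
  if (any(V < 0) || any(I < 0)) stop("V and I must be nonnegative")
  p$beta2 * V * I / (1 + p$eta1 * V + p$eta2 * I + p$eta3 * V * I)
}

#' Drift of the stochastic delayed SVIR model
#'
#' Evaluates the deterministic part of the three model equations at a
#' given state, with the delayed infected and vaccinated densities
#' supplied explicitly:
#' \deqn{dS = \mu - (\mu+\alpha)S - F_1(S,I) + \gamma_1 e^{-\mu\tau_1} I(t-\tau_1)}
#' \deqn{dV = \alpha S - (\gamma_2+\mu)V - F_2(V,I) + \gamma_2 e^{-\mu\tau_2} V(t-\tau_2)}
#' \deqn{dI = F_1(S,I) + F_2(V,I) - (\gamma_1+\mu)I}
#'
#' At the disease-free equilibrium with disease-free history the drift
#' is the zero vector.
#'
#' @param p An `svir_params` object.
#' @param S,V,I Nonnegative current state.
#' @param I_delayed Infected density one `tau1`-lag in the past.
#' @param V_delayed Vaccinated density one `tau2`-lag in the past.
#' @return Named numeric vector `c(dS, dV, dI)`.
#' @export
svir_drift <- function(p, S, V, I, I_delayed, V_delayed) {
  if (any(c(S, V, I, I_delayed, V_delayed) < 0))
    stop("state and delayed values must be nonnegative")
  f1 <- incidence_si(p, S, I)
  f2 <- incidence_vi(p, V, I)
  c(dS = p$mu - (p$mu + p$alpha) * S - f1 +
      p$gamma1 * exp(-p$mu * p$tau1) * I_delayed,
    dV = p$alpha * S - (p$gamma2 + p$mu) * V - f2 +
      p$gamma2 * exp(-p$mu * p$tau2) * V_delayed,
    dI = f1 + f2 - (p$gamma1 + p$mu) * I)
}
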