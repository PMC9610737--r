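#' Closed-form threshold quantities of the SVIR model
#'
#' Computes every derived constant of the model's threshold theory:
#' the composite rates `c1 = (gamma1*(1 - exp(-mu*tau1)) + mu)*(alpha + mu)`
#' and `c2` (same with `gamma2`, `tau2`), the disease-free equilibrium
#' `E0 = (mu/(alpha+mu), alpha*mu/c2, 0)`, the stochastic and
#' deterministic reproduction numbers, the persistence-condition value,
#' and both variants of the persistence denominator constant `L2`.
#'
#' The stochastic reproduction number is
#' \deqn{R_0^s = \frac{\beta_1\mu}{(\alpha+(1+\lambda_1)\mu)(\gamma_1+\mu+\sigma_3^2/2)}
#'   + \frac{\beta_2\alpha\mu}{(\eta_1\alpha\mu+c_2)(\gamma_1+\mu+\sigma_3^2/2)},}
#' and `R0d` is the same expression with `sigma3 = 0`, so `R0s <= R0d`
#' with equality exactly when `sigma3 = 0`.  Infection noise only ever
#' lowers the threshold: large `sigma3` can push `R0s` below 1 (disease
#' extinction almost surely) while `R0d > 1`.
#'
#' `L2` enters the persistence-in-mean threshold `I*` (see
#' [persistence_thresholds()]).  Two readings coexist: the closed form
#' stated with the persistence theorem (`L2_theorem`) and the coefficient
#' `beta2*c1/(eta1*alpha*mu + c2)` that actually arises in the
#' integral-expansion step of its derivation (`L2_expansion`).  Both are
#' returned; they coincide (at zero) when `beta2 = 0`.
#'
#' @param p A validated `svir_params` object.
#' @return An object of class `svir_constants`: a list with elements
#'   `c1`, `c2`, `S0_dfe`, `V0_dfe`, `R0s`, `R0d`, `L1`, `L2_expansion`,
#'   `L2_theorem`, `condition_value`.
#' @seealso [persistence_condition()], [persistence_thresholds()]
#' @examples
#' p <- svir_params(beta1 = 10.5, beta2 = 5.5)
#' round(derived_constants(p)$R0s, 4)
#' @export
derived_constants <- function(p) {
  p <- validate_params(p)
  c1 <- (p$gamma1 * (1 - exp(-p$mu * p$tau1)) + p$mu) * (p$alpha + p$mu)
  c2 <- (p$gamma2 * (1 - exp(-p$mu * p$tau2)) + p$mu) * (p$alpha + p$mu)
  amu <- p$alpha * p$mu
  # eta1*alpha*mu + c2 in the V-contact term: c2, not c1 -- c2 is the only
  # composite consistent with the V-compartment bounds the term comes from
  den2 <- p$eta1 * amu + c2
  kill <- function(s3) p$gamma1 + p$mu + s3^2 / 2
  r0 <- function(s3) {
    p$beta1 * p$mu / ((p$alpha + (1 + p$lambda1) * p$mu) * kill(s3)) +
      p$beta2 * amu / (den2 * kill(s3))
  }
  L1 <- (p$beta1 * p$mu / ((1 + p$lambda1) * p$mu + p$alpha)) *
    (p$lambda2 + p$lambda3 * p$mu / (p$alpha + p$mu)) +
    (p$beta2 * amu / den2) * (p$eta2 + p$eta3 * amu / c2)
  L2_theorem <- p$beta2 * p$alpha *
    (p$beta2 * amu * (p$alpha + p$mu) + c1 * den2) /
    (den2^2 * (p$alpha + p$mu))
  L2_expansion <- p$beta2 * c1 / den2
  structure(
    list(c1 = c1, c2 = c2,
         S0_dfe = p$mu / (p$alpha + p$mu),
         V0_dfe = amu / c2,
         R0s = r0(p$sigma3), R0d = r0(0),
         L1 = L1, L2_expansion = L2_expansion, L2_theorem = L2_theorem,
         condition_value = c1 / (p$alpha + p$mu) - p$beta2 * amu / den2),
    class = "svir_constants")
}

#' @export
print.svir_constants <- function(x, ...) {
  cat("SVIR threshold constants\n")
  cat(sprintf("  c1 = %.4f   c2 = %.4f\n", x$c1, x$c2))
  cat(sprintf("  disease-free equilibrium: S0 = %.5f, V0 = %.5f, I0 = 0\n",
              x$S0_dfe, x$V0_dfe))
  cat(sprintf("  R0s = %.4f   R0d = %.4f\n", x$R0s, x$R0d))
  cat(sprintf("  persistence condition value = %.4f (%s)\n",
              x$condition_value,
              if (x$condition_value > 0) "satisfied" else "violated"))
  invisible(x)
}

#' Persistence-in-mean condition value
#'
#' Left-hand side of the side condition required (together with
#' `R0s > 1`) for persistence in mean:
#' `c1/(alpha + mu) - beta2*alpha*mu/(eta1*alpha*mu + c2)`.
#' A strictly positive value means the condition holds.
#'
#' @inheritParams derived_constants
#' @return The condition value (scalar).
#' @export
persistence_condition <- function(p) {
  derived_constants(p)$condition_value
}

#' Persistence-in-mean thresholds
#'
#' For `R0s > 1` (and the side condition positive) the long-run time
#' averages satisfy `<I> >= I*`, `<S> <= S*` and `<V> -> V*`, with
#' \deqn{I^* = \frac{(\gamma_1+\mu+\sigma_3^2/2)(R_0^s-1)}{L_1+L_2},}
#' `S* = mu/(alpha+mu) - condition_value * I* / (alpha+mu)` and
#' `V* = (mu*(alpha+mu)/c2)*(1 - S*) - (c1/c2)*I*`.
#'
#' The `mode` argument selects which `L2` variant enters the
#' denominator: `"expansion"` (default) uses the coefficient
#' `beta2*c1/(eta1*alpha*mu + c2)` from the derivation's expansion step,
#' `"theorem"` the closed form stated with the theorem.  The two give
#' materially different `I*` whenever `beta2 > 0`; see the methods
#' vignette for why the expansion variant is the default.
#'
#' The `I*` formula is evaluated regardless of applicability; the
#' `applicable` flag records whether `R0s > 1` and the side condition
#' hold, in which case the thresholds carry their persistence meaning.
#'
#' @inheritParams derived_constants
#' @param mode `"expansion"` or `"theorem"` (choice of `L2`).
#' @return A list with `I_star`, `S_star`, `V_star`, `mode`,
#'   `applicable`, and the `svir_constants` used (`constants`).
#' @examples
#' p <- svir_params(beta1 = 14, beta2 = 7)
#' persistence_thresholds(p)$I_star
#' @export
persistence_thresholds <- function(p, mode = c("expansion", "theorem")) {
  mode <- match.arg(mode)
  k <- derived_constants(p)
  L2 <- if (mode == "expansion") k$L2_expansion else k$L2_theorem
  kill <- p$gamma1 + p$mu + p$sigma3^2 / 2
  I_star <- kill * (k$R0s - 1) / (k$L1 + L2)
  S_star <- p$mu / (p$alpha + p$mu) -
    k$condition_value * I_star / (p$alpha + p$mu)
  V_star <- (p$mu * (p$alpha + p$mu) / k$c2) * (1 - S_star) -
    (k$c1 / k$c2) * I_star
  list(I_star = I_star, S_star = S_star, V_star = V_star,
       mode = mode,
       applicable = k$R0s > 1 && k$condition_value > 0,
       constants = k)
}

#' Thresholds at reporting precision
#'
#' Rounds the persistence thresholds to the precision at which they are
#' conventionally quoted (`I*` to 3 decimals, `S*` and `V*` to 4), with
#' `V*` recomputed from the already-rounded `I*` and `S*` so the three
#' reported numbers are mutually consistent at that precision.  Internal
#' computations elsewhere always use full precision.
#'
#' @inheritParams persistence_thresholds
#' @return A list with rounded `I_star`, `S_star`, `V_star` and `mode`.
#' @export
threshold_report <- function(p, mode = c("expansion", "theorem")) {
  mode <- match.arg(mode)
  th <- persistence_thresholds(p, mode)
  k <- th$constants
  I_rep <- round(th$I_star, 3)
  S_rep <- round(th$S_star, 4)
  V_rep <- round((p$mu * (p$alpha + p$mu) / k$c2) * (1 - S_rep) -
                   (k$c1 / k$c2) * I_rep, 4)
  list(I_star = I_rep, S_star = S_rep, V_star = V_rep, mode = mode)
}
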