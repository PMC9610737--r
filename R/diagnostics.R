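#' Time average of a trajectory component
#'
#' Trapezoidal approximation of `(1/T) * integral_0^T g(s) ds`, the
#' long-run average whose limit behaviour the extinction and
#' persistence theory bounds.  Exact for constant and linear paths.
#'
#' @param traj An `svir_trajectory`.
#' @param component `"S"`, `"V"` or `"I"`.
#' @return The time average over `[0, T]` (or over the pre-divergence
#'   window if the run was truncated).
#' @export
time_average <- function(traj, component = c("S", "V", "I")) {
  component <- match.arg(component)
  g <- traj[[component]]
  t <- traj$times
  ok <- !is.na(g)
  g <- g[ok]; t <- t[ok]
  if (length(g) < 2) stop("trajectory too short for a time average")
  span <- t[length(t)] - t[1]
  sum(diff(t) * (g[-1] + g[-length(g)]) / 2) / span
}

#' Extinction diagnostic
#'
#' Compares the realized exponential decay rate of the infection,
#' `ln I(T) / T`, with the closed-form almost-sure bound
#' `(gamma1 + mu + sigma3^2/2) * (R0s - 1)`: when `R0s < 1` the bound
#' is negative and the infection dies out exponentially fast.  Both
#' numbers refer to the finite horizon actually simulated; the verdict
#' is an observation at that horizon, not a limit claim.
#'
#' @param traj An `svir_trajectory`.
#' @param p The `svir_params` used (defaults to those stored in `traj`).
#' @return A list: `logI_rate` (`-Inf` if `I(T) = 0`),
#'   `extinction_bound`, `R0s`, `horizon`, `rate_below_bound`, and
#'   `extinction_predicted` (`R0s < 1`).
#' @export
extinction_report <- function(traj, p = traj$params) {
  k <- derived_constants(p)
  idx <- max(which(!is.na(traj$I)))
  Tend <- traj$times[idx]
  I_end <- traj$I[idx]
  rate <- if (I_end > 0) log(I_end) / Tend else -Inf
  bound <- (p$gamma1 + p$mu + p$sigma3^2 / 2) * (k$R0s - 1)
  list(logI_rate = rate, extinction_bound = bound, R0s = k$R0s,
       horizon = Tend, rate_below_bound = rate <= bound,
       extinction_predicted = k$R0s < 1)
}

#' Persistence-in-mean diagnostic
#'
#' Reports the time averages of S, V and I (ensemble-averaged when an
#' `svir_ensemble` is given) next to the persistence thresholds
#' `I*`, `S*`, `V*` and the three inequalities the persistence theory
#' predicts for the long run: `<I> >= I*`, `<S> <= S*`, `<V> -> V*`.
#' At a finite horizon these are observations, not assertions; the
#' report records the horizon alongside.
#'
#' @param x An `svir_trajectory` or `svir_ensemble`.
#' @param p Parameters (default: stored in the (first) trajectory).
#' @param mode `L2` variant for the thresholds, see
#'   [persistence_thresholds()].
#' @return A list with `avg` (named S/V/I averages), `thresholds`,
#'   `condition_value`, `R0s`, `horizon` and logical observations
#'   `I_above_I_star`, `S_below_S_star`.
#' @export
persistence_report <- function(x, p = NULL, mode = c("expansion", "theorem")) {
  mode <- match.arg(mode)
  trajs <- if (inherits(x, "svir_ensemble")) x$paths else list(x)
  if (is.null(p)) p <- trajs[[1]]$params
  avg_one <- function(tr) vapply(c("S", "V", "I"),
                                 function(cc) time_average(tr, cc), numeric(1))
  avg <- rowMeans(vapply(trajs, avg_one, numeric(3)))
  th <- persistence_thresholds(p, mode)
  if (!th$applicable)
    warning("R0s <= 1 or side condition violated: persistence thresholds ",
            "do not carry their persistence meaning here")
  list(avg = avg, thresholds = th[c("I_star", "S_star", "V_star", "mode")],
       condition_value = th$constants$condition_value,
       R0s = th$constants$R0s,
       horizon = max(trajs[[1]]$times),
       n_paths = length(trajs),
       I_above_I_star = unname(avg["I"] >= th$I_star),
       S_below_S_star = unname(avg["S"] <= th$S_star))
}

#' Discrete boundedness certificate for the NSFD scheme
#'
#' The boundedness theory of the nonstandard scheme gives a recursive
#' envelope for the total density: with `sigma = max(sigma1..3)` and
#' `dW_n = max` of the three increments at step `n`,
#' `M[-1] = T*` and `M[n] = mu * v(h) + (1 + sigma*dW_n) * M[n-1]`,
#' then `S[n+1] + V[n+1] + I[n+1] <= M[n]` whenever the initial total
#' is below the ceiling `T* = mu/(gamma2*(1-exp(-mu*tau2)) + mu) +
#' alpha*mu/c2`.
#'
#' Because the increments are signed Gaussians, a step with
#' `1 + sigma*dW_n <= 0` makes the recursion meaningless there; such
#' steps void the certificate and are flagged rather than patched.
#' When the initial total exceeds `T*` the theorem's hypothesis fails;
#' by default the recursion is started from
#' `max(T*, S0 + V0 + I0)` so the monitor still tracks the path, while
#' `strict = TRUE` enforces the hypothesis and errors instead.
#'
#' @param traj An `svir_trajectory` produced by [ssstnsfd_simulate()]
#'   (the certificate consumes the noise stored in it).
#' @param p Parameters (default: stored in `traj`).
#' @param T_star_override Optional replacement for the ceiling `T*`
#'   (e.g. to explore an alternative reading of the constant).
#' @param strict If `TRUE`, require `S0 + V0 + I0 <= T*`.
#' @return A list: `T_star`, `M` (length `n_steps`, `M[n]` bounding the
#'   state at step `n`), `sums` (total density at steps `1..n_steps`),
#'   `bound_violations` (steps where the total exceeds the envelope),
#'   `void_steps` (steps where `1 + sigma*dW <= 0`).
#' @export
boundedness_certificate <- function(traj, p = traj$params,
                                    T_star_override = NULL,
                                    strict = FALSE) {
  k <- derived_constants(p)
  T_star <- if (!is.null(T_star_override)) T_star_override else
    p$mu / (p$gamma2 * (1 - exp(-p$mu * p$tau2)) + p$mu) +
    p$alpha * p$mu / k$c2
  tot0 <- traj$S[1] + traj$V[1] + traj$I[1]
  if (strict && tot0 > T_star)
    stop(sprintf("initial total density %.4f exceeds T* = %.4f", tot0, T_star))
  start <- if (strict) T_star else max(T_star, tot0)
  sig <- max(p$sigma1, p$sigma2, p$sigma3)
  dW_max <- apply(unclass(traj$noise), 2, max)
  v <- nsfd_denominator(traj$grid$h)
  N <- traj$grid$n_steps
  M <- numeric(N)
  prev <- start
  growth <- 1 + sig * dW_max
  for (n in seq_len(N)) {
    M[n] <- p$mu * v + growth[n] * prev
    prev <- M[n]
  }
  sums <- traj$S[-1] + traj$V[-1] + traj$I[-1]
  list(T_star = T_star, M = M, sums = sums,
       bound_violations = which(!is.na(sums) & sums > M),
       void_steps = which(growth <= 0))
}

#' Full diagnostics report for a run
#'
#' Bundles the time averages, extinction comparison, persistence
#' comparison, boundedness certificate (NSFD runs only) and positivity
#' summary into one object that serializes to JSON.
#'
#' @param traj An `svir_trajectory`.
#' @param p Parameters (default from `traj`).
#' @param mode Threshold mode, see [persistence_thresholds()].
#' @return A list of class `svir_diagnostics`.
#' @export
diagnostics_report <- function(traj, p = traj$params,
                               mode = c("expansion", "theorem")) {
  mode <- match.arg(mode)
  ext <- extinction_report(traj, p)
  per <- suppressWarnings(persistence_report(traj, p, mode))
  bnd <- if (traj$method == "ssstnsfd")
    boundedness_certificate(traj, p) else NULL
  structure(
    list(method = traj$method, seed = traj$seed,
         horizon = ext$horizon, h = traj$grid$h,
         averages = as.list(per$avg),
         extinction = ext[c("logI_rate", "extinction_bound", "R0s",
                            "rate_below_bound", "extinction_predicted")],
         persistence = per[c("thresholds", "condition_value",
                             "I_above_I_star", "S_below_S_star")],
         boundedness = if (!is.null(bnd))
           list(T_star = bnd$T_star,
                n_bound_violations = length(bnd$bound_violations),
                n_void_steps = length(bnd$void_steps)),
         positivity = list(
           n_violations = nrow(traj$positivity_violations),
           components = unique(traj$positivity_violations$component),
           diverged_at = traj$diverged_at)),
    class = "svir_diagnostics")
}

#' @export
print.svir_diagnostics <- function(x, ...) {
  cat(sprintf("SVIR diagnostics (%s, T=%g, h=%g)\n", x$method, x$horizon, x$h))
  cat(sprintf("  time averages: <S>=%.4f <V>=%.4f <I>=%.5g\n",
              x$averages$S, x$averages$V, x$averages$I))
  cat(sprintf("  R0s=%.4f; ln I(T)/T = %.4f vs bound %.4f\n",
              x$extinction$R0s, x$extinction$logI_rate,
              x$extinction$extinction_bound))
  cat(sprintf("  thresholds (%s): I*=%.5f S*=%.5f V*=%.5f\n",
              x$persistence$thresholds$mode, x$persistence$thresholds$I_star,
              x$persistence$thresholds$S_star, x$persistence$thresholds$V_star))
  cat(sprintf("  positivity violations: %d\n", x$positivity$n_violations))
  invisible(x)
}

#' Serialize diagnostics to JSON
#'
#' @param report An `svir_diagnostics` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
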