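#' Simulate the delayed SVIR model by the split-step theta-Milstein scheme
#'
#' Explicit Milstein-type discretization of the three stochastic delay
#' equations with the delayed states interpolated by the split-step
#' theta rule.  The update is sequential within each step: `S[n+1]` is
#' computed first and feeds the `alpha * S[n+1]` inflow of the V update;
#' `S[n+1]` and `V[n+1]` then enter the incidence fractions of the I
#' update (paired with `I[n]`).  Each equation carries its own diagonal
#' Milstein correction `(sigma^2/2) * X[n] * (dW^2 - h)`.
#'
#' The scheme does not guarantee positivity: any step producing a
#' negative component is recorded in `positivity_violations` and the
#' value is kept as computed, never clipped.  If a state becomes
#' non-finite the run is truncated there (remaining values `NA`,
#' `diverged_at` set, warning raised).
#'
#' @param p A validated `svir_params`.
#' @param grid An `svir_grid` built from the same parameters.
#' @param history An `svir_history`.
#' @param noise An `svir_noise` increment table matching the grid (or
#'   `NULL` for a zero-noise table; note the `sigma` parameters still
#'   scale the Milstein correction's `-h` term, so a true deterministic
#'   run should also set the sigmas to zero — see
#'   [deterministic_simulate()]).
#' @return An object of class `svir_trajectory`: list with `times`,
#'   `S`, `V`, `I`, `method`, `seed`, `positivity_violations` (data
#'   frame of step and component), `diverged_at`, `params`, `noise`.
#' @seealso [ssstnsfd_simulate()], [deterministic_simulate()],
#'   [ensemble_run()]
#' @export
sstm_simulate <- function(p, grid, history, noise = NULL) {
  run_scheme(p, grid, history, noise, method = "sstm")
}

#' Simulate by the split-step theta nonstandard finite difference scheme
#'
#' Positivity-oriented discretization in the Mickens sense: the step
#' `h` is replaced by the denominator function `v(h) = 1 - exp(-h)`,
#' loss terms are treated implicitly (they move to the denominator of
#' the update), gain terms explicitly, and the delayed states use the
#' same split-step theta interpolation as the Milstein scheme.  The
#' resulting update is explicit after a Gauss-Seidel-style sweep:
#' `S[n+1]` first, then `V[n+1]` (using `S[n+1]`), then `I[n+1]` (using
#' both).
#'
#' With zero noise every numerator and denominator is positive, so the
#' scheme preserves positivity from positive history for any `h > 0`.
#' With noise, a large negative increment can still push a numerator
#' negative (`sigma3 * dW3 < -1` in the I update); such steps are
#' recorded in `positivity_violations`, never masked.
#'
#' @inheritParams sstm_simulate
#' @return An `svir_trajectory` (see [sstm_simulate()]).
#' @export
ssstnsfd_simulate <- function(p, grid, history, noise = NULL) {
  run_scheme(p, grid, history, noise, method = "ssstnsfd")
}

#' Deterministic counterpart of either scheme
#'
#' Runs the chosen scheme with all noise intensities and all increments
#' set to zero: the explicit Milstein scheme collapses to an explicit
#' Euler-type method for the delay ODE, the NSFD scheme to its
#' deterministic nonstandard counterpart.
#'
#' @inheritParams sstm_simulate
#' @param method `"sstm"` or `"ssstnsfd"`.
#' @return An `svir_trajectory` with `seed = NA`.
#' @export
deterministic_simulate <- function(p, grid, history,
                                   method = c("ssstnsfd", "sstm")) {
  method <- match.arg(method)
  p0 <- p
  p0$sigma1 <- p0$sigma2 <- p0$sigma3 <- 0
  run_scheme(p0, grid, history, zero_noise(grid), method = method)
}

# Shared stepping loop for both schemes.  Written as one function so the
# per-step RNG/noise layout, history resolution, violation recording and
# divergence handling are identical between methods.
run_scheme <- function(p, grid, history, noise, method) {
  p <- validate_params(p)
  stopifnot(inherits(grid, "svir_grid"), inherits(history, "svir_history"))
  if (is.null(noise)) noise <- zero_noise(grid)
  if (!inherits(noise, "svir_noise") || ncol(noise) != grid$n_steps)
    stop("noise table does not match the grid (need 3 x ", grid$n_steps, ")")
  if (abs(attr(noise, "h") - grid$h) > 1e-12)
    stop("noise table was drawn for a different step size")

  N <- grid$n_steps
  h <- grid$h
  th <- p$theta
  k1 <- p$gamma1 * exp(-p$mu * p$tau1)
  k2 <- p$gamma2 * exp(-p$mu * p$tau2)
  v <- nsfd_denominator(h)

  S <- V <- I <- numeric(N + 1L)
  init <- history_at(history, 0)
  S[1] <- init[1]; V[1] <- init[2]; I[1] <- init[3]

  viol_step <- integer(0)
  viol_comp <- character(0)
  diverged_at <- NA_integer_

  for (n in 0:(N - 1L)) {
    Id <- delayed_value(I, n, grid$m1, th, history, 3L, h)
    Vd <- delayed_value(V, n, grid$m2, th, history, 2L, h)
    Sn <- S[n + 1L]; Vn <- V[n + 1L]; In <- I[n + 1L]
    dW1 <- noise[1L, n + 1L]; dW2 <- noise[2L, n + 1L]; dW3 <- noise[3L, n + 1L]

    if (method == "sstm") {
      f1 <- p$beta1 * Sn * In /
        (1 + p$lambda1 * Sn + p$lambda2 * In + p$lambda3 * Sn * In)
      S1 <- Sn + (p$mu - (p$mu + p$alpha) * Sn + k1 * Id - f1) * h +
        p$sigma1 * Sn * dW1 + (p$sigma1^2 / 2) * Sn * (dW1^2 - h)
      f2 <- p$beta2 * Vn * In /
        (1 + p$eta1 * Vn + p$eta2 * In + p$eta3 * Vn * In)
      V1 <- Vn + (p$alpha * S1 - (p$mu + p$gamma2) * Vn + k2 * Vd - f2) * h +
        p$sigma2 * Vn * dW2 + (p$sigma2^2 / 2) * Vn * (dW2^2 - h)
      g1 <- p$beta1 * S1 * In /
        (1 + p$lambda1 * S1 + p$lambda2 * In + p$lambda3 * S1 * In)
      g2 <- p$beta2 * V1 * In /
        (1 + p$eta1 * V1 + p$eta2 * In + p$eta3 * V1 * In)
      I1 <- In + (g1 + g2 - (p$mu + p$gamma1) * In) * h +
        p$sigma3 * In * dW3 + (p$sigma3^2 / 2) * In * (dW3^2 - h)
    } else {
      den_s <- 1 + p$lambda1 * Sn + p$lambda2 * In + p$lambda3 * Sn * In
      S1 <- (Sn + (p$mu + k1 * Id) * v + p$sigma1 * Sn * dW1) /
        (1 + (p$alpha + p$mu + p$beta1 * In / den_s) * v)
      den_v <- 1 + p$eta1 * Vn + p$eta2 * In + p$eta3 * Vn * In
      V1 <- (Vn + (p$alpha * S1 + k2 * Vd) * v + p$sigma2 * Vn * dW2) /
        (1 + (p$gamma2 + p$mu + p$beta2 * In / den_v) * v)
      inc_s <- p$beta1 * S1 /
        (1 + p$lambda1 * S1 + p$lambda2 * In + p$lambda3 * S1 * In)
      inc_v <- p$beta2 * V1 /
        (1 + p$eta1 * V1 + p$eta2 * In + p$eta3 * V1 * In)
      I1 <- In * (1 + (inc_s + inc_v) * v + p$sigma3 * dW3) /
        (1 + (p$gamma1 + p$mu) * v)
    }

    if (!all(is.finite(c(S1, V1, I1)))) {
      diverged_at <- n + 1L
      S[(n + 2L):(N + 1L)] <- NA_real_
      V[(n + 2L):(N + 1L)] <- NA_real_
      I[(n + 2L):(N + 1L)] <- NA_real_
      warning(sprintf("%s run diverged (non-finite state) at step %d (t = %g); ",
                      method, n + 1L, (n + 1L) * h),
              "remaining steps set to NA", call. = FALSE)
      break
    }
    neg <- c(S1, V1, I1) < 0
    if (any(neg)) {
      viol_step <- c(viol_step, rep.int(n + 1L, sum(neg)))
      viol_comp <- c(viol_comp, c("S", "V", "I")[neg])
    }
    S[n + 2L] <- S1; V[n + 2L] <- V1; I[n + 2L] <- I1
  }

  structure(
    list(times = (0:N) * h, S = S, V = V, I = I,
         method = method, seed = attr(noise, "seed"),
         positivity_violations = data.frame(step = viol_step,
                                            component = viol_comp,
                                            stringsAsFactors = FALSE),
         diverged_at = diverged_at,
         params = p, grid = grid, noise = noise),
    class = "svir_trajectory")
}

#' @export
print.svir_trajectory <- function(x, ...) {
  cat(sprintf("SVIR trajectory: method=%s, T=%g, h=%g (%d steps), seed=%s\n",
              x$method, x$grid$T, x$grid$h, x$grid$n_steps,
              ifelse(is.na(x$seed), "none", x$seed)))
  ok <- !is.na(x$S)
  cat(sprintf("  final state: S=%.5f V=%.5f I=%.5g\n",
              x$S[max(which(ok))], x$V[max(which(ok))], x$I[max(which(ok))]))
  nv <- nrow(x$positivity_violations)
  if (nv) cat("  positivity violations:", nv, "\n")
  if (!is.na(x$diverged_at)) cat("  diverged at step", x$diverged_at, "\n")
  invisible(x)
}

#' @export
as.data.frame.svir_trajectory <- function(x, ...) {
  data.frame(t = x$times, S = x$S, V = x$V, I = x$I,
             method = x$method, seed = x$seed)
}

#' Ensemble of seeded simulations
#'
#' Runs `n_paths` independent realizations of the chosen scheme, path
#' `k` seeded with `base_seed + k - 1`, and summarizes them pointwise.
#'
#' @inheritParams deterministic_simulate
#' @param n_paths Number of realizations (`>= 1`).
#' @param base_seed Integer seed of the first path.
#' @param probs Quantile levels for the pointwise summary.
#' @return A list of class `svir_ensemble`: `paths` (list of
#'   trajectories) and `summary`, a data frame with time and pointwise
#'   mean and quantiles of S, V and I.
#' @export
ensemble_run <- function(p, grid, history, method = c("ssstnsfd", "sstm"),
                         n_paths, base_seed,
                         probs = c(0.025, 0.5, 0.975)) {
  method <- match.arg(method)
  stopifnot(n_paths >= 1)
  sim <- if (method == "sstm") sstm_simulate else ssstnsfd_simulate
  paths <- lapply(seq_len(n_paths), function(k) {
    sim(p, grid, history, svir_noise(grid, base_seed + k - 1L))
  })
  comp_summary <- function(comp) {
    m <- vapply(paths, function(tr) tr[[comp]], numeric(grid$n_steps + 1L))
    out <- data.frame(rowMeans(m))
    names(out) <- paste0("mean_", comp)
    for (q in probs)
      out[[sprintf("q%g_%s", 100 * q, comp)]] <-
        apply(m, 1, stats::quantile, probs = q, na.rm = TRUE)
    out
  }
  summary <- cbind(data.frame(t = paths[[1]]$times),
                   comp_summary("S"), comp_summary("V"), comp_summary("I"))
  structure(list(paths = paths, summary = summary, method = method,
                 base_seed = base_seed),
            class = "svir_ensemble")
}

#' Write a trajectory to CSV
#'
#' Columns `t, S, V, I, method, seed`, full double precision
#' (round-trips through `read_trajectory()` exactly).
#'
#' @param traj An `svir_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  for (cc in c("t", "S", "V", "I"))
    df[[cc]] <- formatC(df[[cc]], format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot an SVIR trajectory
#'
#' Overlays the three compartments over time; if `deterministic` is
#' supplied its paths are drawn dashed for comparison.
#'
#' @param x An `svir_trajectory`.
#' @param deterministic Optional second trajectory (typically from
#'   [deterministic_simulate()]) drawn dashed.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.svir_trajectory <- function(x, deterministic = NULL, ...) {
  graphics::matplot(x$times, cbind(x$S, x$V, x$I), type = "l", lty = 1,
                    col = c("steelblue", "darkgreen", "firebrick"),
                    xlab = "time", ylab = "density",
                    main = sprintf("SVIR (%s)", x$method), ...)
  if (!is.null(deterministic))
    graphics::matlines(deterministic$times,
                       cbind(deterministic$S, deterministic$V, deterministic$I),
                       lty = 2, col = c("steelblue", "darkgreen", "firebrick"))
  graphics::legend("topright", c("S", "V", "I"), lty = 1,
                   col = c("steelblue", "darkgreen", "firebrick"), bty = "n")
  invisible(x)
}
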