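#' Simulation grid for the delayed SVIR schemes
#'
#' Both schemes are defined on a uniform grid over `[0, T]` whose step
#' `h` must divide the horizon and both delays: the integer offsets
#' `m1 = tau1/h` and `m2 = tau2/h` index the delayed states directly.
#' Non-commensurate `h` is an error, never silently rounded.
#'
#' @param T Positive time horizon.
#' @param h Positive step size; `T/h`, `tau1/h`, `tau2/h` must be
#'   integers (relative tolerance `1e-9`).
#' @param p An `svir_params` object supplying `tau1`, `tau2`.
#' @return An object of class `svir_grid` with fields `T`, `h`,
#'   `n_steps`, `m1`, `m2`.
#' @export
svir_grid <- function(T, h, p) {
  if (!is.finite(T) || T <= 0) stop("T must be a positive finite horizon")
  if (!is.finite(h) || h <= 0) stop("h must be a positive step size")
  as_int <- function(x, what) {
    n <- round(x)
    if (n < 1 || abs(x - n) > 1e-9 * max(1, abs(x)))
      stop(what, "/h = ", format(x), " is not a positive integer: ",
           "the scheme requires a commensurate grid")
    as.integer(n)
  }
  structure(
    list(T = T, h = h,
         n_steps = as_int(T / h, "T"),
         m1 = as_int(p$tau1 / h, "tau1"),
         m2 = as_int(p$tau2 / h, "tau2")),
    class = "svir_grid")
}

#' Initial history for the delay equations
#'
#' The model needs the state on `[-max(tau1, tau2), 0]`.  A length-3
#' positive numeric vector `(S, V, I)` gives the constant extension of
#' the initial point (the default reading when only initial values are
#' given); alternatively a function `f(t)` returning a positive triple
#' for `t` in `[-max(tau), 0]` specifies a full history.
#'
#' @param values Either `c(S, V, I)` (all `> 0`; `I = 0` is allowed so
#'   the disease-free axis can be simulated exactly) or a function of
#'   time.
#' @return An object of class `svir_history`.
#' @export
svir_history <- function(values = c(S = 0.3, V = 0.3, I = 0.2)) {
  if (is.function(values)) {
    return(structure(list(mode = "function", fn = values),
                     class = "svir_history"))
  }
  values <- as.numeric(values)
  if (length(values) != 3 || !all(is.finite(values)))
    stop("constant history must be a finite numeric triple (S, V, I)")
  if (values[1] <= 0 || values[2] <= 0 || values[3] < 0)
    stop("history must have S > 0, V > 0, I >= 0")
  structure(list(mode = "constant", values = values), class = "svir_history")
}

history_at <- function(history, t) {
  if (history$mode == "constant") return(history$values)
  v <- as.numeric(history$fn(t))
  if (length(v) != 3 || !all(is.finite(v)) || v[1] <= 0 || v[2] <= 0 || v[3] < 0)
    stop("history function must return a positive triple at t = ", t)
  v
}

#' Seeded Brownian increments for a simulation
#'
#' Draws the full table of Gaussian increments `dW[i, n] = sqrt(h) *
#' xi[i, n]`, `xi ~ N(0, 1)` independent over components `i = 1..3`
#' (S, V, I noise) and steps `n`.  The per-step draw order is fixed
#' (dW1, dW2, dW3) so the two schemes can be driven by identical noise
#' for coupled comparisons, and a given seed always reproduces the same
#' table.
#'
#' @param grid An `svir_grid`.
#' @param seed Integer RNG seed.
#' @return An object of class `svir_noise`: a `3 x n_steps` matrix of
#'   increments with attributes `seed` and `h`.
#' @export
svir_noise <- function(grid, seed) {
  stopifnot(inherits(grid, "svir_grid"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dW <- matrix(stats::rnorm(3L * grid$n_steps, sd = sqrt(grid$h)),
               nrow = 3L, ncol = grid$n_steps)
  structure(dW, seed = as.integer(seed), h = grid$h, class = "svir_noise")
}

zero_noise <- function(grid) {
  structure(matrix(0, nrow = 3L, ncol = grid$n_steps),
            seed = NA_integer_, h = grid$h, class = "svir_noise")
}

#' Mickens denominator function
#'
#' The nonstandard finite difference scheme replaces the raw step `h`
#' by `v(h) = 1 - exp(-h)`, which satisfies `v(h) = h + O(h^2)` and
#' `0 < v(h) < 1` for every `h > 0`.  This bounded denominator is what
#' lets the scheme remain positive and stable at arbitrarily large
#' steps.
#'
#' @param h Positive step size.
#' @return `1 - exp(-h)`.
#' @export
nsfd_denominator <- function(h) {
  if (any(!is.finite(h)) || any(h <= 0)) stop("h must be positive")
  1 - exp(-h)
}

#' Split-step interpolation of a delayed state
#'
#' The delayed value at lag `m*h` behind step `n` is approximated by the
#' convex combination `theta * x[n-m+1] + (1-theta) * x[n-m]`.  Indices
#' at or before time zero resolve through the history.
#'
#' `series` is the full state array indexed so that position `k+1`
#' holds the value at time `k*h` for `k = 0..n`; earlier times come
#' from `history` (component `comp`: 1 = S, 2 = V, 3 = I).
#'
#' @param series Numeric vector of on-grid values from time 0 onward.
#' @param n Current step index (value at `n*h` is `series[n+1]`).
#' @param m Integer delay offset.
#' @param theta Weight in \[0, 1\].
#' @param history An `svir_history`.
#' @param comp Component index into the history triple.
#' @param h Step size (to convert negative indices to times).
#' @return The interpolated delayed value.
#' @export
delayed_value <- function(series, n, m, theta, history, comp, h) {
  at <- function(k) {
    if (k >= 0) {
      if (k + 1L > length(series)) stop("delay index beyond computed series")
      series[k + 1L]
    } else {
      history_at(history, k * h)[comp]
    }
  }
  theta * at(n - m + 1L) + (1 - theta) * at(n - m)
}
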