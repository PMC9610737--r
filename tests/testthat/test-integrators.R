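test_that("one Milstein step matches the hand-evaluated update", {
  p <- params_nonoise(beta1 = 10.5, beta2 = 5.5)
  g <- svir_grid(0.1, 0.1, p)
  tr <- sstm_simulate(p, g, hist_default())
  # S1 = 0.3 + (1 - 11*0.3 + 1.5*exp(-1)*0.2 - 0.63/1.144) * 0.1
  S1 <- 0.3 + (1 - 11 * 0.3 + 1.5 * exp(-1) * 0.2 - 0.63 / 1.144) * 0.1
  expect_equal(tr$S[2], S1, tolerance = 1e-14)
  expect_equal(tr$S[2], 0.02596645, tolerance = 1e-6)
  # V1 uses the freshly computed S1 in the inflow term
  V1 <- 0.3 + (10 * S1 - 3.4 * 0.3 + 2.4 * exp(-2) * 0.3 - 0.33 / 1.166) * 0.1
  expect_equal(tr$V[2], V1, tolerance = 1e-14)
  # I1 pairs S1, V1 with I0 inside the incidence fractions
  f1 <- 10.5 * S1 * 0.2 / (1 + 0.2 * S1 + 0.3 * 0.2 + 0.4 * S1 * 0.2)
  f2 <- 5.5 * V1 * 0.2 / (1 + 0.4 * V1 + 0.2 * 0.2 + 0.1 * V1 * 0.2)
  expect_equal(tr$I[2], 0.2 + (f1 + f2 - 2.5 * 0.2) * 0.1, tolerance = 1e-14)
})

test_that("one NSFD step matches the hand-evaluated update", {
  p <- params_nonoise(beta1 = 10.5, beta2 = 5.5)
  g <- svir_grid(0.1, 0.1, p)
  tr <- ssstnsfd_simulate(p, g, hist_default())
  v <- 1 - exp(-0.1)
  S1 <- (0.3 + (1 + 1.5 * exp(-1) * 0.2) * v) /
    (1 + (11 + 10.5 * 0.2 / 1.144) * v)
  expect_equal(tr$S[2], S1, tolerance = 1e-14)
  expect_equal(tr$S[2], 0.1826107, tolerance = 1e-7)
  V1 <- (0.3 + (10 * S1 + 2.4 * exp(-2) * 0.3) * v) /
    (1 + (3.4 + 5.5 * 0.2 / 1.166) * v)
  expect_equal(tr$V[2], V1, tolerance = 1e-14)
  inc <- 10.5 * S1 / (1 + 0.2 * S1 + 0.3 * 0.2 + 0.4 * S1 * 0.2) +
    5.5 * V1 / (1 + 0.4 * V1 + 0.2 * 0.2 + 0.1 * V1 * 0.2)
  expect_equal(tr$I[2], 0.2 * (1 + inc * v) / (1 + 2.5 * v), tolerance = 1e-14)
})

test_that("zero transmission reduces the infection to a scalar recursion", {
  p <- params_nonoise(beta1 = 0, beta2 = 0)
  g <- svir_grid(5, 0.1, p)
  n <- 0:g$n_steps
  tr_m <- sstm_simulate(p, g, hist_default())
  expect_equal(tr_m$I, 0.2 * (1 - 2.5 * 0.1)^n, tolerance = 1e-13)
  tr_n <- ssstnsfd_simulate(p, g, hist_default())
  expect_equal(tr_n$I, 0.2 / (1 + 2.5 * nsfd_denominator(0.1))^n,
               tolerance = 1e-13)
})

test_that("identical seed and inputs give bit-identical trajectories", {
  p <- params_base(beta1 = 14, beta2 = 7)
  g <- svir_grid(10, 0.1, p)
  a <- sstm_simulate(p, g, hist_default(), svir_noise(g, 5))
  b <- sstm_simulate(p, g, hist_default(), svir_noise(g, 5))
  expect_identical(a$S, b$S); expect_identical(a$V, b$V)
  expect_identical(a$I, b$I)
  c1 <- ssstnsfd_simulate(p, g, hist_default(), svir_noise(g, 5))
  c2 <- ssstnsfd_simulate(p, g, hist_default(), svir_noise(g, 5))
  expect_identical(c1$I, c2$I)
})

test_that("the disease-free axis is invariant for both schemes", {
  p <- params_base(beta1 = 14, beta2 = 7)
  g <- svir_grid(20, 0.1, p)
  hist0 <- svir_history(c(0.3, 0.3, 0))
  noise <- svir_noise(g, 3)
  for (sim in list(sstm_simulate, ssstnsfd_simulate)) {
    tr <- sim(p, g, hist0, noise)
    expect_identical(tr$I, rep(0, g$n_steps + 1L))
  }
})

test_that("deterministic mode holds the disease-free equilibrium", {
  p <- params_base(beta1 = 14, beta2 = 7)
  k <- derived_constants(p)
  g <- svir_grid(100, 0.1, p)   # 1000 steps
  e0 <- svir_history(c(k$S0_dfe, k$V0_dfe, 0))
  for (m in c("sstm", "ssstnsfd")) {
    tr <- deterministic_simulate(p, g, e0, m)
    expect_lt(max(abs(tr$S - k$S0_dfe)), 1e-10)
    expect_lt(max(abs(tr$V - k$V0_dfe)), 1e-10)
    expect_identical(tr$I, rep(0, g$n_steps + 1L))
  }
})

test_that("deterministic mode equals a zero-noise, zero-sigma run", {
  p <- params_base(beta1 = 14, beta2 = 7)
  p0 <- p; p0$sigma1 <- p0$sigma2 <- p0$sigma3 <- 0
  g <- svir_grid(10, 0.1, p)
  det <- deterministic_simulate(p, g, hist_default(), "sstm")
  man <- sstm_simulate(p0, g, hist_default())
  expect_identical(det$S, man$S)
  expect_identical(det$I, man$I)
})

test_that("noise-free NSFD stays strictly positive for any step size", {
  hist <- hist_default()
  for (h in c(0.01, 0.1, 0.5, 1)) {
    p <- params_nonoise(beta1 = 14, beta2 = 7)
    tr <- deterministic_simulate(p, svir_grid(100, h, p), hist, "ssstnsfd")
    expect_gt(min(tr$S, tr$V, tr$I), 0)
    expect_identical(nrow(tr$positivity_violations), 0L)
  }
  # h = 5 needs delays commensurate with the step
  p5 <- params_nonoise(beta1 = 14, beta2 = 7, tau1 = 5, tau2 = 10)
  tr5 <- deterministic_simulate(p5, svir_grid(100, 5, p5), hist, "ssstnsfd")
  expect_gt(min(tr5$S, tr5$V, tr5$I), 0)
})

test_that("both schemes converge to each other as the step is refined", {
  p <- params_nonoise(beta1 = 14, beta2 = 7)
  hist <- hist_default()
  gap <- vapply(c(0.1, 0.05, 0.025, 0.0125), function(h) {
    g <- svir_grid(10, h, p)
    a <- deterministic_simulate(p, g, hist, "sstm")
    b <- deterministic_simulate(p, g, hist, "ssstnsfd")
    max(abs(c(a$S - b$S, a$V - b$V, a$I - b$I)))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))      # monotone decrease under refinement
  expect_lt(gap[4], gap[1] / 8)        # roughly first-order shrinkage
})

test_that("schemes driven by shared noise agree closely at a fine step", {
  p <- params_base(beta1 = 14, beta2 = 7)
  g <- svir_grid(10, 0.01, p)
  n <- svir_noise(g, 3)
  a <- sstm_simulate(p, g, hist_default(), n)
  b <- ssstnsfd_simulate(p, g, hist_default(), n)
  # empirical gap at this step is ~0.011; frozen ceiling leaves headroom
  expect_lt(max(abs(c(a$S - b$S, a$V - b$V, a$I - b$I))), 0.05)
})

test_that("a diverging Milstein run is truncated and flagged, not hidden", {
  p <- params_nonoise(beta1 = 14, beta2 = 7)
  g <- svir_grid(400, 1, p)  # |1 - (mu+alpha)h| = 10: explosive recursion
  expect_warning(tr <- sstm_simulate(p, g, hist_default()), "diverged")
  expect_false(is.na(tr$diverged_at))
  expect_true(anyNA(tr$S))
  expect_gt(nrow(tr$positivity_violations), 0)
  # values before the divergence step are retained
  expect_false(anyNA(tr$S[seq_len(tr$diverged_at)]))
})

test_that("mismatched noise tables are rejected", {
  p <- params_base()
  g1 <- svir_grid(10, 0.1, p)
  g2 <- svir_grid(20, 0.1, p)
  expect_error(sstm_simulate(p, g1, hist_default(), svir_noise(g2, 1)),
               "does not match the grid")
  gh <- svir_grid(10, 0.5, p)
  n_wrong_h <- svir_noise(gh, 1)
  g3 <- svir_grid(5, 0.25, p)
  expect_error(ssstnsfd_simulate(p, g3, hist_default(), n_wrong_h),
               "different step size|does not match")
})

test_that("ensembles derive per-path seeds and reduce correctly", {
  p <- params_base(beta1 = 10.5, beta2 = 5.5)
  g <- svir_grid(5, 0.1, p)
  ens <- ensemble_run(p, g, hist_default(), "ssstnsfd", 3, base_seed = 11)
  expect_length(ens$paths, 3)
  # path 1 reproduces a direct call with the derived seed
  direct <- ssstnsfd_simulate(p, g, hist_default(), svir_noise(g, 11))
  expect_identical(ens$paths[[1]]$I, direct$I)
  expect_identical(ens$paths[[2]]$seed, 12L)
  # sigma = 0: all paths identical, mean equals the single path
  p0 <- params_nonoise(beta1 = 10.5, beta2 = 5.5)
  e0 <- ensemble_run(p0, g, hist_default(), "ssstnsfd", 4, base_seed = 1)
  expect_identical(e0$paths[[1]]$S, e0$paths[[4]]$S)
  expect_equal(e0$summary$mean_I, e0$paths[[1]]$I, tolerance = 1e-15)
})

test_that("trajectory CSV round-trips at full precision", {
  p <- params_base(beta1 = 14, beta2 = 7)
  g <- svir_grid(2, 0.1, p)
  tr <- ssstnsfd_simulate(p, g, hist_default(), svir_noise(g, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(nrow(back), g$n_steps + 1L)
  expect_identical(names(back), c("t", "S", "V", "I", "method", "seed"))
  expect_identical(back$S, tr$S)
  expect_identical(back$I, tr$I)
})
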