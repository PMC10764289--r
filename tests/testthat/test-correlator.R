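# Multi-tau correlator against the definitional brute-force estimator and
# its statistical invariants.

test_that("multi-tau equals the brute-force estimator at unrebinned lags", {
  set.seed(21)
  n <- 1e4
  a <- rpois(n, 3)
  b <- pmax(0, a + rpois(n, 2) - 2) # correlated channels
  tr <- photon_trace(a, b, bin_width = 10)
  for (kind in c("auto_green", "cross")) {
    cv <- multi_tau_correlate(tr, kind, m = 16, n_segments = 1)
    direct <- brute_force_correlate(
      if (kind == "cross") a else a,
      if (kind == "cross") b else a,
      1:32)
    expect_equal(cv$g[1:32], direct, tolerance = 1e-12)
    expect_equal(cv$lags[1:32], (1:32) * 10)
  }
})

test_that("constant signal has zero correlation at all lags", {
  tr <- photon_trace(rep(5L, 4096), rep(3L, 4096), bin_width = 10)
  cv <- multi_tau_correlate(tr, "auto_green", n_segments = 1)
  expect_true(all(abs(cv$g) < 1e-12))
})

test_that("zero-mean channel is rejected, short traces are rejected", {
  tr <- photon_trace(rep(0L, 4096), rpois(4096, 2), bin_width = 10)
  expect_error(multi_tau_correlate(tr, "auto_green"), "zero-mean")
  expect_error(multi_tau_correlate(tr, "cross"), "zero-mean")
  tr2 <- photon_trace(rpois(40, 2), rpois(40, 2), bin_width = 10)
  expect_error(multi_tau_correlate(tr2, "auto_green"), "too short")
})

test_that("autocorrelation is invariant under time reversal", {
  set.seed(22)
  mix <- equilibrium_mixture(80, 0, Inf, triplet_fraction = 0)
  # power-of-two bin count keeps pairwise rebinning aligned under reversal
  tr <- simulate_fccs_trace(mix, test_green_vol(), test_red_vol(),
                            simulation_box(2, 50, 0.4096, seed = 23))
  rev_tr <- photon_trace(rev(tr$counts_green), rev(tr$counts_red),
                         tr$bin_width)
  c1 <- multi_tau_correlate(tr, "auto_green", n_segments = 1)
  c2 <- multi_tau_correlate(rev_tr, "auto_green", n_segments = 1)
  expect_equal(c1$g, c2$g, tolerance = 1e-12)
})

test_that("cross-correlation of a trace with itself equals its autocorrelation", {
  set.seed(24)
  a <- rpois(5000, 4)
  tr <- photon_trace(a, a, bin_width = 10)
  auto <- multi_tau_correlate(tr, "auto_green", n_segments = 5)
  cross <- multi_tau_correlate(tr, "cross", n_segments = 5)
  expect_identical(auto$g, cross$g)
  expect_identical(auto$sigma, cross$sigma)
})

test_that("independent Poisson channels show no spurious cross-correlation", {
  set.seed(25)
  tr <- photon_trace(rpois(2e5, 3), rpois(2e5, 4), bin_width = 10)
  cv <- multi_tau_correlate(tr, "cross", n_segments = 10)
  ok <- abs(cv$g) < 3 * cv$sigma
  expect_gte(mean(ok), 0.95)
})

test_that("amplitude consistency: G(0) ~ 1/(C V_ef N_A) for a single species", {
  gv <- test_green_vol()
  n_expected <- 100 * MOLEC_PER_FL_NM * gv$v_eff
  g0 <- vapply(1:6, function(sd) {
    mix <- equilibrium_mixture(100, 0, Inf, triplet_fraction = 0)
    tr <- simulate_fccs_trace(mix, gv, test_red_vol(),
                              simulation_box(2, 50, 4, seed = 30 + sd))
    cv <- multi_tau_correlate(tr, "auto_green")
    f <- fit_curve(cv, "triplet_diffusion",
                   fixed = list(structure_parameter = 3,
                                triplet_fraction = 0, triplet_tau = 5),
                   max_lag = 16 * half_decay_lag(cv))
    1 / f$par[["n"]]
  }, 0)
  m <- mean(g0)
  se <- sd(g0) / sqrt(length(g0))
  expect_lt(abs(m - 1 / n_expected), 3 * se + 0.02 / n_expected)
})
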