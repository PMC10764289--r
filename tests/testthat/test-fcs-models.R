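# Correlation model evaluation and curve fitting.

test_that("triplet-diffusion model has the stated values and limits", {
  expect_equal(triplet_diffusion_model(0, 2, 100, 0, 5, 5), 0.5)
  expect_equal(triplet_diffusion_model(100, 2, 100, 0, 5, 5),
               0.25 / sqrt(1.04), tolerance = 1e-12)
  expect_lt(triplet_diffusion_model(1e12, 2, 100, 0, 5, 5), 1e-10)
  # monotone decreasing for T = 0
  tau <- 10^seq(-1, 5, length.out = 100)
  g <- triplet_diffusion_model(tau, 2, 100, 0, 5, 5)
  expect_true(all(diff(g) < 0))
  expect_true(all(is.finite(g)) && all(g > 0))
  expect_error(triplet_diffusion_model(1, 2, 100, 1, 5, 5), "singular")
  expect_error(triplet_diffusion_model(1, -2, 100, 0, 5, 5), "positive")
})

test_that("pure diffusion equals triplet model with T = 0", {
  tau <- c(0, 1, 10, 100, 1e4)
  expect_equal(pure_diffusion_model(tau, 3, 50, 4),
               triplet_diffusion_model(tau, 3, 50, 0, 7, 4))
  expect_equal(pure_diffusion_model(0, 3, 50, 4), 1 / 3)
  # S -> infinity removes the axial term: G(tau_D) -> 1/(2N)
  expect_equal(pure_diffusion_model(50, 3, 50, 1e9), 1 / 6,
               tolerance = 1e-9)
})

test_that("noiseless curves are fit back to the generating parameters", {
  lags <- 10^seq(0.3, 4.5, length.out = 60)
  g <- triplet_diffusion_model(lags, 5, 120, 0.12, 4, 3)
  cv <- correlation_curve(lags, g, kind = "auto_green")
  f <- fit_curve(cv, "triplet_diffusion",
                 fixed = list(structure_parameter = 3, triplet_tau = 4))
  expect_true(f$converged)
  expect_equal(f$par[["n"]], 5, tolerance = 1e-6)
  expect_equal(f$par[["tau_d"]], 120, tolerance = 1e-6)
  expect_equal(f$par[["triplet_fraction"]], 0.12, tolerance = 1e-5)

  gp <- pure_diffusion_model(lags, 40, 800, 3)
  fp <- fit_curve(correlation_curve(lags, gp, kind = "cross"),
                  "pure_diffusion", fixed = list(structure_parameter = 3))
  expect_equal(fp$par[["n"]], 40, tolerance = 1e-6)
  expect_equal(fp$par[["tau_d"]], 800, tolerance = 1e-6)
})

test_that("degenerate curves produce failure records, not crashes", {
  lags <- 10^seq(0.3, 3, length.out = 30)
  flat <- correlation_curve(lags, rep(0, 30), kind = "cross")
  f <- fit_curve(flat, "pure_diffusion",
                 fixed = list(structure_parameter = 3))
  expect_false(f$converged)
  expect_true("fit_failure" %in% f$flags)

  tiny <- correlation_curve(lags[1:5], rep(0.1, 5), kind = "cross")
  expect_error(fit_curve(tiny, "triplet_diffusion"), "too few lags")
})

test_that("diffusion time is recovered from simulated single-species traces", {
  gv <- test_green_vol()
  # fast dye-like species: tau_D = w^2 / (4D)
  tau_true <- 0.2^2 / (4 * 400) * 1e6
  tds <- vapply(1:4, function(sd) {
    tr <- simulate_dye_trace(5, "green", gv, test_red_vol(),
                             simulation_box(4, 2, 5, seed = 40 + sd))
    cv <- multi_tau_correlate(tr, "auto_green")
    f <- fit_curve(cv, "triplet_diffusion",
                   max_lag = 16 * half_decay_lag(cv))
    f$par[["tau_d"]]
  }, 0)
  expect_lt(abs(median(tds) - tau_true) / tau_true, 0.15)
})

test_that("fitted N tracks concentration within 10% (median over seeds)", {
  gv <- test_green_vol()
  conc <- 100
  n_true <- conc * MOLEC_PER_FL_NM * gv$v_eff
  ns <- vapply(1:10, function(sd) {
    mix <- equilibrium_mixture(conc, 0, Inf)
    tr <- simulate_fccs_trace(mix, gv, test_red_vol(),
                              simulation_box(2, 50, 4, seed = 50 + sd))
    cv <- multi_tau_correlate(tr, "auto_green")
    f <- fit_curve(cv, "triplet_diffusion",
                   fixed = list(structure_parameter = 3, triplet_tau = 5),
                   max_lag = 16 * half_decay_lag(cv))
    f$par[["n"]]
  }, 0)
  expect_lt(abs(median(ns) - n_true) / n_true, 0.10)
})

test_that("fixing S at the calibration value does not distort tau_D", {
  # on conformant (noiseless) data, fixing S changes tau_D by far less
  # than 5%; on noisy single curves the *free* fit wanders along the
  # S-tau_D ridge, so the free side of the comparison is checked in the
  # asymptotic limit and the fixed side against the known truth
  lags <- 10^seq(0.5, 3.5, length.out = 50)
  g <- triplet_diffusion_model(lags, 0.5, 25, 0.03, 2, 3)
  cv0 <- correlation_curve(lags, g, kind = "auto_green")
  f_free0 <- fit_curve(cv0, "triplet_diffusion",
                       fixed = list(triplet_tau = 2))
  f_fix0 <- fit_curve(cv0, "triplet_diffusion",
                      fixed = list(structure_parameter = 3,
                                   triplet_tau = 2))
  expect_lt(abs(f_free0$par[["tau_d"]] - f_fix0$par[["tau_d"]]) /
              f_fix0$par[["tau_d"]], 0.05)

  # fixed-S fit of a simulated dye trace recovers the true diffusion time
  gv <- test_green_vol()
  tau_true <- 0.2^2 / (4 * 400) * 1e6
  tr <- simulate_dye_trace(6, "green", gv, test_red_vol(),
                           simulation_box(4, 2, 10, seed = 61))
  cv <- multi_tau_correlate(tr, "auto_green")
  f_fix <- fit_curve(cv, "triplet_diffusion",
                     fixed = list(structure_parameter = 3),
                     max_lag = 16 * half_decay_lag(cv))
  expect_lt(abs(f_fix$par[["tau_d"]] - tau_true) / tau_true, 0.05)
})

test_that("adding the triplet term never worsens the fit of blinking data", {
  gv <- test_green_vol()
  tr <- simulate_dye_trace(6, "green", gv, test_red_vol(),
                           simulation_box(4, 2, 5, seed = 62),
                           triplet_fraction = 0.25, triplet_tau = 4)
  cv <- multi_tau_correlate(tr, "auto_green")
  ml <- 16 * half_decay_lag(cv)
  f_trip <- fit_curve(cv, "triplet_diffusion",
                      fixed = list(structure_parameter = 3), max_lag = ml)
  f_pure <- fit_curve(cv, "pure_diffusion",
                      fixed = list(structure_parameter = 3), max_lag = ml)
  expect_lte(f_trip$chi2, f_pure$chi2 * (1 + 1e-8))
})
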