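# TCSPC decay fitting, FRET efficiency and the Forster relation.

test_that("noiseless binned decays are fit back to their parameters", {
  # build an exact model histogram: exponential through the Gaussian IRF
  edges <- seq(0, 25, by = 0.05)
  mids <- head(edges, -1) + 0.025
  tau <- 2.2
  sigma <- 0.1
  dens <- fccsfret:::.emg_density(mids, tau, sigma, 0)
  counts <- round(dens / sum(dens) * 5e6)
  decay <- structure(list(bin_edges = edges, counts = counts,
                          irf_sigma = sigma,
                          total_photons = sum(counts),
                          metadata = list()), class = "tcspc_decay")
  f <- fit_decay(decay, n_components = 1)
  expect_true(f$converged)
  expect_equal(f$components$lifetime, tau, tolerance = 1e-4)
  expect_equal(f$tau_amp, tau, tolerance = 1e-4)
  expect_lt(abs(f$t0), 1e-3)
})

test_that("mono-exponential lifetimes are recovered within 2% at 1e5 photons", {
  for (tau in c(1, 2.41, 4)) {
    fits <- vapply(1:3, function(sd) {
      d <- simulate_tcspc(list(c(1, tau)), 1e5, irf_sigma = 0.1,
                          range = max(25, 10 * tau), seed = 700 + sd)
      fit_decay(d, 1)$tau_amp
    }, 0)
    expect_lt(abs(mean(fits) - tau) / tau, 0.02)
  }
})

test_that("bi-exponential components are separated and ordered", {
  d <- simulate_tcspc(list(c(0.5, 1), c(0.5, 4)), 2e5, irf_sigma = 0.1,
                      range = 40, seed = 710)
  f <- fit_decay(d, 2)
  expect_true(f$converged)
  expect_gt(f$components$lifetime[1], f$components$lifetime[2])
  expect_lt(abs(f$components$lifetime[1] - 4) / 4, 0.10)
  expect_lt(abs(f$components$lifetime[2] - 1) / 1, 0.10)
  expect_lt(abs(f$components$amplitude[1] - 0.5), 0.1)
  expect_true(f$tau_amp >= min(f$components$lifetime) &&
              f$tau_amp <= max(f$components$lifetime))
})

test_that("low-signal and empty decays are flagged, not crashed", {
  d <- simulate_tcspc(list(c(1, 2.5)), 500, seed = 1)
  f <- fit_decay(d, 1)
  expect_true("low_signal" %in% f$flags)
  d0 <- simulate_tcspc(list(c(1, 2.5)), 0, seed = 1)
  f0 <- fit_decay(d0, 1)
  expect_false(f0$converged)
  expect_true("fit_failure" %in% f0$flags)
})

test_that("FRET efficiency follows the lifetime ratio with clipping", {
  expect_equal(as.numeric(fret_efficiency(2.5, 2.5)), 0)
  expect_equal(as.numeric(fret_efficiency(2.25, 2.50)), 0.10)
  e <- fret_efficiency(2.6, 2.5)
  expect_equal(as.numeric(e), 0)
  expect_true(any(attr(e, "clipped")))
  expect_error(fret_efficiency(2, 0), "positive")
  # strictly decreasing in tau_da
  tda <- seq(0.1, 2.4, by = 0.1)
  expect_true(all(diff(as.numeric(fret_efficiency(tda, 2.5))) < 0))
})

test_that("the Forster relation anchors at R0 and is monotone", {
  expect_equal(donor_acceptor_distance(0.5), 52.4)
  expect_equal(donor_acceptor_distance(0.5, 60), 60)
  expect_equal(donor_acceptor_distance(0.10), 52.4 * 9^(1 / 6),
               tolerance = 1e-9)
  expect_lt(donor_acceptor_distance(1 - 1e-12), 1)
  expect_true(is.na(donor_acceptor_distance(0)))
  expect_true(is.na(donor_acceptor_distance(1)))
  e <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(donor_acceptor_distance(e)) < 0))
  expect_error(donor_acceptor_distance(1.2), "within")
})

test_that("distance is below 100 A exactly when E exceeds the inverse threshold", {
  e_star <- 1 / (1 + (100 / 52.4)^6)
  set.seed(72)
  e <- runif(200, 0.001, 0.999)
  r <- donor_acceptor_distance(e)
  expect_identical(r < 100, e > e_star)
})

test_that("ROI analysis recovers simulated quenching within noise", {
  tau_d <- 2.5
  donors <- lapply(1:4, function(sd) {
    simulate_tcspc(list(c(1, tau_d)), 1e5, seed = 720 + sd)
  })
  # null case: ROIs identical to donor-only give E ~ 0
  null_rois <- lapply(1:4, function(sd) {
    simulate_tcspc(list(c(1, tau_d)), 1e5, seed = 730 + sd)
  })
  res0 <- roi_fret_analysis(donors, null_rois)
  expect_lt(mean(res0$efficiency), 0.01)

  e_true <- 0.2
  rois <- lapply(1:4, function(sd) {
    simulate_tcspc(list(c(1, tau_d * (1 - e_true))), 1e5, seed = 740 + sd)
  })
  res <- roi_fret_analysis(donors, rois)
  se <- sd(res$efficiency) / sqrt(nrow(res))
  expect_lt(abs(mean(res$efficiency) - e_true), 3 * se + 0.01)
  expect_true(all(res$detectable))

  expect_error(roi_fret_analysis(list(), rois), "missing donor-only")
})
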