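# Generator module: mass-action equilibrium, Brownian photon traces, TCSPC
# decays, reporter cell grids.

test_that("equilibrium mixture solves the binding quadratic", {
  m <- equilibrium_mixture(300, 400, 600)
  expect_equal(m$complex, 100, tolerance = 1e-12)
  # back-substitution oracle: free concentrations reproduce the K_d
  expect_equal(m$free_green * m$free_red / m$complex, 600,
               tolerance = 1e-9)

  expect_equal(equilibrium_mixture(200, 500, 0)$complex, 200)
  expect_equal(equilibrium_mixture(200, 500, Inf)$complex, 0)

  expect_error(equilibrium_mixture(-1, 10, 100), "non-negative")
  expect_error(equilibrium_mixture(10, 10, -5), "kd_true")
})

test_that("mass-action residual is tiny across random mixtures", {
  set.seed(41)
  for (i in 1:200) {
    g <- runif(1, 1, 3000)
    r <- runif(1, 1, 3000)
    kd <- 10^runif(1, -1, 4)
    m <- equilibrium_mixture(g, r, kd)
    expect_lt(abs((m$free_green * m$free_red / m$complex) - kd) / kd, 1e-6)
    expect_true(all(c(m$free_green, m$free_red, m$complex) >= 0))
    expect_lte(m$complex, min(g, r))
  }
})

test_that("empty mixtures give all-zero traces and identical seeds give identical traces", {
  gv <- test_green_vol()
  rv <- test_red_vol()
  box <- simulation_box(2, 50, 0.5, seed = 5)
  tr0 <- simulate_fccs_trace(equilibrium_mixture(0, 0, 100), gv, rv, box)
  expect_true(all(tr0$counts_green == 0))
  expect_true(all(tr0$counts_red == 0))
  expect_equal(length(tr0$counts_green), 10000)

  mix <- equilibrium_mixture(100, 100, 500)
  t1 <- simulate_fccs_trace(mix, gv, rv, simulation_box(2, 50, 0.5, seed = 7))
  t2 <- simulate_fccs_trace(mix, gv, rv, simulation_box(2, 50, 0.5, seed = 7))
  expect_identical(t1$counts_green, t2$counts_green)
  expect_identical(t1$counts_red, t2$counts_red)
  t3 <- simulate_fccs_trace(mix, gv, rv, simulation_box(2, 50, 0.5, seed = 8))
  expect_false(identical(t1$counts_green, t3$counts_green))
})

test_that("a too-small box is rejected", {
  gv <- test_green_vol()
  rv <- test_red_vol()
  expect_error(
    simulate_fccs_trace(equilibrium_mixture(10, 10, 100), gv, rv,
                        simulation_box(1.5, 25, 0.1, seed = 1)),
    "box side")
})

test_that("mean count rates match the analytic expectation over seeds", {
  gv <- test_green_vol()
  rv <- test_red_vol()
  mix <- equilibrium_mixture(150, 100, 400, triplet_fraction = 0.15)
  expected_g <- expected_count_rate(150, mix$brightness_green, gv$v_eff,
                                    0.15)
  expected_r <- expected_count_rate(100, mix$brightness_red, rv$v_eff, 0.15)
  rates <- t(vapply(1:10, function(sd) {
    tr <- simulate_fccs_trace(mix, gv, rv,
                              simulation_box(2, 50, 1, seed = 100 + sd))
    c(sum(tr$counts_green) / tr$duration, sum(tr$counts_red) / tr$duration)
  }, c(0, 0)))
  for (j in 1:2) {
    m <- mean(rates[, j])
    se <- sd(rates[, j]) / sqrt(nrow(rates))
    expect_lt(abs(m - c(expected_g, expected_r)[j]), 3 * se)
  }
})

test_that("triplet telegraph occupancy converges to the stationary fraction", {
  occ <- telegraph_occupancy(0.15, 5, 0.5, 10, seed = 3)
  expect_lt(abs(occ - 0.15), 0.01 * 0.15 + 0.005)
  occ2 <- telegraph_occupancy(0.3, 2, 0.5, 10, seed = 4)
  expect_lt(abs(occ2 - 0.3), 0.01)
})

test_that("TCSPC simulation has the right arrival statistics", {
  # single component: sample mean arrival ~ tau within 3 s.e.
  d <- simulate_tcspc(list(c(1, 2.5)), 1e5, irf_sigma = 1e-9, range = 40,
                      seed = 11)
  mids <- (head(d$bin_edges, -1) + d$bin_edges[-1]) / 2
  mbar <- sum(mids * d$counts) / sum(d$counts)
  se <- 2.5 / sqrt(sum(d$counts))
  expect_lt(abs(mbar - 2.5), 3 * se + 0.01)

  # two equal components: per-component photon shares ~ 0.5 each
  set.seed(12)
  idx <- sample.int(2, 2e4, replace = TRUE, prob = c(0.5, 0.5))
  expect_lt(abs(mean(idx == 1) - 0.5), 3 * sqrt(0.25 / 2e4))
  d2 <- simulate_tcspc(list(c(0.5, 1), c(0.5, 4)), 2e4, seed = 12)
  mids2 <- (head(d2$bin_edges, -1) + d2$bin_edges[-1]) / 2
  mbar2 <- sum(mids2 * d2$counts) / sum(d2$counts)
  expect_lt(abs(mbar2 - 2.5), 0.1) # mixture mean 0.5*1 + 0.5*4

  # empty decay is valid and flagged
  d0 <- simulate_tcspc(list(c(1, 2.5)), 0, seed = 1)
  expect_true(all(d0$counts == 0))
  expect_true(d0$metadata$empty)

  expect_error(simulate_tcspc(list(c(0.7, 1), c(0.7, 4)), 10), "sum to 1")
  expect_error(simulate_tcspc(list(c(1, -2)), 10), "positive")
})

test_that("cell grid distances come from adjacency and activity drives calls", {
  clone <- cbind(rep(1, 4), 1:4)
  g <- generate_cell_grid(6, 4, clone, c("1" = 1.0), seed = 2)
  expect_true(all(g$row_distance[g$is_clone] == 0))
  expect_true(all(xor(g$is_clone, g$row_distance > 0)))
  # full clone row: distance equals row offset
  expect_equal(g$row_distance, g$row - 1L)

  act <- ktr_activity(g$nuclear_intensity, g$cytoplasmic_intensity)
  expect_true(all(act$active[g$row_distance == 1]))

  g0 <- generate_cell_grid(6, 4, clone, c("1" = 0, "2" = 0), seed = 2)
  act0 <- ktr_activity(g0$nuclear_intensity, g0$cytoplasmic_intensity)
  expect_false(any(act0$active[!g0$is_clone]))

  expect_error(generate_cell_grid(6, 4, cbind(7, 1), c("1" = 1)),
               "clone outside grid")
})

test_that("step activity profile is recovered within binomial error", {
  clone <- cbind(rep(1, 30), 1:30)
  prof_p <- c("1" = 0.8, "2" = 0.8, "3" = 0.8, "4" = 0.8, "5" = 0.8,
              "6" = 0.1, "7" = 0.1)
  # pool several grids per row so the check tests the generator's
  # calibration rather than one binomial draw
  profs <- lapply(1:5, function(sd) {
    g <- generate_cell_grid(8, 30, clone, prof_p, seed = sd)
    paracrine_profile(g, max_rows = 5)
  })
  for (i in 1:5) {
    n <- sum(vapply(profs, function(pr) pr$n_cells[i], 0))
    k <- sum(vapply(profs, function(pr) pr$n_active[i], 0))
    p <- 0.8
    ci <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(k / n - p), ci + 1e-9)
  }
})
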