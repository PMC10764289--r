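# Concentration and K_d equations, exclusion, aggregation, rescaling,
# binning, and the end-to-end recovery property.

test_that("channel concentration converts molecule numbers through V_ef", {
  expect_equal(channel_concentration(1, 0.65), 2.5547, tolerance = 1e-4)
  expect_equal(channel_concentration(2, 0.65),
               2 * channel_concentration(1, 0.65))
  expect_lt(channel_concentration(1, 1e9), 1e-8)
  expect_error(channel_concentration(1, 0), "positive")
})

test_that("complex concentration follows the amplitude-reciprocal reading", {
  expect_equal(complex_concentration(4, 5, 10, 0.65), 5.1093,
               tolerance = 1e-4)
  n <- 7
  expect_equal(complex_concentration(n, n, n, 0.65),
               channel_concentration(n, 0.65))
  expect_lt(complex_concentration(4, 5, 1e12, 0.65), 1e-9)
  expect_error(complex_concentration(4, 5, 0, 0.65), "cross-correlation")
})

test_that("the K_d equation and its round trips hold", {
  expect_equal(dissociation_constant(300, 400, 100), 600)
  expect_equal(dissociation_constant(50, 50, 50), 0)
  m <- equilibrium_mixture(300, 400, 600)
  expect_equal(dissociation_constant(m$total_green, m$total_red, m$complex),
               600, tolerance = 1e-9)
  expect_error(dissociation_constant(300, 400, 0), "lower bound")
  expect_warning(kd <- dissociation_constant(100, 200, 150), "clipping")
  expect_equal(as.numeric(kd), 0) # clipped to c_green
})

test_that("K_d inverts the equilibrium mixture across random truths", {
  set.seed(91)
  for (i in 1:100) {
    g <- runif(1, 10, 2000)
    r <- runif(1, 10, 2000)
    kd <- 10^runif(1, 0, 4)
    m <- equilibrium_mixture(g, r, kd)
    expect_equal(dissociation_constant(g, r, m$complex), kd,
                 tolerance = 1e-6)
  }
})

test_that("exclusion rule partitions strictly above the threshold", {
  mk <- function(cg, cr) {
    structure(list(c_green = cg, c_red = cr, kd = 100, kd_is_bound = FALSE,
                   excluded = FALSE, exclusion_reason = NA_character_,
                   flags = character(0)),
              class = "fccs_measurement")
  }
  ms <- list(mk(2500, 100), mk(1999, 1999), mk(2000, 2000), mk(100, 2100))
  part <- apply_exclusion(ms)
  expect_equal(length(part$excluded), 2)
  expect_equal(length(part$retained), 2)
  expect_true(all(vapply(part$excluded, function(m) m$excluded, TRUE)))
  # boundary 2000 exactly is retained
  expect_true(any(vapply(part$retained,
                         function(m) m$c_green == 2000, TRUE)))
  part_both <- apply_exclusion(ms, rule = "both")
  expect_equal(length(part_both$excluded), 0)
  empty <- apply_exclusion(list())
  expect_equal(length(empty$retained), 0)
  expect_equal(length(empty$excluded), 0)
})

test_that("aggregation averages finite estimates and keeps bounds apart", {
  mk <- function(kd, bound = FALSE) {
    structure(list(c_green = 100, c_red = 100, kd = kd,
                   kd_is_bound = bound, excluded = FALSE,
                   flags = character(0)),
              class = "fccs_measurement")
  }
  agg <- aggregate_kd(list(mk(400), mk(440), mk(480)))
  expect_equal(agg$mean, 440)
  expect_equal(agg$sd, 40)
  expect_equal(agg$n, 3)

  single <- aggregate_kd(list(mk(500)))
  expect_true(is.na(single$sd))

  mixed <- aggregate_kd(list(mk(400), mk(9301, bound = TRUE), mk(440)))
  expect_equal(mixed$mean, 420)
  expect_equal(mixed$n_bounds, 1)
  expect_equal(mixed$min_bound, 9301)
})

test_that("relative affinity maps the anchors to 0 and 100 and is linear in 1/Kd", {
  expect_equal(relative_affinity(229, 9301, 229), 100)
  expect_equal(relative_affinity(9301, 9301, 229), 0)
  a_mid <- 2 / (1 / 229 + 1 / 9301) # Kd whose 1/Kd is the anchor midpoint
  expect_equal(relative_affinity(a_mid, 9301, 229), 50, tolerance = 1e-9)
  s <- relative_affinity(0, 9301, 229)
  expect_equal(as.numeric(s), 100)
  expect_true(any(attr(s, "saturated")))
  expect_error(relative_affinity(100, 500, 500), "distinct")
})

test_that("K_d binning yields percentages that sum to 100", {
  b <- bin_kd(c(100, 150, 180), c(0, 200, 400))
  expect_equal(b$percent, c(100, 0))
  set.seed(92)
  kds <- runif(50, 0, 1500)
  b2 <- bin_kd(kds, c(0, 250, 500, 1000, 1500))
  expect_equal(sum(b2$percent), 100, tolerance = 1e-9)
  expect_equal(sum(b2$count), 50)
  expect_error(bin_kd(kds, c(0, 500, 400)), "increasing")
})

test_that("K_d estimate is invariant under channel relabelling", {
  m1 <- simulate_and_analyze(500, seed = 333, total_green = 150,
                             total_red = 250, duration = 4)
  # same physical system with the labels swapped: swap totals and channels
  mix <- equilibrium_mixture(250, 150, 500)
  tr <- simulate_fccs_trace(mix, test_green_vol(), test_red_vol(),
                            simulation_box(2, 50, 4, seed = 333))
  m2 <- analyze_fccs_trace(tr, cached_calibration(), triplet_tau = 5)
  # identical-by-symmetry estimators, independent noise realizations:
  # both must land near the common truth
  expect_lt(abs(m1$kd - 500) / 500, 0.5)
  expect_lt(abs(m2$kd - 500) / 500, 0.5)
})

test_that("full pipeline recovers K_d across the affinity range (median over seeds)", {
  cal <- cached_calibration()
  # the weak binder's cross amplitude is a few-fold above the noise floor
  # only over a full recording, so it gets the standard 10 s; the tighter
  # binders are comfortably detectable on short traces
  for (kd_true in c(100, 500, 2000)) {
    dur <- if (kd_true >= 2000) 10 else 4
    kds <- vapply(1:20, function(sd) {
      m <- simulate_and_analyze(kd_true, seed = 4000 + sd,
                                total_green = 300, total_red = 300,
                                duration = dur, calibration = cal)
      if (isTRUE(m$kd_is_bound)) NA_real_ else m$kd
    }, 0)
    kds <- kds[is.finite(kds)]
    expect_gte(length(kds), 15)
    expect_lt(abs(median(kds) - kd_true), 0.25 * kd_true)
  }
})
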