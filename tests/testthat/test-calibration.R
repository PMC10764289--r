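# Detection-volume calibration: closed-form pieces and dye-trace recovery.

test_that("waist follows from diffusion time and known D", {
  expect_equal(waist_from_diffusion(25, 400), 0.2)
  expect_error(waist_from_diffusion(0, 400), "positive")
  expect_error(waist_from_diffusion(25, -1), "positive")
  # scale consistency: doubling D with tau_D halved leaves the waist fixed
  expect_equal(waist_from_diffusion(12.5, 800), waist_from_diffusion(25, 400))
})

test_that("effective volume is the 3D Gaussian formula", {
  expect_equal(effective_volume(0.2, 1.0), pi^1.5 * 0.04, tolerance = 1e-12)
  expect_equal(effective_volume(0.3, 0.3), pi^1.5 * 0.3^3)
  expect_equal(effective_volume(0.4, 1.0), 4 * effective_volume(0.2, 1.0))
  expect_error(effective_volume(0, 1), "positive")
})

test_that("detection volume invariants hold", {
  v <- detection_volume(0.2, 0.6, "green")
  expect_equal(v$v_eff, pi^1.5 * 0.04 * 0.6, tolerance = 1e-9)
  expect_equal(v$structure_parameter, 3)
  expect_error(detection_volume(-0.1, 1), "positive")
})

test_that("cross volume reduces to V_ef for identical channels and matches arithmetic", {
  g <- detection_volume(0.2, 1.0, "green")
  r <- detection_volume(0.2, 1.0, "red")
  expect_equal(cross_volume(g, r), g$v_eff, tolerance = 1e-12)

  g2 <- detection_volume(0.20, 1.00, "green")
  r2 <- detection_volume(0.25, 1.25, "red")
  # mean squared waist (0.04 + 0.0625)/2 = 0.05125
  expect_equal(cross_volume(g2, r2),
               pi^1.5 * 0.05125 * sqrt(1.28125), tolerance = 1e-12)
})

test_that("cross volume lies between the channel volumes under a shared S", {
  set.seed(71)
  for (i in 1:100) {
    s <- runif(1, 2, 8)
    wg <- runif(1, 0.15, 0.4)
    wr <- runif(1, 0.15, 0.4)
    g <- detection_volume(wg, s * wg, "green")
    r <- detection_volume(wr, s * wr, "red")
    vcc <- cross_volume(g, r)
    expect_gte(vcc, min(g$v_eff, r$v_eff) - 1e-12)
    expect_lte(vcc, max(g$v_eff, r$v_eff) + 1e-12)
  }
})

test_that("volumes back-derived from V_ef give an S-independent cross volume", {
  ref <- cross_volume(volume_from_veff(0.56, 3, "green"),
                      volume_from_veff(0.75, 3, "red"))
  expect_equal(round(ref, 2), 0.65)
  for (s in c(5, 8, 11.7)) {
    g <- volume_from_veff(0.56, s, "green")
    r <- volume_from_veff(0.75, s, "red")
    expect_equal(g$v_eff, 0.56, tolerance = 1e-9)
    expect_equal(cross_volume(g, r), ref, tolerance = 1e-9)
  }
})

test_that("channel calibration recovers the detection volume from dye traces", {
  cal <- cached_calibration()
  true_v <- test_green_vol()$v_eff
  expect_lt(abs(cal$green$v_eff - true_v) / true_v, 0.15)
  expect_lt(abs(cal$red$v_eff - true_v) / true_v, 0.15)
  expect_lt(abs(cal$v_cc - true_v) / true_v, 0.15)
  # fitted N is linear in concentration: the dilution ratio of the fits
  # matches the ratio of realized emitter numbers within 15% (the realized
  # counts absorb the frozen Poisson placement of each boxed trace)
  for (ch in c("green", "red")) {
    audit <- attr(cal[[ch]], "calibration")
    hi <- audit$concentrations == max(audit$concentrations)
    ratio_fit <- mean(audit$n_fitted[hi]) / mean(audit$n_fitted[!hi])
    ratio_real <- mean(audit$n_realized[hi]) / mean(audit$n_realized[!hi])
    expect_lt(abs(ratio_fit - ratio_real) / ratio_real, 0.15)
  }
})

test_that("calibration rejects single traces and inconsistent dilutions", {
  gv <- test_green_vol()
  tr <- simulate_dye_trace(3, "green", gv, test_red_vol(),
                           simulation_box(4, 2, 1, seed = 81))
  expect_error(calibrate_channel(list(tr), 3), ">= 2")
})
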