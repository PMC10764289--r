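# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code at test time; the detection geometry mirrors the package
# defaults (0.2 um waist, structure parameter 3).

test_green_vol <- function() detection_volume(0.2, 0.6, "green")
test_red_vol <- function() detection_volume(0.2, 0.6, "red")

# molecules per fl per nM (N_A * 1e-9 / 1e15)
MOLEC_PER_FL_NM <- 6.02214076e-1

# Direct (brute-force) correlation estimator with symmetric normalization:
# the definitional computation the multi-tau scheme must reproduce at
# unrebinned lags. Kept deliberately naive and independent of the C++ path.
brute_force_correlate <- function(a, b, lags_bins) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- length(a)
  vapply(lags_bins, function(k) {
    ah <- a[1:(n - k)]
    bt <- b[(k + 1):n]
    ma <- mean(ah)
    mb <- mean(bt)
    (mean(ah * bt) - ma * mb) / (ma * mb)
  }, 0)
}

# area and perimeter of a regular n-gon with circumradius r
regular_polygon <- function(n, r = 1) {
  list(area = 0.5 * n * r^2 * sin(2 * pi / n),
       perimeter = 2 * n * r * sin(pi / n))
}

# One shared full-quality calibration (10-s dye traces at the stated
# dilutions, two repeat recordings each, 6-um box), computed once per test
# run and reused by every test that needs calibrated volumes. ~2 min of
# simulation.
.cal_cache <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (!is.null(.cal_cache$cal)) return(.cal_cache$cal)
  gvol <- test_green_vol()
  rvol <- test_red_vol()
  gconc <- rep(c(3, 6), each = 2)
  rconc <- rep(c(4, 8), each = 2)
  gtr <- lapply(seq_along(gconc), function(i) {
    simulate_dye_trace(gconc[i], "green", gvol, rvol,
                       simulation_box(6, 2, 10, seed = 910 + i))
  })
  rtr <- lapply(seq_along(rconc), function(i) {
    simulate_dye_trace(rconc[i], "red", gvol, rvol,
                       simulation_box(6, 2, 10, seed = 920 + i))
  })
  .cal_cache$cal <- calibrate_fccs(gtr, gconc, rtr, rconc)
  .cal_cache$cal
}

# Simulate and analyse one two-colour measurement at the given truth.
simulate_and_analyze <- function(kd_true, seed, total_green = 300,
                                 total_red = 300, duration = 10,
                                 calibration = cached_calibration()) {
  mix <- equilibrium_mixture(total_green, total_red, kd_true)
  tr <- simulate_fccs_trace(mix, test_green_vol(), test_red_vol(),
                            simulation_box(2, 50, duration, seed = seed))
  analyze_fccs_trace(tr, calibration, triplet_tau = 5)
}
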