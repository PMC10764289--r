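#!/usr/bin/env Rscript
# Detection-volume calibration on synthetic reference-dye series.
#
# Simulates the two-dilution ATTO-style calibration of both spectral
# channels (D = 400 um^2/s; 3/6 nM green, 4/8 nM red; 10-s recordings),
# derives per-channel waists, axial extents and effective volumes, and the
# cross-correlation volume. Also evaluates the instrument worked example:
# per-channel effective volumes of 0.56 and 0.75 fl combine to a 0.65 fl
# cross-correlation volume.

library(fccsfret)

dir.create("results", showWarnings = FALSE)
seed <- 20240901

gvol <- detection_volume(0.2, 0.6, "green")
rvol <- detection_volume(0.2, 0.6, "red")

message("simulating dye dilution series (4 x 10 s) ...")
green_traces <- lapply(1:2, function(i) {
  simulate_dye_trace(c(3, 6)[i], "green", gvol, rvol,
                     simulation_box(6, 2, 10, seed = child_seed(seed, i)))
})
red_traces <- lapply(1:2, function(i) {
  simulate_dye_trace(c(4, 8)[i], "red", gvol, rvol,
                     simulation_box(6, 2, 10,
                                    seed = child_seed(seed, 10 + i)))
})

cal <- calibrate_fccs(green_traces, c(3, 6), red_traces, c(4, 8),
                      dye_diffusion = 400)
print(cal)

tab <- data.frame(
  quantity = c("waist_green_um", "axial_green_um", "v_eff_green_fl",
               "waist_red_um", "axial_red_um", "v_eff_red_fl", "v_cc_fl"),
  calibrated = c(cal$green$waist, cal$green$axial, cal$green$v_eff,
                 cal$red$waist, cal$red$axial, cal$red$v_eff, cal$v_cc),
  truth = c(gvol$waist, gvol$axial, gvol$v_eff,
            rvol$waist, rvol$axial, rvol$v_eff, cross_volume(gvol, rvol)))
tab$rel_error <- tab$calibrated / tab$truth - 1
write.table(format(tab, digits = 4), "results/calibration.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
message("recovered both effective volumes within ",
        sprintf("%.0f%%", 100 * max(abs(tab$rel_error))),
        " of the simulated geometry -> results/calibration.csv")

# instrument worked example: V_ef pair -> V_cc, shared structure parameter
vcc_ref <- cross_volume(volume_from_veff(0.56, 5, "green"),
                        volume_from_veff(0.75, 5, "red"))
message(sprintf(
  "worked example: V_ef 0.56 / 0.75 fl -> V_cc = %.2f fl", vcc_ref))
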