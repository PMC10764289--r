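#!/usr/bin/env Rscript
# FLIM-FRET lifetime, efficiency and distance analysis on synthetic TCSPC
# decays.
#
# Donor-only decays set the unquenched lifetime; quenched ROI decays at
# three transfer efficiencies (the two printed controls and a mid value)
# are fit by Poisson MLE, converted to efficiencies against the mean
# donor-only lifetime, and to donor-acceptor distances via the Forster
# relation (R0 = 52.4 A for the EGFP-mCherry pair).

library(fccsfret)

dir.create("results", showWarnings = FALSE)
seed <- 20240903
tau_donor <- 2.5   # ns, GFP-like
n_photons <- 1e5
n_rep <- 8

donors <- lapply(seq_len(n_rep), function(k) {
  simulate_tcspc(list(c(1, tau_donor)), n_photons, irf_sigma = 0.1,
                 seed = child_seed(seed, k))
})

conditions <- data.frame(
  label = c("negative_control", "positive_control", "strong_fret"),
  e_true = c(0.046, 0.1092, 0.30))

rows <- lapply(seq_len(nrow(conditions)), function(i) {
  e <- conditions$e_true[i]
  rois <- lapply(seq_len(n_rep), function(k) {
    simulate_tcspc(list(c(1, tau_donor * (1 - e))), n_photons,
                   irf_sigma = 0.1,
                   seed = child_seed(seed, 100 * i + k))
  })
  res <- roi_fret_analysis(donors, rois, forster_r0 = 52.4)
  data.frame(condition = conditions$label[i],
             e_true = e,
             tau_donor_fit = attr(res, "tau_donor_unquenched"),
             tau_da = mean(res$tau_da),
             efficiency = mean(res$efficiency),
             distance_A = mean(res$distance),
             distance_true_A = donor_acceptor_distance(e))
})
tab <- do.call(rbind, rows)
print(format(tab, digits = 4))
write.table(format(tab, digits = 5), "results/fret_summary.csv", sep = ",",
            row.names = FALSE, quote = FALSE)

message(sprintf(
  "recovered efficiencies within %.2f points of truth; distances within %.1f A",
  100 * max(abs(tab$efficiency - tab$e_true)),
  max(abs(tab$distance_A - tab$distance_true_A))))
message("-> results/fret_summary.csv")
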