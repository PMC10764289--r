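#' Concentration of molecules in one channel
#'
#' Converts a fitted molecule number into a molar concentration through the
#' channel's effective volume: \eqn{C = N / (V_{ef} N_A)}, reported in nM.
#'
#' @param n_molecules fitted molecule number (amplitude reciprocal).
#' @param v_eff effective volume, fl.
#' @return concentration in nM.
#' @examples
#' channel_concentration(1, 0.65) # 2.5547 nM
#' @export
channel_concentration <- function(n_molecules, v_eff) {
  if (any(v_eff <= 0)) stop("effective volume must be positive")
  if (any(n_molecules < 0)) stop("molecule number must be non-negative")
  n_molecules / (v_eff * .MOLEC_PER_FL_NM)
}

#' Concentration of co-diffusing (cross-correlating) molecules
#'
#' \deqn{C_{cc} = \frac{N_1 N_2}{N_{cc}} \cdot \frac{1}{V_{cc} N_A}}
#' where `N1`, `N2` are the molecule numbers fitted to the two
#' autocorrelations and `Ncc` is the amplitude reciprocal of the
#' cross-correlation fit (so the bound-molecule count is `N1 * N2 / Ncc`).
#'
#' @param n1,n2 autocorrelation molecule numbers.
#' @param ncc cross-correlation amplitude reciprocal (> 0).
#' @param v_cc cross-correlation effective volume, fl.
#' @return complex concentration in nM.
#' @export
complex_concentration <- function(n1, n2, ncc, v_cc) {
  if (v_cc <= 0) stop("v_cc must be positive")
  if (ncc <= 0) stop("no detectable cross-correlation (ncc <= 0)")
  (n1 * n2 / ncc) / (v_cc * .MOLEC_PER_FL_NM)
}

#' Equilibrium dissociation constant from channel concentrations
#'
#' \deqn{K_d = \frac{(C_{green} - C_{cc})(C_{red} - C_{cc})}{C_{cc}}}
#' If the complex concentration exceeds a channel concentration (possible
#' through fit noise) it is clipped to that channel with a warning flag.
#'
#' @param c_green,c_red,c_cc concentrations in nM.
#' @return K_d in nM, with attribute `clipped = TRUE` when inputs were
#'   clipped.
#' @export
dissociation_constant <- function(c_green, c_red, c_cc) {
  if (c_cc <= 0) {
    stop("c_cc must be positive; absent cross-correlation is a lower bound")
  }
  clipped <- FALSE
  if (c_cc > min(c_green, c_red)) {
    warning("c_cc exceeds a channel concentration; clipping")
    c_cc <- min(c_green, c_red)
    clipped <- TRUE
  }
  kd <- (c_green - c_cc) * (c_red - c_cc) / c_cc
  if (clipped) attr(kd, "clipped") <- TRUE
  kd
}

#' Analyse one FCCS measurement end to end
#'
#' Runs the full estimator on a two-channel photon trace: multi-tau
#' correlation of both autocorrelations and the cross-correlation,
#' triplet-diffusion fits of the autocorrelations and a pure-diffusion fit
#' of the cross-correlation (structure parameters fixed from calibration),
#' conversion of the fitted amplitudes to concentrations, and the K_d
#' equation.
#'
#' When the fitted cross-correlation amplitude falls below its noise floor
#' (three times the per-lag standard error near zero lag), no point estimate
#' is made: the complex concentration is set to the floor's concentration
#' equivalent and K_d is reported as a lower bound.
#'
#' @param trace a [photon_trace()].
#' @param calibration a [calibrate_fccs()] result.
#' @param m,n_segments correlator settings.
#' @param triplet_tau optional fixed triplet relaxation time (us) for the
#'   autocorrelation fits; `NULL` leaves it free.
#' @param location_label free-text label (e.g. producing cell / cytoneme /
#'   receiving cell).
#' @param window fit-window length in multiples of each curve's
#'   [half_decay_lag()].
#' @return an object of class `fccs_measurement`: fields `n1`, `n2`, `ncc`,
#'   `c_green`, `c_red`, `c_cc`, `kd`, `kd_is_bound`, `excluded`,
#'   `exclusion_reason`, `flags`, `location_label`, `fits`.
#' @export
analyze_fccs_trace <- function(trace, calibration, m = 16, n_segments = 10,
                               triplet_tau = NULL, location_label = "",
                               window = 16) {
  stopifnot(inherits(calibration, "calibration_result"))
  g_curve <- multi_tau_correlate(trace, "auto_green", m, n_segments)
  r_curve <- multi_tau_correlate(trace, "auto_red", m, n_segments)
  x_curve <- multi_tau_correlate(trace, "cross", m, n_segments)
  measurement_from_curves(g_curve, r_curve, x_curve, calibration,
                          triplet_tau = triplet_tau,
                          location_label = location_label, window = window)
}

#' Build an FCCS measurement from already-computed correlation curves
#'
#' The fitting and concentration part of [analyze_fccs_trace()]; useful when
#' curves are stored on disk between pipeline stages.
#'
#' @param g_curve,r_curve,x_curve the two autocorrelations and the
#'   cross-correlation ([correlation_curve()] objects).
#' @inheritParams analyze_fccs_trace
#' @return an `fccs_measurement` (see [analyze_fccs_trace()]).
#' @export
measurement_from_curves <- function(g_curve, r_curve, x_curve, calibration,
                                    triplet_tau = NULL,
                                    location_label = "", window = 16) {
  stopifnot(inherits(calibration, "calibration_result"))
  fixed_auto_g <- list(structure_parameter =
                         calibration$green$structure_parameter)
  fixed_auto_r <- list(structure_parameter =
                         calibration$red$structure_parameter)
  if (!is.null(triplet_tau)) {
    fixed_auto_g$triplet_tau <- triplet_tau
    fixed_auto_r$triplet_tau <- triplet_tau
  }
  fit_g <- fit_curve(g_curve, "triplet_diffusion", fixed = fixed_auto_g,
                     max_lag = window * half_decay_lag(g_curve))
  fit_r <- fit_curve(r_curve, "triplet_diffusion", fixed = fixed_auto_r,
                     max_lag = window * half_decay_lag(r_curve))
  s_cc <- .cross_structure(calibration$green, calibration$red)
  fit_x <- fit_curve(x_curve, "pure_diffusion",
                     fixed = list(structure_parameter = s_cc),
                     max_lag = window * half_decay_lag(x_curve))

  flags <- character(0)
  if (!fit_g$converged || !fit_r$converged) {
    return(structure(list(
      n1 = NA_real_, n2 = NA_real_, ncc = NA_real_,
      c_green = NA_real_, c_red = NA_real_, c_cc = NA_real_,
      kd = NA_real_, kd_is_bound = FALSE, excluded = FALSE,
      exclusion_reason = NA_character_,
      flags = c("autocorrelation_fit_failure"),
      location_label = location_label,
      fits = list(green = fit_g, red = fit_r, cross = fit_x)),
      class = "fccs_measurement"))
  }

  n1 <- fit_g$par[["n"]]
  n2 <- fit_r$par[["n"]]
  c_green <- channel_concentration(n1, calibration$green$v_eff)
  c_red <- channel_concentration(n2, calibration$red$v_eff)

  # amplitude noise floor near zero lag
  sig0 <- median(head(x_curve$sigma, 5), na.rm = TRUE)
  amp_floor <- 3 * sig0
  amp <- if (fit_x$converged) 1 / fit_x$par[["n"]] else NA_real_

  if (!fit_x$converged || !is.finite(amp) || amp <= 0 ||
      (is.finite(amp_floor) && amp < amp_floor)) {
    # no resolvable cross-correlation: report K_d as a lower bound at the
    # concentration equivalent of the noise floor
    if (!is.finite(amp_floor) || amp_floor <= 0) {
      flags <- c(flags, "no_noise_floor")
      kd <- NA_real_
      c_cc <- NA_real_
      ncc <- NA_real_
      is_bound <- FALSE
    } else {
      ncc <- 1 / amp_floor
      c_cc <- complex_concentration(n1, n2, ncc, calibration$v_cc)
      c_cc <- min(c_cc, c_green, c_red)
      kd <- (c_green - c_cc) * (c_red - c_cc) / c_cc
      is_bound <- TRUE
      flags <- c(flags, "cross_amplitude_below_noise_floor")
    }
  } else {
    ncc <- fit_x$par[["n"]]
    c_cc <- complex_concentration(n1, n2, ncc, calibration$v_cc)
    if (c_cc > min(c_green, c_red)) flags <- c(flags, "c_cc_clipped")
    kd <- suppressWarnings(dissociation_constant(c_green, c_red, c_cc))
    kd <- as.numeric(kd)
    is_bound <- FALSE
  }

  structure(list(
    n1 = n1, n2 = n2, ncc = ncc,
    c_green = c_green, c_red = c_red, c_cc = c_cc,
    kd = kd, kd_is_bound = is_bound,
    excluded = FALSE, exclusion_reason = NA_character_,
    flags = flags, location_label = location_label,
    fits = list(green = fit_g, red = fit_r, cross = fit_x)),
    class = "fccs_measurement")
}

#' @export
print.fccs_measurement <- function(x, ...) {
  kd_str <- if (isTRUE(x$kd_is_bound)) sprintf("> %.4g nM", x$kd)
  else sprintf("%.4g nM", x$kd)
  cat(sprintf(
    "fccs_measurement: C_green %.4g nM, C_red %.4g nM, C_cc %.4g nM, Kd %s\n",
    x$c_green, x$c_red, x$c_cc, kd_str))
  invisible(x)
}

#' Apply the concentration exclusion rule
#'
#' Measurements whose channel concentration exceeds the threshold (strictly)
#' are excluded from aggregation; the default 2000 nM guards against
#' over-expression artefacts. The rule excludes a measurement when either
#' channel is over the threshold (the conservative reading; set
#' `rule = "both"` to require both channels over).
#'
#' @param measurements list of [analyze_fccs_trace()] results.
#' @param threshold exclusion threshold, nM.
#' @param rule `"either"` or `"both"`.
#' @return list with elements `retained` and `excluded`; excluded
#'   measurements carry their reason.
#' @export
apply_exclusion <- function(measurements, threshold = 2000,
                            rule = c("either", "both")) {
  rule <- match.arg(rule)
  retained <- list()
  excluded <- list()
  for (m in measurements) {
    over_g <- is.finite(m$c_green) && m$c_green > threshold
    over_r <- is.finite(m$c_red) && m$c_red > threshold
    out <- if (rule == "either") over_g || over_r else over_g && over_r
    if (out) {
      m$excluded <- TRUE
      m$exclusion_reason <- sprintf(
        "channel concentration over %g nM (green %.4g, red %.4g)",
        threshold, m$c_green, m$c_red)
      excluded[[length(excluded) + 1]] <- m
    } else {
      retained[[length(retained) + 1]] <- m
    }
  }
  list(retained = retained, excluded = excluded)
}

#' Aggregate dissociation constants over retained measurements
#'
#' Mean and standard deviation over finite point estimates; lower-bound
#' records are summarized separately and never averaged in.
#'
#' @param measurements list of [analyze_fccs_trace()] results (typically the
#'   `retained` part of [apply_exclusion()]).
#' @return a list with `mean`, `sd` (NA for a single value), `n`,
#'   `n_bounds`, `min_bound` (smallest lower bound, NA when none) and the
#'   point estimates in `values`.
#' @export
aggregate_kd <- function(measurements) {
  kds <- vapply(measurements, function(m) {
    if (isTRUE(m$kd_is_bound)) NA_real_ else m$kd
  }, 0)
  bounds <- vapply(measurements, function(m) {
    if (isTRUE(m$kd_is_bound)) m$kd else NA_real_
  }, 0)
  vals <- kds[is.finite(kds)]
  bnds <- bounds[is.finite(bounds)]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) sd(vals) else NA_real_,
       n = length(vals),
       n_bounds = length(bnds),
       min_bound = if (length(bnds)) min(bnds) else NA_real_,
       values = vals, bounds = bnds)
}

#' Rescale a dissociation constant to a 0-100 relative affinity
#'
#' The affinity measure `1/K_d` is linearly rescaled so that the
#' non-binding (negative-control) anchor maps to 0 and the tight-binding
#' (positive-control) anchor maps to 100. `kd = 0` saturates at the scale
#' maximum and is flagged.
#'
#' @param kd dissociation constant(s), nM.
#' @param kd_negative_anchor K_d of the non-binding reference, nM.
#' @param kd_positive_anchor K_d of the tight-binding reference, nM.
#' @return relative affinity score(s); attribute `saturated` marks kd = 0
#'   inputs.
#' @export
relative_affinity <- function(kd, kd_negative_anchor, kd_positive_anchor) {
  if (kd_negative_anchor == kd_positive_anchor) {
    stop("anchors must be distinct")
  }
  a <- 1 / kd
  a_neg <- 1 / kd_negative_anchor
  a_pos <- 1 / kd_positive_anchor
  score <- 100 * (a - a_neg) / (a_pos - a_neg)
  sat <- kd == 0
  score[sat] <- 100
  if (any(sat)) attr(score, "saturated") <- sat
  score
}

#' Bin dissociation constants and report per-bin percentages
#'
#' @param kds dissociation constants, nM (finite point estimates).
#' @param bin_edges strictly increasing bin edges, nM; bins are
#'   `[e_i, e_{i+1})`, with the last bin closed.
#' @return a data.frame with `bin`, `lower`, `upper`, `count`, `percent`
#'   (percentages sum to 100 over in-range values); attribute
#'   `n_out_of_range` counts values outside the edges.
#' @export
bin_kd <- function(kds, bin_edges) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing")
  }
  kds <- kds[is.finite(kds)]
  idx <- findInterval(kds, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1 & idx <= length(bin_edges) - 1
  counts <- tabulate(idx[in_range], nbins = length(bin_edges) - 1)
  total <- sum(counts)
  out <- data.frame(
    bin = paste0("[", head(bin_edges, -1), ", ", bin_edges[-1], ")"),
    lower = head(bin_edges, -1),
    upper = bin_edges[-1],
    count = counts,
    percent = if (total > 0) 100 * counts / total else rep(0, length(counts)))
  attr(out, "n_out_of_range") <- sum(!in_range)
  out
}
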