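#' Mass-action equilibrium mixture of two labelled species and their complex
#'
#' Solves the binding equilibrium for a green-labelled species (total
#' concentration `total_green`), a red-labelled species (`total_red`) and
#' their 1:1 complex at a chosen true dissociation constant. The complex
#' concentration is the physical root of
#' \deqn{C^2 - (G_t + R_t + K_d) C + G_t R_t = 0,}
#' taken with the minus sign so that \eqn{0 \le C \le \min(G_t, R_t)}.
#' `kd_true = 0` gives the infinite-affinity limit (complex = smaller total);
#' `kd_true = Inf` gives no binding.
#'
#' The remaining fields describe how the mixture diffuses and emits photons in
#' [simulate_fccs_trace()]: per-species diffusion coefficients, per-channel
#' molecular brightness (counts per molecule per second, molecule-averaged
#' over the effective volume, i.e. the counts-per-molecule convention of FCS
#' instruments), and the blinking dark-state parameters shared by all
#' fluorophores. Complexes carry both fluorophores and emit the summed
#' brightness in each channel.
#'
#' Defaults emulate GFP/mCherry-tagged membrane-proximal signalling proteins
#' in embryonic tissue: slow diffusion (4 um^2/s free, 2.5 um^2/s bound),
#' moderate brightness, 15 % triplet occupancy with a 5 us relaxation time.
#'
#' @param total_green,total_red total channel concentrations in nM.
#' @param kd_true true dissociation constant in nM; may be `Inf`.
#' @param diffusion named numeric: diffusion coefficients (um^2/s) for
#'   `free_green`, `free_red`, `complex`.
#' @param brightness_green,brightness_red molecular brightness (counts /
#'   molecule / s) of the green and red fluorophore.
#' @param triplet_fraction stationary dark-state occupancy in `[0, 1)`.
#' @param triplet_tau dark-state relaxation time in us.
#' @return an object of class `species_mix`.
#' @examples
#' m <- equilibrium_mixture(300, 400, 600)
#' m$complex # 100 nM
#' @export
equilibrium_mixture <- function(total_green, total_red, kd_true,
                                diffusion = c(free_green = 4, free_red = 4,
                                              complex = 2.5),
                                brightness_green = 4000,
                                brightness_red = 4000,
                                triplet_fraction = 0.15,
                                triplet_tau = 5) {
  if (!is.finite(total_green) || !is.finite(total_red) ||
      total_green < 0 || total_red < 0) {
    stop("total concentrations must be finite and non-negative")
  }
  if (is.na(kd_true) || kd_true < 0) stop("kd_true must be >= 0 (or Inf)")
  if (triplet_fraction < 0 || triplet_fraction >= 1) {
    stop("triplet_fraction must be in [0, 1)")
  }
  stopifnot(all(c("free_green", "free_red", "complex") %in% names(diffusion)))

  if (is.infinite(kd_true)) {
    cplx <- 0
  } else if (kd_true == 0) {
    cplx <- min(total_green, total_red)
  } else {
    s <- total_green + total_red + kd_true
    # numerically stable form of the physical quadratic root
    cplx <- 2 * total_green * total_red /
      (s + sqrt(s^2 - 4 * total_green * total_red))
  }

  mix <- structure(list(
    total_green = total_green,
    total_red = total_red,
    kd_true = kd_true,
    free_green = total_green - cplx,
    free_red = total_red - cplx,
    complex = cplx,
    diffusion = diffusion[c("free_green", "free_red", "complex")],
    brightness_green = brightness_green,
    brightness_red = brightness_red,
    triplet_fraction = triplet_fraction,
    triplet_tau = triplet_tau
  ), class = "species_mix")
  validate_species_mix(mix)
  mix
}

validate_species_mix <- function(mix) {
  with(mix, {
    stopifnot(abs(free_green + complex - total_green) < 1e-9,
              abs(free_red + complex - total_red) < 1e-9,
              free_green >= 0, free_red >= 0, complex >= 0)
    if (is.finite(kd_true) && complex > 0 && kd_true > 0) {
      resid <- abs(free_green * free_red / complex - kd_true) / kd_true
      stopifnot(resid < 1e-6)
    }
  })
  invisible(mix)
}

#' @export
print.species_mix <- function(x, ...) {
  cat(sprintf(
    "species_mix: Gt = %.4g nM, Rt = %.4g nM, Kd = %.4g nM -> complex %.4g nM\n",
    x$total_green, x$total_red, x$kd_true, x$complex))
  invisible(x)
}

#' Simulation box for Brownian-dynamics photon traces
#'
#' A periodic cube holding the diffusing emitters. The side must be at least
#' ten beam waists so the periodic images do not bias the correlation at
#' accessible lags (checked against the detection volumes at simulation
#' time). Recording duration defaults to 10 s, the standard length of one
#' FCCS measurement.
#'
#' @param side_length box side in um.
#' @param bin_width photon-count bin width in us.
#' @param duration recording time in s; must be a whole number of bins.
#' @param seed integer seed; the same box and inputs give bit-identical
#'   traces.
#' @return an object of class `simulation_box`.
#' @export
simulation_box <- function(side_length = 2, bin_width = 50, duration = 10,
                           seed = 1) {
  stopifnot(side_length > 0, bin_width > 0, duration > 0)
  n_bins <- duration * 1e6 / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-6) {
    stop("duration must be a whole number of bins")
  }
  structure(list(side_length = side_length, bin_width = bin_width,
                 duration = duration, seed = as.integer(seed)),
            class = "simulation_box")
}

#' Two-channel photon-count trace
#'
#' @param counts_green,counts_red non-negative integer count vectors of equal
#'   length.
#' @param bin_width bin width in us.
#' @param metadata free-form list carried along (ground truth, settings).
#' @return an object of class `photon_trace` with fields `counts_green`,
#'   `counts_red`, `bin_width` (us), `duration` (s) and `metadata`.
#' @export
photon_trace <- function(counts_green, counts_red, bin_width,
                         metadata = list()) {
  stopifnot(length(counts_green) == length(counts_red),
            all(counts_green >= 0), all(counts_red >= 0), bin_width > 0)
  structure(list(
    counts_green = as.integer(counts_green),
    counts_red = as.integer(counts_red),
    bin_width = bin_width,
    duration = length(counts_green) * bin_width * 1e-6,
    metadata = metadata
  ), class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf(
    "photon_trace: %d bins of %g us (%.3g s), mean rates %.3g / %.3g kHz\n",
    length(x$counts_green), x$bin_width, x$duration,
    mean(x$counts_green) / x$bin_width * 1e3,
    mean(x$counts_red) / x$bin_width * 1e3))
  invisible(x)
}

# shared stability rule: resolve diffusion relative to the beam waist
.substeps_for <- function(bin_width_us, max_diffusion, min_waist) {
  dt_max_s <- (min_waist / 10)^2 / (2 * max_diffusion)
  max(1L, as.integer(ceiling(bin_width_us * 1e-6 / dt_max_s)))
}

# low-level species simulation shared by the mixture and dye front ends
.simulate_species <- function(conc, diffusion, eps_green, eps_red,
                              triplet_fraction, triplet_tau,
                              green_vol, red_vol, box) {
  stopifnot(inherits(green_vol, "detection_volume"),
            inherits(red_vol, "detection_volume"),
            inherits(box, "simulation_box"))
  max_w <- max(green_vol$waist, red_vol$waist)
  if (box$side_length < 10 * max_w) {
    stop(sprintf(
      "box side %.3g um too small: must be >= 10 x max waist (%.3g um)",
      box$side_length, 10 * max_w))
  }
  live <- conc > 0
  if (!any(live)) {
    n_bins <- as.integer(round(box$duration * 1e6 / box$bin_width))
    return(list(counts_green = integer(n_bins), counts_red = integer(n_bins),
                n_particles = integer(sum(live))))
  }
  substeps <- .substeps_for(box$bin_width, max(diffusion[live]),
                            min(green_vol$waist, red_vol$waist))
  sim_fccs_cpp(conc[live], diffusion[live], eps_green[live], eps_red[live],
               triplet_fraction, triplet_tau,
               green_vol$waist, green_vol$axial,
               red_vol$waist, red_vol$axial,
               box$side_length, box$bin_width, substeps, box$duration,
               box$seed)
}

#' Simulate a two-colour FCCS photon trace from an equilibrium mixture
#'
#' Places each species Poisson-distributed at its equilibrium concentration in
#' the periodic box, propagates isotropic Brownian steps (s.d.
#' \eqn{\sqrt{2 D \Delta t}} per axis, sub-stepped whenever a full bin step
#' would exceed a tenth of the beam waist), accumulates the expected photon
#' rate of every emitter through the two 3D Gaussian detection profiles,
#' applies two-state triplet blinking, and draws per-bin counts from a
#' Poisson distribution. Complexes emit in both channels. Deterministic
#' given `box$seed`.
#'
#' @param mix a [equilibrium_mixture()] object.
#' @param green_vol,red_vol calibrated [detection_volume()] objects.
#' @param box a [simulation_box()].
#' @return a [photon_trace()] whose metadata records the ground truth.
#' @export
simulate_fccs_trace <- function(mix, green_vol, red_vol, box) {
  stopifnot(inherits(mix, "species_mix"))
  res <- .simulate_species(
    conc = c(mix$free_green, mix$free_red, mix$complex),
    diffusion = as.numeric(mix$diffusion),
    eps_green = c(mix$brightness_green, 0, mix$brightness_green),
    eps_red = c(0, mix$brightness_red, mix$brightness_red),
    triplet_fraction = mix$triplet_fraction, triplet_tau = mix$triplet_tau,
    green_vol = green_vol, red_vol = red_vol, box = box)
  photon_trace(res$counts_green, res$counts_red, box$bin_width,
               metadata = list(truth = mix[c("total_green", "total_red",
                                             "kd_true", "complex")],
                               seed = box$seed,
                               n_particles = res$n_particles))
}

#' Simulate a single-species reference-dye trace in one channel
#'
#' Used for detection-volume calibration: a freely diffusing dye of known
#' diffusion coefficient emitting in a single spectral channel. ATTO-class
#' dyes are bright and have little triplet occupancy at moderate excitation,
#' hence the defaults.
#'
#' @param concentration dye concentration in nM.
#' @param channel `"green"` or `"red"`.
#' @param green_vol,red_vol the detection volumes (both are needed to define
#'   the box geometry even though only one channel records photons).
#' @param box a [simulation_box()].
#' @param diffusion dye diffusion coefficient in um^2/s.
#' @param brightness molecular brightness, counts/molecule/s.
#' @param triplet_fraction,triplet_tau blinking parameters.
#' @return a [photon_trace()] (the other channel is all zeros).
#' @export
simulate_dye_trace <- function(concentration, channel = c("green", "red"),
                               green_vol, red_vol, box,
                               diffusion = 400, brightness = 50000,
                               triplet_fraction = 0.03, triplet_tau = 2) {
  channel <- match.arg(channel)
  stopifnot(concentration >= 0, diffusion > 0)
  res <- .simulate_species(
    conc = concentration, diffusion = diffusion,
    eps_green = if (channel == "green") brightness else 0,
    eps_red = if (channel == "red") brightness else 0,
    triplet_fraction = triplet_fraction, triplet_tau = triplet_tau,
    green_vol = green_vol, red_vol = red_vol, box = box)
  photon_trace(res$counts_green, res$counts_red, box$bin_width,
               metadata = list(dye = list(concentration = concentration,
                                          diffusion = diffusion,
                                          channel = channel),
                               seed = box$seed,
                               n_particles = res$n_particles))
}

#' Expected mean count rate of a simulated trace
#'
#' Analytic expectation for a 3D Gaussian detection profile under the
#' counts-per-molecule brightness convention:
#' \eqn{\langle I \rangle = \sum_s C_s V_{ef} N_A \epsilon_s (1 - T)},
#' with the factor \eqn{(1 - T)} for the triplet dark fraction.
#'
#' @param conc species concentrations, nM.
#' @param eps species brightness in the channel, counts/molecule/s.
#' @param v_eff channel effective volume, fl.
#' @param triplet_fraction stationary dark fraction.
#' @return expected count rate in counts/s.
#' @export
expected_count_rate <- function(conc, eps, v_eff, triplet_fraction = 0) {
  sum(conc * eps) * v_eff * .MOLEC_PER_FL_NM * (1 - triplet_fraction)
}

#' Stationary occupancy of the triplet blinking telegraph
#'
#' Runs the discrete two-state telegraph used by the simulator and returns
#' the realized dark fraction; converges to `triplet_fraction` for long
#' traces.
#'
#' @param triplet_fraction stationary dark fraction.
#' @param triplet_tau relaxation time, us.
#' @param dt_us time step, us.
#' @param duration_s simulated time, s.
#' @param seed integer seed.
#' @export
telegraph_occupancy <- function(triplet_fraction, triplet_tau, dt_us,
                                duration_s, seed = 1) {
  stopifnot(triplet_fraction >= 0, triplet_fraction < 1, triplet_tau > 0)
  telegraph_occupancy_cpp(triplet_fraction, triplet_tau, dt_us, duration_s,
                          as.integer(seed))
}

#' Simulate a TCSPC lifetime decay histogram
#'
#' Photon arrival times are exponential draws from a mixture of lifetime
#' components (component chosen by its amplitude fraction) plus Gaussian
#' instrument-response jitter, histogrammed on `[0, range)`. Photons jittered
#' outside the window are dropped and counted in the metadata.
#'
#' @param components a list of `c(fraction, lifetime_ns)` pairs or a
#'   two-column matrix; fractions must sum to 1, lifetimes must be positive.
#' @param n_photons number of photons to draw; 0 gives an empty (flagged)
#'   histogram.
#' @param irf_sigma Gaussian IRF width, ns.
#' @param bin_width histogram bin width, ns.
#' @param range histogram window, ns.
#' @param t0 arrival-time offset, ns.
#' @param seed integer seed.
#' @return an object of class `tcspc_decay` with fields `bin_edges`,
#'   `counts`, `irf_sigma`, `total_photons` and `metadata`.
#' @export
simulate_tcspc <- function(components, n_photons, irf_sigma = 0.1,
                           bin_width = 0.05, range = 25, t0 = 0, seed = 1) {
  comp <- do.call(rbind, lapply(components, function(x) as.numeric(x)))
  if (ncol(comp) != 2) stop("components must be (fraction, lifetime) pairs")
  fr <- comp[, 1]; tau <- comp[, 2]
  if (abs(sum(fr) - 1) > 1e-9) stop("amplitude fractions must sum to 1")
  if (any(tau <= 0)) stop("lifetimes must be positive")
  stopifnot(n_photons >= 0, irf_sigma >= 0, bin_width > 0, range > bin_width)

  edges <- seq(0, range, by = bin_width)
  n_bins <- length(edges) - 1
  if (n_photons == 0) {
    return(structure(list(bin_edges = edges, counts = integer(n_bins),
                          irf_sigma = irf_sigma, total_photons = 0L,
                          metadata = list(empty = TRUE, n_generated = 0L,
                                          seed = seed)),
                     class = "tcspc_decay"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- sample.int(length(fr), n_photons, replace = TRUE, prob = fr)
  t <- rexp(n_photons, rate = 1) * tau[idx] + t0
  if (irf_sigma > 0) t <- t + rnorm(n_photons, 0, irf_sigma)
  keep <- t >= 0 & t < range
  counts <- tabulate(findInterval(t[keep], edges), nbins = n_bins)
  structure(list(bin_edges = edges, counts = as.integer(counts),
                 irf_sigma = irf_sigma, total_photons = sum(counts),
                 metadata = list(empty = FALSE, n_generated = n_photons,
                                 n_dropped = n_photons - sum(keep),
                                 components = comp, t0 = t0, seed = seed)),
            class = "tcspc_decay")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labelled cell grid for reporter-assay fixtures
#'
#' Builds a rectangular grid of cells containing a clone of
#' reporter-source cells and draws each remaining cell's
#' nuclear/cytoplasmic reporter ratio according to a per-row activation
#' probability. Row distance from the clone is breadth-first graph distance
#' on 4-neighbour cell adjacency (cells, not micrometres). Active cells draw
#' a ratio below the call threshold (nuclear exclusion of the reporter),
#' inactive cells above it.
#'
#' @param n_rows,n_cols grid size.
#' @param clone_cells two-column matrix / data.frame of (row, col) indices of
#'   the clone.
#' @param activity_vs_row named numeric vector mapping row distance (as
#'   character or integer names) to activation probability, or a function of
#'   distance; distances without an entry get probability 0.
#' @param seed integer seed.
#' @param threshold nuclear/cytoplasmic call threshold used to place the
#'   drawn ratios.
#' @return a `cell_grid` data.frame with columns `row`, `col`,
#'   `row_distance`, `is_clone`, `nuclear_intensity`,
#'   `cytoplasmic_intensity`.
#' @export
generate_cell_grid <- function(n_rows, n_cols, clone_cells, activity_vs_row,
                               seed = 1, threshold = 1) {
  clone <- as.matrix(clone_cells)
  if (ncol(clone) != 2) stop("clone_cells must be (row, col) pairs")
  if (any(clone[, 1] < 1 | clone[, 1] > n_rows |
          clone[, 2] < 1 | clone[, 2] > n_cols)) {
    stop("clone outside grid")
  }
  p_active <- if (is.function(activity_vs_row)) {
    activity_vs_row
  } else {
    function(d) {
      v <- activity_vs_row[as.character(d)]
      ifelse(is.na(v), 0, v)
    }
  }

  dist <- matrix(NA_integer_, n_rows, n_cols)
  queue <- clone
  dist[clone] <- 0L
  d <- 0L
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(queue))) {
      r <- queue[i, 1]; cc <- queue[i, 2]
      for (step in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + step[1]; c2 <- cc + step[2]
        if (rr >= 1 && rr <= n_rows && c2 >= 1 && c2 <= n_cols &&
            is.na(dist[rr, c2])) {
          dist[rr, c2] <- d + 1L
          nxt <- rbind(nxt, c(rr, c2))
        }
      }
    }
    queue <- if (is.null(nxt)) matrix(integer(), 0, 2) else nxt
    d <- d + 1L
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cells <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  cells$row_distance <- dist[cbind(cells$row, cells$col)]
  cells$is_clone <- cells$row_distance == 0L
  prob <- vapply(cells$row_distance, p_active, numeric(1))
  prob[cells$is_clone] <- 0
  stopifnot(all(prob >= 0 & prob <= 1))
  active <- runif(nrow(cells)) < prob
  cyto <- runif(nrow(cells), 80, 120)
  ratio <- ifelse(active,
                  runif(nrow(cells), 0.1, 0.9) * threshold,
                  runif(nrow(cells), 1.1, 2.0) * threshold)
  cells$nuclear_intensity <- ratio * cyto
  cells$cytoplasmic_intensity <- cyto
  class(cells) <- c("cell_grid", "data.frame")
  attr(cells, "threshold") <- threshold
  cells
}
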