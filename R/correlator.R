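#' Construct a correlation curve
#'
#' @param lags lag times in us, strictly increasing and positive.
#' @param g dimensionless correlation amplitudes G(tau).
#' @param sigma per-lag standard errors (may be NA when unavailable).
#' @param kind one of `"auto_green"`, `"auto_red"`, `"cross"`.
#' @param settings free-form list of correlator settings.
#' @return an object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, g, sigma = rep(NA_real_, length(lags)),
                              kind = c("auto_green", "auto_red", "cross"),
                              settings = list()) {
  kind <- match.arg(kind)
  stopifnot(length(lags) == length(g), length(sigma) == length(g),
            all(lags > 0), all(diff(lags) > 0), all(is.finite(g)),
            all(is.na(sigma) | sigma >= 0))
  structure(list(lags = lags, g = g, sigma = sigma, kind = kind,
                 settings = settings),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation_curve (%s): %d lags, %g - %g us, G(first) = %.4g\n",
              x$kind, length(x$lags), min(x$lags), max(x$lags), x$g[1]))
  invisible(x)
}

#' Multi-tau correlation of a two-channel photon trace
#'
#' Computes the normalized fluctuation correlation
#' \deqn{G(\tau) = \frac{\langle \delta I_a(t)\, \delta I_b(t+\tau)\rangle}
#'                     {\langle I_a \rangle \langle I_b \rangle}}
#' on a quasi-logarithmic lag grid using a multi-tau scheme with `m` points
#' per octave and pairwise rebinning, with symmetric normalization (means
#' re-estimated per lag over the overlapping windows). The shortest lag is
#' one bin; lag zero is excluded as shot-noise dominated. Per-lag standard
#' errors come from splitting the trace into `n_segments` equal segments and
#' taking the standard error of the per-segment curves; the reported curve is
#' restricted to lags reachable within one segment.
#'
#' @param trace a [photon_trace()].
#' @param kind which correlation to compute: `"auto_green"`, `"auto_red"` or
#'   `"cross"`.
#' @param m points per octave.
#' @param n_segments number of segments for the uncertainty estimate; set to
#'   1 to skip (sigma all NA).
#' @return a [correlation_curve()].
#' @export
multi_tau_correlate <- function(trace, kind = c("auto_green", "auto_red",
                                                "cross"),
                                m = 16, n_segments = 10) {
  kind <- match.arg(kind)
  stopifnot(inherits(trace, "photon_trace"))
  a <- switch(kind, auto_green = trace$counts_green,
              auto_red = trace$counts_red, cross = trace$counts_green)
  b <- switch(kind, auto_green = trace$counts_green,
              auto_red = trace$counts_red, cross = trace$counts_red)
  if (length(a) < 4 * m) stop("trace too short: need >= 2 octaves of bins")
  if (mean(a) <= 0 || mean(b) <= 0) {
    stop("zero-mean channel: correlation undefined")
  }

  full <- multitau_cpp(as.numeric(a), as.numeric(b), m, trace$bin_width)

  if (n_segments > 1) {
    seg_len <- floor(length(a) / n_segments)
    if (seg_len < 4 * m) stop("segments too short for uncertainty estimate")
    seg_g <- NULL
    for (s in seq_len(n_segments)) {
      idx <- ((s - 1) * seg_len + 1):(s * seg_len)
      sg <- multitau_cpp(as.numeric(a[idx]), as.numeric(b[idx]), m,
                         trace$bin_width)
      seg_g <- cbind(seg_g, sg$g)
    }
    n_lag <- nrow(seg_g)
    sigma <- apply(seg_g, 1, sd) / sqrt(n_segments)
    # a sd over few segments is itself noisy; smooth it across neighbouring
    # lags (running geometric mean) so 1/sigma^2 weights do not over-weight
    # lags whose segment spread happened to come out small
    pos <- sigma[sigma > 0]
    if (length(pos)) {
      sigma[sigma <= 0] <- min(pos)
      ls <- log(sigma)
      sigma <- exp(vapply(seq_len(n_lag), function(i) {
        mean(ls[max(1, i - 2):min(n_lag, i + 2)])
      }, 0))
    }
    lags <- full$lag_us[seq_len(n_lag)]
    g <- full$g[seq_len(n_lag)]
  } else {
    lags <- full$lag_us
    g <- full$g
    sigma <- rep(NA_real_, length(g))
  }

  correlation_curve(lags, g, sigma, kind,
                    settings = list(m = m, n_segments = n_segments,
                                    bin_width = trace$bin_width,
                                    duration = trace$duration))
}
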