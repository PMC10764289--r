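# On-disk formats: delimited text with '#'-prefixed header lines for traces,
# curves and decays; JSON lines for measurement records; plain JSON for
# ground-truth sidecars and manifests. Every writer round-trips through its
# reader.

.write_header <- function(con, fields) {
  for (nm in names(fields)) {
    val <- fields[[nm]]
    if (is.list(val)) {
      val <- jsonlite::toJSON(val, auto_unbox = TRUE, digits = NA)
    }
    writeLines(sprintf("# %s: %s", nm, as.character(val)), con)
  }
}

.read_header <- function(path) {
  lines <- readLines(path, n = 100)
  hdr <- grep("^# ", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Write / read a photon trace as delimited text
#'
#' Two count columns with '#'-prefixed header lines carrying the bin width
#' and JSON-encoded metadata.
#'
#' @param trace a [photon_trace()].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [photon_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "fccsfret-trace-v1",
                          bin_width_us = trace$bin_width,
                          duration_s = trace$duration,
                          metadata = trace$metadata))
  writeLines("counts_green counts_red", con)
  writeLines(paste(trace$counts_green, trace$counts_red), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- .read_header(path)
  if (!identical(hdr$format, "fccsfret-trace-v1")) {
    stop("not a photon trace file: ", path)
  }
  d <- read.table(path, header = TRUE, comment.char = "#")
  meta <- if (!is.null(hdr$metadata)) {
    jsonlite::fromJSON(hdr$metadata, simplifyVector = TRUE)
  } else list()
  photon_trace(d$counts_green, d$counts_red,
               as.numeric(hdr$bin_width_us), metadata = meta)
}

#' Write / read a correlation curve as delimited text
#'
#' Columns `lag_us`, `G`, `sigma`; the header records the curve kind and
#' correlator settings.
#'
#' @param curve a [correlation_curve()].
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "fccsfret-curve-v1", kind = curve$kind,
                          settings = curve$settings))
  writeLines("lag_us G sigma", con)
  writeLines(sprintf("%.17g %.17g %.17g", curve$lags, curve$g, curve$sigma),
             con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  hdr <- .read_header(path)
  if (!identical(hdr$format, "fccsfret-curve-v1")) {
    stop("not a correlation curve file: ", path)
  }
  d <- read.table(path, header = TRUE, comment.char = "#")
  settings <- if (!is.null(hdr$settings)) {
    jsonlite::fromJSON(hdr$settings, simplifyVector = TRUE)
  } else list()
  correlation_curve(d$lag_us, d$G, d$sigma, hdr$kind, settings)
}

#' Write / read a TCSPC decay as delimited text
#'
#' @param decay a [simulate_tcspc()] object.
#' @param path file path.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "tcspc_decay"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "fccsfret-decay-v1",
                          irf_sigma_ns = decay$irf_sigma,
                          bin_width_ns = decay$bin_edges[2] -
                            decay$bin_edges[1],
                          range_ns = max(decay$bin_edges)))
  writeLines("bin_start_ns counts", con)
  writeLines(paste(head(decay$bin_edges, -1), decay$counts), con)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  hdr <- .read_header(path)
  if (!identical(hdr$format, "fccsfret-decay-v1")) {
    stop("not a decay file: ", path)
  }
  d <- read.table(path, header = TRUE, comment.char = "#")
  bw <- as.numeric(hdr$bin_width_ns)
  structure(list(bin_edges = c(d$bin_start_ns, max(d$bin_start_ns) + bw),
                 counts = as.integer(d$counts),
                 irf_sigma = as.numeric(hdr$irf_sigma_ns),
                 total_photons = sum(d$counts),
                 metadata = list()),
            class = "tcspc_decay")
}

#' Write / read FCCS measurement records as JSON lines
#'
#' One JSON object per measurement (fit results, concentrations, K_d,
#' flags, location label); per-curve fit objects are reduced to their
#' parameter vectors.
#'
#' @param measurements list of [analyze_fccs_trace()] results.
#' @param path file path.
#' @export
write_measurements <- function(measurements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in measurements) {
    rec <- m[c("n1", "n2", "ncc", "c_green", "c_red", "c_cc", "kd",
               "kd_is_bound", "excluded", "exclusion_reason", "flags",
               "location_label")]
    rec$fit_pars <- lapply(m$fits, function(f) {
      if (isTRUE(f$converged)) as.list(f$par) else list()
    })
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    rec$flags <- as.character(rec$flags)
    if (is.null(rec$kd)) rec$kd <- NA_real_
    if (is.null(rec$exclusion_reason)) rec$exclusion_reason <- NA_character_
    structure(rec, class = "fccs_measurement")
  })
}
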