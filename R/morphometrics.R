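#' Classify a membrane protrusion as a filopodium
#'
#' A protrusion counts as a filopodium as soon as both its length and width
#' reach 1 um (boundary inclusive). The alternative reading for thin
#' protrusions (length at least, width at most, the cutoff) is selectable.
#'
#' @param length,width protrusion measurements, um (base to tip).
#' @param rule `"both_at_least"` (literal conjunctive reading) or
#'   `"thin"` (length >= cutoff and width <= cutoff).
#' @param cutoff size cutoff, um.
#' @return logical.
#' @export
classify_filopodium <- function(length, width,
                                rule = c("both_at_least", "thin"),
                                cutoff = 1) {
  rule <- match.arg(rule)
  if (any(length < 0) || any(width < 0)) {
    stop("length and width must be non-negative")
  }
  if (rule == "both_at_least") {
    length >= cutoff & width >= cutoff
  } else {
    length >= cutoff & width <= cutoff
  }
}

#' Bin protrusion lengths
#'
#' @param lengths lengths in um.
#' @param edges strictly increasing bin edges, um (last bin closed).
#' @return data.frame with `bin`, `count`, `fraction` (fractions sum to 1
#'   over non-empty input).
#' @export
bin_lengths <- function(lengths, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing")
  }
  idx <- findInterval(lengths, edges, rightmost.closed = TRUE)
  in_range <- idx >= 1 & idx <= length(edges) - 1
  counts <- tabulate(idx[in_range], nbins = length(edges) - 1)
  total <- sum(counts)
  data.frame(bin = paste0("[", head(edges, -1), ", ", edges[-1], ")"),
             count = counts,
             fraction = if (total > 0) counts / total
                        else rep(0, length(counts)))
}

#' Circularity of a cell outline
#'
#' \eqn{4\pi A / P^2}: 1 for a circle, smaller for elongated shapes
#' (isoperimetric inequality), used to score cell shape in the notochord
#' during convergence and extension.
#'
#' @param area area, um^2.
#' @param perimeter perimeter, um (> 0).
#' @return circularity in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  if (any(area < 0)) stop("area must be non-negative")
  if (any(perimeter^2 < 4 * pi * area - 1e-9)) {
    stop("perimeter^2 < 4*pi*area violates the isoperimetric inequality")
  }
  pmin(4 * pi * area / perimeter^2, 1)
}

#' Width-to-length ratio of an expression domain
#'
#' Used for the axial-mesoderm marker domain: widening and shortening of the
#' domain raises the ratio.
#'
#' @param width,length measurements, same units.
#' @return width / length.
#' @export
domain_ratio <- function(width, length) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(width < 0)) stop("width must be non-negative")
  width / length
}

#' Kinase-translocation-reporter activity call
#'
#' Active kinase signalling exports the reporter from the nucleus, so a
#' nuclear/cytoplasmic intensity ratio below the threshold is called active.
#'
#' @param nuclear,cytoplasmic intensities, a.u.
#' @param threshold call threshold on the ratio (default parity).
#' @return a data.frame with `ratio` and `active`.
#' @export
ktr_activity <- function(nuclear, cytoplasmic, threshold = 1) {
  if (any(cytoplasmic <= 0)) stop("cytoplasmic intensity must be positive")
  if (any(nuclear < 0)) stop("nuclear intensity must be non-negative")
  ratio <- nuclear / cytoplasmic
  data.frame(ratio = ratio, active = ratio < threshold)
}

#' Paracrine activation profile by cell-row distance from a clone
#'
#' Fraction of active (reporter-excluding) cells per cell-row distance from
#' the source clone, up to `max_rows` rows (the paracrine range analysed);
#' row distance is graph distance on cell adjacency, i.e. counted in cells.
#'
#' @param grid a [generate_cell_grid()] data.frame (columns `row_distance`,
#'   `is_clone`, `nuclear_intensity`, `cytoplasmic_intensity`).
#' @param max_rows analyse up to this row distance.
#' @param threshold activity-call threshold.
#' @return data.frame with `row_distance`, `n_cells`, `n_active`,
#'   `fraction_active` (NA where a row has no cells).
#' @export
paracrine_profile <- function(grid, max_rows = 5, threshold = 1) {
  req <- c("row_distance", "is_clone", "nuclear_intensity",
           "cytoplasmic_intensity")
  stopifnot(all(req %in% names(grid)))
  if (!any(grid$is_clone)) stop("grid contains no clone cells")
  act <- ktr_activity(grid$nuclear_intensity, grid$cytoplasmic_intensity,
                      threshold)
  rows <- lapply(seq_len(max_rows), function(d) {
    sel <- !grid$is_clone & grid$row_distance == d
    n <- sum(sel)
    data.frame(row_distance = d, n_cells = n, n_active = sum(act$active[sel]),
               fraction_active = if (n > 0) sum(act$active[sel]) / n
                                 else NA_real_)
  })
  do.call(rbind, rows)
}
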