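#' Log-spaced frequency band scheme
#'
#' Defines the 11 contiguous frequency bins used for all spectral and
#' temporal-correlation biomarkers: one delta bin from 1 to 4 Hz and ten
#' logarithmically spaced bins between 4 and 44.8 Hz, so that
#' `edge(k+1)/edge(k) = (44.8/4)^(1/10)` above 4 Hz. Bins are grouped into
#' five canonical bands: delta (bin 1), theta (bins 2-4), alpha (bins 5-6),
#' beta (bins 7-8) and high beta/gamma (bins 9-11).
#'
#' Edges are kept at full precision internally; `display_edges` rounds to one
#' decimal for reporting (1, 4, 5.1, 6.5, 8.3, 10.5, 13.4, 17, 21.7, 27.6,
#' 35.2, 44.8 Hz).
#'
#' @return An object of class `band_scheme` with elements
#'   `edges` (12 unrounded bin edges in Hz), `display_edges` (rounded),
#'   `groups` (named list mapping canonical band to bin indices),
#'   `band_edges` (named list of canonical band frequency ranges) and
#'   `range` (the 1-45 Hz total-power integration range).
#' @examples
#' sch <- band_scheme()
#' sch$display_edges
#' sch$groups$alpha
#' @export
band_scheme <- function() {
  ratio <- (44.8 / 4)^(1 / 10)
  edges <- c(1, 4 * ratio^(0:10))
  groups <- list(
    delta = 1L,
    theta = 2:4,
    alpha = 5:6,
    beta = 7:8,
    beta_gamma = 9:11
  )
  band_edges <- lapply(groups, function(idx) {
    c(edges[min(idx)], edges[max(idx) + 1L])
  })
  structure(
    list(
      edges = edges,
      display_edges = round(edges, 1),
      groups = groups,
      band_edges = band_edges,
      range = c(1, 45),
      n_bins = 11L
    ),
    class = "band_scheme"
  )
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Frequency band scheme: 11 bins, 1-44.8 Hz (log-spaced above 4 Hz)\n")
  lo <- x$display_edges[-length(x$display_edges)]
  hi <- x$display_edges[-1]
  bands <- rep(names(x$groups), lengths(x$groups))
  cat(sprintf("  bin %2d: %5.1f - %5.1f Hz  [%s]\n", 1:11, lo, hi, bands), sep = "")
  invisible(x)
}

#' Canonical band labels in scheme order
#' @param scheme a [band_scheme()]
#' @return character vector of the five canonical band names
#' @export
canonical_bands <- function(scheme = band_scheme()) names(scheme$groups)

#' The seven functional network labels
#'
#' Large-scale resting-state networks used for spatial aggregation:
#' default (DEF), somatomotor (SOM), salience/ventral attention (SVA),
#' dorsal attention (DA), visual (VIS), limbic (LIM) and control (CON).
#' @return character vector of length 7
#' @export
network_labels <- function() c("DEF", "SOM", "SVA", "DA", "VIS", "LIM", "CON")
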