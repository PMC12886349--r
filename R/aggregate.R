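# Aggregation of parcel x bin biomarker values into the 35-feature
# band-by-network representation (5 canonical bands x 7 networks).

#' Default parcel-to-network mapping
#'
#' A synthetic, balanced 100-parcel mapping: each hemisphere contains all
#' seven networks with 7-8 parcels each. It stands in for an atlas-derived
#' mapping table, which can be supplied instead via [read_parcel_map()].
#'
#' @return data.frame with columns `parcel_id`, `network`, `hemisphere`
#' @export
default_parcel_map <- function() {
  sizes <- c(DEF = 8, SOM = 8, SVA = 7, DA = 7, VIS = 7, LIM = 6, CON = 7) # 50 per hemisphere
  data.frame(
    parcel_id = 1:100,
    network = rep(rep(names(sizes), sizes), 2),
    hemisphere = rep(c("L", "R"), each = 50),
    stringsAsFactors = FALSE
  )
}

#' Read and validate a parcel-to-network map from CSV
#'
#' @param path CSV with columns `parcel_id`, `network`, `hemisphere`
#' @return validated data.frame
#' @export
read_parcel_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_parcel_map(map)
  map
}

validate_parcel_map <- function(map) {
  need <- c("parcel_id", "network", "hemisphere")
  if (!all(need %in% names(map))) {
    stop("parcel map must have columns parcel_id, network, hemisphere")
  }
  if (anyDuplicated(map$parcel_id)) stop("every parcel must be mapped exactly once")
  if (!all(map$network %in% network_labels())) {
    stop(
      "unknown network label(s): ",
      paste(setdiff(unique(map$network), network_labels()), collapse = ", ")
    )
  }
  if (!all(map$hemisphere %in% c("L", "R"))) stop("hemisphere must be 'L' or 'R'")
  tab <- table(map$network, map$hemisphere)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop(sprintf(
      "network %s has no parcels in hemisphere %s",
      rownames(tab)[miss[1, 1]], colnames(tab)[miss[1, 2]]
    ))
  }
  invisible(map)
}

#' Collapse 11 bins into the 5 canonical bands
#'
#' Power biomarkers are sum-aggregated across the bins of each canonical
#' band (with dB values first converted to linear power, summed, and
#' reconverted, since decibels do not add); DFA exponents are
#' median-aggregated.
#'
#' @param values parcels x 11 matrix of per-bin values, bin order as in the
#'   scheme
#' @param scheme a [band_scheme()]
#' @param method `"sum"` for power biomarkers, `"median"` for DFA exponents
#' @param db set `TRUE` when summing values expressed in dB
#' @return parcels x 5 matrix with canonical-band column names
#' @export
bins_to_bands <- function(values, scheme = band_scheme(), method = c("sum", "median"),
                          db = FALSE) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (ncol(values) != scheme$n_bins) {
    stop(sprintf("expected %d bin columns, got %d", scheme$n_bins, ncol(values)))
  }
  out <- vapply(scheme$groups, function(idx) {
    block <- values[, idx, drop = FALSE]
    if (method == "median") {
      apply(block, 1, stats::median)
    } else if (db) {
      10 * log10(rowSums(10^(block / 10)))
    } else {
      rowSums(block)
    }
  }, numeric(nrow(values)))
  out <- matrix(out, nrow = nrow(values), dimnames = list(rownames(values), names(scheme$groups)))
  out
}

#' Collapse parcels into the 35 band-by-network features
#'
#' For each canonical band: the median across parcels within each (network,
#' hemisphere) cell, then the arithmetic mean of the left and right
#' hemisphere medians, giving 7 network values per band and 35 features in
#' total, named `band_network`.
#'
#' @param values parcels x 5 matrix of canonical-band values
#'   (from [bins_to_bands()]); rows in parcel-id order matching `map`
#' @param map a parcel-to-network map ([default_parcel_map()] layout)
#' @return named numeric vector of 35 features
#' @export
parcels_to_networks <- function(values, map = default_parcel_map()) {
  values <- as.matrix(values)
  validate_parcel_map(map)
  if (nrow(values) != nrow(map)) {
    stop(sprintf("map covers %d parcels but %d rows of values supplied", nrow(map), nrow(values)))
  }
  bands <- colnames(values)
  if (is.null(bands)) bands <- canonical_bands()
  nets <- network_labels()
  out <- numeric(0)
  for (b in seq_along(bands)) {
    for (net in nets) {
      hemi_med <- vapply(c("L", "R"), function(h) {
        stats::median(values[map$network == net & map$hemisphere == h, b])
      }, numeric(1))
      out[paste(bands[b], net, sep = "_")] <- mean(hemi_med)
    }
  }
  out
}

#' Full biomarker feature extraction for one subject
#'
#' Runs the spectral and temporal-correlation stages on a parcel signal block
#' and aggregates to the 35-feature representation for each of the three
#' biomarkers: absolute power (dB, linear-sum aggregated), relative power
#' (%, summed) and LRTC (DFA exponents, median aggregated).
#'
#' @param signals parcels x samples matrix
#' @param fs sampling rate (Hz)
#' @param map parcel-to-network map
#' @param scheme a [band_scheme()]
#' @param config a [dfa_config()]
#' @param biomarkers subset of `c("absolute", "relative", "lrtc")`
#' @return named list of 35-feature vectors, one per requested biomarker
#' @export
subject_features <- function(signals, fs, map = default_parcel_map(),
                             scheme = band_scheme(), config = dfa_config(),
                             biomarkers = c("absolute", "relative", "lrtc")) {
  biomarkers <- match.arg(biomarkers, several.ok = TRUE)
  out <- list()
  if (any(c("absolute", "relative") %in% biomarkers)) {
    bp <- parcel_band_powers(signals, fs, scheme)
    absm <- matrix(bp$absolute_db, ncol = scheme$n_bins, byrow = TRUE)
    relm <- matrix(bp$relative_pct, ncol = scheme$n_bins, byrow = TRUE)
    if ("absolute" %in% biomarkers) {
      out$absolute <- parcels_to_networks(bins_to_bands(absm, scheme, "sum", db = TRUE), map)
    }
    if ("relative" %in% biomarkers) {
      out$relative <- parcels_to_networks(bins_to_bands(relm, scheme, "sum"), map)
    }
  }
  if ("lrtc" %in% biomarkers) {
    dv <- parcel_dfa(signals, fs, scheme, config, bands = "bins")
    dfam <- matrix(dv$dfa_exponent, ncol = scheme$n_bins, byrow = TRUE)
    out$lrtc <- parcels_to_networks(bins_to_bands(dfam, scheme, "median"), map)
  }
  out
}
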