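bin_index <- function(pos, len, n_bins) {
  # equal-width bins over [0, len); the last bin absorbs the remainder
  w <- len / n_bins
  pmin(as.integer(pos / w) + 1L, n_bins)
}

#' Build a binned Hi-C contact map for a replicon pair
#'
#' End positions are binned into `n_bins` equal-width bins per replicon
#' (each bin covers 1% of its replicon at the default of 100 bins; the
#' last bin absorbs any remainder), and each read pair increments the
#' corresponding matrix cell. Intra-replicon maps are symmetric, with
#' each pair counted once on the unordered bin pair, so the total link
#' count is conserved (see [contact_map_total()]). Optional restriction
#' maps add per-bin site histograms for display margins.
#'
#' @param links a link table; only pairs with both ends on
#'   `replicon_a`/`replicon_b` are used.
#' @param replicon_a,replicon_b replicon ids (equal for an intra map).
#' @param len_a,len_b replicon lengths in bp.
#' @param n_bins number of bins per axis (default 100); must not exceed
#'   either replicon length.
#' @param rmap_a,rmap_b optional `restriction_map`s for the site
#'   histograms.
#' @return A list of class `contact_map`: `matrix` (`n_bins` x
#'   `n_bins`), `replicon_a`, `replicon_b`, `n_bins`, `transform`
#'   (`"none"`), `n_links`, `site_histogram_a`, `site_histogram_b`.
#' @export
build_contact_map <- function(links, replicon_a, replicon_b, len_a, len_b,
                              n_bins = 100, rmap_a = NULL, rmap_b = NULL) {
  if (n_bins > len_a || n_bins > len_b)
    stop_param("`n_bins` must not exceed the replicon length")
  intra <- replicon_a == replicon_b
  fwd <- links$ref_a == replicon_a & links$ref_b == replicon_b
  rev <- !intra & links$ref_a == replicon_b & links$ref_b == replicon_a
  pa <- c(links$pos_a[fwd], links$pos_b[rev])
  pb <- c(links$pos_b[fwd], links$pos_a[rev])
  ia <- bin_index(pa, len_a, n_bins)
  ib <- bin_index(pb, len_b, n_bins)
  if (intra) {
    lo <- pmin(ia, ib)
    hi <- pmax(ia, ib)
    ia <- lo; ib <- hi
  }
  m <- unclass(table(factor(ia, levels = seq_len(n_bins)),
                     factor(ib, levels = seq_len(n_bins))))
  dimnames(m) <- NULL
  if (intra) m <- m + t(m) - diag(diag(m))
  site_hist <- function(rmap, len) {
    if (is.null(rmap)) return(NULL)
    tabulate(bin_index(rmap$positions, len, n_bins), nbins = n_bins)
  }
  structure(list(matrix = m, replicon_a = replicon_a,
                 replicon_b = replicon_b, n_bins = as.integer(n_bins),
                 transform = "none", n_links = length(pa),
                 site_histogram_a = site_hist(rmap_a, len_a),
                 site_histogram_b = site_hist(rmap_b, len_b)),
            class = "contact_map")
}

#' Total pair count represented by a contact map
#'
#' For intra-replicon (symmetric) maps the total is the upper-triangle
#' sum including the diagonal; for inter-replicon maps, the full sum.
#'
#' @param map a raw `contact_map`.
#' @return Total link count.
#' @export
contact_map_total <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (map$replicon_a == map$replicon_b) {
    sum(map$matrix[upper.tri(map$matrix, diag = TRUE)])
  } else {
    sum(map$matrix)
  }
}

#' Log-scale a contact map
#'
#' Replaces each count by `log(1 + count)` — monotone and
#' zero-preserving.
#'
#' @param map a `contact_map` with `transform = "none"`.
#' @return The transformed `contact_map`.
#' @export
transform_log <- function(map) {
  stopifnot(inherits(map, "contact_map"), map$transform == "none")
  map$matrix <- log1p(map$matrix)
  map$transform <- "log"
  map
}

#' Spearman-rank transform of a contact map
#'
#' Each element (i, j) is replaced by the Spearman rank correlation
#' between row i and column j of the raw matrix. The transform
#' highlights structural signals — on a circular replicon the map's
#' corners light up because the first and last bins have correlated
#' contact profiles. Elements whose row or column is constant have an
#' undefined correlation and are stored as `NA` (not zero, which would
#' fake anticorrelation). Restricted to square (intra-replicon or
#' equal-bin) maps; ranks use average-rank tie handling.
#'
#' @param map a square `contact_map` with `transform = "none"`.
#' @return The transformed `contact_map` (values in `[-1, 1]` or `NA`).
#' @export
transform_spearman <- function(map) {
  stopifnot(inherits(map, "contact_map"), map$transform == "none")
  m <- map$matrix
  if (nrow(m) != ncol(m)) stop_param("Spearman transform needs a square map")
  rr <- apply(m, 1, rank)          # column k = ranks of row k
  cc <- apply(m, 2, rank)          # column k = ranks of column k
  out <- suppressWarnings(stats::cor(rr, cc, method = "pearson"))
  const_row <- apply(m, 1, function(v) length(unique(v)) == 1L)
  const_col <- apply(m, 2, function(v) length(unique(v)) == 1L)
  out[const_row, ] <- NA_real_
  out[, const_col] <- NA_real_
  map$matrix <- out
  map$transform <- "spearman"
  map
}

#' Normalized insert-distance histogram
#'
#' Minimum-path (circular) distances of intra-replicon read pairs are
#' computed, pairs closer than `min_separation` are discarded, and the
#' survivors are binned into `n_bins` equal bins over
#' `[min_separation, range_max]` (left-closed bins; the final bin is
#' right-closed). Counts are normalized to sum to 1.
#'
#' @param links a link table.
#' @param replicon replicon id.
#' @param replicon_length length in bp.
#' @param n_bins number of bins (default 100).
#' @param min_separation discard pairs closer than this (default
#'   1,000 bp).
#' @param range_max histogram upper bound; defaults to the maximum
#'   circular distance `floor(replicon_length / 2)`.
#' @param circular treat the replicon as circular.
#' @return data.frame with `lower`, `upper`, `count`, `density`
#'   (normalized to sum 1), or zero rows when no pair survives (with a
#'   warning).
#' @export
insert_histogram <- function(links, replicon, replicon_length,
                             n_bins = 100, min_separation = 1000,
                             range_max = NULL, circular = TRUE) {
  range_max <- range_max %||% floor(replicon_length / 2)
  sel <- links$ref_a == replicon & links$ref_b == replicon
  d <- circular_distance(links$pos_a[sel], links$pos_b[sel],
                         replicon_length, circular)
  d <- d[d >= min_separation & d <= range_max]
  edges <- seq(min_separation, range_max, length.out = n_bins + 1)
  if (length(d) == 0) {
    warning("no read pairs survive the separation filter")
    return(data.frame(lower = edges[-length(edges)], upper = edges[-1],
                      count = 0L, density = numeric(n_bins)))
  }
  idx <- pmin(findInterval(d, edges), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = counts, density = counts / sum(counts))
}
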