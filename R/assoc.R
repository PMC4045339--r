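#' Build a contig-by-contig association matrix from Hi-C links
#'
#' Entry `c_ij` counts the read pairs with one end aligning in contig i
#' and the other in contig j, regardless of read-end order. Self-links
#' (both ends in one contig) are recorded on the diagonal but are never
#' emitted as clustering edges.
#'
#' @param links a link table in contig coordinates (see
#'   [liftover_links()]).
#' @param contigs contig ids and lengths: a `contig_set` or a data.frame
#'   with `id` and `length`.
#' @return A list of class `assoc_matrix`: `ids`, `lengths`, `counts`
#'   (symmetric sparse matrix, zero diagonal), `self_counts`, and
#'   `normalized` (`NULL` until [normalize_assoc()]).
#' @export
build_association_matrix <- function(links, contigs) {
  refs <- ref_lookup(contigs)
  ids <- refs$id
  ia <- match(links$ref_a, ids)
  ib <- match(links$ref_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(links$ref_a[is.na(ia)], links$ref_b[is.na(ib)]))
    stop_param("links reference unknown contig(s): %s",
               paste(head(bad, 3), collapse = ", "))
  }
  n <- length(ids)
  i <- pmin(ia, ib)
  j <- pmax(ia, ib)
  self <- i == j
  self_counts <- integer(n)
  if (any(self)) {
    tab <- table(i[self])
    self_counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts <- Matrix::sparseMatrix(i = i[!self], j = j[!self],
                                 x = rep(1, sum(!self)),
                                 dims = c(n, n), symmetric = TRUE)
  dimnames(counts) <- list(ids, ids)
  structure(list(ids = ids, lengths = refs$length, counts = counts,
                 self_counts = self_counts, normalized = NULL),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  nnz <- length(Matrix::which(x$counts != 0)) / 2
  cat(sprintf("<assoc_matrix> %d contigs, %.0f edges, %s\n",
              length(x$ids), nnz,
              if (is.null(x$normalized)) "raw counts" else "normalized"))
  invisible(x)
}

#' Filter an association matrix by contig size and contact count
#'
#' Drops contigs shorter than `min_contig_len` (with all their edges),
#' then drops edges supported by `min_contacts` or fewer read pairs:
#' only associations strictly greater than the contact minimum survive
#' (with `min_contacts = 5`, pairs associated by 5 or fewer read pairs
#' are excluded). Applied before normalization.
#'
#' @param mat an `assoc_matrix` with raw counts.
#' @param min_contacts contact minimum k (edges with `c_ij <= k` drop).
#' @param min_contig_len contig size minimum in bp.
#' @return The filtered `assoc_matrix`.
#' @export
filter_assoc <- function(mat, min_contacts = 0, min_contig_len = 0) {
  stopifnot(inherits(mat, "assoc_matrix"))
  if (min_contacts < 0 || min_contig_len < 0)
    stop_param("filter thresholds must be >= 0")
  keep <- mat$lengths >= min_contig_len
  counts <- mat$counts[keep, keep, drop = FALSE]
  counts <- Matrix::drop0(counts * (counts > min_contacts))
  structure(list(ids = mat$ids[keep], lengths = mat$lengths[keep],
                 counts = counts, self_counts = mat$self_counts[keep],
                 normalized = NULL),
            class = "assoc_matrix")
}

#' Length-normalize an association matrix
#'
#' Raw counts inflate with contig length; the normalized weight
#' `c'_ij = max(L)^2 * c_ij / (l_i * l_j)` (with `max(L)` taken over the
#' contigs present in the matrix) corrects this, and is invariant to
#' rescaling all lengths by a common factor.
#'
#' @param mat an `assoc_matrix` (usually after [filter_assoc()]).
#' @return The `assoc_matrix` with `normalized` populated.
#' @export
normalize_assoc <- function(mat) {
  stopifnot(inherits(mat, "assoc_matrix"))
  if (length(mat$ids) == 0) {
    mat$normalized <- mat$counts
    return(mat)
  }
  if (any(mat$lengths <= 0)) stop_param("contig lengths must be > 0")
  maxL <- max(mat$lengths)
  inv <- Matrix::Diagonal(x = 1 / mat$lengths)
  norm <- maxL^2 * (inv %*% mat$counts %*% inv)
  norm <- as(Matrix::forceSymmetric(norm), "CsparseMatrix")
  dimnames(norm) <- dimnames(mat$counts)
  mat$normalized <- norm
  mat
}

#' Replicon-level association table and within-cell association rate
#'
#' Counts, for every replicon pair, the read pairs joining them (after
#' excluding intra-replicon pairs closer than `exclude_below`, which are
#' uninformative local fragments), and computes the within-cell rate:
#' the fraction of counted pairs whose two ends fall in replicons of the
#' same cell. Also returns the length-normalized, log-scaled table used
#' for heat-map display, and each plasmid's most-associated foreign
#' replicon (its inferred host chromosome).
#'
#' @param links a link table in replicon coordinates.
#' @param community an `hic_community`.
#' @param exclude_below intra-replicon distance threshold in bp
#'   (default 1,000).
#' @return A list of class `replicon_assoc`: `table` (symmetric count
#'   matrix, diagonal = intra-replicon pairs kept), `norm_log`,
#'   `within_cell_rate`, `n_used`, and `host_assignment` (data.frame for
#'   plasmids).
#' @export
replicon_association_table <- function(links, community,
                                       exclude_below = 1000) {
  stopifnot(inherits(community, "hic_community"))
  refs <- replicon_info(community)
  if (!all(c(links$ref_a, links$ref_b) %in% refs$id))
    stop_param("links reference replicons missing from the community")
  d <- pair_distance(links, refs)
  keep <- is.na(d) | d >= exclude_below
  lk <- links[keep, , drop = FALSE]
  ids <- refs$id
  n <- length(ids)
  ia <- pmin(match(lk$ref_a, ids), match(lk$ref_b, ids))
  ib <- pmax(match(lk$ref_a, ids), match(lk$ref_b, ids))
  tab <- unclass(table(factor(ia, levels = seq_len(n)),
                       factor(ib, levels = seq_len(n))))
  dimnames(tab) <- list(ids, ids)
  tab <- tab + t(tab) - diag(diag(tab))
  cell_of <- refs$cell_id[match(ids, refs$id)]
  same_cell <- cell_of[ia] == cell_of[ib]
  rate <- if (length(ia) > 0) mean(same_cell) else NA_real_
  lens <- refs$length[match(ids, refs$id)]
  norm_log <- log1p(max(lens)^2 * tab / outer(lens, lens))
  plasmids <- refs$id[community$replicons$role == "plasmid"]
  host <- NULL
  if (length(plasmids) > 0) {
    host <- do.call(rbind, lapply(plasmids, function(p) {
      foreign <- tab[p, setdiff(ids, p)]
      data.frame(plasmid = p,
                 top_partner = names(which.max(foreign)),
                 count = max(foreign), stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, norm_log = norm_log,
                 within_cell_rate = rate, n_used = length(ia),
                 exclude_below = exclude_below, host_assignment = host),
            class = "replicon_assoc")
}

#' @export
print.replicon_assoc <- function(x, ...) {
  cat(sprintf(
    "<replicon_assoc> %d pairs counted (intra < %d bp excluded)\n",
    x$n_used, x$exclude_below))
  cat(sprintf("  within-cell association rate: %.4f\n",
              x$within_cell_rate))
  if (!is.null(x$host_assignment)) {
    for (i in seq_len(nrow(x$host_assignment)))
      cat(sprintf("  plasmid %s -> %s (%d pairs)\n",
                  x$host_assignment$plasmid[i],
                  x$host_assignment$top_partner[i],
                  x$host_assignment$count[i]))
  }
  invisible(x)
}

#' Write an association matrix as an edge list
#'
#' Writes the de-facto "abc" TSV edge-list format (`id_a id_b weight`,
#' upper triangle only) plus a companion lengths TSV.
#'
#' @param mat an `assoc_matrix`.
#' @param path edge-list output path.
#' @param lengths_path optional path for the `id length` table.
#' @param normalized write normalized weights (if present) instead of
#'   raw counts.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(mat, path, lengths_path = NULL,
                        normalized = !is.null(mat$normalized)) {
  m <- if (normalized) mat$normalized else mat$counts
  tri <- as(Matrix::triu(m, 1), "TsparseMatrix")
  df <- data.frame(id_a = mat$ids[tri@i + 1L], id_b = mat$ids[tri@j + 1L],
                   weight = tri@x)
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(data.frame(id = mat$ids, length = mat$lengths),
                       lengths_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an edge-list association matrix
#'
#' @param path edge-list TSV (`id_a id_b weight`).
#' @param lengths_path lengths TSV (`id length`).
#' @return An `assoc_matrix` (weights land in `counts`).
#' @export
read_assoc <- function(path, lengths_path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  lens <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  ids <- lens$id
  i <- match(edges$id_a, ids)
  j <- match(edges$id_b, ids)
  if (anyNA(i) || anyNA(j))
    stop_param("edge list references ids missing from the lengths table")
  counts <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j),
                                 x = edges$weight,
                                 dims = c(length(ids), length(ids)),
                                 symmetric = TRUE)
  dimnames(counts) <- list(ids, ids)
  structure(list(ids = ids, lengths = lens$length, counts = counts,
                 self_counts = integer(length(ids)), normalized = NULL),
            class = "assoc_matrix")
}
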