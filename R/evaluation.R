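#' Label contigs by substring vote against labeled references
#'
#' Every `k`-bp substring of each contig (taken every `step` bp, on both
#' strands) is matched exactly against the reference sequences. A
#' substring that occurs in references of exactly one species casts a
#' species vote; one that occurs in exactly one reference also casts a
#' strain vote (substrings shared between near-identical strains are
#' ambiguous at strain level, mirroring a mapping-quality cutoff). Each
#' contig is labeled by plurality; ties or contigs with no confident
#' substring are left `NA` and reported.
#'
#' @param contig_seqs [Biostrings::DNAStringSet] of contig sequences.
#' @param ref_seqs [Biostrings::DNAStringSet] of reference replicons.
#' @param ref_species character vector: species of each reference
#'   (parallel to `ref_seqs`, or named by reference).
#' @param k substring length in bp (>= 20; default 70).
#' @param step distance between successive substring starts (default 1,
#'   every substring; larger steps trade resolution for speed).
#' @return data.frame of class `label_map`: `contig_id`, `species`,
#'   `strain` (reference id), `n_substrings`, `n_species_votes`,
#'   `n_strain_votes`.
#' @export
assign_labels_by_substring_vote <- function(contig_seqs, ref_seqs,
                                            ref_species, k = 70,
                                            step = 1) {
  if (k < 20) stop_param("`k` must be >= 20")
  if (step < 1) stop_param("`step` must be >= 1")
  if (!is.null(names(ref_species)))
    ref_species <- ref_species[names(ref_seqs)]
  stopifnot(length(ref_species) == length(ref_seqs))
  subs <- list()
  owner <- list()
  for (ci in seq_along(contig_seqs)) {
    s <- contig_seqs[[ci]]
    if (length(s) < k) next
    starts <- seq.int(1L, length(s) - k + 1L, by = step)
    subs[[length(subs) + 1L]] <-
      Biostrings::DNAStringSet(s, start = starts, width = k)
    owner[[length(owner) + 1L]] <- rep(ci, length(starts))
  }
  ids <- names(contig_seqs)
  if (length(subs) == 0) {
    return(structure(data.frame(contig_id = ids, species = NA_character_,
                                strain = NA_character_, n_substrings = 0L,
                                n_species_votes = 0L, n_strain_votes = 0L,
                                stringsAsFactors = FALSE),
                     class = c("label_map", "data.frame")))
  }
  pats <- do.call(c, subs)
  owner <- unlist(owner)
  pd <- Biostrings::PDict(pats)
  hits <- sapply(seq_along(ref_seqs), function(ri) {
    r <- ref_seqs[[ri]]
    Biostrings::countPDict(pd, r) +
      Biostrings::countPDict(pd, Biostrings::reverseComplement(r)) > 0
  })
  hits <- matrix(hits, ncol = length(ref_seqs))
  n_refs_hit <- rowSums(hits)
  sp_hit <- sapply(unique(ref_species), function(sp) {
    rowSums(hits[, ref_species == sp, drop = FALSE]) > 0
  })
  sp_hit <- matrix(sp_hit, ncol = length(unique(ref_species)),
                   dimnames = list(NULL, unique(ref_species)))
  n_sp_hit <- rowSums(sp_hit)
  plurality <- function(votes) {
    if (length(votes) == 0) return(NA_character_)
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
    names(tab)[1]
  }
  res <- lapply(seq_along(ids), function(ci) {
    mine <- owner == ci
    sp_votes <- colnames(sp_hit)[
      max.col(sp_hit[mine & n_sp_hit == 1, , drop = FALSE], "first")]
    st_rows <- mine & n_refs_hit == 1
    st_votes <- names(ref_seqs)[
      max.col(hits[st_rows, , drop = FALSE], "first")]
    data.frame(contig_id = ids[ci], species = plurality(sp_votes),
               strain = plurality(st_votes), n_substrings = sum(mine),
               n_species_votes = length(sp_votes),
               n_strain_votes = length(st_votes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  n_un <- sum(is.na(out$species))
  if (n_un > 0)
    message(sprintf("assign_labels: %d contig(s) unlabeled at species level",
                    n_un))
  class(out) <- c("label_map", "data.frame")
  out
}

#' Score a cluster solution by size-weighted pair sampling
#'
#' Samples `n_pairs` random contig pairs, each contig drawn
#' independently with probability proportional to its length (pairs of
#' two identical draws are redrawn), and tallies agreement between
#' ground-truth labels and cluster assignments: same label and same
#' cluster is a true positive (TP), same label but different clusters a
#' false negative (FN), different labels in one cluster a false positive
#' (FP), and different labels in different clusters a true negative
#' (TN). Rates follow the standard formulae: TPR = TP/(TP+FN),
#' FPR = FP/(FP+TN), PPV = TP/(TP+FP), NPV = TN/(TN+FN). At
#' `level = "species"` the near-identical strain pair counts as one
#' class; at `level = "strain"` the strains are distinct classes (shared
#' co-assembled contigs, which have no single strain of origin, form
#' their own class). Labeled contigs absent from the solution are scored
#' as singleton clusters; unlabeled contigs are excluded from sampling.
#'
#' @param solution a `cluster_solution` (or data.frame `contig_id`,
#'   `cluster`).
#' @param labels a label data.frame with `contig_id`, `species`,
#'   `strain` and `length` (see [truth_labels()]).
#' @param n_pairs number of sampled pairs.
#' @param level `"species"` or `"strain"`.
#' @param seed integer seed.
#' @return A list of class `quality_report` with counts `TP`, `FP`,
#'   `FN`, `TN`, rates `TPR`, `FPR`, `PPV`, `NPV`, plus `level`,
#'   `n_pairs`, `n_unlabeled`, `seed`.
#' @export
sample_pair_quality <- function(solution, labels, n_pairs = 100000,
                                level = c("species", "strain"),
                                seed = NULL) {
  level <- match.arg(level)
  assign <- if (inherits(solution, "cluster_solution"))
    solution$assignment else solution
  stopifnot(all(c("contig_id", "cluster") %in% names(assign)),
            all(c("contig_id", "species", "length") %in% names(labels)))
  if (n_pairs < 1) stop_param("`n_pairs` must be >= 1")
  lab <- if (level == "species") labels$species else {
    ifelse(is.na(labels$strain), paste0(labels$species, "::shared"),
           labels$strain)
  }
  ok <- !is.na(lab) & labels$length > 0
  n_unlabeled <- sum(!ok)
  lab <- lab[ok]
  ids <- labels$contig_id[ok]
  lens <- labels$length[ok]
  if (length(ids) < 2) stop_param("need at least two labeled contigs")
  cl <- assign$cluster[match(ids, assign$contig_id)]
  miss <- is.na(cl)
  if (any(miss)) cl[miss] <- max(c(0, cl), na.rm = TRUE) + seq_len(sum(miss))
  with_local_seed(seed, {
    p <- lens / sum(lens)
    i <- sample.int(length(ids), n_pairs, replace = TRUE, prob = p)
    j <- sample.int(length(ids), n_pairs, replace = TRUE, prob = p)
    while (any(i == j)) {
      # redraw the whole pair so the joint law stays proportional to
      # p_i * p_j over distinct pairs
      eq <- which(i == j)
      i[eq] <- sample.int(length(ids), length(eq), replace = TRUE, prob = p)
      j[eq] <- sample.int(length(ids), length(eq), replace = TRUE, prob = p)
    }
    same_lab <- lab[i] == lab[j]
    same_cl <- cl[i] == cl[j]
    TP <- sum(same_lab & same_cl)
    FN <- sum(same_lab & !same_cl)
    FP <- sum(!same_lab & same_cl)
    TN <- sum(!same_lab & !same_cl)
    structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                   TPR = TP / (TP + FN), FPR = FP / (FP + TN),
                   PPV = TP / (TP + FP), NPV = TN / (TN + FN),
                   level = level, n_pairs = n_pairs,
                   n_unlabeled = n_unlabeled, seed = seed),
              class = "quality_report")
  })
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> level=%s n=%d  TPR=%.4f FPR=%.4f PPV=%.4f NPV=%.4f\n",
    x$level, x$n_pairs, x$TPR, x$FPR, x$PPV, x$NPV))
  invisible(x)
}

#' Sweep filtering and inflation parameters
#'
#' For each combination of contact minimum `k` and contig size minimum,
#' the association matrix is filtered and normalized, then clustered at
#' every inflation value, and each solution is scored against the labels
#' with size-weighted pair sampling. The pair-sampling universe of each
#' run is the post-size-filter contig set (the clustering run's input);
#' contigs that drop out of the clustered graph are scored as
#' singletons.
#'
#' @param mat a raw-count `assoc_matrix` over all contigs.
#' @param labels label data.frame (`contig_id`, `species`, `strain`,
#'   `length`).
#' @param contact_grid contact minimums (e.g. `c(0, 3, 5, 7, 9)`).
#' @param size_grid contig size minimums in bp.
#' @param inflation_grid inflation values (> 1).
#' @param n_pairs sampled pairs per scored solution.
#' @param level evaluation level passed to [sample_pair_quality()].
#' @param seed integer seed.
#' @param params base [mcl_params()].
#' @return Long-format data.frame: one row per
#'   `(min_contacts, min_contig_len, inflation)` with `n_clusters` and
#'   the quality counts and rates.
#' @export
sweep_parameters <- function(mat, labels, contact_grid = c(0, 3, 5, 7, 9),
                             size_grid = c(0, 5000), inflation_grid = 1.1,
                             n_pairs = 10000, level = "species",
                             seed = NULL, params = mcl_params()) {
  stopifnot(inherits(mat, "assoc_matrix"))
  rows <- list()
  for (L in size_grid) {
    for (k in contact_grid) {
      f <- normalize_assoc(filter_assoc(mat, min_contacts = k,
                                        min_contig_len = L))
      universe <- mat$ids[mat$lengths >= L]
      lab_run <- labels[labels$contig_id %in% universe, , drop = FALSE]
      for (r in inflation_grid) {
        sol <- mcl_cluster(f, params, inflation = r)
        sol <- complete_solution(sol, universe)
        q <- sample_pair_quality(sol, lab_run, n_pairs = n_pairs,
                                 level = level,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed,
                                          sprintf("sweep_%g_%g_%g", k, L, r)))
        rows[[length(rows) + 1L]] <- data.frame(
          min_contacts = k, min_contig_len = L, inflation = r,
          n_clusters = sol$n_clusters, TP = q$TP, FP = q$FP, FN = q$FN,
          TN = q$TN, TPR = q$TPR, FPR = q$FPR, PPV = q$PPV, NPV = q$NPV)
      }
    }
  }
  do.call(rbind, rows)
}
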