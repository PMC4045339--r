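#' Describe a synthetic microbial community
#'
#' A community specification lists the cells (with relative abundances and
#' species labels) and the replicons each cell carries (chromosomes and
#' plasmids, with lengths and GC content). Two cells may be declared a
#' near-identical strain pair: their chromosomes are then derived from a
#' common ancestor sequence by planting per-base substitutions at a stated
#' divergence rate, and the planted SNP positions are returned as ground
#' truth.
#'
#' @param cells data.frame with columns `cell_id`, `species`, `abundance`.
#' @param replicons data.frame with columns `id`, `cell_id`, `length`,
#'   `gc`, `circular`, `role` (`"chromosome"` or `"plasmid"`).
#' @param strain_pair character vector of two `cell_id`s whose (single)
#'   chromosomes form a strain pair, or `NULL`.
#' @param divergence per-base substitution rate between the two strain
#'   chromosomes, in `[0, 0.2]`.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(cells, replicons, strain_pair = NULL,
                           divergence = 0) {
  stopifnot(is.data.frame(cells), is.data.frame(replicons))
  need_c <- c("cell_id", "species", "abundance")
  need_r <- c("id", "cell_id", "length", "gc", "circular", "role")
  if (!all(need_c %in% names(cells)))
    stop_param("`cells` must have columns %s", paste(need_c, collapse = ", "))
  if (!all(need_r %in% names(replicons)))
    stop_param("`replicons` must have columns %s", paste(need_r, collapse = ", "))
  if (any(replicons$length < 1000))
    stop_param("replicon lengths must be >= 1 kb")
  if (any(replicons$gc < 0 | replicons$gc > 1))
    stop_param("gc must lie in [0, 1]")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.2)
    stop_param("`divergence` must lie in [0, 0.2]")
  if (any(cells$abundance <= 0))
    stop_param("abundances must be positive")
  if (!all(replicons$cell_id %in% cells$cell_id))
    stop_param("every replicon must belong to a listed cell")
  if (!is.null(strain_pair)) {
    if (length(strain_pair) != 2L || !all(strain_pair %in% cells$cell_id))
      stop_param("`strain_pair` must name two cells in `cells`")
    for (cl in strain_pair) {
      if (sum(replicons$cell_id == cl) != 1L)
        stop_param("strain-pair cell '%s' must carry exactly one replicon", cl)
    }
    len <- replicons$length[match(strain_pair, replicons$cell_id)]
    if (len[1] != len[2])
      stop_param("strain-pair chromosomes must have equal declared length")
  }
  structure(list(cells = cells, replicons = replicons,
                 strain_pair = strain_pair, divergence = divergence),
            class = "community_spec")
}

#' Five-cell community mirroring a mixed lactic-acid / enteric roster
#'
#' The default study community: five cells covering the structural cases
#' the method must resolve — a cell with a chromosome plus two plasmids
#' (Lac), a cell with two chromosomes (Bur), a single-chromosome cell
#' (Ped), and a pair of near-identical *E. coli*-like strains (K12, BL21)
#' at 99.5% nucleotide identity. Chromosome lengths are scaled to roughly
#' a tenth of the source organisms so the full pipeline runs at desk
#' scale; plasmids keep realistic sizes (13.4 kb and 35.6 kb) and all
#' replicons keep realistic GC content.
#'
#' @param divergence strain-pair per-base substitution rate (default
#'   0.005, i.e. 99.5% identity).
#' @return A `community_spec`.
#' @export
default_community_spec <- function(divergence = 0.005) {
  cells <- data.frame(
    cell_id  = c("Lac", "Ped", "Bur", "K12cell", "BL21cell"),
    species  = c("Lac", "Ped", "Bur", "Ecoli", "Ecoli"),
    abundance = rep(0.2, 5),
    stringsAsFactors = FALSE
  )
  replicons <- data.frame(
    id       = c("Lac0", "Lac1", "Lac2", "Ped", "Bur1", "Bur2", "K12", "BL21"),
    cell_id  = c("Lac", "Lac", "Lac", "Ped", "Bur", "Bur", "K12cell", "BL21cell"),
    length   = c(229122L, 13413L, 35595L, 183239L, 291477L, 380920L,
                 460000L, 460000L),
    gc       = c(0.462, 0.386, 0.385, 0.373, 0.680, 0.672, 0.507, 0.508),
    circular = rep(TRUE, 8),
    role     = c("chromosome", "plasmid", "plasmid", "chromosome",
                 "chromosome", "chromosome", "chromosome", "chromosome"),
    stringsAsFactors = FALSE
  )
  community_spec(cells, replicons, strain_pair = c("K12cell", "BL21cell"),
                 divergence = divergence)
}

random_dna <- function(length, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic community with ground truth
#'
#' Sequences are drawn as i.i.d. bases at each replicon's target GC.
#' For a declared strain pair, a single ancestor chromosome is generated
#' and each position is independently substituted in the second strain
#' with probability `divergence`; the substituted base is drawn uniformly
#' from the three alternatives, and the planted SNP positions (0-based,
#' shared coordinates — the strains are colinear) are returned.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed; the result is deterministic given
#'   `(spec, seed)`.
#' @return A list of class `hic_community` with elements `cells`,
#'   `replicons`, `sequences` (a [Biostrings::DNAStringSet]), `snps`
#'   (data.frame of planted SNPs with 0-based `pos`), `strain_pair` and
#'   `spec`.
#' @export
generate_community <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  with_local_seed(seed, {
    reps <- spec$replicons
    seqs <- character(nrow(reps))
    names(seqs) <- reps$id
    snps <- data.frame(pos = integer(0), base_a = character(0),
                       base_b = character(0))
    strain_reps <- character(0)
    if (!is.null(spec$strain_pair)) {
      strain_reps <- reps$id[match(spec$strain_pair, reps$cell_id)]
    }
    for (i in seq_len(nrow(reps))) {
      if (reps$id[i] %in% strain_reps) next
      seqs[reps$id[i]] <- random_dna(reps$length[i], reps$gc[i])
    }
    if (length(strain_reps) == 2L) {
      len <- reps$length[match(strain_reps[1], reps$id)]
      gc <- mean(reps$gc[match(strain_reps, reps$id)])
      anc <- random_dna(len, gc)
      a <- anc
      b_chars <- strsplit(anc, "", fixed = TRUE)[[1]]
      is_snp <- which(runif(len) < spec$divergence)
      if (length(is_snp) > 0) {
        alt <- vapply(b_chars[is_snp], function(base) {
          sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        }, character(1))
        snps <- data.frame(pos = is_snp - 1L,
                           base_a = b_chars[is_snp],
                           base_b = unname(alt),
                           stringsAsFactors = FALSE)
        b_chars[is_snp] <- alt
      }
      seqs[strain_reps[1]] <- a
      seqs[strain_reps[2]] <- paste(b_chars, collapse = "")
    }
    out <- list(
      cells = spec$cells,
      replicons = spec$replicons,
      sequences = Biostrings::DNAStringSet(seqs),
      snps = snps,
      strain_pair = spec$strain_pair,
      strain_replicons = if (length(strain_reps)) strain_reps else NULL,
      spec = spec,
      seed = seed
    )
    class(out) <- "hic_community"
    out
  })
}

#' @export
print.hic_community <- function(x, ...) {
  cat(sprintf("<hic_community> %d cells, %d replicons, %.2f Mb total\n",
              nrow(x$cells), nrow(x$replicons),
              sum(x$replicons$length) / 1e6))
  if (!is.null(x$strain_pair)) {
    cat(sprintf("  strain pair: %s (%d planted SNPs)\n",
                paste(x$strain_pair, collapse = " / "), nrow(x$snps)))
  }
  invisible(x)
}

#' Write community replicon sequences to FASTA
#'
#' @param community an `hic_community`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(community, path) {
  Biostrings::writeXStringSet(community$sequences, filepath = path)
  invisible(path)
}

#' Serialize community ground truth to JSON
#'
#' Writes the cell-to-replicon map, abundances, planted SNP positions and
#' the strain pair, the sidecar against which downstream stages are
#' validated.
#'
#' @param community an `hic_community`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(community, path) {
  gt <- list(
    cells = community$cells,
    replicons = community$replicons[, c("id", "cell_id", "length",
                                        "circular", "role")],
    strain_pair = community$strain_pair,
    snp_positions = community$snps$pos
  )
  jsonlite::write_json(gt, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Lengths/circularity lookup shared by link-level operations.
replicon_info <- function(community) {
  data.frame(id = community$replicons$id,
             length = community$replicons$length,
             circular = community$replicons$circular,
             cell_id = community$replicons$cell_id,
             stringsAsFactors = FALSE)
}
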