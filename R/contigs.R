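# Contig fragmentation of community replicons, standing in for a
# metagenome assembly. Tiles are a renewal process: lengths are drawn
# i.i.d. as min_contig_len + Exp(mean - min) and laid end to end, so
# contigs partition each replicon without overlap; a final remainder
# shorter than min_contig_len is merged into the preceding contig.

tile_lengths <- function(L, mean_len, min_len) {
  if (mean_len >= L) return(L)
  if (mean_len <= min_len) {
    k <- floor(L / mean_len)
    lens <- rep(mean_len, k)
  } else {
    lens <- numeric(0)
    total <- 0
    while (total < L) {
      draw <- min_len + stats::rexp(ceiling(L / mean_len) + 8,
                                    rate = 1 / (mean_len - min_len))
      lens <- c(lens, draw)
      total <- sum(lens)
    }
    lens <- lens[cumsum(lens) < L]
  }
  lens <- round(lens)
  rem <- L - sum(lens)
  if (rem >= min_len || length(lens) == 0L) {
    lens <- c(lens, rem)
  } else {
    lens[length(lens)] <- lens[length(lens)] + rem
  }
  as.integer(lens)
}

#' Fragment community replicons into contigs with coordinate liftover
#'
#' Emulates a metagenome assembly of the community: each replicon is
#' tiled into non-overlapping contigs whose lengths follow a shifted
#' exponential law (`min_contig_len + Exp(mean - min)`), and a liftover
#' table maps any replicon coordinate to its (contig, offset). For a
#' declared strain pair the two chromosomes are colinear, and the
#' assembler's collapse of near-identical regions is emulated
#' stochastically: each tile is emitted as a single co-assembled contig
#' shared by both strains with probability `coassembly_prob`, and as two
#' strain-specific contigs otherwise. (At realistic SNP densities no
#' multi-kilobase interval is strictly identical between the strains, so
#' the collapse is modelled as a rate rather than by exact identity.)
#'
#' @param community an `hic_community`.
#' @param mean_contig_len target mean contig length (bp).
#' @param min_contig_len minimum contig length (bp);
#'   `mean_contig_len >= min_contig_len >= 1`.
#' @param coassembly_prob probability that a strain-pair tile is emitted
#'   as one shared contig (0 disables co-assembly emulation).
#' @param seed integer seed.
#' @return A list of class `contig_set`: `contigs` (data.frame with
#'   `contig_id`, `length`, `start`, `end` (0-based half-open on the
#'   source replicon), `source_replicon`, `cell_id`, `species`, `strain`,
#'   `shared`) and `liftover` (per replicon: tile starts and contig ids).
#' @export
fragment_to_contigs <- function(community, mean_contig_len,
                                min_contig_len = 1000,
                                coassembly_prob = 0.5, seed = NULL) {
  stopifnot(inherits(community, "hic_community"))
  if (min_contig_len < 1 || mean_contig_len < min_contig_len)
    stop_param("need mean_contig_len >= min_contig_len >= 1")
  check_fraction(coassembly_prob, "coassembly_prob")
  reps <- community$replicons
  cells <- community$cells
  strain_reps <- community$strain_replicons
  with_local_seed(seed, {
    rows <- list()
    lift <- list()
    add_tiles <- function(rep_id) {
      L <- reps$length[reps$id == rep_id]
      lens <- tile_lengths(L, mean_contig_len, min_contig_len)
      starts <- c(0L, cumsum(lens)[-length(lens)])
      data.frame(start = as.integer(starts),
                 end = as.integer(starts + lens),
                 length = lens, stringsAsFactors = FALSE)
    }
    species_of <- function(cell) cells$species[cells$cell_id == cell]
    plain_reps <- setdiff(reps$id, strain_reps)
    for (r in plain_reps) {
      t <- add_tiles(r)
      cell <- reps$cell_id[reps$id == r]
      ids <- sprintf("%s_c%03d", r, seq_len(nrow(t)))
      rows[[r]] <- data.frame(
        contig_id = ids, length = t$length, start = t$start, end = t$end,
        source_replicon = r, cell_id = cell, species = species_of(cell),
        strain = cell, shared = FALSE, stringsAsFactors = FALSE)
      lift[[r]] <- list(starts = t$start, ids = ids)
    }
    if (length(strain_reps) == 2L) {
      ra <- strain_reps[1]; rb <- strain_reps[2]
      cell_a <- reps$cell_id[reps$id == ra]
      cell_b <- reps$cell_id[reps$id == rb]
      sp <- species_of(cell_a)
      t <- add_tiles(ra)
      shared <- runif(nrow(t)) < coassembly_prob
      ids_a <- ids_b <- character(nrow(t))
      sub <- list()
      for (i in seq_len(nrow(t))) {
        if (shared[i]) {
          id <- sprintf("%s_sh_c%03d", sp, i)
          ids_a[i] <- ids_b[i] <- id
          sub[[length(sub) + 1L]] <- data.frame(
            contig_id = id, length = t$length[i], start = t$start[i],
            end = t$end[i], source_replicon = ra, cell_id = NA_character_,
            species = sp, strain = NA_character_, shared = TRUE,
            stringsAsFactors = FALSE)
        } else {
          ida <- sprintf("%s_c%03d", ra, i)
          idb <- sprintf("%s_c%03d", rb, i)
          ids_a[i] <- ida; ids_b[i] <- idb
          sub[[length(sub) + 1L]] <- data.frame(
            contig_id = c(ida, idb), length = t$length[i],
            start = t$start[i], end = t$end[i],
            source_replicon = c(ra, rb), cell_id = c(cell_a, cell_b),
            species = sp, strain = c(cell_a, cell_b), shared = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      rows[["strainpair"]] <- do.call(rbind, sub)
      lift[[ra]] <- list(starts = t$start, ids = ids_a)
      lift[[rb]] <- list(starts = t$start, ids = ids_b)
    }
    contigs <- do.call(rbind, rows)
    rownames(contigs) <- NULL
    structure(list(contigs = contigs, liftover = lift,
                   mean_contig_len = mean_contig_len,
                   min_contig_len = min_contig_len,
                   coassembly_prob = coassembly_prob, seed = seed),
              class = "contig_set")
  })
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs (%d shared), mean length %.0f bp\n",
              nrow(x$contigs), sum(x$contigs$shared),
              mean(x$contigs$length)))
  invisible(x)
}

#' Map replicon coordinates of a link table to contig coordinates
#'
#' Each end's `(replicon, position)` is re-expressed as
#' `(contig, offset)` using the contig set's liftover table.
#'
#' @param links a link table in replicon coordinates.
#' @param contig_set a [fragment_to_contigs()] result.
#' @return The link table with `ref_a`/`ref_b` replaced by contig ids and
#'   positions replaced by contig offsets.
#' @export
liftover_links <- function(links, contig_set) {
  stopifnot(inherits(contig_set, "contig_set"))
  lift_one <- function(refs, pos) {
    out_ref <- character(length(refs))
    out_pos <- integer(length(refs))
    for (r in unique(refs)) {
      lv <- contig_set$liftover[[r]]
      if (is.null(lv)) stop_param("unknown replicon '%s' in links", r)
      idx <- which(refs == r)
      tile <- findInterval(pos[idx], lv$starts)
      out_ref[idx] <- lv$ids[tile]
      out_pos[idx] <- pos[idx] - lv$starts[tile]
    }
    list(ref = out_ref, pos = out_pos)
  }
  a <- lift_one(links$ref_a, links$pos_a)
  b <- lift_one(links$ref_b, links$pos_b)
  links$ref_a <- a$ref; links$pos_a <- a$pos
  links$ref_b <- b$ref; links$pos_b <- b$pos
  links
}

#' Extract contig sequences from the community genomes
#'
#' Shared (co-assembled) contigs take the first strain's sequence as
#' their representative.
#'
#' @param contig_set a [fragment_to_contigs()] result.
#' @param community the `hic_community` the contigs were derived from.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
contig_sequences <- function(contig_set, community) {
  ct <- contig_set$contigs
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ct)), function(i) {
    as.character(Biostrings::subseq(
      community$sequences[[ct$source_replicon[i]]],
      start = ct$start[i] + 1L, end = ct$end[i]))
  }, character(1)))
  names(seqs) <- ct$contig_id
  seqs
}

#' Ground-truth label map for a contig set
#'
#' @param contig_set a [fragment_to_contigs()] result.
#' @return data.frame with `contig_id`, `species`, `strain` (NA for
#'   shared contigs) and `length`.
#' @export
truth_labels <- function(contig_set) {
  ct <- contig_set$contigs
  data.frame(contig_id = ct$contig_id, species = ct$species,
             strain = ct$strain, length = ct$length,
             stringsAsFactors = FALSE)
}
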