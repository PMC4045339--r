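#' In silico restriction digest
#'
#' Finds every occurrence of a restriction motif on the given strand
#' (HindIII's site AAGCTT is palindromic, so one strand suffices).
#' Overlapping occurrences are all reported; IUPAC ambiguity codes in the
#' sequence are never matched.
#'
#' @param sequence a character string or [Biostrings::DNAString].
#' @param motif recognition motif, uppercase ACGT (default HindIII,
#'   `"AAGCTT"`).
#' @param id optional replicon id recorded in the result.
#' @return A list of class `restriction_map` with `positions` (0-based,
#'   strictly increasing site start coordinates), `motif`, `length` and
#'   `replicon_id`.
#' @export
digest <- function(sequence, motif = "AAGCTT", id = NA_character_) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L ||
      grepl("[^ACGT]", motif)) {
    stop_param("`motif` must be a non-empty uppercase ACGT string")
  }
  subject <- if (is(sequence, "XString")) sequence else {
    Biostrings::DNAString(as.character(sequence))
  }
  m <- Biostrings::matchPattern(motif, subject, fixed = TRUE)
  structure(list(replicon_id = id, motif = motif,
                 positions = Biostrings::start(m) - 1L,
                 length = length(subject)),
            class = "restriction_map")
}

#' Digest every replicon of a community
#'
#' @param community an `hic_community`.
#' @param motif restriction motif (default HindIII).
#' @return Named list of `restriction_map`s, one per replicon.
#' @export
digest_community <- function(community, motif = "AAGCTT") {
  maps <- lapply(names(community$sequences), function(id) {
    digest(community$sequences[[id]], motif, id = id)
  })
  names(maps) <- names(community$sequences)
  maps
}

#' Expected spacing between restriction sites
#'
#' For a motif of length m over uniform random sequence, sites occur on
#' average every 4^m bp; a 6-cutter such as HindIII cuts on average every
#' 4,096 bp.
#'
#' @param motif_length motif length in bp (>= 1).
#' @return Expected inter-site spacing in bp.
#' @export
expected_cut_spacing <- function(motif_length) {
  if (!is.numeric(motif_length) || any(motif_length < 1))
    stop_param("`motif_length` must be >= 1")
  4^motif_length
}

#' Fraction of a genome lying in long inter-site gaps
#'
#' Monte-Carlo estimate of the genome fraction located in inter-site gaps
#' longer than `threshold` when restriction sites are treated as points
#' placed uniformly at random. Each replicate places
#' `floor(genome_length / mean_spacing)` sites, measures gaps between
#' consecutive site starts (plus the two terminal segments on a linear
#' layout, or the single wrap-around gap on a circular one), sums the
#' gaps exceeding the threshold and divides by the genome length. In the
#' Poisson-process limit the estimate converges to
#' `exp(-x/mu) * (1 + x/mu)` with `x = threshold`, `mu = mean_spacing`;
#' for a 4 Mbp genome cut on average every 4,096 bp, more than 25% of the
#' genome is expected to sit in gaps over 10 kb.
#'
#' @param genome_length genome size in bp.
#' @param mean_spacing mean inter-site spacing in bp (4^m for an m-cutter).
#' @param threshold gap-length threshold in bp (> 0).
#' @param reps number of Monte-Carlo replicates (>= 1).
#' @param circular treat the genome as circular (closes the wrap gap).
#' @param seed integer seed.
#' @return List with `estimate`, `se` (standard error over replicates),
#'   `reps`, and `closed_form` (the Poisson-process limit).
#' @export
intersite_gap_fraction <- function(genome_length, mean_spacing, threshold,
                                   reps = 200, circular = FALSE,
                                   seed = NULL) {
  if (threshold <= 0) stop_param("`threshold` must be > 0")
  if (mean_spacing <= 0) stop_param("`mean_spacing` must be > 0")
  if (reps < 1) stop_param("`reps` must be >= 1")
  closed <- exp(-threshold / mean_spacing) * (1 + threshold / mean_spacing)
  if (threshold >= genome_length) {
    warning("threshold >= genome_length; returning 0")
    return(list(estimate = 0, se = 0, reps = reps, closed_form = closed))
  }
  n_sites <- max(1L, floor(genome_length / mean_spacing))
  with_local_seed(seed, {
    fracs <- vapply(seq_len(reps), function(r) {
      pos <- sort(runif(n_sites, 0, genome_length))
      gaps <- if (circular) {
        c(diff(pos), genome_length - pos[n_sites] + pos[1])
      } else {
        c(pos[1], diff(pos), genome_length - pos[n_sites])
      }
      sum(gaps[gaps > threshold]) / genome_length
    }, numeric(1))
    list(estimate = mean(fracs),
         se = stats::sd(fracs) / sqrt(reps),
         reps = reps,
         closed_form = closed)
  })
}
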