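link_columns <- c("read_id", "ref_a", "pos_a", "mapq_a", "full_a",
                  "ref_b", "pos_b", "mapq_b", "full_b")

check_links <- function(links) {
  if (!is.data.frame(links) || !all(link_columns %in% names(links)))
    stop_param("a link table needs columns: %s",
               paste(link_columns, collapse = ", "))
  invisible(links)
}

#' Read a link table
#'
#' Reads paired-alignment data into one record per read pair. Two input
#' formats are supported: the package's plain TSV link format (header
#' `read_id ref_a pos_a mapq_a full_a ref_b pos_b mapq_b full_b`,
#' 0-based leftmost coordinates) and SAM/BAM paired alignments (requires
#' the Rsamtools package). For alignments, mates are matched by read
#' name among primary records; pairs with an unmapped end and orphan
#' mates are skipped with a reported count, and an end is flagged
#' "full" when its CIGAR is a single full-length match (e.g. `160M` for
#' a 160 bp read).
#'
#' @param path input path; format inferred from the extension
#'   (`.tsv`/`.txt`, `.sam`, `.bam`) unless given.
#' @param format `"auto"`, `"tsv"`, `"sam"` or `"bam"`.
#' @return A link table (data.frame).
#' @export
read_links <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") {
    links <- utils::read.delim(path, stringsAsFactors = FALSE)
    check_links(links)
    links$full_a <- as.logical(links$full_a)
    links$full_b <- as.logical(links$full_b)
    return(links)
  }
  read_links_alignment(path, format)
}

read_links_alignment <- function(path, format) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package", call. = FALSE)
  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar", "flag", "qwidth"),
    flag = flags)
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  full <- grepl("^[0-9]+M$", rec$cigar) &
    (as.integer(sub("M$", "", ifelse(grepl("^[0-9]+M$", rec$cigar),
                                     rec$cigar, "0M"))) == rec$qwidth)
  df <- data.frame(qname = rec$qname, ref = as.character(rec$rname),
                   pos = rec$pos - 1L, mapq = rec$mapq, full = full,
                   first = bitwAnd(rec$flag, 64L) > 0L,
                   stringsAsFactors = FALSE)
  a <- df[df$first, , drop = FALSE]
  b <- df[!df$first, , drop = FALSE]
  m <- match(a$qname, b$qname)
  ok <- !is.na(m)
  n_orphan <- sum(!ok) + sum(!(b$qname %in% a$qname))
  if (n_orphan > 0)
    message(sprintf("read_links: skipped %d orphan/unpaired records",
                    n_orphan))
  a <- a[ok, , drop = FALSE]
  b <- b[m[ok], , drop = FALSE]
  data.frame(read_id = a$qname, ref_a = a$ref, pos_a = a$pos,
             mapq_a = a$mapq, full_a = a$full,
             ref_b = b$ref, pos_b = b$pos, mapq_b = b$mapq,
             full_b = b$full, stringsAsFactors = FALSE)
}

#' Write a link table as TSV
#'
#' @param links a link table.
#' @param path output path.
#' @param truth keep simulator truth columns (`cell_a`, `cell_b`, ...)?
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path, truth = FALSE) {
  check_links(links)
  cols <- if (truth) names(links) else link_columns
  utils::write.table(links[, intersect(cols, names(links))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Distance between two coordinates on a replicon
#'
#' On a circular replicon the minimum path length over both arc
#' directions, `min(|a - b|, length - |a - b|)`; on a linear one,
#' `|a - b|`. Vectorized.
#'
#' @param pos_a,pos_b 0-based coordinates.
#' @param replicon_length replicon length in bp.
#' @param circular logical.
#' @return Integer distances in bp.
#' @export
circular_distance <- function(pos_a, pos_b, replicon_length,
                              circular = TRUE) {
  if (any(pos_a < 0 | pos_a >= replicon_length |
          pos_b < 0 | pos_b >= replicon_length, na.rm = TRUE))
    stop_param("positions must lie in [0, replicon_length)")
  d <- abs(pos_a - pos_b)
  ifelse(rep_len(circular, length(d)), pmin(d, replicon_length - d), d)
}

#' Alignment-quality and insert filter parameters
#'
#' @param mapq_min minimum mapping quality required of both ends
#'   (0-254).
#' @param require_full require both ends to align end-to-end (single
#'   full-length CIGAR match).
#' @param insert_min minimum insert size (bp) for intra-replicon pairs;
#'   pairs joining two replicons are never insert-filtered.
#' @param fragment_threshold fragment/Hi-C boundary in bp (see
#'   [classify_pairs()]).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(mapq_min = 0, require_full = FALSE,
                          insert_min = 0, fragment_threshold = 1000) {
  if (mapq_min < 0 || mapq_min > 254) stop_param("mapq_min must be 0-254")
  if (insert_min < 0) stop_param("insert_min must be >= 0")
  structure(list(mapq_min = as.integer(mapq_min),
                 require_full = isTRUE(require_full),
                 insert_min = as.integer(insert_min),
                 fragment_threshold = as.integer(fragment_threshold)),
            class = "filter_params")
}

ref_lookup <- function(ref_info) {
  if (inherits(ref_info, "hic_community")) ref_info <- replicon_info(ref_info)
  if (inherits(ref_info, "contig_set")) {
    ref_info <- data.frame(id = ref_info$contigs$contig_id,
                           length = ref_info$contigs$length,
                           circular = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(ref_info),
            all(c("id", "length") %in% names(ref_info)))
  if (is.null(ref_info$circular)) ref_info$circular <- TRUE
  ref_info[!duplicated(ref_info$id), , drop = FALSE]
}

pair_distance <- function(links, ref_info) {
  refs <- ref_lookup(ref_info)
  intra <- links$ref_a == links$ref_b
  d <- rep(NA_integer_, nrow(links))
  if (any(intra)) {
    m <- match(links$ref_a[intra], refs$id)
    if (anyNA(m)) stop_param("link references unknown replicon '%s'",
                             links$ref_a[intra][which(is.na(m))[1]])
    d[intra] <- circular_distance(links$pos_a[intra], links$pos_b[intra],
                                  refs$length[m], refs$circular[m])
  }
  d
}

#' Filter a link table on mapping quality, alignment completeness and
#' insert size
#'
#' Retains pairs with both mapping qualities at or above `mapq_min`,
#' both ends fully aligned when `require_full`, and — for pairs whose
#' two ends lie on the same replicon — an insert (minimum-path distance
#' between leftmost coordinates) of at least `insert_min`. Pairs joining
#' two different replicons are never insert-filtered. The filter is
#' idempotent and monotone: stricter parameters retain a subset.
#'
#' @param links a link table.
#' @param params a [filter_params()].
#' @param ref_info replicon/contig lengths: a data.frame with `id`,
#'   `length` (and optional `circular`), an `hic_community` or a
#'   `contig_set`. Only needed when `insert_min > 0`.
#' @param verbose report the retained fraction.
#' @return The surviving subset of `links`.
#' @export
filter_links <- function(links, params = filter_params(), ref_info = NULL,
                         verbose = FALSE) {
  check_links(links)
  keep <- links$mapq_a >= params$mapq_min & links$mapq_b >= params$mapq_min
  if (params$require_full) keep <- keep & links$full_a & links$full_b
  if (params$insert_min > 0) {
    if (is.null(ref_info))
      stop_param("`ref_info` is required when insert_min > 0")
    d <- pair_distance(links, ref_info)
    keep <- keep & (is.na(d) | d >= params$insert_min)
  }
  if (verbose)
    message(sprintf("filter_links: retained %d/%d pairs (%.2f%%)",
                    sum(keep), length(keep), 100 * mean(keep)))
  links[keep, , drop = FALSE]
}

#' Classify read pairs as fragment, Hi-C or inter-replicon
#'
#' Pairs with both ends on one replicon and separated by less than
#' `fragment_threshold` (default 1,000 bp) are uninformative local
#' fragments; intra-replicon pairs at or beyond the threshold are Hi-C
#' (informative long-range) pairs; pairs joining two replicons are
#' `inter`. The boundary value itself is assigned to `hic`.
#'
#' @param links a link table.
#' @param ref_info see [filter_links()].
#' @param fragment_threshold boundary in bp.
#' @return Factor with levels `fragment`, `hic`, `inter`, one per row.
#' @export
classify_pairs <- function(links, ref_info, fragment_threshold = 1000) {
  check_links(links)
  d <- pair_distance(links, ref_info)
  cls <- ifelse(is.na(d), "inter",
                ifelse(d < fragment_threshold, "fragment", "hic"))
  factor(cls, levels = c("fragment", "hic", "inter"))
}
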