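#' Hi-C simulation parameters
#'
#' Defaults encode the statistical structure a metagenomic Hi-C library
#' is assumed to have: read pairs overwhelmingly join loci of the same
#' cell; most pairs are uninformative local fragments (insert below
#' 1,000 bp, 97% of pairs); the informative remainder has a long-tailed
#' insert distribution over the circular chromosome; and pair ends are
#' preferentially anchored near restriction sites.
#'
#' @param n_pairs number of read pairs to emit.
#' @param frac_fragment fraction of within-replicon pairs drawn from the
#'   short-insert (fragment) component.
#' @param noise_rate probability that a pair joins loci of two different
#'   cells.
#' @param insert_short_mean,insert_short_sd Normal parameters (bp) of the
#'   fragment component.
#' @param insert_long_min lower bound (bp) of the long-range component;
#'   long-range inserts are drawn log-uniformly on
#'   `[insert_long_min, floor(L/2)]`, a heavy-tailed law whose density
#'   decays like 1/d.
#' @param p_cross_replicon probability that a within-cell pair joins two
#'   different replicons of that cell (applies only to multi-replicon
#'   cells).
#' @param site_anchoring probability that a pair's anchor end is placed
#'   within `site_jitter` bp downstream of a restriction site.
#' @param site_jitter maximum distance (bp) from the anchoring site.
#' @param read_length read length in bp.
#' @param seed integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 100000, frac_fragment = 0.97,
                       noise_rate = 0, insert_short_mean = 300,
                       insert_short_sd = 100, insert_long_min = 1000,
                       p_cross_replicon = 0.2, site_anchoring = 0.9,
                       site_jitter = 500, read_length = 160, seed = NULL) {
  if (n_pairs < 0) stop_param("`n_pairs` must be >= 0")
  check_fraction(frac_fragment, "frac_fragment")
  check_fraction(noise_rate, "noise_rate")
  check_fraction(p_cross_replicon, "p_cross_replicon")
  check_fraction(site_anchoring, "site_anchoring")
  structure(list(n_pairs = as.integer(n_pairs),
                 frac_fragment = frac_fragment, noise_rate = noise_rate,
                 insert_short_mean = insert_short_mean,
                 insert_short_sd = insert_short_sd,
                 insert_long_min = insert_long_min,
                 p_cross_replicon = p_cross_replicon,
                 site_anchoring = site_anchoring,
                 site_jitter = site_jitter,
                 read_length = as.integer(read_length), seed = seed),
            class = "sim_params")
}

empty_links <- function() {
  data.frame(read_id = character(0), ref_a = character(0),
             pos_a = integer(0), mapq_a = integer(0), full_a = logical(0),
             ref_b = character(0), pos_b = integer(0), mapq_b = integer(0),
             full_b = logical(0), stringsAsFactors = FALSE)
}

# Draw `n` positions on replicon `rep_id`: anchored near a restriction
# site with probability `p_anchor` (when a map with sites is available),
# uniform otherwise.
draw_positions <- function(n, rep_len, sites, p_anchor, jitter) {
  pos <- floor(runif(n, 0, rep_len))
  if (length(sites) > 0 && p_anchor > 0) {
    anch <- runif(n) < p_anchor
    k <- sum(anch)
    if (k > 0) {
      s <- sites[sample.int(length(sites), k, replace = TRUE)]
      pos[anch] <- (s + floor(runif(k, 0, jitter))) %% rep_len
    }
  }
  as.integer(pos)
}

draw_insert <- function(n, rep_len, params) {
  frag <- runif(n) < params$frac_fragment
  d <- integer(n)
  nf <- sum(frag)
  if (nf > 0) {
    d[frag] <- pmax(1L, as.integer(round(abs(
      rnorm(nf, params$insert_short_mean, params$insert_short_sd)))))
  }
  nl <- n - nf
  if (nl > 0) {
    hi <- floor(rep_len / 2)
    lo <- params$insert_long_min
    if (hi <= lo) {
      d[!frag] <- pmax(1L, as.integer(floor(runif(nl, 1, hi + 1))))
    } else {
      d[!frag] <- as.integer(round(exp(runif(nl, log(lo), log(hi)))))
    }
  }
  d
}

#' Simulate a metagenomic Hi-C read-pair library
#'
#' Each pair is assigned to a single cell (chosen proportionally to
#' abundance times total replicon length) with probability
#' `1 - noise_rate`, or to two different cells with probability
#' `noise_rate` (spurious inter-cell ligation). Within a cell, pairs
#' join two different replicons with probability `p_cross_replicon`
#' (replicons chosen proportionally to length); otherwise both ends fall
#' on one replicon separated by an insert drawn from the
#' fragment/long-range mixture law. Anchor ends are placed near
#' restriction sites with probability `site_anchoring`. Every record
#' carries its true source cells for downstream validation.
#'
#' @param community an `hic_community`.
#' @param params a [sim_params()].
#' @param rmaps optional named list of `restriction_map`s (from
#'   [digest_community()]); omit to disable site anchoring.
#' @param seed integer seed, overriding `params$seed`.
#' @return A link table: one row per read pair with columns `read_id`,
#'   `ref_a`, `pos_a`, `mapq_a`, `full_a`, `ref_b`, `pos_b`, `mapq_b`,
#'   `full_b`, plus truth columns `cell_a`, `cell_b`, `is_noise`, `kind`.
#' @export
simulate_hic_pairs <- function(community, params = sim_params(),
                               rmaps = NULL, seed = NULL) {
  stopifnot(inherits(community, "hic_community"),
            inherits(params, "sim_params"))
  seed <- seed %||% params$seed
  reps <- community$replicons
  cells <- community$cells
  cell_len <- tapply(reps$length, reps$cell_id, sum)[cells$cell_id]
  if (any(cell_len <= 0) || any(is.na(cell_len)))
    stop("cell with zero total replicon length", call. = FALSE)
  n <- params$n_pairs
  if (n == 0L) return(empty_links())
  w_cell <- cells$abundance * as.numeric(cell_len)
  site_list <- lapply(reps$id, function(id) {
    if (is.null(rmaps) || is.null(rmaps[[id]])) integer(0)
    else rmaps[[id]]$positions
  })
  names(site_list) <- reps$id

  with_local_seed(seed, {
    is_noise <- runif(n) < params$noise_rate
    ref_a <- ref_b <- cell_a <- cell_b <- character(n)
    pos_a <- pos_b <- integer(n)
    kind <- character(n)

    ## -- within-cell pairs ------------------------------------------------
    w_idx <- which(!is_noise)
    if (length(w_idx) > 0) {
      cw <- sample(cells$cell_id, length(w_idx), replace = TRUE,
                   prob = w_cell)
      cell_a[w_idx] <- cell_b[w_idx] <- cw
      for (cl in unique(cw)) {
        idx <- w_idx[cw == cl]
        crep <- reps[reps$cell_id == cl, , drop = FALSE]
        multi <- nrow(crep) > 1L
        cross <- multi & (runif(length(idx)) < params$p_cross_replicon)
        ## intra-replicon pairs
        ii <- idx[!cross]
        if (length(ii) > 0) {
          ra <- crep$id[sample.int(nrow(crep), length(ii), replace = TRUE,
                                   prob = crep$length)]
          for (r in unique(ra)) {
            jj <- ii[ra == r]
            L <- crep$length[crep$id == r]
            circ <- crep$circular[crep$id == r]
            pa <- draw_positions(length(jj), L, site_list[[r]],
                                 params$site_anchoring, params$site_jitter)
            d <- draw_insert(length(jj), L, params)
            sgn <- ifelse(runif(length(jj)) < 0.5, 1L, -1L)
            pb <- pa + sgn * d
            if (circ) {
              pb <- ((pb %% L) + L) %% L
            } else {
              out <- pb < 0 | pb >= L
              pb[out] <- pa[out] - sgn[out] * d[out]
              pb <- pmin(pmax(pb, 0L), L - 1L)
            }
            ref_a[jj] <- r; ref_b[jj] <- r
            pos_a[jj] <- pa; pos_b[jj] <- as.integer(pb)
            kind[jj] <- "intra"
          }
        }
        ## cross-replicon pairs within the cell
        ci <- idx[cross]
        if (length(ci) > 0) {
          ra <- crep$id[sample.int(nrow(crep), length(ci), replace = TRUE,
                                   prob = crep$length)]
          rb <- vapply(ra, function(r) {
            oth <- crep[crep$id != r, , drop = FALSE]
            oth$id[sample.int(nrow(oth), 1L, prob = oth$length)]
          }, character(1))
          for (side in 1:2) {
            rr <- if (side == 1) ra else rb
            for (r in unique(rr)) {
              jj <- ci[rr == r]
              L <- crep$length[crep$id == r]
              p <- draw_positions(length(jj), L, site_list[[r]],
                                  params$site_anchoring, params$site_jitter)
              if (side == 1) { ref_a[jj] <- r; pos_a[jj] <- p }
              else { ref_b[jj] <- r; pos_b[jj] <- p }
            }
          }
          kind[ci] <- "cross"
        }
      }
    }

    ## -- inter-cell (noise) pairs ----------------------------------------
    n_idx <- which(is_noise)
    if (length(n_idx) > 0) {
      if (nrow(cells) < 2L)
        stop_param("noise_rate > 0 requires at least two cells")
      ca <- sample(cells$cell_id, length(n_idx), replace = TRUE,
                   prob = w_cell)
      cb <- vapply(ca, function(cl) {
        oth <- cells$cell_id != cl
        sample(cells$cell_id[oth], 1L, prob = w_cell[oth])
      }, character(1))
      cell_a[n_idx] <- ca; cell_b[n_idx] <- cb
      for (side in 1:2) {
        cc <- if (side == 1) ca else cb
        for (cl in unique(cc)) {
          jj <- n_idx[cc == cl]
          crep <- reps[reps$cell_id == cl, , drop = FALSE]
          rr <- crep$id[sample.int(nrow(crep), length(jj), replace = TRUE,
                                   prob = crep$length)]
          for (r in unique(rr)) {
            kk <- jj[rr == r]
            L <- crep$length[crep$id == r]
            p <- draw_positions(length(kk), L, site_list[[r]],
                                params$site_anchoring, params$site_jitter)
            if (side == 1) { ref_a[kk] <- r; pos_a[kk] <- p }
            else { ref_b[kk] <- r; pos_b[kk] <- p }
          }
        }
      }
      kind[n_idx] <- "noise"
    }

    data.frame(read_id = sprintf("P%07d", seq_len(n)),
               ref_a = ref_a, pos_a = pos_a,
               mapq_a = 60L, full_a = TRUE,
               ref_b = ref_b, pos_b = pos_b,
               mapq_b = 60L, full_b = TRUE,
               cell_a = cell_a, cell_b = cell_b,
               is_noise = is_noise, kind = kind,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a mate-pair (jumping) library on a single replicon
#'
#' Ends are separated by `Normal(insert_mean, insert_sd)` truncated to
#' `[read_length, replicon_length - 1]` and placed uniformly along the
#' replicon.
#'
#' @param replicon_length replicon length in bp.
#' @param n number of pairs.
#' @param insert_mean,insert_sd insert size law (bp); `insert_mean` must
#'   be smaller than the replicon length.
#' @param replicon_id reference name recorded in the link table.
#' @param circular wrap inserts around the origin.
#' @param read_length read length in bp (truncation floor).
#' @param seed integer seed.
#' @return A link table (see [simulate_hic_pairs()]) with truth columns
#'   `cell_a = cell_b = NA`.
#' @export
simulate_mate_pairs <- function(replicon_length, n, insert_mean,
                                insert_sd = 0, replicon_id = "chr",
                                circular = TRUE, read_length = 160,
                                seed = NULL) {
  if (insert_mean <= 0) stop_param("`insert_mean` must be > 0")
  if (insert_sd < 0) stop_param("`insert_sd` must be >= 0")
  if (insert_mean >= replicon_length)
    stop("`insert_mean` must be smaller than the replicon length",
         call. = FALSE)
  if (n == 0) return(empty_links())
  with_local_seed(seed, {
    d <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
    d <- pmin(pmax(d, as.integer(read_length)),
              as.integer(replicon_length - 1))
    pa <- as.integer(floor(runif(n, 0, replicon_length)))
    pb <- pa + d
    if (circular) {
      pb <- pb %% as.integer(replicon_length)
    } else {
      out <- pb >= replicon_length
      pb[out] <- pa[out] - d[out]
      pb <- pmin(pmax(pb, 0L), as.integer(replicon_length - 1))
    }
    data.frame(read_id = sprintf("M%07d", seq_len(n)),
               ref_a = replicon_id, pos_a = pa, mapq_a = 60L, full_a = TRUE,
               ref_b = replicon_id, pos_b = as.integer(pb), mapq_b = 60L,
               full_b = TRUE, cell_a = NA_character_, cell_b = NA_character_,
               is_noise = FALSE, kind = "matepair",
               stringsAsFactors = FALSE)
  })
}
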