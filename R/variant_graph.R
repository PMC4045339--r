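#' Build a SNP variant graph from read-pair links
#'
#' Nodes are SNP sites on a reference scaffold; an edge joins two sites
#' observed together in a read pair. A read end covers a site when the
#' site position lies in `[pos, pos + read_length)`; when an end covers
#' several sites, every cross combination between the first end's sites
#' and the second end's sites becomes an edge (sites covered by the
#' same single end are not self-paired across, and self-edges are
#' dropped). Edge multiplicities accumulate over read pairs.
#'
#' @param links a link table whose positions are scaffold coordinates
#'   (all ends on one reference).
#' @param sites sorted vector of 0-based SNP positions (unique).
#' @param read_length read length in bp.
#' @return A list of class `variant_graph`: `sites`, `n_nodes`, `edges`
#'   (data.frame `a`, `b`, `weight` with `a < b`, node indices into
#'   `sites`).
#' @export
build_variant_graph <- function(links, sites, read_length = 160) {
  if (read_length <= 0) stop_param("`read_length` must be > 0")
  sites <- sort(unique(as.integer(sites)))
  n <- length(sites)
  cover <- function(pos) {
    # per end: indices of sites in [pos, pos + read_length)
    lo <- findInterval(pos - 0.5, sites) + 1L   # first site >= pos
    hi <- findInterval(pos + read_length - 0.5, sites)  # last site < pos+rl
    list(lo = lo, cnt = pmax(0L, hi - lo + 1L))
  }
  ca <- cover(links$pos_a)
  cb <- cover(links$pos_b)
  keep <- ca$cnt > 0 & cb$cnt > 0
  if (!any(keep)) {
    return(structure(list(sites = sites, n_nodes = n,
                          edges = data.frame(a = integer(0), b = integer(0),
                                             weight = numeric(0))),
                     class = "variant_graph"))
  }
  la <- ca$lo[keep]; na <- ca$cnt[keep]
  lb <- cb$lo[keep]; nb <- cb$cnt[keep]
  # expand the cross product of covered-site runs per pair
  reps <- na * nb
  pair_id <- rep.int(seq_along(reps), reps)
  within <- sequence(reps) - 1L
  ai <- la[pair_id] + within %/% nb[pair_id]
  bi <- lb[pair_id] + within %% nb[pair_id]
  lo <- pmin(ai, bi); hi <- pmax(ai, bi)
  ok <- lo != hi
  lo <- lo[ok]; hi <- hi[ok]
  if (length(lo) == 0) {
    edges <- data.frame(a = integer(0), b = integer(0), weight = numeric(0))
  } else {
    key <- paste(lo, hi)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    edges <- data.frame(a = as.integer(parts[, 1]),
                        b = as.integer(parts[, 2]),
                        weight = as.numeric(tab))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(sites = sites, n_nodes = n, edges = edges),
            class = "variant_graph")
}

#' @export
print.variant_graph <- function(x, ...) {
  cat(sprintf("<variant_graph> %d SNP nodes, %d distinct edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

vg_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("a", "b")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n_nodes)))
}

#' Connected components of a variant graph
#'
#' @param graph a `variant_graph`.
#' @return Integer component id per node; components are labeled
#'   deterministically in order of their smallest member index.
#' @export
vg_components <- function(graph) {
  stopifnot(inherits(graph, "variant_graph"))
  if (graph$n_nodes == 0) return(integer(0))
  memb <- igraph::components(vg_igraph(graph))$membership
  first <- tapply(seq_len(graph$n_nodes), memb, min)
  unname(match(memb, as.integer(names(sort(first)))))
}

# Adjacency list of a variant graph (list of integer neighbor vectors).
vg_adjacency <- function(graph) {
  adj <- vector("list", graph$n_nodes)
  e <- graph$edges
  if (nrow(e) > 0) {
    from <- c(e$a, e$b)
    to <- c(e$b, e$a)
    o <- order(from)
    adj_split <- split(to[o], from[o])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  adj
}

# Breadth-first search distances (in edges) from `source` to all nodes;
# unreachable nodes get NA.
bfs_distances <- function(adj, source) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  queue <- integer(n)
  queue[1L] <- source
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    nb <- adj[[v]]
    if (length(nb) > 0) {
      new <- nb[is.na(dist[nb])]
      if (length(new) > 0) {
        dist[new] <- dist[v] + 1L
        queue[(tail + 1L):(tail + length(new))] <- new
        tail <- tail + length(new)
      }
    }
  }
  dist
}

#' Sample shortest path lengths between random SNP pairs
#'
#' Node pairs are drawn uniformly at random (self-pairs redrawn, with
#' replacement across pairs) and the shortest path length in edges is
#' computed by breadth-first search. Unreachable pairs are recorded; the
#' mean and maximum path length are computed over reachable pairs only,
#' and the fraction of pairs whose two nodes share a connected component
#' is reported separately.
#'
#' @param graph a `variant_graph` with at least 2 nodes.
#' @param n_pairs number of sampled pairs (default 10,000).
#' @param seed integer seed.
#' @return A list of class `path_sample`: `pairs` (data.frame `node_a`,
#'   `node_b`, `path_length` with `NA` when unreachable), `n_sampled`,
#'   `frac_same_component`, `max_path`, `mean_path`, `seed`.
#' @export
sample_shortest_paths <- function(graph, n_pairs = 10000, seed = NULL) {
  stopifnot(inherits(graph, "variant_graph"))
  n <- graph$n_nodes
  if (n < 2) stop_param("graph must have at least 2 nodes")
  with_local_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    while (any(i == j)) {
      eq <- which(i == j)
      j[eq] <- sample.int(n, length(eq), replace = TRUE)
    }
    adj <- vg_adjacency(graph)
    len <- rep(NA_integer_, n_pairs)
    for (s in unique(i)) {
      idx <- which(i == s)
      d <- bfs_distances(adj, s)
      len[idx] <- d[j[idx]]
    }
    reach <- !is.na(len)
    structure(list(pairs = data.frame(node_a = i, node_b = j,
                                      path_length = len),
                   n_sampled = n_pairs,
                   frac_same_component = mean(reach),
                   max_path = if (any(reach)) max(len[reach]) else NA_integer_,
                   mean_path = if (any(reach)) mean(len[reach]) else NA_real_,
                   seed = seed),
              class = "path_sample")
  })
}

#' @export
print.path_sample <- function(x, ...) {
  cat(sprintf(
    "<path_sample> %d pairs: %.2f%% same component, mean %.2f, max %s\n",
    x$n_sampled, 100 * x$frac_same_component, x$mean_path,
    format(x$max_path)))
  invisible(x)
}

#' Bin sampled path lengths by genomic separation
#'
#' Reachable sampled pairs are binned by the distance between their SNP
#' sites on the reference, the mean path length is computed per
#' `bin_width` segment (default 20 kb), and the binned means are
#' smoothed with LOWESS for display. Empty bins are skipped.
#'
#' @param sample a `path_sample`.
#' @param sites the site positions of the graph the sample was drawn
#'   from.
#' @param bin_width bin width in bp (default 20,000).
#' @param lowess_span LOWESS smoother span (default 0.3).
#' @param circular_length replicon length for minimum-path (circular)
#'   separation; `NULL` uses the linear coordinate difference.
#' @return A list: `bins` (data.frame `bin_mid`, `mean_path`, `n`) and
#'   `smooth` (data.frame `x`, `y`), plus `slope`, the least-squares
#'   slope of mean path length against distance (edges per bp).
#' @export
bin_paths_by_distance <- function(sample, sites, bin_width = 20000,
                                  lowess_span = 0.3,
                                  circular_length = NULL) {
  stopifnot(inherits(sample, "path_sample"))
  if (bin_width <= 0) stop_param("`bin_width` must be > 0")
  p <- sample$pairs
  reach <- !is.na(p$path_length)
  d <- abs(sites[p$node_a[reach]] - sites[p$node_b[reach]])
  if (!is.null(circular_length)) d <- pmin(d, circular_length - d)
  len <- p$path_length[reach]
  bin <- floor(d / bin_width)
  agg <- tapply(len, bin, mean)
  cnt <- tapply(len, bin, length)
  bins <- data.frame(bin_mid = (as.numeric(names(agg)) + 0.5) * bin_width,
                     mean_path = as.numeric(agg),
                     n = as.integer(cnt))
  sm <- if (nrow(bins) >= 3) {
    s <- stats::lowess(bins$bin_mid, bins$mean_path, f = lowess_span)
    data.frame(x = s$x, y = s$y)
  } else {
    data.frame(x = bins$bin_mid, y = bins$mean_path)
  }
  slope <- if (nrow(bins) >= 2) {
    unname(stats::coef(stats::lm(mean_path ~ bin_mid, data = bins))[2])
  } else NA_real_
  list(bins = bins, smooth = sm, slope = slope)
}

#' Compare variant-graph connectivity across library designs
#'
#' Simulates a read library per design on the community's strain-pair
#' scaffold, builds the variant graph over the planted SNP sites,
#' samples shortest paths, and reports the connectivity statistics that
#' distinguish library designs: mate-pair libraries only join sites
#' within their insert span (path length grows with genomic distance),
#' whereas Hi-C inserts span the chromosome (path length stays flat and
#' distant sites stay in one component).
#'
#' Designs are lists with `type = "matepair"` (fields `insert_mean`,
#' `insert_sd`) or `type = "hic"` (fields of [sim_params()] such as
#' `frac_fragment`; `insert_min` applies the post-hoc insert filter that
#' removes short non-ligation products).
#'
#' @param community an `hic_community` with a strain pair (planted SNP
#'   ground truth).
#' @param designs named list of design descriptions; defaults to
#'   mate-pair libraries of 5/10/20/40 kb plus an all-insert and a
#'   `> 1 kb` Hi-C design.
#' @param n_reads read pairs simulated per design.
#' @param n_sample_pairs SNP pairs sampled per graph.
#' @param read_length read length in bp.
#' @param bin_width distance-bin width for the path-vs-distance curves.
#' @param seed integer seed.
#' @return A list of class `design_comparison`: `table` (data.frame with
#'   `design`, `n_reads`, `n_edges`, `max_path`, `mean_path`,
#'   `pct_same_cc`, `distance_slope`) and `curves` (per-design binned
#'   path-vs-distance data).
#' @export
compare_library_designs <- function(community, designs = NULL,
                                    n_reads = 30000,
                                    n_sample_pairs = 10000,
                                    read_length = 160, bin_width = 20000,
                                    seed = NULL) {
  stopifnot(inherits(community, "hic_community"))
  if (is.null(community$strain_replicons) || nrow(community$snps) == 0)
    stop_param("community must carry a strain pair with planted SNPs")
  if (is.null(designs)) {
    designs <- list(
      mp5  = list(type = "matepair", insert_mean = 5000,  insert_sd = 500),
      mp10 = list(type = "matepair", insert_mean = 10000, insert_sd = 1000),
      mp20 = list(type = "matepair", insert_mean = 20000, insert_sd = 2000),
      mp40 = list(type = "matepair", insert_mean = 40000, insert_sd = 5000),
      hic_all = list(type = "hic", frac_fragment = 0.97, insert_min = 0),
      hic_gt1kb = list(type = "hic", frac_fragment = 0.97,
                       insert_min = 1000)
    )
  }
  scaffold <- community$strain_replicons[1]
  L <- community$replicons$length[community$replicons$id == scaffold]
  circ <- community$replicons$circular[community$replicons$id == scaffold]
  sites <- sort(community$snps$pos)
  rows <- list()
  curves <- list()
  for (nm in names(designs)) {
    de <- designs[[nm]]
    dseed <- if (is.null(seed)) NULL else derive_seed(seed, nm)
    links <- if (identical(de$type, "matepair")) {
      simulate_mate_pairs(L, n_reads, de$insert_mean, de$insert_sd,
                          replicon_id = scaffold, circular = circ,
                          read_length = read_length, seed = dseed)
    } else {
      sub <- subset_community(community, scaffold)
      p <- sim_params(n_pairs = n_reads,
                      frac_fragment = de$frac_fragment %||% 0.97,
                      noise_rate = 0, read_length = read_length)
      lk <- simulate_hic_pairs(sub, p, seed = dseed)
      im <- de$insert_min %||% 0
      if (im > 0) {
        lk <- filter_links(lk, filter_params(insert_min = im),
                           ref_info = sub)
      }
      lk
    }
    g <- build_variant_graph(links, sites, read_length = read_length)
    ps <- sample_shortest_paths(g, n_pairs = n_sample_pairs,
                                seed = if (is.null(dseed)) NULL
                                       else dseed + 1L)
    bp <- bin_paths_by_distance(ps, g$sites, bin_width = bin_width,
                                circular_length = if (circ) L else NULL)
    rows[[nm]] <- data.frame(design = nm, n_reads = nrow(links),
                             n_edges = nrow(g$edges),
                             max_path = ps$max_path,
                             mean_path = ps$mean_path,
                             pct_same_cc = 100 * ps$frac_same_component,
                             distance_slope = bp$slope,
                             stringsAsFactors = FALSE)
    curves[[nm]] <- bp
  }
  structure(list(table = do.call(rbind, rows), curves = curves),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# One-cell view of a community restricted to a single replicon, so the
# Hi-C simulator can generate an intra-replicon library on a scaffold.
subset_community <- function(community, replicon_id) {
  reps <- community$replicons[community$replicons$id == replicon_id, ,
                              drop = FALSE]
  cells <- community$cells[community$cells$cell_id == reps$cell_id, ,
                           drop = FALSE]
  out <- list(cells = cells, replicons = reps,
              sequences = community$sequences[replicon_id],
              snps = community$snps, strain_pair = NULL,
              strain_replicons = NULL, spec = NULL, seed = NULL)
  class(out) <- "hic_community"
  out
}
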