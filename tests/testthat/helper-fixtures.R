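# Shared fixtures, built in code at test time.

# A small three-cell community (one multi-replicon cell, one plasmid
# cell, no strain pair) that keeps simulation-heavy tests fast.
tiny_community_spec <- function() {
  cells <- data.frame(
    cell_id = c("A", "B", "C"),
    species = c("A", "B", "C"),
    abundance = c(0.4, 0.3, 0.3),
    stringsAsFactors = FALSE)
  replicons <- data.frame(
    id = c("A1", "A2", "B1", "C1"),
    cell_id = c("A", "A", "B", "C"),
    length = c(60000L, 8000L, 50000L, 40000L),
    gc = c(0.5, 0.45, 0.4, 0.6),
    circular = TRUE,
    role = c("chromosome", "plasmid", "chromosome", "chromosome"),
    stringsAsFactors = FALSE)
  community_spec(cells, replicons)
}

tiny_community <- function(seed = 1) {
  generate_community(tiny_community_spec(), seed = seed)
}

# Construct a link table by hand.
make_links <- function(ref_a, pos_a, ref_b, pos_b, mapq_a = 60L,
                       mapq_b = 60L, full_a = TRUE, full_b = TRUE) {
  n <- length(ref_a)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             ref_a = ref_a, pos_a = as.integer(pos_a),
             mapq_a = rep_len(as.integer(mapq_a), n),
             full_a = rep_len(full_a, n),
             ref_b = ref_b, pos_b = as.integer(pos_b),
             mapq_b = rep_len(as.integer(mapq_b), n),
             full_b = rep_len(full_b, n),
             stringsAsFactors = FALSE)
}

# Random undirected graph as a variant_graph over n synthetic "sites".
random_variant_graph <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_edge
    edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                        weight = rep(1, sum(keep)))
    structure(list(sites = seq(0, by = 1000, length.out = n_nodes),
                   n_nodes = n_nodes,
                   edges = edges[order(edges$a, edges$b), , drop = FALSE]),
              class = "variant_graph")
  })
}
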