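test_that("variant graph edges follow the site-coverage rule", {
  sites <- c(100L, 5000L, 5100L, 9000L)
  # one pair covering {100} and {9000}
  g1 <- build_variant_graph(make_links("chr", 50, "chr", 8950), sites,
                            read_length = 160)
  expect_equal(g1$edges, data.frame(a = 1L, b = 4L, weight = 1),
               ignore_attr = TRUE)
  # an end covering two sites pairs each with the mate's site
  g2 <- build_variant_graph(make_links("chr", 4990, "chr", 8950), sites,
                            read_length = 160)
  expect_equal(g2$edges[, c("a", "b")],
               data.frame(a = c(2L, 3L), b = c(4L, 4L)),
               ignore_attr = TRUE)
  # multiplicities accumulate; self-edges are dropped
  g3 <- build_variant_graph(
    make_links(rep("chr", 3), c(50, 50, 60), rep("chr", 3),
               c(8950, 8950, 100)), sites, read_length = 160)
  expect_equal(g3$edges$weight[g3$edges$a == 1 & g3$edges$b == 4], 2)
  expect_false(any(g3$edges$a == g3$edges$b))
})

test_that("variant graph matches a brute-force interval-overlap scan", {
  com <- tiny_community(seed = 1)
  withr::with_seed(81, {
    sites <- sort(sample(0:59999, 300))
  })
  links <- simulate_hic_pairs(
    com, sim_params(n_pairs = 3000, frac_fragment = 0.5,
                    p_cross_replicon = 0), seed = 82)
  links <- links[links$ref_a == "A1" & links$ref_b == "A1", ]
  g <- build_variant_graph(links, sites, read_length = 160)
  # brute force
  acc <- new.env()
  for (i in seq_len(nrow(links))) {
    sa <- which(sites >= links$pos_a[i] & sites < links$pos_a[i] + 160)
    sb <- which(sites >= links$pos_b[i] & sites < links$pos_b[i] + 160)
    for (x in sa) for (y in sb) {
      if (x == y) next
      key <- paste(min(x, y), max(x, y))
      acc[[key]] <- (acc[[key]] %||% 0) + 1
    }
  }
  brute <- ls(acc)
  got <- paste(g$edges$a, g$edges$b)
  expect_setequal(got, brute)
  for (k in brute) {
    expect_equal(g$edges$weight[got == k], acc[[k]], info = k)
  }
})

test_that("connected components agree with a union-find oracle", {
  g0 <- random_variant_graph(20, 0, seed = 83)
  expect_equal(vg_components(g0), 1:20)
  chain <- structure(list(sites = c(0, 1000, 2000), n_nodes = 3L,
                          edges = data.frame(a = c(1L, 2L), b = c(2L, 3L),
                                             weight = 1)),
                     class = "variant_graph")
  expect_equal(vg_components(chain), c(1L, 1L, 1L))
  union_find <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$a[i]); rb <- find(edges$b[i])
      # union by value keeps every root at its component's minimum index
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
  }
  for (s in 84:86) {
    g <- random_variant_graph(25, 0.06, seed = s)
    uf <- union_find(g$n_nodes, g$edges)
    got <- vg_components(g)
    # same partition and the same smallest-member labeling order
    expect_equal(got, uf, info = s)
  }
})

test_that("BFS path lengths match the all-pairs igraph oracle", {
  chain <- structure(list(sites = seq(0, 10000, by = 1000),
                          n_nodes = 11L,
                          edges = data.frame(a = 1:10, b = 2:11,
                                             weight = 1)),
                     class = "variant_graph")
  ps <- sample_shortest_paths(chain, n_pairs = 200, seed = 87)
  ends <- ps$pairs$path_length[
    (ps$pairs$node_a == 1 & ps$pairs$node_b == 11) |
      (ps$pairs$node_a == 11 & ps$pairs$node_b == 1)]
  expect_true(all(ends == 10))
  for (s in 88:90) {
    g <- random_variant_graph(30, 0.08, seed = s)
    ps <- sample_shortest_paths(g, n_pairs = 400, seed = s + 100)
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("a", "b")], directed = FALSE,
      vertices = data.frame(name = 1:30))
    dm <- igraph::distances(ig)
    oracle <- dm[cbind(ps$pairs$node_a, ps$pairs$node_b)]
    oracle[is.infinite(oracle)] <- NA
    expect_equal(ps$pairs$path_length, as.integer(oracle), info = s)
    comp <- igraph::components(ig)$membership
    expect_equal(ps$frac_same_component,
                 mean(comp[ps$pairs$node_a] == comp[ps$pairs$node_b]))
  }
})

test_that("two components yield unreachable cross pairs", {
  g <- structure(list(sites = c(0, 1000, 2000, 3000), n_nodes = 4L,
                      edges = data.frame(a = c(1L, 3L), b = c(2L, 4L),
                                         weight = 1)),
                 class = "variant_graph")
  ps <- sample_shortest_paths(g, n_pairs = 500, seed = 91)
  cross <- (ps$pairs$node_a <= 2) != (ps$pairs$node_b <= 2)
  expect_true(all(is.na(ps$pairs$path_length[cross])))
  expect_true(all(!is.na(ps$pairs$path_length[!cross])))
  expect_equal(ps$frac_same_component, mean(!cross))
  expect_gte(ps$mean_path, 1)
})

test_that("densifying a graph never lengthens shortest paths", {
  g1 <- random_variant_graph(25, 0.06, seed = 92)
  extra <- random_variant_graph(25, 0.06, seed = 93)$edges
  both <- unique(rbind(g1$edges[, c("a", "b")], extra[, c("a", "b")]))
  g2 <- structure(list(sites = g1$sites, n_nodes = 25L,
                       edges = data.frame(both, weight = 1)),
                  class = "variant_graph")
  p1 <- sample_shortest_paths(g1, n_pairs = 300, seed = 94)
  p2 <- sample_shortest_paths(g2, n_pairs = 300, seed = 94)
  len1 <- p1$pairs$path_length
  len2 <- p2$pairs$path_length
  expect_true(all(is.na(len1) | len2 <= len1, na.rm = TRUE))
  expect_false(any(is.na(len2) & !is.na(len1)))
})

test_that("path binning matches a hand-binned oracle", {
  g <- structure(list(sites = c(0, 5000, 30000, 55000), n_nodes = 4L,
                      edges = data.frame(a = c(1L, 2L, 3L),
                                         b = c(2L, 3L, 4L), weight = 1)),
                 class = "variant_graph")
  ps <- sample_shortest_paths(g, n_pairs = 2000, seed = 95)
  bp <- bin_paths_by_distance(ps, g$sites, bin_width = 20000)
  d <- abs(g$sites[ps$pairs$node_a] - g$sites[ps$pairs$node_b])
  for (k in seq_len(nrow(bp$bins))) {
    lo <- bp$bins$bin_mid[k] - 10000
    sel <- d >= lo & d < lo + 20000
    expect_equal(bp$bins$mean_path[k],
                 mean(ps$pairs$path_length[sel]))
    expect_equal(bp$bins$n[k], sum(sel))
  }
  # all pairs in one bin: the bin mean is the overall mean
  bp1 <- bin_paths_by_distance(ps, g$sites, bin_width = 1e6)
  expect_equal(bp1$bins$mean_path, ps$mean_path)
})

test_that("an empty library leaves all SNP nodes isolated", {
  com <- generate_community(default_community_spec(), seed = 96)
  g <- build_variant_graph(empty_links <- make_links(character(0),
                                                     integer(0),
                                                     character(0),
                                                     integer(0)),
                           com$snps$pos)
  expect_equal(nrow(g$edges), 0)
  ps <- sample_shortest_paths(g, n_pairs = 100, seed = 97)
  expect_equal(ps$frac_same_component, 0)
  expect_true(is.na(ps$mean_path))
})
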