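test_that("noise-free Hi-C pairs always join loci of one cell", {
  com <- tiny_community(seed = 1)
  links <- simulate_hic_pairs(com, sim_params(n_pairs = 5000,
                                              noise_rate = 0),
                              seed = 2)
  expect_equal(nrow(links), 5000)
  expect_true(all(links$cell_a == links$cell_b))
  refs <- replicon_info(com)
  cell_of <- refs$cell_id[match(links$ref_a, refs$id)]
  expect_true(all(cell_of == links$cell_a))
  expect_true(all(links$pos_a >= 0 &
                    links$pos_a < refs$length[match(links$ref_a, refs$id)]))
})

test_that("cross-cell fraction follows the binomial noise rate", {
  com <- tiny_community(seed = 1)
  n <- 50000; p <- 0.012
  links <- simulate_hic_pairs(com, sim_params(n_pairs = n, noise_rate = p),
                              seed = 3)
  obs <- mean(links$cell_a != links$cell_b)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(links$is_noise == (links$cell_a != links$cell_b)))
})

test_that("fragment fraction matches the mixture weight", {
  com <- tiny_community(seed = 1)
  links <- simulate_hic_pairs(com, sim_params(n_pairs = 20000,
                                              frac_fragment = 0.97,
                                              noise_rate = 0,
                                              p_cross_replicon = 0),
                              seed = 4)
  cls <- classify_pairs(links, com, fragment_threshold = 1000)
  obs <- mean(cls == "fragment")
  # fragment inserts are |N(300,100)| so essentially all fall under 1 kb
  expect_lt(abs(obs - 0.97), 3 * sqrt(0.97 * 0.03 / 20000) + 0.002)
})

test_that("Hi-C simulation is reproducible and site-anchored", {
  com <- tiny_community(seed = 1)
  rmaps <- digest_community(com)
  p <- sim_params(n_pairs = 2000, site_anchoring = 1, site_jitter = 400)
  l1 <- simulate_hic_pairs(com, p, rmaps = rmaps, seed = 5)
  l2 <- simulate_hic_pairs(com, p, rmaps = rmaps, seed = 5)
  expect_identical(l1, l2)
  # with anchoring probability 1 every intra-pair anchor end sits within
  # the jitter window downstream of a restriction site
  intra <- l1[l1$kind == "intra", ]
  near_site <- vapply(seq_len(nrow(intra)), function(i) {
    sites <- rmaps[[intra$ref_a[i]]]$positions
    L <- com$replicons$length[com$replicons$id == intra$ref_a[i]]
    any(((intra$pos_a[i] - sites) %% L) < 400)
  }, logical(1))
  expect_true(all(near_site))
  expect_error(simulate_hic_pairs(com, sim_params(noise_rate = 2)),
               "noise_rate")
})

test_that("mate pairs honor the insert law", {
  # sd 0: every pair separated by exactly the mean (circular distance)
  mp <- simulate_mate_pairs(50000, 500, insert_mean = 5000, insert_sd = 0,
                            replicon_id = "B1", seed = 6)
  d <- circular_distance(mp$pos_a, mp$pos_b, 50000, circular = TRUE)
  expect_true(all(d == 5000))
  # sample mean within 3 sigma for a 40 kb +/- 5 kb library
  mp40 <- simulate_mate_pairs(500000, 4000, insert_mean = 40000,
                              insert_sd = 5000, seed = 7)
  raw <- (mp40$pos_b - mp40$pos_a) %% 500000
  expect_lt(abs(mean(raw) - 40000), 3 * 5000 / sqrt(4000))
  expect_equal(nrow(simulate_mate_pairs(50000, 0, 5000)), 0)
  expect_error(simulate_mate_pairs(10000, 10, insert_mean = 20000),
               "replicon length")
})

test_that("contig fragmentation partitions every replicon", {
  com <- tiny_community(seed = 1)
  cs <- fragment_to_contigs(com, mean_contig_len = 5000,
                            min_contig_len = 1000, seed = 8)
  for (r in com$replicons$id) {
    ct <- cs$contigs[cs$contigs$source_replicon == r, ]
    ct <- ct[order(ct$start), ]
    L <- com$replicons$length[com$replicons$id == r]
    expect_equal(ct$start[1], 0)
    expect_equal(ct$end[nrow(ct)], L)
    expect_true(all(ct$start[-1] == ct$end[-nrow(ct)]))
    expect_true(all(ct$length >= 1000))
    # concatenating the contig sequences in interval order reconstructs
    # the replicon
    seqs <- contig_sequences(cs, com)
    expect_identical(paste(as.character(seqs[ct$contig_id]),
                           collapse = ""),
                     as.character(com$sequences[[r]]))
  }
  # mean = replicon length: a single contig, identity liftover
  one <- fragment_to_contigs(com, mean_contig_len = 60000,
                             min_contig_len = 1000, seed = 9)
  expect_equal(sum(one$contigs$source_replicon == "A1"), 1)
})

test_that("contig count follows the documented renewal law", {
  com <- generate_community(default_community_spec(), seed = 10)
  L <- 460000; mean_len <- 8000; min_len <- 1000
  cs <- fragment_to_contigs(com, mean_len, min_len,
                            coassembly_prob = 0, seed = 11)
  n_k12 <- sum(cs$contigs$source_replicon == "K12")
  # renewal count: E[N] = L/mu, Var[N] = L * sigma^2 / mu^3 with
  # mu = mean_len and sigma = mean_len - min_len (shifted exponential)
  mu <- mean_len; sig <- mean_len - min_len
  expect_lt(abs(n_k12 - L / mu), 3 * sqrt(L * sig^2 / mu^3) + 1)
})

test_that("strain-pair co-assembly emits shared contigs at the set rate", {
  com <- generate_community(default_community_spec(), seed = 12)
  cs <- fragment_to_contigs(com, 8000, 1000, coassembly_prob = 0.5,
                            seed = 13)
  ec <- cs$contigs[cs$contigs$species == "Ecoli", ]
  n_tiles <- length(cs$liftover[["K12"]]$ids)
  n_shared <- sum(ec$shared)
  expect_lt(abs(n_shared - 0.5 * n_tiles),
            3 * sqrt(n_tiles * 0.25) + 1)
  # shared contigs are reachable from both strain replicons
  expect_true(any(grepl("sh", cs$liftover[["K12"]]$ids)))
  expect_true(any(cs$liftover[["K12"]]$ids %in% cs$liftover[["BL21"]]$ids))
  # with probability 0 the strains never share contigs
  cs0 <- fragment_to_contigs(com, 8000, 1000, coassembly_prob = 0,
                             seed = 13)
  expect_equal(sum(cs0$contigs$shared), 0)
})

test_that("link liftover matches a brute-force interval search", {
  com <- tiny_community(seed = 1)
  cs <- fragment_to_contigs(com, 5000, 1000, seed = 14)
  links <- simulate_hic_pairs(com, sim_params(n_pairs = 500,
                                              noise_rate = 0.1),
                              seed = 15)
  lifted <- liftover_links(links, cs)
  for (i in sample.int(nrow(links), 50)) {
    ct <- cs$contigs[cs$contigs$source_replicon == links$ref_a[i] &
                       cs$contigs$start <= links$pos_a[i] &
                       cs$contigs$end > links$pos_a[i], ]
    expect_equal(lifted$ref_a[i], ct$contig_id[1])
    expect_equal(lifted$pos_a[i], links$pos_a[i] - ct$start[1])
  }
  expect_error(liftover_links(make_links("nope", 1, "A1", 2), cs),
               "unknown replicon")
})
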