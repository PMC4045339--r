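test_that("substring voting labels contigs by plurality", {
  withr::with_seed(61, {
    refA <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
    refB <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  })
  refs <- Biostrings::DNAStringSet(c(spA = refA, spB = refB))
  species <- c(spA = "A", spB = "B")
  # a verbatim slice of reference A; a chimera 70% A / 30% B
  slice <- substr(refA, 501, 2500)
  chimera <- paste0(substr(refA, 1001, 2400), substr(refB, 1001, 1600))
  contigs <- Biostrings::DNAStringSet(c(ctg1 = slice, ctg2 = chimera))
  labs <- assign_labels_by_substring_vote(contigs, refs, species,
                                          k = 70, step = 10)
  expect_equal(labs$species, c("A", "A"))
  expect_equal(labs$strain, c("spA", "spA"))
  expect_error(assign_labels_by_substring_vote(contigs, refs, species,
                                               k = 10), "k")
})

test_that("substring voting recovers truth on simulated contigs", {
  com <- tiny_community(seed = 1)
  cs <- fragment_to_contigs(com, 6000, 2000, seed = 62)
  seqs <- contig_sequences(cs, com)
  species <- setNames(
    com$cells$species[match(com$replicons$cell_id, com$cells$cell_id)],
    com$replicons$id)
  # a subset keeps the oracle cheap; exact matching suffices at 0 error
  pick <- seq(1, length(seqs), by = 4)
  labs <- assign_labels_by_substring_vote(seqs[pick], com$sequences,
                                          species, k = 70, step = 50)
  truth <- truth_labels(cs)
  expect_equal(labs$species,
               truth$species[match(labs$contig_id, truth$contig_id)])
})

test_that("pair-sampling quality matches exhaustive enumeration", {
  # 10 contigs, two equal-size species, one giant cluster
  labels <- data.frame(
    contig_id = sprintf("c%02d", 1:10),
    species = rep(c("A", "B"), each = 5),
    strain = rep(c("A", "B"), each = 5),
    length = c(4000, 3000, 1000, 1000, 1000, 2000, 2000, 2000, 2000,
               2000),
    stringsAsFactors = FALSE)
  giant <- data.frame(contig_id = labels$contig_id, cluster = 1L)
  q <- sample_pair_quality(giant, labels, n_pairs = 40000, seed = 63)
  expect_equal(q$TP + q$FP + q$FN + q$TN, 40000)
  expect_equal(q$TPR, 1)  # nothing is ever split
  expect_equal(q$FN + q$TN, 0)
  # exhaustive oracle: P(same species | distinct ordered pair)
  p <- labels$length / sum(labels$length)
  same <- outer(labels$species, labels$species, "==")
  num <- sum(outer(p, p) * same) - sum(p^2)
  den <- 1 - sum(p^2)
  exp_ppv <- num / den
  expect_lt(abs(q$PPV - exp_ppv),
            3 * sqrt(exp_ppv * (1 - exp_ppv) / 40000))

  # perfect clustering: clusters = label classes
  perfect <- data.frame(contig_id = labels$contig_id,
                        cluster = as.integer(factor(labels$species)))
  qp <- sample_pair_quality(perfect, labels, n_pairs = 20000, seed = 64)
  expect_equal(qp$PPV, 1)
  expect_equal(qp$TPR, 1)
  expect_equal(qp$FPR, 0)
})

test_that("size weighting follows contig length", {
  # exhaustive oracle on a 4-contig instance with unequal sizes: check
  # sampled TP rate against the exact size-weighted pair probability
  labels <- data.frame(contig_id = c("a", "b", "c", "d"),
                       species = c("X", "X", "Y", "Y"),
                       strain = c("X", "X", "Y", "Y"),
                       length = c(8000, 1000, 500, 500),
                       stringsAsFactors = FALSE)
  sol <- data.frame(contig_id = labels$contig_id,
                    cluster = c(1L, 1L, 2L, 2L))
  q <- sample_pair_quality(sol, labels, n_pairs = 50000, seed = 65)
  p <- labels$length / sum(labels$length)
  same <- outer(labels$species, labels$species, "==")
  tp_exact <- (sum(outer(p, p) * same) - sum(p^2)) / (1 - sum(p^2))
  expect_lt(abs(q$TP / q$n_pairs - tp_exact),
            3 * sqrt(tp_exact * (1 - tp_exact) / 50000))
})

test_that("species-level scoring merges the strain pair", {
  labels <- data.frame(
    contig_id = sprintf("c%02d", 1:8),
    species = rep("Ecoli", 8),
    strain = c(rep("K12", 3), rep("BL21", 3), NA, NA),
    length = rep(1000, 8),
    stringsAsFactors = FALSE)
  # solution clusters strains separately
  split_sol <- data.frame(contig_id = labels$contig_id,
                          cluster = c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 2L))
  qs <- sample_pair_quality(split_sol, labels, n_pairs = 5000,
                            level = "species", seed = 66)
  qt <- sample_pair_quality(split_sol, labels, n_pairs = 5000,
                            level = "strain", seed = 66)
  # species level sees strain splits as FN, so TPR < 1
  expect_lt(qs$TPR, 1)
  # strain level treats them as distinct classes (shared contigs form
  # their own class), so the same solution scores a higher TPR
  expect_gte(qt$TPR, qs$TPR)
  # merged solution is perfect at species level
  merged <- data.frame(contig_id = labels$contig_id, cluster = 1L)
  qm <- sample_pair_quality(merged, labels, n_pairs = 5000,
                            level = "species", seed = 67)
  expect_equal(qm$TPR, 1)
  expect_equal(qm$PPV, 1)
})

test_that("contigs missing from the solution score as singletons", {
  labels <- data.frame(contig_id = c("a", "b", "c"),
                       species = c("X", "X", "X"),
                       strain = c("X", "X", "X"),
                       length = c(1000, 1000, 1000),
                       stringsAsFactors = FALSE)
  sol <- data.frame(contig_id = c("a", "b"), cluster = c(1L, 1L))
  q <- sample_pair_quality(sol, labels, n_pairs = 3000, seed = 68)
  # pairs touching c are FN (same species, different cluster)
  expect_gt(q$FN, 0)
  expect_equal(q$FP, 0)
  expect_error(sample_pair_quality(sol, labels[0, ], n_pairs = 10),
               "labeled contigs")
})

test_that("the parameter sweep reproduces a manual run and is
           deterministic", {
  com <- tiny_community(seed = 1)
  cs <- fragment_to_contigs(com, 6000, 1000, seed = 69)
  links <- liftover_links(
    simulate_hic_pairs(com, sim_params(n_pairs = 20000, frac_fragment = 0,
                                       noise_rate = 0.01), seed = 70), cs)
  mat <- build_association_matrix(links, cs)
  labels <- truth_labels(cs)
  sw <- sweep_parameters(mat, labels, contact_grid = 5, size_grid = 3000,
                         inflation_grid = 1.1, n_pairs = 5000, seed = 71)
  expect_equal(nrow(sw), 1)
  # manual pipeline with the same seed policy
  f <- normalize_assoc(filter_assoc(mat, 5, 3000))
  sol <- complete_solution(mcl_cluster(f, inflation = 1.1),
                           mat$ids[mat$lengths >= 3000])
  universe <- labels[labels$contig_id %in%
                       mat$ids[mat$lengths >= 3000], ]
  q <- sample_pair_quality(sol, universe, n_pairs = 5000,
                           seed = hicdecon:::derive_seed(
                             71, sprintf("sweep_%g_%g_%g", 5, 3000, 1.1)))
  expect_equal(sw$TPR, q$TPR)
  expect_equal(sw$PPV, q$PPV)
  expect_equal(sw$n_clusters, sol$n_clusters)
  # determinism
  sw2 <- sweep_parameters(mat, labels, contact_grid = 5,
                          size_grid = 3000, inflation_grid = 1.1,
                          n_pairs = 5000, seed = 71)
  expect_identical(sw, sw2)
  # with sufficient contact filtering, precision stays ~1 and the false
  # positive rate ~0 across inflation values; the fixture's link density
  # is high, so the contact minimum scales up accordingly
  sw3 <- sweep_parameters(mat, labels, contact_grid = c(5, 12),
                          size_grid = 3000,
                          inflation_grid = c(1.1, 1.5), n_pairs = 5000,
                          seed = 72)
  strict <- sw3[sw3$min_contacts == 12, ]
  expect_true(all(strict$PPV > 0.95))
  expect_true(all(strict$FPR < 0.05))
  # insufficient filtering lets site-anchored noise links survive and
  # degrades precision at low inflation
  expect_true(min(sw3$PPV) < min(strict$PPV) + 1e-9)
})
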