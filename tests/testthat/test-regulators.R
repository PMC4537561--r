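block_es <- function(noise = 0, seed = 31) {
  set.seed(seed)
  n <- 12
  f1 <- c(rep(2, 6), rep(-2, 6))
  f2 <- c(rep(-1, 3), rep(1, 6), rep(-1, 3))
  m <- rbind(t(sapply(1:8, function(i) 5 + i / 4 + f1 + rnorm(n, 0, noise))),
             t(sapply(1:8, function(i) 7 + i / 4 + f2 + rnorm(n, 0, noise))))
  rownames(m) <- sprintf("g%03d", 1:16)
  es_from_matrix(exp(m / 3), 6, 6)
}

test_that("Gibbs clustering is deterministic and separates clean blocks", {
  es <- block_es(noise = 0)
  p1 <- gibbs_cluster_genes(es, n_clusters = 6, seed = 7)
  p2 <- gibbs_cluster_genes(es, n_clusters = 6, seed = 7)
  expect_identical(p1, p2)
  expect_length(unique(p1[1:8]), 1)
  expect_length(unique(p1[9:16]), 1)
  expect_false(p1[1] == p1[9])
  p3 <- gibbs_cluster_genes(es, n_clusters = 6, seed = 8)
  expect_length(unique(p3[1:8]), 1)   # separation independent of seed
})

test_that("a single Gibbs run recovers planted modules well", {
  sim <- simulate_dataset(tiny_sim_config(seed = 3))
  es <- sqrt_transform(sim$expr)
  part <- gibbs_cluster_genes(es, n_clusters = 15, seed = 3)
  truth <- sim$truth$modules
  planted <- truth$gene_id[truth$module > 0]
  ari <- adjusted_rand_index(truth$module[match(planted, truth$gene_id)],
                             part[planted])
  expect_gte(ari, 0.8)
})

test_that("consensus of identical partitions returns the qualifying blocks
           and of random partitions returns nothing", {
  genes <- sprintf("g%03d", 1:30)
  p <- setNames(rep(1:2, each = 15), genes)
  cfg <- regulator_config(min_cluster_size = 10)
  tc <- consensus_tight_clusters(list(p, p, p), cfg)
  expect_equal(sort(unique(tc$cluster_id)), c(0L, 1L))
  expect_equal(nrow(tc), 30)
  # single run reproduces its own qualifying blocks
  tc1 <- consensus_tight_clusters(list(p), cfg)
  expect_equal(dplyr::count(tc1, cluster_id)$n, c(15, 15))
  # independent random partitions: no stable pair
  set.seed(5)
  rand <- lapply(1:6, function(i) setNames(sample(1:10, 30, TRUE), genes))
  expect_warning(tc2 <- consensus_tight_clusters(rand, cfg), "No consensus")
  expect_equal(nrow(tc2), 0)
  expect_equal(formals(regulator_config)$min_cluster_size, 10)
  expect_equal(formals(regulator_config)$n_clusters_select, 50)
})

test_that("tight clusters are disjoint gene sets", {
  sim <- simulate_dataset(tiny_sim_config(seed = 4))
  es <- sqrt_transform(sim$expr)
  parts <- lapply(1:3, function(i)
    gibbs_cluster_genes(es, n_clusters = 15, seed = i))
  tc <- consensus_tight_clusters(parts, regulator_config())
  expect_equal(anyDuplicated(tc$gene_id), 0)
})

test_that("sample trees split bimodal profiles at the gap and leave
           constants alone", {
  prof <- setNames(c(rep(5, 7), rep(1, 5)), sprintf("s%02d", 1:12))
  tree <- build_sample_tree(prof)
  expect_false(tree$leaf)
  expect_setequal(tree$right$samples, sprintf("s%02d", 1:7))
  flat <- build_sample_tree(setNames(rep(2, 10), sprintf("s%02d", 1:10)))
  expect_true(flat$leaf)
  expect_equal(score_regulator(prof, flat), 0)
})

test_that("regulator scores are affine-invariant and maximal for the
           profile itself", {
  set.seed(41)
  prof <- setNames(c(rnorm(7, 3), rnorm(5, -3)), sprintf("s%02d", 1:12))
  tree <- build_sample_tree(prof)
  s0 <- score_regulator(prof, tree)
  expect_gt(s0, 0)
  expect_equal(score_regulator(2.5 * prof + 7, tree), s0, tolerance = 1e-9)
  # the profile outranks random genes on its own tree
  others <- sapply(1:50, function(i)
    score_regulator(setNames(rnorm(12), names(prof)), tree))
  expect_gt(s0, max(others))
})

test_that("permuted candidates score like random controls", {
  set.seed(55)
  prof <- setNames(c(rnorm(8, 2), rnorm(8, -2)), sprintf("s%02d", 1:16))
  tree <- build_sample_tree(prof)
  x <- prof + rnorm(16, 0, 0.5)
  perm_scores <- sapply(1:200, function(i)
    score_regulator(setNames(sample(as.numeric(x)), names(x)), tree))
  null_scores <- sapply(1:200, function(i)
    score_regulator(setNames(rnorm(16, 0, sd(x)), names(x)), tree))
  expect_gt(suppressWarnings(ks.test(perm_scores, null_scores))$p.value,
            0.01)
})

test_that("top-percent assignment flags ties conservatively", {
  es <- block_es(noise = 0.2)
  clusters <- tibble::tibble(cluster_id = rep(c(0L, 1L), each = 8),
                             gene_id = rownames(es$values))
  out <- assign_regulators(es, rownames(es$values)[1:4], clusters)
  expect_equal(nrow(out), 8)
  cutoff <- attr(out, "cutoff")
  expect_true(all(out$p_score[out$is_regulator] >= cutoff))
  # degenerate all-equal scores: nothing flagged
  flat_es <- es_from_matrix(matrix(5, 6, 8,
                                   dimnames = list(sprintf("g%03d", 1:6),
                                                   NULL)), 4, 4)
  flat_cl <- tibble::tibble(cluster_id = 0L,
                            gene_id = rownames(flat_es$values))
  expect_warning(out2 <- assign_regulators(flat_es,
                                           rownames(flat_es$values)[1:3],
                                           flat_cl),
                 "equal")
  expect_false(any(out2$is_regulator))
  expect_error(assign_regulators(es, character(0), clusters), "Empty")
})

test_that("control calibration handles degenerate scores and short
           universes", {
  es <- block_es(noise = 0.2)
  clusters <- tibble::tibble(cluster_id = rep(c(0L, 1L), each = 8),
                             gene_id = rownames(es$values))
  cfg <- regulator_config(n_controls = 5, seed = 2)
  cal <- calibrate_with_controls(es, rownames(es$values)[1:4], clusters,
                                 cfg = cfg)
  expect_true(cal$computable)
  expect_true(is.finite(cal$z))
  cfg_big <- regulator_config(n_controls = 50)
  expect_error(
    calibrate_with_controls(es, rownames(es$values)[1:4], clusters,
                            cfg = cfg_big),
    "Not enough")
  flat_es <- es_from_matrix(matrix(5, 10, 8,
                                   dimnames = list(sprintf("g%03d", 1:10),
                                                   NULL)), 4, 4)
  flat_cl <- tibble::tibble(cluster_id = 0L,
                            gene_id = rownames(flat_es$values))
  cal2 <- calibrate_with_controls(flat_es, rownames(flat_es$values)[1:3],
                                  flat_cl,
                                  cfg = regulator_config(n_controls = 5))
  expect_false(cal2$computable)
  expect_true(is.na(cal2$z))
})

test_that("sample trees serialize to text and newick", {
  prof <- setNames(c(rep(4, 5), rep(1, 5)), sprintf("s%02d", 1:10))
  tree <- build_sample_tree(prof)
  txt <- format_sample_tree(tree)
  expect_match(txt, "node \\(n=10")
  nwk <- format_sample_tree(tree, "newick")
  expect_match(nwk, ";$")
  expect_match(nwk, "s01")
})
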