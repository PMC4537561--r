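test_that("correlation matrix matches the pairwise formula and drops
           constant genes", {
  es <- toy_expr_set(20, 5, 5, seed = 2)
  cc <- correlation_matrix(es)
  set.seed(33)
  for (k in 1:15) {
    i <- sample(20, 1); j <- sample(20, 1)
    x <- es$values[i, ]; y <- es$values[j, ]
    expect_equal(cc[i, j],
                 sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
                 tolerance = 1e-12)
  }
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
             d = c(2, 2, 2, 2))
  es2 <- es_from_matrix(m, 2, 2)
  expect_warning(cc2 <- correlation_matrix(es2), "zero-variance.*d")
  expect_equal(nrow(cc2), 3)
  expect_equal(cc2["a", "b"], 1)
  expect_equal(cc2["a", "c"], -1)
})

test_that("soft adjacency is the beta power of absolute correlation", {
  cc <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3, 3)
  a <- soft_adjacency(cc, 6)
  expect_equal(a[1, 2], 0.5^6)
  expect_equal(a[1, 3], 1)
  expect_true(all(diag(a) == 1))
  expect_equal(formals(soft_adjacency)$beta, 6)
})

test_that("topological overlap matches the triple-loop oracle", {
  a0 <- diag(4)                        # no off-diagonal adjacency
  expect_equal(topological_overlap(a0), diag(4))
  a1 <- matrix(1, 3, 3)                # fully connected
  expect_true(all(topological_overlap(a1) == 1))
  a <- random_adjacency(15, seed = 4)
  expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-10)
})

test_that("TOM of a block-diagonal adjacency stays block-diagonal in [0,1]", {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 0.8; a[6:10, 6:10] <- 0.6
  diag(a) <- 1
  tom <- topological_overlap(a)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_true(all(tom[1:5, 6:10] == 0))
})

test_that("module detection separates planted blocks and greys small sets", {
  set.seed(6)
  f1 <- rnorm(12); f2 <- rnorm(12)
  m <- rbind(t(sapply(1:40, function(i) 2 + f1)),
             t(sapply(1:40, function(i) 5 + f2)))
  m <- m + matrix(rnorm(960, 0, 1e-3), 80, 12)
  rownames(m) <- sprintf("g%03d", 1:80)
  cc <- abs(cor(t(m)))^6
  diag(cc) <- 1
  tom <- topological_overlap(cc)
  det <- detect_modules(1 - tom, min_module_size = 30)
  mods <- setdiff(unique(det$labels), "grey")
  expect_length(mods, 2)
  expect_length(unique(det$labels[1:40]), 1)
  expect_length(unique(det$labels[41:80]), 1)

  small <- 1 - topological_overlap(random_adjacency(20, 9))
  expect_warning(det2 <- detect_modules(small, min_module_size = 30),
                 "unassigned")
  expect_true(all(det2$labels == "grey"))
})

test_that("module eigengene equals the SVD first component up to sign", {
  es <- toy_expr_set(15, 5, 5, seed = 11)
  genes <- rownames(es$values)[1:8]
  me <- module_eigengene(es, genes)
  xs <- t(scale(t(es$values[genes, ])))
  sv <- svd(xs)
  v1 <- sv$v[, 1] / sd(sv$v[, 1])
  expect_true(max(abs(me$me - v1)) < 1e-8 || max(abs(me$me + v1)) < 1e-8)
  expect_equal(me$var_explained, sv$d[1]^2 / sum(sv$d^2))
  expect_gte(cor(me$me, colMeans(xs)), 0)

  # identical standardized profiles: ME is that profile, variance explained 1
  base <- es$values[1, ]
  m <- rbind(2 * base, 5 * base, 0.5 * base)
  es2 <- es_from_matrix(m, 5, 5)
  me2 <- module_eigengene(es2, rownames(es2$values))
  prof <- as.numeric(scale(base))
  expect_equal(unname(me2$me), prof, tolerance = 1e-8)
  expect_equal(me2$var_explained, 1)

  # single-gene module: the gene's standardized profile
  me3 <- module_eigengene(es, rownames(es$values)[3])
  expect_equal(unname(me3$me),
               as.numeric(scale(es$values[3, ])), tolerance = 1e-8)
})

test_that("modules with close eigengenes merge below the cut height", {
  set.seed(21)
  n <- 20
  f <- rnorm(n)
  g <- f + rnorm(n, 0, 0.25)           # cor(f, g) ~ 0.97
  h <- rnorm(n)                        # unrelated
  m <- rbind(t(sapply(1:5, function(i) f + rnorm(n, 0, 0.05))),
             t(sapply(1:5, function(i) g + rnorm(n, 0, 0.05))),
             t(sapply(1:5, function(i) h + rnorm(n, 0, 0.05))))
  es <- es_from_matrix(m + 20, 10, 10)   # affine shift keeps correlations
  labels <- setNames(rep(c("m1", "m2", "m3"), each = 5),
                     rownames(es$values))
  merged <- merge_close_modules(es, labels, 0.25)
  lab <- unname(merged$labels)
  expect_equal(lab[1], lab[6])               # close pair merged
  expect_false(lab[1] == lab[11])            # distant module kept
  expect_equal(length(setdiff(unique(lab), "grey")), 2)
  expect_equal(formals(merge_close_modules)$cut_height, 0.25)
})

test_that("gene statistics compute GS, MM and kTotal as defined", {
  es <- toy_expr_set(12, 5, 5, seed = 14)
  adj <- soft_adjacency(correlation_matrix(es), 6)
  labels <- setNames(rep(c("blue", "red"), each = 6), rownames(es$values))
  mes <- acidnet:::module_eigengenes(es, labels)
  trait <- setNames(es$values[1, ], colnames(es$values))
  st <- gene_statistics(es, adj, labels, mes, trait)
  expect_equal(st$gs[1], 1)                  # gene identical to trait
  expect_equal(st$ktotal, unname(rowSums(adj) - 1), tolerance = 1e-12)
  expect_equal(st$mm[3],
               cor(es$values[3, ], mes[, "blue"]), tolerance = 1e-12)
  expect_error(
    gene_statistics(es, adj, labels, mes,
                    setNames(rep(1, 10), colnames(es$values))),
    "constant")
})

test_that("module-trait correlation uses the t transform and the 0.001
           default", {
  es <- toy_expr_set(10, 5, 5, seed = 15)
  labels <- setNames(rep("blue", 10), rownames(es$values))
  mes <- acidnet:::module_eigengenes(es, labels)
  traits <- tibble::tibble(sample_id = colnames(es$values),
                           malate = as.numeric(mes[, "blue"]))
  mt <- module_trait_correlation(mes, traits)
  expect_equal(mt$r, 1)
  expect_lt(mt$p, 1e-12)
  expect_equal(formals(module_trait_correlation)$sig_p, 0.001)
  r <- 0.6; n <- 29
  expect_equal(acidnet:::cor_pvalue(r, n),
               2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
})

test_that("permuting gene order permutes network outputs consistently", {
  es <- toy_expr_set(15, 5, 5, seed = 17)
  fit <- build_network(es, min_module_size = 5)
  perm <- sample(rownames(es$values))
  es_p <- subset_expression(es, gene_ids = perm)
  fit_p <- build_network(es_p, min_module_size = 5)
  expect_equal(fit_p$tom[perm, perm], fit$tom[perm, perm])
  expect_equal(sort(names(fit_p$labels)), sort(names(fit$labels)))
})

test_that("the adjusted Rand index agrees with an independent
           implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:10) {
    x <- sample(1:4, 50, replace = TRUE)
    y <- sample(1:5, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
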