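fake_stats <- function(n = 30, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    module = rep(c("turquoise", "blue", "brown"), length.out = n),
    gs = runif(n, -1, 1),
    mm = runif(n, -1, 1),
    ktotal = runif(n, 0, 30)
  ) |>
    dplyr::mutate(abs_gs = abs(gs), abs_mm = abs(mm))
}

test_that("MSAG selection is calibrated on the guide's absolute GS", {
  st <- fake_stats(40, seed = 2)
  st$abs_gs[st$gene_id == "g001"] <- 0.801
  st$gs[st$gene_id == "g001"] <- 0.801
  msag <- select_msags(st, "g001")
  expect_true("g001" %in% msag$gene_id)
  expect_true(all(msag$abs_gs >= 0.801))
  expect_setequal(msag$gene_id, st$gene_id[st$abs_gs >= 0.801])
  expect_equal(attr(msag, "guide_abs_gs"), 0.801)
  # guide alone when everything else is below
  st2 <- st; st2$abs_gs <- 0.1; st2$abs_gs[st2$gene_id == "g001"] <- 0.9
  expect_equal(select_msags(st2, "g001")$gene_id, "g001")
  # |GS| selection is invariant to a trait sign flip
  st3 <- st; st3$gs <- -st3$gs
  expect_setequal(select_msags(st3, "g001")$gene_id, msag$gene_id)
  expect_error(select_msags(st, "missing"), "missing")
})

test_that("hub selection takes the top-|MM| genes per module", {
  st <- fake_stats(60, seed = 3)
  hubs <- select_hub_genes(st, c("turquoise", "blue"), top_n = 12)
  expect_equal(nrow(hubs), 24)
  for (mod in c("turquoise", "blue")) {
    sub <- st[st$module == mod, ]
    oracle <- sub$gene_id[order(-sub$abs_mm, -sub$ktotal, sub$gene_id)][1:12]
    expect_equal(hubs$gene_id[hubs$module == mod], oracle)
    non_hub_max <- max(sub$abs_mm[!sub$gene_id %in% oracle])
    expect_true(all(hubs$abs_mm[hubs$module == mod] >= non_hub_max))
  }
  # disjoint modules give disjoint hub sets
  expect_equal(anyDuplicated(hubs$gene_id), 0)
  expect_warning(small <- select_hub_genes(st[1:6, ], "turquoise", 12),
                 "only")
  expect_error(select_hub_genes(st, "orange"), "orange")
})

test_that("subgroup kTotal equals combined when the groups are identical", {
  set.seed(4)
  half <- matrix(exp(rnorm(10 * 4, log(10), 0.5)), 10, 4)
  m <- cbind(half, half)               # each sample duplicated across groups
  es <- es_from_matrix(m, 4, 4)
  kt <- subgroup_ktotal(es)
  expect_equal(kt$ktotal_a, kt$ktotal_b, tolerance = 1e-12)
  expect_equal(kt$ktotal_a, kt$ktotal_combined, tolerance = 1e-12)
  expect_true(all(kt$pattern == "mixed"))
})

test_that("subgroup kTotal is sample-order invariant and errors on tiny
           groups", {
  es <- toy_expr_set(12, 5, 4, seed = 5)
  kt <- subgroup_ktotal(es)
  perm <- sample(colnames(es$values))
  kt_p <- subgroup_ktotal(subset_expression(es, sample_ids = perm))
  expect_equal(kt_p$ktotal_combined, kt$ktotal_combined, tolerance = 1e-12)
  expect_equal(kt_p$ktotal_a, kt$ktotal_a, tolerance = 1e-12)
  es_small <- toy_expr_set(5, 2, 4)
  expect_error(subgroup_ktotal(es_small), ">= 3 samples")
})

test_that("a module expressed only in one group gains connectivity there", {
  set.seed(8)
  n_a <- 6; n_b <- 6
  f <- rnorm(n_a)
  block_a <- t(sapply(1:6, function(i) c(10 * exp(f + rnorm(n_a, 0, 0.1)),
                                         exp(rnorm(n_b, 0, 0.1)))))
  noise <- matrix(exp(rnorm(6 * 12, log(5), 0.2)), 6, 12)
  es <- es_from_matrix(rbind(block_a, noise), n_a, n_b)
  kt <- subgroup_ktotal(es)
  expect_true(all(kt$ktotal_a[1:6] > kt$ktotal_b[1:6]))
})

test_that("connectivity-change patterns follow the sign definition", {
  # deltas are (subgroup - combined); combined 50 throughout
  expect_equal(classify_ktotal_pattern(40 - 50, 60 - 50), "major")
  expect_equal(classify_ktotal_pattern(60 - 50, 40 - 50), "reverse")
  expect_equal(classify_ktotal_pattern(45 - 50, 48 - 50), "down_both")
  expect_equal(classify_ktotal_pattern(55 - 50, 52 - 50), "up_both")
  expect_equal(classify_ktotal_pattern(0, 5), "mixed")
  expect_equal(classify_ktotal_pattern(5e-10, -3), "mixed")
  # exhaustive over sign combinations
  for (da in c(-1, 0, 1)) for (db in c(-1, 0, 1)) {
    pat <- classify_ktotal_pattern(da, db)
    if (da == 0 || db == 0) expect_equal(pat, "mixed")
    else if (da < 0 && db > 0) expect_equal(pat, "major")
    else if (da > 0 && db < 0) expect_equal(pat, "reverse")
    else if (da < 0) expect_equal(pat, "down_both")
    else expect_equal(pat, "up_both")
  }
})

test_that("module |MM|-|GS| correlation matches the direct formula", {
  st <- fake_stats(30, seed = 9)
  r1 <- module_mm_gs_correlation(st, "blue")
  sub <- st[st$module == "blue", ]
  expect_equal(r1$r, cor(sub$abs_mm, sub$abs_gs))
  expect_equal(r1$p, acidnet:::cor_pvalue(r1$r, nrow(sub)))
  st_perfect <- st; st_perfect$abs_gs <- st_perfect$abs_mm
  expect_equal(module_mm_gs_correlation(st_perfect, "blue")$r, 1)
  st_const <- st; st_const$abs_mm <- 0.5
  res <- module_mm_gs_correlation(st_const, "blue")
  expect_false(res$computable)
  expect_true(is.na(res$r))
  expect_error(module_mm_gs_correlation(st[1:2, ], "turquoise"), "< 3")
})

test_that("kTotal-|GS| relation reports r-squared with permutation
           invariance", {
  st <- fake_stats(100, seed = 10)
  rel <- ktotal_gs_relation(st)
  expect_equal(rel$r_squared, cor(st$ktotal, st$abs_gs)^2)
  st_prop <- st; st_prop$ktotal <- 3 * st_prop$abs_gs
  expect_equal(ktotal_gs_relation(st_prop)$r_squared, 1)
  rel_p <- ktotal_gs_relation(st[sample(nrow(st)), ])
  expect_equal(rel_p$r_squared, rel$r_squared)
  # independent kTotal and |GS|: r-squared near zero on large n
  set.seed(11)
  st_null <- tibble::tibble(gene_id = as.character(1:1000),
                            abs_gs = runif(1000), ktotal = runif(1000))
  expect_lt(ktotal_gs_relation(st_null)$r_squared, 0.02)
})
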