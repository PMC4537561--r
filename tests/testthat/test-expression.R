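test_that("expression_set validates structure and reports offending cells", {
  es <- toy_expr_set(3, 2, 2)
  expect_s3_class(es, "expr_set")
  expect_equal(dim(es), c(3L, 4L))

  m <- matrix(c(1, 2, -0.5, 4, 5, 6, 7, 8), 2, 4,
              dimnames = list(c("a", "b"), NULL))
  expect_error(es_from_matrix(m, 2, 2), "Negative RPKM.*'a'")

  expr <- tibble::tibble(gene_id = c("a", "a"), s1 = c(1, 2), s2 = c(3, 4))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), group = c("A", "B"))
  expect_error(expression_set(expr, meta), "Duplicate gene IDs")

  expr2 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 2), s2 = c(3, 4),
                          s3 = c(5, 6), s4 = c(1, 1))
  meta2 <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                          group = c("A", "A", "B"))
  expect_error(expression_set(expr2, meta2), "missing from metadata.*s4")
})

test_that("tab-separated files round-trip through the readers", {
  es <- toy_expr_set(3, 2, 2)
  dir <- withr::local_tempdir()
  expr_tbl <- tibble::as_tibble(cbind(
    data.frame(gene_id = rownames(es$values)), es$values))
  readr::write_tsv(expr_tbl, file.path(dir, "e.tsv"))
  readr::write_tsv(es$samples, file.path(dir, "m.tsv"))
  back <- read_expression(file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  expect_equal(back$values, es$values)
  expect_equal(back$groups, es$groups)
})

test_that("group means match a per-gene loop oracle", {
  es <- toy_expr_set(10, 3, 3, seed = 42)
  gm <- group_means(es)
  for (i in seq_len(10)) {
    expect_equal(gm$mean_a[i], mean(es$values[i, 1:3]))
    expect_equal(gm$mean_b[i], mean(es$values[i, 4:6]))
  }
  m <- matrix(c(1, 3, 0, 0), 1, 4)
  es2 <- es_from_matrix(m, 2, 2)
  gm2 <- group_means(es2)
  expect_equal(gm2$mean_a, 2)
  expect_equal(gm2$mean_b, 0)
})

test_that("expressed filter uses strict group-mean threshold with Venn", {
  m <- rbind(c(0.4, 0.4, 0.1, 0.1),   # A-only
             c(0.2, 0.2, 0.2, 0.2),   # not expressed
             c(1.0, 1.0, 1.0, 1.0),   # both
             c(0.1, 0.1, 0.8, 0.8),   # B-only
             c(0.3, 0.3, 0.3, 0.3))   # exactly at threshold: not expressed
  es <- es_from_matrix(m, 2, 2)
  fe <- filter_expressed(es)
  expect_equal(fe$category, c("a_only", NA, "both", "b_only", NA))
  expect_equal(sum(fe$expressed), 3)
  venn <- attr(fe, "venn")
  expect_equal(unname(venn["both"] + venn["a_only"] + venn["b_only"]),
               sum(fe$expressed))
  expect_equal(formals(filter_expressed)$threshold, 0.3)
})

test_that("raising the expression threshold never adds genes", {
  es <- toy_expr_set(50, 4, 3, seed = 7)
  prev <- filter_expressed(es, 0)
  for (thr in c(0.3, 1, 5, 20)) {
    cur <- filter_expressed(es, thr)
    expect_true(all(cur$gene_id[cur$expressed] %in%
                      prev$gene_id[prev$expressed]))
    prev <- cur
  }
})

test_that("square-root transform is the algebraic inverse of squaring", {
  es <- toy_expr_set(8, 3, 3, seed = 3)
  tr <- sqrt_transform(es)
  expect_equal(tr$values^2, es$values, tolerance = 1e-12)
  m <- matrix(c(4, 0, 1, 9), 1, 4)
  es2 <- es_from_matrix(m, 2, 2)
  expect_equal(as.numeric(sqrt_transform(es2)$values), c(2, 0, 1, 3))
})

test_that("trait tables are validated against ranges and samples", {
  es <- toy_expr_set(3, 2, 2)
  good <- tibble::tibble(sample_id = sprintf("s%02d", 1:4),
                         malate = c(7, 8, 2, 2), ph = c(3.3, 3.2, 4, 4.1))
  expect_silent(validate_traits(good, es))
  bad_ph <- good; bad_ph$ph[1] <- 15
  expect_error(validate_traits(bad_ph, es), "pH")
  bad_mal <- good; bad_mal$malate[2] <- -1
  expect_error(validate_traits(bad_mal, es), "malate")
  extra <- good; extra$sample_id[1] <- "zz"
  expect_error(validate_traits(extra, es), "absent")
})

test_that("trait group summary reports per-group means and their ratio", {
  es <- toy_expr_set(3, 2, 2)
  traits <- tibble::tibble(sample_id = sprintf("s%02d", 1:4),
                           malate = c(8, 6, 2, 2))
  sm <- trait_group_summary(traits, es)
  expect_equal(sm$mean[sm$group == "A"], 7)
  expect_equal(sm$mean[sm$group == "B"], 2)
  expect_equal(unname(attr(sm, "ratio")["malate"]), 3.5)
})
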