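#' Weighted two-group proportions test on RPKM columns
#'
#' Moment-based beta-binomial-style test of differential expression between
#' the two genotype groups, after Baggerly et al. (2003). Each sample's
#' per-gene value is converted to a proportion of that sample's column total;
#' within each group, proportions are averaged with weights proportional to
#' the column totals, so deeper samples count more. The statistic is the
#' difference of weighted group means over the pooled standard error of the
#' weighted means; p-values come from a t reference with Welch-Satterthwaite
#' degrees of freedom based on the groups' effective sample sizes.
#'
#' Genes untestable because one group carries zero total signal are flagged
#' (`testable = FALSE`) and given p = 1 by convention.
#'
#' @param es An `expr_set` with at least two samples per group.
#' @return A tibble with one row per gene: `gene_id`, `mean_a`, `mean_b`
#'   (RPKM group means), `statistic`, `p`, `p_fdr` (Benjamini-Hochberg),
#'   `rpkm_range` (max - min across all samples) and `testable`.
#' @export
proportions_test <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$values
  tot <- colSums(m)
  ids_a <- group_sample_ids(es, "a")
  ids_b <- group_sample_ids(es, "b")
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("proportions_test needs >= 2 samples per group")
  }

  group_stats <- function(ids) {
    w <- tot[ids]
    if (sum(w) <= 0) {
      return(list(mean = rep(NA_real_, nrow(m)),
                  se2 = rep(NA_real_, nrow(m)), n_eff = NA_real_))
    }
    p <- sweep(m[, ids, drop = FALSE], 2, ifelse(w > 0, w, 1), "/")
    wn <- w / sum(w)
    n_eff <- 1 / sum(wn^2)
    mu <- as.numeric(p %*% wn)
    # weighted sample variance with effective-sample-size bias correction
    dev2 <- sweep(p, 1, mu, "-")^2
    s2 <- as.numeric(dev2 %*% wn) * n_eff / (n_eff - 1)
    list(mean = mu, se2 = s2 / n_eff, n_eff = n_eff)
  }

  ga <- group_stats(ids_a)
  gb <- group_stats(ids_b)
  testable <- !is.na(ga$mean) & !is.na(gb$mean)
  se2 <- ga$se2 + gb$se2
  stat <- ifelse(se2 > 0, (ga$mean - gb$mean) / sqrt(se2), 0)
  df <- se2^2 / (ga$se2^2 / (ga$n_eff - 1) + gb$se2^2 / (gb$n_eff - 1))
  df[!is.finite(df) | df < 1] <- 1
  p <- ifelse(se2 > 0, 2 * pt(-abs(stat), df), 1)
  p[!testable] <- 1
  stat[!testable] <- 0
  if (any(!testable)) {
    inform(sprintf("%d gene(s) untestable (zero group signal); p set to 1",
                   sum(!testable)))
  }
  gm <- group_means(es)
  tibble::tibble(
    gene_id = rownames(m),
    mean_a = gm$mean_a, mean_b = gm$mean_b,
    statistic = unname(stat), p = unname(pmin(p, 1)),
    p_fdr = bh_adjust(unname(pmin(p, 1))),
    rpkm_range = unname(apply(m, 1, max) - apply(m, 1, min)),
    testable = unname(testable)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values controlling the false discovery rate, in the
#'   original order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Keeps genes with FDR-adjusted p below `alpha` whose RPKM range across all
#' samples is at least `min_range` (low-amplitude genes are removed even when
#' statistically significant).
#'
#' @param d Result of [proportions_test()].
#' @param alpha FDR cutoff; default 0.05.
#' @param min_range Minimum RPKM range (max - min over samples); default 5.
#' @return Character vector of selected gene IDs.
#' @export
select_degs <- function(d, alpha = 0.05, min_range = 5) {
  d$gene_id[d$p_fdr < alpha & d$rpkm_range >= min_range]
}

#' Genes expressed similarly to the guide gene
#'
#' Two filters on the group means: absolute between-group mean difference
#' greater than `min_diff` RPKM, and between-group fold change greater than
#' `min_fc`. A zero denominator counts as an infinite fold change (passes).
#' With `direction = "same_as_guide"` the higher-mean group must additionally
#' match the guide gene's higher-mean group.
#'
#' @param es An `expr_set` containing the guide gene.
#' @param guide_id Guide gene ID.
#' @param min_diff Minimum between-group mean difference in RPKM; default 10.
#' @param min_fc Minimum fold change; default 1.5.
#' @param direction `"same_as_guide"` (default) or `"either"`.
#' @return Character vector of gene IDs passing both filters (the guide
#'   itself is not exempted from them).
#' @export
guide_similarity <- function(es, guide_id, min_diff = 10, min_fc = 1.5,
                             direction = c("same_as_guide", "either")) {
  direction <- match.arg(direction)
  gm <- group_means(es)
  if (!guide_id %in% gm$gene_id) {
    abort(sprintf("Guide gene '%s' absent from the expression data", guide_id))
  }
  diff <- abs(gm$mean_a - gm$mean_b)
  lo <- pmin(gm$mean_a, gm$mean_b)
  hi <- pmax(gm$mean_a, gm$mean_b)
  fc <- ifelse(lo > 0, hi / lo, Inf)
  pass <- diff > min_diff & fc > min_fc
  if (direction == "same_as_guide") {
    g <- gm[gm$gene_id == guide_id, ]
    guide_dir <- sign(g$mean_a - g$mean_b)
    pass <- pass & sign(gm$mean_a - gm$mean_b) == guide_dir
  }
  gm$gene_id[pass]
}

#' Assemble the trait-associated gene set
#'
#' The union of differentially expressed genes and guide-similar genes, with
#' per-gene provenance.
#'
#' @param degs Character vector from [select_degs()].
#' @param similar Character vector from [guide_similarity()].
#' @param guide_id Guide gene ID.
#' @return A tibble with `gene_id` and `provenance` (`"deg"`, `"similar"` or
#'   `"both"`), carrying attribute `counts` (n_deg, n_similar, n_union) and
#'   `guide_id`.
#' @export
assemble_faags <- function(degs, similar, guide_id) {
  union_ids <- union(degs, similar)
  out <- tibble::tibble(
    gene_id = union_ids,
    provenance = dplyr::case_when(
      union_ids %in% degs & union_ids %in% similar ~ "both",
      union_ids %in% degs ~ "deg",
      TRUE ~ "similar"
    )
  )
  attr(out, "counts") <- c(n_deg = length(degs), n_similar = length(similar),
                           n_union = length(union_ids))
  attr(out, "guide_id") <- guide_id
  out
}
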