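#' Most significant acidity genes (guide-calibrated selection)
#'
#' Selects genes whose absolute gene significance (|GS|) is at least the
#' guide gene's observed |GS|; the guide is therefore included by
#' construction.
#'
#' @param stats Gene statistics tibble from [gene_statistics()] (or
#'   `tidy()` of an `acid_network`).
#' @param guide_id Guide gene ID; must be present in `stats`.
#' @return A tibble of selected genes sorted by decreasing |GS| (columns of
#'   `stats`), with the guide's |GS| threshold in attribute
#'   `guide_abs_gs`.
#' @export
select_msags <- function(stats, guide_id) {
  if (!guide_id %in% stats$gene_id) {
    abort(sprintf("Guide gene '%s' not in gene statistics", guide_id))
  }
  thr <- stats$abs_gs[stats$gene_id == guide_id]
  out <- dplyr::arrange(stats[stats$abs_gs >= thr, ], dplyr::desc(.data$abs_gs))
  attr(out, "guide_abs_gs") <- thr
  out
}

#' Intramodular hub genes
#'
#' Per selected module, the `top_n` genes by absolute module membership
#' (|MM|); ties broken by higher kTotal, then lexicographic gene ID. Modules
#' smaller than `top_n` return all members with a warning.
#'
#' @param stats Gene statistics tibble.
#' @param modules Character vector of module names to take hubs from.
#' @param top_n Hubs per module; default 12.
#' @return A tibble with `module`, `rank` and the gene's statistics.
#' @export
select_hub_genes <- function(stats, modules, top_n = 12) {
  unknown <- setdiff(modules, unique(stats$module))
  if (length(unknown)) {
    abort(paste0("Unknown module(s): ", paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(modules, function(mod) {
    sub <- stats[stats$module == mod, ]
    if (nrow(sub) < top_n) {
      warn(sprintf("Module %s has only %d genes (< %d)", mod, nrow(sub), top_n))
    }
    sub <- dplyr::arrange(sub, dplyr::desc(.data$abs_mm),
                          dplyr::desc(.data$ktotal), .data$gene_id)
    sub <- head(sub, top_n)
    dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(sub))),
                     sub)[, c("module", "rank",
                              setdiff(names(sub), "module"))]
  })
}

#' Total connectivity in sample subgroups
#'
#' Rebuilds the correlation -> soft-threshold adjacency pipeline (same
#' `beta`) on (i) all samples, (ii) group A only and (iii) group B only, and
#' returns each gene's kTotal in the three networks plus the change pattern.
#'
#' @param es An `expr_set` restricted to the network genes (RPKM scale;
#'   square-root transform applied internally as in [build_network()]).
#' @param beta Soft-threshold power; default 6.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return A tibble: `gene_id`, `ktotal_combined`, `ktotal_a`, `ktotal_b`,
#'   `delta_a`, `delta_b`, `pattern`. Patterns are `"major"` (up in B, down
#'   in A), `"reverse"`, `"down_both"`, `"up_both"` or `"mixed"` (a delta
#'   within tolerance of zero).
#' @export
subgroup_ktotal <- function(es, beta = 6, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (transform == "sqrt") es <- sqrt_transform(es)
  ids_a <- group_sample_ids(es, "a")
  ids_b <- group_sample_ids(es, "b")
  if (length(ids_a) < 3 || length(ids_b) < 3) {
    abort("Each subgroup needs >= 3 samples")
  }
  kt <- function(sample_ids) {
    sub <- subset_expression(es, sample_ids = sample_ids)
    sds <- apply(sub$values, 1, sd)
    a <- suppressWarnings(soft_adjacency(cor(t(sub$values)), beta))
    a[!is.finite(a)] <- 0        # constant-in-subgroup genes: no edges
    diag(a) <- 1
    rowSums(a) - 1
  }
  k_all <- kt(colnames(es$values))
  k_a <- kt(ids_a)
  k_b <- kt(ids_b)
  out <- tibble::tibble(
    gene_id = rownames(es$values),
    ktotal_combined = unname(k_all),
    ktotal_a = unname(k_a), ktotal_b = unname(k_b),
    delta_a = unname(k_a - k_all), delta_b = unname(k_b - k_all)
  )
  out$pattern <- mapply(classify_ktotal_pattern, out$delta_a, out$delta_b)
  out
}

#' Classify a gene's subgroup connectivity change
#'
#' Sign-based classification of the kTotal deltas (subgroup minus combined):
#' `"major"` when connectivity rises in group B but falls in group A (the
#' dominant pattern reported for low-acidity genotypes), `"reverse"` for the
#' opposite, `"down_both"`/`"up_both"` when both deltas share sign, and
#' `"mixed"` when a delta is zero within tolerance.
#'
#' @param delta_a,delta_b kTotal changes for groups A and B.
#' @param tol Equality tolerance; default 1e-9.
#' @return One of `"major"`, `"reverse"`, `"down_both"`, `"up_both"`,
#'   `"mixed"`.
#' @export
classify_ktotal_pattern <- function(delta_a, delta_b, tol = 1e-9) {
  sa <- if (abs(delta_a) <= tol) 0 else sign(delta_a)
  sb <- if (abs(delta_b) <= tol) 0 else sign(delta_b)
  if (sa == 0 || sb == 0) return("mixed")
  if (sb > 0 && sa < 0) return("major")
  if (sa > 0 && sb < 0) return("reverse")
  if (sa < 0 && sb < 0) return("down_both")
  "up_both"
}

#' Module-level |MM| vs |GS| correlation
#'
#' Pearson correlation between member genes' absolute module membership and
#' absolute gene significance, with a two-sided p-value.
#'
#' @param stats Gene statistics tibble.
#' @param module Module name.
#' @return A tibble with `module`, `n`, `r`, `p`; `r` is `NA` (flagged
#'   `computable = FALSE`) when either statistic is constant.
#' @export
module_mm_gs_correlation <- function(stats, module) {
  sub <- stats[stats$module == module, ]
  if (nrow(sub) < 3) abort(sprintf("Module %s has < 3 genes", module))
  computable <- sd(sub$abs_mm) > 0 && sd(sub$abs_gs) > 0
  r <- if (computable) cor(sub$abs_mm, sub$abs_gs) else NA_real_
  p <- if (computable) cor_pvalue(r, nrow(sub)) else NA_real_
  tibble::tibble(module = module, n = nrow(sub), r = r, p = p,
                 computable = computable)
}

#' Whole-network kTotal vs |GS| relation
#'
#' The network-wide check that more connected genes tend to have higher
#' gene significance: r-squared and p of the Pearson correlation between
#' kTotal and |GS| across all network genes.
#'
#' @param stats Gene statistics tibble.
#' @return A tibble with `n`, `r`, `r_squared`, `p`.
#' @export
ktotal_gs_relation <- function(stats) {
  ok <- stats[is.finite(stats$ktotal) & is.finite(stats$abs_gs), ]
  if (nrow(ok) < 3) abort("Need >= 3 genes")
  r <- cor(ok$ktotal, ok$abs_gs)
  tibble::tibble(n = nrow(ok), r = r, r_squared = r^2,
                 p = cor_pvalue(r, nrow(ok)))
}
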