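#' Build an expression set from tidy tables
#'
#' The universal input container of the pipeline: an RPKM gene-by-sample
#' matrix plus sample metadata assigning every sample to one of two genotype
#' groups (e.g. *Ma_* vs *mama*) and a replicate label.
#'
#' @param expr A data frame whose first column (or a column named `gene_id`)
#'   holds unique gene identifiers; all remaining columns are numeric RPKM
#'   values, one column per sample.
#' @param samples A data frame with columns `sample_id`, `group` and
#'   optionally `replicate`. Every expression column must appear in
#'   `sample_id`, and `group` must take exactly two values with at least two
#'   samples each.
#'
#' @return An object of class `expr_set`: a list with `values` (numeric
#'   gene-by-sample matrix), `samples` (tibble of metadata) and `groups`
#'   (the two group labels; the first is "group A" throughout).
#' @export
expression_set <- function(expr, samples) {
  expr <- tibble::as_tibble(expr)
  samples <- tibble::as_tibble(samples)
  id_col <- if ("gene_id" %in% names(expr)) "gene_id" else names(expr)[1]
  gene_ids <- as.character(expr[[id_col]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("Duplicate gene IDs: ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- expr[setdiff(names(expr), id_col)]
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num)) {
    abort(paste0("Non-numeric expression column(s): ",
                 paste(not_num, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing value at gene '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative RPKM at gene '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  req <- c("sample_id", "group")
  if (!all(req %in% names(samples))) {
    abort("`samples` needs columns sample_id and group")
  }
  samples$sample_id <- as.character(samples$sample_id)
  missing_meta <- setdiff(colnames(m), samples$sample_id)
  if (length(missing_meta)) {
    abort(paste0("Samples missing from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (!"replicate" %in% names(samples)) samples$replicate <- NA_character_
  groups <- unique(as.character(samples$group))
  if (length(groups) != 2) {
    abort(sprintf("Expected exactly 2 groups, found %d (%s)",
                  length(groups), paste(groups, collapse = ", ")))
  }
  n_per <- table(factor(samples$group, levels = groups))
  if (any(n_per < 2)) abort("Each group needs at least 2 samples")
  structure(
    list(values = m, samples = samples, groups = groups),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  n_per <- table(factor(x$samples$group, levels = x$groups))
  cat(sprintf("<expr_set> %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              x$groups[1], n_per[1], x$groups[2], n_per[2]))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read expression and metadata from tab-separated files
#'
#' Expression files have genes in rows, the first column holding gene IDs and
#' a header row of sample IDs. Metadata files have columns `sample_id`,
#' `group` and optionally `replicate`.
#'
#' @param path Path to the tab-separated expression table.
#' @param metadata_path Path to the tab-separated sample metadata table.
#' @return An [expression_set()] object.
#' @export
read_expression <- function(path, metadata_path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  expression_set(expr, meta)
}

#' Read a per-sample trait table
#'
#' Traits are acidity measurements: `malate` (mg/g fresh weight), `ta`
#' (titratable acidity, mg/ml malic-acid equivalent) and `ph`. Any subset of
#' the three columns is allowed.
#'
#' @param path Path to a tab-separated table with a `sample_id` column.
#' @param es Optional `expr_set`; if given, trait sample IDs must be a subset
#'   of its samples.
#' @return A tibble with `sample_id` and trait columns.
#' @export
read_traits <- function(path, es = NULL) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_traits(tr, es)
}

validate_traits <- function(tr, es = NULL) {
  tr <- tibble::as_tibble(tr)
  if (!"sample_id" %in% names(tr)) abort("Trait table needs a sample_id column")
  tr$sample_id <- as.character(tr$sample_id)
  known <- intersect(c("malate", "ta", "ph"), names(tr))
  if (!length(known)) abort("Trait table has none of: malate, ta, ph")
  for (v in intersect(c("malate", "ta"), known)) {
    if (any(tr[[v]] < 0, na.rm = TRUE)) abort(sprintf("Negative %s value", v))
  }
  if ("ph" %in% known && any(tr$ph <= 0 | tr$ph >= 14, na.rm = TRUE)) {
    abort("pH values must lie in (0, 14)")
  }
  if (!is.null(es)) {
    extra <- setdiff(tr$sample_id, colnames(es$values))
    if (length(extra)) {
      abort(paste0("Trait samples absent from expression data: ",
                   paste(extra, collapse = ", ")))
    }
  }
  tr
}

group_sample_ids <- function(es, which = c("a", "b")) {
  which <- match.arg(which)
  g <- es$groups[if (which == "a") 1 else 2]
  es$samples$sample_id[es$samples$group == g]
}

#' Per-gene group mean expression
#'
#' Unweighted arithmetic mean RPKM over the samples of each genotype group.
#'
#' @param es An `expr_set`.
#' @return A tibble with `gene_id`, `mean_a`, `mean_b` (group A is the first
#'   group label of `es`).
#' @export
group_means <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  a <- rowMeans(es$values[, group_sample_ids(es, "a"), drop = FALSE])
  b <- rowMeans(es$values[, group_sample_ids(es, "b"), drop = FALSE])
  tibble::tibble(gene_id = rownames(es$values),
                 mean_a = unname(a), mean_b = unname(b))
}

#' Expressed-gene filter with Venn partition
#'
#' A gene is called expressed when its mean RPKM exceeds `threshold` in at
#' least one of the two group means (strict inequality). The expressed set is
#' partitioned into genes above threshold in both groups, in group A only, or
#' in group B only.
#'
#' @param es An `expr_set`.
#' @param threshold RPKM cutoff on the group means; default 0.3.
#' @return A tibble with `gene_id`, `mean_a`, `mean_b`, `expressed` and
#'   `category` (`"both"`, `"a_only"`, `"b_only"` or `NA` when not
#'   expressed). The Venn counts are attached as attribute `venn`.
#' @export
filter_expressed <- function(es, threshold = 0.3) {
  stopifnot(threshold >= 0)
  gm <- group_means(es)
  in_a <- gm$mean_a > threshold
  in_b <- gm$mean_b > threshold
  gm$expressed <- in_a | in_b
  gm$category <- dplyr::case_when(
    in_a & in_b ~ "both",
    in_a & !in_b ~ "a_only",
    !in_a & in_b ~ "b_only",
    TRUE ~ NA_character_
  )
  venn <- c(both = sum(in_a & in_b), a_only = sum(in_a & !in_b),
            b_only = sum(!in_a & in_b))
  attr(gm, "venn") <- venn
  gm
}

#' Subset an expression set by gene or sample
#'
#' @param es An `expr_set`.
#' @param gene_ids,sample_ids Character vectors of IDs to keep (NULL keeps all).
#' @return A new `expr_set`.
#' @export
subset_expression <- function(es, gene_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$values
  if (!is.null(gene_ids)) {
    missing_g <- setdiff(gene_ids, rownames(m))
    if (length(missing_g)) {
      abort(paste0("Unknown gene ID(s): ", paste(head(missing_g, 5), collapse = ", ")))
    }
    m <- m[gene_ids, , drop = FALSE]
  }
  smp <- es$samples
  if (!is.null(sample_ids)) {
    m <- m[, sample_ids, drop = FALSE]
    smp <- smp[match(sample_ids, smp$sample_id), , drop = FALSE]
  }
  out <- es
  out$values <- m
  out$samples <- smp
  out
}

#' Square-root transform of RPKM values
#'
#' Variance-stabilizing normalization applied before network construction:
#' each RPKM value is replaced by its square root.
#'
#' @param es An `expr_set`.
#' @return An `expr_set` of the same shape with transformed values.
#' @export
sqrt_transform <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  es$values <- sqrt(es$values)
  attr(es, "transformed") <- "sqrt"
  es
}

#' Group summary of trait measurements
#'
#' Mean, standard deviation and sample count of each trait per genotype group,
#' plus the between-group ratio of means (group A over group B).
#'
#' @param traits A data frame with `sample_id` and trait columns, or an
#'   already-grouped table with columns `group` and per-group means.
#' @param es An `expr_set` supplying the sample-to-group mapping.
#' @return A tibble with one row per (trait, group) and the mean ratio in
#'   attribute `ratio` (named by trait).
#' @export
trait_group_summary <- function(traits, es) {
  traits <- validate_traits(traits, es)
  smp <- es$samples[, c("sample_id", "group")]
  long <- tidyr::pivot_longer(
    dplyr::inner_join(traits, smp, by = "sample_id"),
    cols = dplyr::any_of(c("malate", "ta", "ph")),
    names_to = "trait", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$trait, .data$group),
    mean = mean(.data$value), sd = sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(out[, c("trait", "group", "mean")],
                             names_from = "group", values_from = "mean")
  ga <- es$groups[1]; gb <- es$groups[2]
  ratio <- setNames(wide[[ga]] / wide[[gb]], wide$trait)
  attr(out, "ratio") <- ratio
  out
}
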