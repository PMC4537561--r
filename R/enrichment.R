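#' Read a gene-annotation table
#'
#' @param path Tab-separated file with columns `gene_id`, `namespace`,
#'   `term_id`, `term_name`.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "namespace", "term_id")
  if (!all(req %in% names(ann))) {
    abort("Annotation needs columns gene_id, namespace, term_id")
  }
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  tibble::as_tibble(ann)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For every annotation term (with at least `min_term_size` background
#' genes), tests over-representation (`p_over = P(X >= k)`) and
#' under-representation (`p_under = P(X <= k)`) of the term among the module
#' genes under `Hypergeometric(N, K, n)`, where `N` is the namespace
#' background size, `K` the term's background count, `n` the module genes in
#' the background and `k` the overlap. Benjamini-Hochberg adjustment is
#' applied across the terms tested within each (namespace, module) family.
#'
#' @param module_genes Character vector of gene IDs (one module).
#' @param annotation Annotation tibble (`gene_id`, `namespace`, `term_id`,
#'   `term_name`).
#' @param background Character vector of background gene IDs (the expressed
#'   universe). Terms and module genes are intersected with it; module genes
#'   absent from the background are dropped with a warning.
#' @param background_size Optional named vector giving the background size
#'   `N` per namespace (e.g. the counts of annotated expressed genes);
#'   defaults to the number of background genes annotated in that namespace.
#' @param alpha FDR cutoff for the significance flags; default 0.05.
#' @param min_term_size Smallest background term tested; default 1.
#' @param module Optional module name recorded in the output.
#' @return A tibble per term: `module`, `namespace`, `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `p_over`, `p_under`, `p_fdr_over`, `p_fdr_under`,
#'   `enriched`, `repressed`.
#' @export
hypergeom_enrich <- function(module_genes, annotation, background,
                             background_size = NULL, alpha = 0.05,
                             min_term_size = 1, module = "set") {
  annotation <- tibble::as_tibble(annotation)
  if (!nrow(annotation)) abort("Empty annotation (term universe)")
  dropped <- setdiff(module_genes, background)
  if (length(dropped)) {
    warn(paste0("Module gene(s) absent from background, dropped: ",
                paste(head(dropped, 5), collapse = ", ")))
    module_genes <- intersect(module_genes, background)
  }
  ann_bg <- annotation[annotation$gene_id %in% background, ]
  out <- purrr::map_dfr(unique(ann_bg$namespace), function(ns) {
    sub <- ann_bg[ann_bg$namespace == ns, ]
    override <- !is.null(background_size) && ns %in% names(background_size)
    annotated <- unique(sub$gene_id)
    # with an explicit background size the sampling universe is the full
    # background; by default it is the namespace's annotated genes
    ns_n <- if (override) background_size[[ns]] else length(annotated)
    n <- if (override) length(intersect(module_genes, background)) else
      length(intersect(module_genes, annotated))
    terms <- dplyr::summarise(
      dplyr::group_by(sub, .data$term_id, .data$term_name),
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, module_genes)),
      .groups = "drop")
    terms <- terms[terms$K >= min_term_size, ]
    if (!nrow(terms)) return(NULL)
    terms$namespace <- ns
    terms$n <- n
    terms$N <- ns_n
    terms$p_over <- phyper(terms$k - 1, terms$K, terms$N - terms$K, terms$n,
                           lower.tail = FALSE)
    terms$p_under <- phyper(terms$k, terms$K, terms$N - terms$K, terms$n)
    terms$p_fdr_over <- bh_adjust(terms$p_over)
    terms$p_fdr_under <- bh_adjust(terms$p_under)
    terms
  })
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(module = character(0)))
  }
  out$module <- module
  out$enriched <- out$p_fdr_over < alpha
  out$repressed <- out$p_fdr_under < alpha
  out[, c("module", "namespace", "term_id", "term_name", "k", "n", "K", "N",
          "p_over", "p_under", "p_fdr_over", "p_fdr_under",
          "enriched", "repressed")]
}

#' Enrichment over several modules
#'
#' Applies [hypergeom_enrich()] to each module of a module-label vector.
#'
#' @param labels Named character vector gene -> module.
#' @param modules Modules to test (default: all non-grey).
#' @inheritParams hypergeom_enrich
#' @return Row-bound enrichment tibble over the tested modules.
#' @export
enrich_modules <- function(labels, annotation, background,
                           modules = NULL, background_size = NULL,
                           alpha = 0.05, min_term_size = 1) {
  modules <- modules %||% setdiff(unique(labels), "grey")
  purrr::map_dfr(modules, function(mod) {
    hypergeom_enrich(names(labels)[labels == mod], annotation, background,
                     background_size, alpha, min_term_size, module = mod)
  })
}
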