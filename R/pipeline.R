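#' Run the full guide-anchored co-expression pipeline
#'
#' Orchestrates the stages in order: expressed-gene filter, trait-associated
#' gene selection (differential expression union guide-similarity), network
#' construction with module detection and module-trait statistics,
#' guide-calibrated selections (most-significant genes, intramodular hubs),
#' subgroup connectivity patterns, term enrichment, and regulator detection.
#' A manifest records the seed, parameter values and per-stage gene counts;
#' rerunning with the same inputs and seed reproduces all outputs.
#'
#' @param es An `expr_set` of RPKM values.
#' @param traits Traits tibble (`sample_id`, `malate`/`ta`/`ph`).
#' @param annotation Annotation tibble.
#' @param guide_id Guide gene ID.
#' @param expressed_threshold Group-mean RPKM expression cutoff; default 0.3.
#' @param alpha DE FDR cutoff; default 0.05.
#' @param min_range Minimum RPKM range for DE genes; default 5.
#' @param min_diff,min_fc Guide-similarity thresholds; defaults 10 and 1.5.
#' @param beta,min_module_size,merge_cut_height Network parameters; defaults
#'   6, 30, 0.25.
#' @param sig_p Module-trait significance cutoff; default 0.001.
#' @param trait_name Trait driving GS and module selection; default
#'   `"malate"`.
#' @param top_n_hubs Hubs per significant module; default 12.
#' @param enrich_alpha Enrichment FDR cutoff; default 0.05.
#' @param candidate_term_ids Annotation terms marking candidate regulators.
#' @param run_regulators Set `FALSE` to skip the regulator stage.
#' @param regulator_cfg Optional [regulator_config()]; defaults to the
#'   standard configuration seeded with `seed`.
#' @param edge_threshold Network-export TOM weight cutoff; default 0.10.
#' @param seed Pipeline seed (drives the regulator stage and control draw).
#' @param out_dir Optional directory; when given, all stage tables, the
#'   network export and the manifest are written there.
#' @return A list of class `acid_pipeline` with components `expressed`,
#'   `de`, `faags`, `network`, `msags`, `hubs`, `subgroup`, `enrichment`,
#'   `regulators`, `manifest`.
#' @export
run_pipeline <- function(es, traits, annotation, guide_id,
                         expressed_threshold = 0.3, alpha = 0.05,
                         min_range = 5, min_diff = 10, min_fc = 1.5,
                         beta = 6, min_module_size = 30,
                         merge_cut_height = 0.25, sig_p = 0.001,
                         trait_name = "malate", top_n_hubs = 12,
                         enrich_alpha = 0.05,
                         candidate_term_ids = "GO:TFST",
                         run_regulators = TRUE, regulator_cfg = NULL,
                         edge_threshold = 0.10,
                         seed = 1L, out_dir = NULL) {
  stopifnot(inherits(es, "expr_set"))
  traits <- validate_traits(traits, es)

  expressed <- filter_expressed(es, expressed_threshold)
  expressed_ids <- expressed$gene_id[expressed$expressed]
  if (!guide_id %in% expressed_ids) {
    abort(sprintf("Guide gene '%s' is not expressed above threshold",
                  guide_id))
  }
  es_expr <- subset_expression(es, gene_ids = expressed_ids)

  de <- proportions_test(es_expr)
  degs <- select_degs(de, alpha, min_range)
  similar <- guide_similarity(es_expr, guide_id, min_diff, min_fc)
  faags <- assemble_faags(degs, similar, guide_id)
  if (nrow(faags) < 3) abort("Fewer than 3 trait-associated genes")

  es_faag <- subset_expression(es, gene_ids = faags$gene_id)
  fit <- build_network(es_faag, traits, trait_name, beta, min_module_size,
                       merge_cut_height, sig_p = sig_p)

  stats <- fit$gene_stats
  msags <- if (guide_id %in% stats$gene_id) {
    select_msags(stats, guide_id)
  } else {
    warn("Guide gene dropped before network stage; no MSAG selection")
    NULL
  }
  mt <- fit$module_trait
  sig_modules <- mt$module[mt$trait == trait_name & mt$significant &
                             mt$module != "grey"]
  hubs <- if (length(sig_modules)) {
    suppressWarnings(select_hub_genes(stats, sig_modules, top_n_hubs))
  } else {
    warn("No module significantly correlated with the trait; no hubs")
    NULL
  }
  subgroup <- subgroup_ktotal(subset_expression(es, rownames(fit$es$values)),
                              beta)
  subgroup$module <- fit$labels[subgroup$gene_id]
  relation <- ktotal_gs_relation(stats)

  enr <- enrich_modules(fit$labels, annotation, expressed_ids,
                        modules = if (length(sig_modules)) sig_modules else NULL,
                        alpha = enrich_alpha)

  regulators <- NULL
  if (run_regulators) {
    cfg <- regulator_cfg %||% regulator_config(seed = seed)
    candidates <- select_candidates(annotation, faags$gene_id,
                                    candidate_term_ids, cfg$n_candidates,
                                    seed)
    if (length(candidates) >= 2) {
      regulators <- detect_regulators(sqrt_transform(es_faag), candidates, cfg)
    } else {
      warn("Fewer than 2 candidate regulators; regulator stage skipped")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("acidnet")),
    seed = seed,
    parameters = list(
      expressed_threshold = expressed_threshold, alpha = alpha,
      min_range = min_range, min_diff = min_diff, min_fc = min_fc,
      beta = beta, min_module_size = min_module_size,
      merge_cut_height = merge_cut_height, sig_p = sig_p,
      trait_name = trait_name, top_n_hubs = top_n_hubs,
      enrich_alpha = enrich_alpha, edge_threshold = edge_threshold),
    counts = list(
      n_genes = nrow(es$values),
      n_expressed = length(expressed_ids),
      venn = as.list(attr(expressed, "venn")),
      n_deg = length(degs), n_similar = length(similar),
      n_faag = nrow(faags),
      n_modules = length(setdiff(unique(fit$labels), "grey")),
      n_grey = sum(fit$labels == "grey"),
      n_sig_modules = length(sig_modules),
      n_msag = if (is.null(msags)) 0L else nrow(msags),
      n_hubs = if (is.null(hubs)) 0L else nrow(hubs),
      n_enriched = sum(enr$enriched %||% logical(0)),
      n_regulator_pairs = if (is.null(regulators)) 0L else
        nrow(regulators$regulators))
  )

  out <- structure(list(
    expressed = expressed, de = de, faags = faags, network = fit,
    msags = msags, hubs = hubs, subgroup = subgroup,
    ktotal_gs = relation, enrichment = enr, regulators = regulators,
    manifest = manifest, guide_id = guide_id
  ), class = "acid_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir, edge_threshold)
  out
}

#' @export
print.acid_pipeline <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(paste0(
    "<acid_pipeline> %d genes; %d expressed; %d trait-associated ",
    "(%d DE, %d guide-similar)\n  %d modules (%d significant), %d MSAGs, ",
    "%d hubs, %d regulator assignments\n"),
    cts$n_genes, cts$n_expressed, cts$n_faag, cts$n_deg, cts$n_similar,
    cts$n_modules, cts$n_sig_modules, cts$n_msag, cts$n_hubs,
    cts$n_regulator_pairs))
  invisible(x)
}

write_pipeline <- function(res, out_dir, edge_threshold = 0.10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl)) {
      readr::write_tsv(tbl, file.path(out_dir, name), progress = FALSE)
    }
  }
  w(res$expressed, "expressed.tsv")
  w(res$de, "differential_expression.tsv")
  w(res$faags, "faags.tsv")
  w(res$network$gene_stats, "gene_statistics.tsv")
  w(res$network$module_trait, "module_trait.tsv")
  me <- res$network$eigengenes
  w(tibble::as_tibble(cbind(data.frame(sample_id = rownames(me)), me)),
    "eigengenes.tsv")
  w(res$msags, "msags.tsv")
  w(res$hubs, "hubs.tsv")
  w(res$subgroup, "subgroup_ktotal.tsv")
  w(res$enrichment, "enrichment.tsv")
  if (!is.null(res$regulators)) {
    w(res$regulators$clusters, "tight_clusters.tsv")
    w(res$regulators$assignments, "regulator_scores.tsv")
    w(res$regulators$calibration, "regulator_calibration.tsv")
    trees <- res$regulators$trees
    txt <- paste(vapply(names(trees), function(nm) {
      paste0("cluster ", nm, "\n", format_sample_tree(trees[[nm]]))
    }, character(1)), collapse = "\n\n")
    writeLines(txt, file.path(out_dir, "sample_trees.txt"))
    nwk <- vapply(trees, format_sample_tree, character(1), format = "newick")
    writeLines(nwk, file.path(out_dir, "sample_trees.nwk"))
  }
  export_network(res$network, edge_threshold, path = out_dir)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export the weighted network as an edge list and GraphML
#'
#' Edges are gene pairs with TOM weight strictly above `weight_threshold`,
#' optionally restricted to the genes of selected modules.
#'
#' @param fit An `acid_network`.
#' @param weight_threshold TOM cutoff in \[0, 1\]; default 0.10.
#' @param modules Optional character vector of modules to restrict to.
#' @param path Optional directory; writes `network_edges.tsv` and
#'   `network.graphml` there.
#' @return A list with `edges` (tibble: gene1, gene2, weight),
#'   `edge_counts` (tibble: gene_id, module, n_edges) and `graph` (igraph).
#' @export
export_network <- function(fit, weight_threshold = 0.10, modules = NULL,
                           path = NULL) {
  stopifnot(inherits(fit, "acid_network"))
  if (weight_threshold < 0 || weight_threshold > 1) {
    abort("weight_threshold must lie in [0, 1]")
  }
  labels <- fit$labels
  genes <- if (is.null(modules)) names(labels) else
    names(labels)[labels %in% modules]
  tom <- fit$tom[genes, genes, drop = FALSE]
  idx <- which(upper.tri(tom) & tom > weight_threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    weight = tom[idx]
  )
  counts <- tibble::tibble(gene_id = genes, module = unname(labels[genes]))
  counts$n_edges <- vapply(counts$gene_id, function(g) {
    sum(edges$gene1 == g) + sum(edges$gene2 == g)
  }, numeric(1), USE.NAMES = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = genes, module = unname(labels[genes])))
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(edges, file.path(path, "network_edges.tsv"),
                     progress = FALSE)
    igraph::write_graph(g, file.path(path, "network.graphml"),
                        format = "graphml")
  }
  list(edges = edges, edge_counts = counts, graph = g)
}
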