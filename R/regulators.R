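#' Configuration for module-network regulator detection
#'
#' @param n_runs Independent Gibbs sampler runs; default 10.
#' @param min_cluster_size Minimum genes per tight cluster; default 10.
#' @param n_clusters_select Tight clusters retained (largest first),
#'   numbered from 0; default 50.
#' @param top_percent Candidate (gene, cluster) scores within this top
#'   percentage are flagged as regulators; default 1.
#' @param n_candidates Cap on candidate regulators; default 96.
#' @param n_controls Randomly drawn control genes; default 96.
#' @param consensus_threshold Co-clustering frequency (fraction of runs)
#'   required for two genes to join a tight cluster; default 0.5.
#' @param n_mixture Mixture components of each Gibbs run; default 25.
#' @param n_sweeps Gibbs sweeps per run (burn-in included; the final sweep's
#'   assignment is kept); default 150.
#' @param max_depth Sample-tree depth; default 3.
#' @param dirichlet_alpha Symmetric Dirichlet concentration; default 1.
#' @param seed Integer seed; run `i` uses `seed + i`.
#' @return A `regulator_config` list.
#' @export
regulator_config <- function(n_runs = 10, min_cluster_size = 10,
                             n_clusters_select = 50, top_percent = 1,
                             n_candidates = 96, n_controls = 96,
                             consensus_threshold = 0.5, n_mixture = 25,
                             n_sweeps = 150, max_depth = 3,
                             dirichlet_alpha = 1, seed = 1L) {
  stopifnot(n_runs >= 1, top_percent > 0, top_percent <= 100,
            consensus_threshold > 0, consensus_threshold <= 1,
            min_cluster_size >= 1)
  structure(as.list(environment()), class = "regulator_config")
}

#' One Gibbs-sampled gene partition
#'
#' Collapsed Gibbs sampler over a finite Bayesian mixture of Gaussians:
#' genes (standardized across samples) are points in sample space, each
#' mixture component has per-sample means and precisions with a conjugate
#' normal-gamma prior, and cluster sizes follow a symmetric Dirichlet prior.
#' The final sweep's assignment is returned; the draw is deterministic given
#' the seed.
#'
#' @param es An `expr_set` (e.g. restricted to trait-associated genes).
#' @param n_clusters Mixture components; default 25.
#' @param n_sweeps Total sweeps; default 150.
#' @param dirichlet_alpha Dirichlet concentration; default 1.
#' @param seed Integer seed.
#' @return Named integer vector gene -> cluster (1-based, may have gaps).
#' @export
gibbs_cluster_genes <- function(es, n_clusters = 25, n_sweeps = 150,
                                dirichlet_alpha = 1, seed = 1L) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$values
  if (nrow(m) < 2 || ncol(m) < 3) abort("Need >= 2 genes and >= 3 samples")
  xs <- t(scale(t(m)))
  xs[!is.finite(xs)] <- 0       # constant genes regularized to the prior mean
  set.seed(as.integer(seed))
  z <- gibbs_mixture_cpp(xs, as.integer(n_clusters), dirichlet_alpha,
                         0, 0.1, 1, 1, as.integer(n_sweeps))
  setNames(as.integer(z), rownames(m))
}

#' Consensus tight clusters across Gibbs runs
#'
#' Builds the co-clustering frequency matrix over the runs, links gene pairs
#' co-clustered in at least `consensus_threshold` of runs, and takes the
#' connected components of that graph. Components with at least
#' `min_cluster_size` genes are kept, sorted by decreasing size, the largest
#' `n_clusters_select` retained and numbered from 0.
#'
#' @param partitions List of named integer partitions from
#'   [gibbs_cluster_genes()].
#' @param cfg A [regulator_config()].
#' @return A tibble with `cluster_id` (0-based) and `gene_id`; empty (with a
#'   warning) when no component reaches the minimum size.
#' @export
consensus_tight_clusters <- function(partitions, cfg = regulator_config()) {
  stopifnot(length(partitions) >= 1)
  genes <- names(partitions[[1]])
  co <- matrix(0, length(genes), length(genes),
               dimnames = list(genes, genes))
  for (p in partitions) {
    p <- p[genes]
    co <- co + outer(p, p, "==")
  }
  co <- co / length(partitions)
  adj <- co >= cfg$consensus_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- order(sizes, decreasing = TRUE)
  keep <- keep[sizes[keep] >= cfg$min_cluster_size]
  keep <- head(keep, cfg$n_clusters_select)
  if (!length(keep)) {
    warn("No consensus cluster reaches min_cluster_size")
    return(tibble::tibble(cluster_id = integer(0), gene_id = character(0)))
  }
  purrr::map_dfr(seq_along(keep), function(i) {
    tibble::tibble(cluster_id = i - 1L,
                   gene_id = sort(genes[comp$membership == keep[i]]))
  })
}

# Log marginal likelihood of a sample under the normal-gamma model;
# used as the Bayesian two-mean node score.
log_marginal_ng <- function(x, mu0 = 0, kappa0 = 0.1, a0 = 1, b0 = 1) {
  n <- length(x)
  if (!n) return(0)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  kappa_n <- kappa0 + n
  a_n <- a0 + n / 2
  b_n <- b0 + 0.5 * ss + kappa0 * n * (xbar - mu0)^2 / (2 * kappa_n)
  lgamma(a_n) - lgamma(a0) + a0 * log(b0) - a_n * log(b_n) +
    0.5 * (log(kappa0) - log(kappa_n)) - n / 2 * log(2 * pi)
}

#' Recursive binary sample tree of a cluster profile
#'
#' Splits the samples by exact one-dimensional two-means on the cluster's
#' mean expression profile, recursively down to `max_depth` or fewer than 4
#' samples. Each internal node carries a Bayesian two-mean separation score
#' (log marginal likelihood gain of the split). A constant profile yields a
#' single leaf.
#'
#' @param profile Named numeric vector: the cluster's mean expression per
#'   sample.
#' @param max_depth Maximum split depth; default 3.
#' @return A nested list tree; each node has `samples`, and internal nodes
#'   have `left`, `right`, `score`.
#' @export
build_sample_tree <- function(profile, max_depth = 3) {
  stopifnot(!is.null(names(profile)))
  grow <- function(ids, depth) {
    node <- list(samples = ids, leaf = TRUE)
    if (depth >= max_depth || length(ids) < 4 ||
        !isTRUE(sd(profile[ids]) > 0)) {
      return(node)
    }
    high <- best_binary_split(profile[ids])
    l <- ids[!high]; r <- ids[high]
    score <- log_marginal_ng(profile[l]) + log_marginal_ng(profile[r]) -
      log_marginal_ng(profile[ids])
    node$leaf <- FALSE
    node$score <- score
    node$left <- grow(l, depth + 1)
    node$right <- grow(r, depth + 1)
    node
  }
  grow(names(profile), 0)
}

# Flatten internal nodes to (left ids, right ids, n) triples.
tree_internal_nodes <- function(tree) {
  out <- list()
  rec <- function(node) {
    if (isTRUE(node$leaf)) return(invisible())
    out[[length(out) + 1]] <<- list(left = node$left$samples,
                                    right = node$right$samples,
                                    n = length(node$samples),
                                    score = node$score)
    rec(node$left); rec(node$right)
  }
  rec(tree)
  out
}

# Two-sided pooled-variance two-sample t-test p-value; returns 1 when
# untestable. Pooled variance matches the shared-precision assumption of the
# Bayesian two-mean node score (and keeps full df for step-like patterns
# whose variance concentrates on one side).
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(1)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(1)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

#' Probabilistic regulator score against a sample tree
#'
#' For each internal node, the candidate's ability to separate the node's
#' two sample sets is scored as `-log10` of the two-sided two-sample t-test
#' p-value (pooled variance) on the candidate's expression; contributions
#' are weighted by the node's sample fraction and summed. A single-leaf tree scores 0, and a
#' zero-variance candidate contributes 0 at a node.
#'
#' @param x Named numeric candidate expression over the tree's samples.
#' @param tree A [build_sample_tree()] tree.
#' @return Non-negative probabilistic score.
#' @export
score_regulator <- function(x, tree) {
  nodes <- tree_internal_nodes(tree)
  if (!length(nodes)) return(0)
  n_root <- length(tree$samples)
  sum(vapply(nodes, function(nd) {
    p <- pooled_t_p(x[nd$left], x[nd$right])
    if (p <= 0) p <- .Machine$double.xmin
    -log10(p) * nd$n / n_root
  }, numeric(1)))
}

#' Select candidate regulators by annotation term
#'
#' Picks genes carrying any of the given annotation terms (the field's
#' transcription-factor / signal-transducer labels) within a gene universe,
#' capped at `n_candidates` by a seeded draw.
#'
#' @param annotation Annotation tibble.
#' @param universe Character vector of eligible gene IDs.
#' @param term_ids Term IDs marking candidates; default `"GO:TFST"` (the
#'   synthetic generator's label).
#' @param n_candidates Cap; default 96.
#' @param seed Seed for the capping draw.
#' @return Character vector of candidate gene IDs.
#' @export
select_candidates <- function(annotation, universe, term_ids = "GO:TFST",
                              n_candidates = 96, seed = 1L) {
  cand <- sort(unique(annotation$gene_id[annotation$term_id %in% term_ids]))
  cand <- intersect(cand, universe)
  if (length(cand) > n_candidates) {
    set.seed(derive_seed(seed, "candidate_cap"))
    cand <- sort(sample(cand, n_candidates))
  }
  cand
}

# Score every candidate against every cluster tree.
score_candidates <- function(es, candidates, clusters, trees) {
  purrr::map_dfr(unique(clusters$cluster_id), function(cid) {
    tree <- trees[[as.character(cid)]]
    tibble::tibble(
      gene_id = candidates, cluster_id = cid,
      p_score = vapply(candidates, function(g) {
        score_regulator(es$values[g, ], tree)
      }, numeric(1))
    )
  })
}

#' Assign regulators by the top-percent rule
#'
#' Scores every (candidate, tight cluster) pair and flags as regulators the
#' pairs whose probabilistic score reaches the `(100 - top_percent)`
#' percentile of the full candidate score pool. A candidate may regulate
#' several clusters. When all scores tie the percentile is degenerate; no
#' pair is flagged and a warning is raised.
#'
#' @param es An `expr_set` containing all candidates.
#' @param candidates Character vector of candidate gene IDs.
#' @param clusters Tight-cluster tibble from [consensus_tight_clusters()].
#' @param trees Named list of sample trees (names are cluster IDs); built
#'   from the cluster mean profiles when omitted.
#' @param cfg A [regulator_config()].
#' @return A tibble: `gene_id`, `cluster_id`, `p_score`, `is_regulator`,
#'   with the score cutoff in attribute `cutoff`.
#' @export
assign_regulators <- function(es, candidates, clusters, trees = NULL,
                              cfg = regulator_config()) {
  if (!length(candidates)) abort("Empty candidate set")
  missing_c <- setdiff(candidates, rownames(es$values))
  if (length(missing_c)) {
    abort(paste0("Candidate(s) absent from expression: ",
                 paste(head(missing_c, 5), collapse = ", ")))
  }
  trees <- trees %||% cluster_sample_trees(es, clusters, cfg$max_depth)
  scores <- score_candidates(es, candidates, clusters, trees)
  if (max(scores$p_score) - min(scores$p_score) < 1e-12) {
    warn("All candidate scores equal; no regulator flagged")
    scores$is_regulator <- FALSE
    attr(scores, "cutoff") <- NA_real_
    return(scores)
  }
  cutoff <- quantile(scores$p_score, 1 - cfg$top_percent / 100, names = FALSE)
  scores$is_regulator <- scores$p_score >= cutoff
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Sample trees for all tight clusters
#'
#' @param es An `expr_set`.
#' @param clusters Tight-cluster tibble.
#' @param max_depth Tree depth; default 3.
#' @return Named list (by cluster ID) of [build_sample_tree()] trees built
#'   from each cluster's mean expression profile.
#' @export
cluster_sample_trees <- function(es, clusters, max_depth = 3) {
  ids <- unique(clusters$cluster_id)
  trees <- lapply(ids, function(cid) {
    genes <- clusters$gene_id[clusters$cluster_id == cid]
    prof <- colMeans(t(scale(t(es$values[genes, , drop = FALSE]))),
                     na.rm = TRUE)
    prof[!is.finite(prof)] <- 0       # constant genes carry no profile
    names(prof) <- colnames(es$values)
    build_sample_tree(prof, max_depth)
  })
  names(trees) <- as.character(ids)
  trees
}

#' Random-control calibration of candidate scores
#'
#' Draws `n_controls` genes (seeded) from the non-candidate universe, scores
#' them identically against the tight clusters, and compares the candidate
#' and control score sets with a two-sample z test. Each gene enters the
#' comparison with its best-assignment score (the maximum over clusters),
#' the per-gene probabilistic score a regulator is reported with.
#'
#' @param es An `expr_set`.
#' @param candidates Candidate gene IDs (already scored or not).
#' @param clusters Tight-cluster tibble.
#' @param trees Optional pre-built sample trees.
#' @param cfg A [regulator_config()].
#' @param candidate_scores Optional tibble from [assign_regulators()] to
#'   avoid re-scoring candidates.
#' @return A tibble with `z`, `p`, `n_candidates`, `n_controls`, and mean
#'   scores; `z` is `NA` (flagged `computable = FALSE`) when both score sets
#'   are degenerate.
#' @export
calibrate_with_controls <- function(es, candidates, clusters, trees = NULL,
                                    cfg = regulator_config(),
                                    candidate_scores = NULL) {
  universe <- setdiff(rownames(es$values), candidates)
  if (length(universe) < cfg$n_controls) {
    abort("Not enough non-candidate genes for controls")
  }
  trees <- trees %||% cluster_sample_trees(es, clusters, cfg$max_depth)
  if (is.null(candidate_scores)) {
    candidate_scores <- score_candidates(es, candidates, clusters, trees)
  }
  set.seed(derive_seed(cfg$seed, "controls"))
  controls <- sample(universe, cfg$n_controls)
  control_scores <- score_candidates(es, controls, clusters, trees)
  best <- function(sc) {
    vapply(split(sc$p_score, sc$gene_id), max, numeric(1))
  }
  a <- best(candidate_scores)
  b <- best(control_scores)
  va <- var(a); vb <- var(b)
  if (va + vb == 0) {
    return(tibble::tibble(z = NA_real_, p = NA_real_, computable = FALSE,
                          n_candidates = length(candidates),
                          n_controls = length(controls),
                          mean_candidate = mean(a), mean_control = mean(b)))
  }
  z <- (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)), computable = TRUE,
                 n_candidates = length(candidates),
                 n_controls = length(controls),
                 mean_candidate = mean(a), mean_control = mean(b))
}

#' Full regulator-detection stage
#'
#' Runs `n_runs` Gibbs clusterings, forms consensus tight clusters, builds
#' sample trees, scores the candidates, applies the top-percent rule and
#' calibrates against random controls.
#'
#' @param es An `expr_set` of the trait-associated genes.
#' @param candidates Candidate regulator gene IDs.
#' @param cfg A [regulator_config()].
#' @return A list of class `acid_regulators`: `clusters`, `trees`,
#'   `assignments`, `regulators` (flagged subset), `calibration`,
#'   `partitions`.
#' @export
detect_regulators <- function(es, candidates, cfg = regulator_config()) {
  partitions <- lapply(seq_len(cfg$n_runs), function(i) {
    gibbs_cluster_genes(es, cfg$n_mixture, cfg$n_sweeps,
                        cfg$dirichlet_alpha, cfg$seed + i)
  })
  clusters <- consensus_tight_clusters(partitions, cfg)
  if (!nrow(clusters)) {
    abort("Regulator detection found no tight clusters")
  }
  trees <- cluster_sample_trees(es, clusters, cfg$max_depth)
  assignments <- assign_regulators(es, candidates, clusters, trees, cfg)
  calibration <- calibrate_with_controls(es, candidates, clusters, trees,
                                         cfg, candidate_scores = assignments)
  structure(list(clusters = clusters, trees = trees,
                 assignments = assignments,
                 regulators = assignments[assignments$is_regulator, ],
                 calibration = calibration, partitions = partitions,
                 config = cfg),
            class = "acid_regulators")
}

#' @export
print.acid_regulators <- function(x, ...) {
  cat(sprintf(
    "<acid_regulators> %d tight clusters, %d candidate pairs, %d flagged\n",
    length(unique(x$clusters$cluster_id)), nrow(x$assignments),
    nrow(x$regulators)))
  invisible(x)
}

#' Serialize a sample tree
#'
#' @param tree A [build_sample_tree()] tree.
#' @param format `"text"` (indented) or `"newick"`.
#' @return A character scalar.
#' @export
format_sample_tree <- function(tree, format = c("text", "newick")) {
  format <- match.arg(format)
  if (format == "text") {
    rec <- function(node, indent) {
      pad <- strrep("  ", indent)
      if (isTRUE(node$leaf)) {
        paste0(pad, "- ", paste(node$samples, collapse = ","))
      } else {
        paste(c(sprintf("%snode (n=%d, score=%.3f)", pad,
                        length(node$samples), node$score),
                rec(node$left, indent + 1), rec(node$right, indent + 1)),
              collapse = "\n")
      }
    }
    rec(tree, 0)
  } else {
    rec <- function(node) {
      if (isTRUE(node$leaf)) {
        if (length(node$samples) == 1) return(node$samples)
        paste0("(", paste(node$samples, collapse = ","), ")")
      } else {
        paste0("(", rec(node$left), ",", rec(node$right), ")")
      }
    }
    paste0(rec(tree), ";")
  }
}
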