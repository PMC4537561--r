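# Module color sequence used for size-ranked module naming, largest first.
wgcna_color_sequence <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Gene-gene Pearson correlation matrix
#'
#' Zero-variance genes cannot be correlated and are removed with a warning
#' listing their IDs.
#'
#' @param es An `expr_set` (normally square-root transformed).
#' @return A symmetric gene-by-gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$values
  if (ncol(m) < 3) abort("Need >= 3 samples for correlations")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    drop <- rownames(m)[sds == 0]
    warn(paste0("Removing zero-variance gene(s): ",
                paste(head(drop, 10), collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
  }
  cc <- cor(t(m))
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency from correlations
#'
#' Unsigned weighted network: `a_ij = |cor_ij|^beta`, diagonal fixed at 1.
#'
#' @param cor_mat Correlation matrix.
#' @param beta Soft-threshold power; default 6.
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
soft_adjacency <- function(cor_mat, beta = 6) {
  stopifnot(beta >= 1)
  a <- abs(cor_mat)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` counts shared neighbors and
#' `k_i = sum_{u != i} a_iu` is the connectivity. Diagonal is 1.
#'
#' @param adj Adjacency matrix (symmetric, unit diagonal, entries in \[0,1\]).
#' @return The TOM, same shape, entries in \[0, 1\].
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # excludes u = i and u = j since diag 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

assign_module_colors <- function(labels_int) {
  tab <- sort(table(labels_int[labels_int != 0]), decreasing = TRUE)
  ids <- names(tab)
  cols <- c(wgcna_color_sequence,
            paste0("module", seq_len(max(0, length(ids) -
                                           length(wgcna_color_sequence)))))
  map <- setNames(cols[seq_along(ids)], ids)
  out <- rep("grey", length(labels_int))
  nz <- labels_int != 0
  out[nz] <- map[as.character(labels_int[nz])]
  names(out) <- names(labels_int)
  out
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM` with a recursive
#' branch cut: the tree is cut at `cut_quantile` of its maximum merge
#' height, and every branch of at least `min_module_size` genes is
#' re-clustered and cut the same way until it stops splitting into two or
#' more valid branches. Genes falling off at a split are left unassigned
#' ("grey"). When the expression data are supplied, two refinements follow:
#' branches whose eigengene explains less than `min_var_explained` of the
#' branch variance (incoherent, noise-dominated blobs) are dissolved to
#' grey, and genes are then re-assigned by eigengene correlation — a member
#' with `|kME|` below `kme_threshold` for every module goes grey, and an
#' unassigned gene with `|kME|` at or above the threshold joins its
#' best-matching module. Modules are named by the standard color sequence,
#' largest first.
#'
#' @param dissim Dissimilarity matrix, normally `1 - TOM`.
#' @param min_module_size Smallest branch kept as a module; default 30.
#' @param cut_quantile Branch cut height as a fraction of the branch's
#'   maximum merge height; default 0.97.
#' @param es Optional `expr_set` on the analysis (square-root) scale; when
#'   given, enables the eigengene coherence filter and kME refinement.
#' @param min_var_explained Minimum fraction of branch variance the first
#'   principal component must explain; default 0.3.
#' @param kme_threshold Absolute eigengene correlation for module
#'   membership during refinement; default 0.6.
#' @param refine_iter kME refinement passes; default 2.
#' @return A list with `dendro` (the top-level `hclust`) and `labels`
#'   (named character vector of module colors, `"grey"` = unassigned).
#' @export
detect_modules <- function(dissim, min_module_size = 30, cut_quantile = 0.97,
                           es = NULL, min_var_explained = 0.3,
                           kme_threshold = 0.6, refine_iter = 2) {
  stopifnot(min_module_size >= 2, cut_quantile > 0, cut_quantile <= 1)
  n <- nrow(dissim)
  genes <- rownames(dissim) %||% as.character(seq_len(n))
  dend <- hclust(as.dist(dissim), method = "average")
  if (n < min_module_size) {
    warn("Fewer genes than min_module_size; all genes unassigned")
    labels <- setNames(rep("grey", n), genes)
    return(list(dendro = dend, labels = labels))
  }

  # Recursively split a branch (by position index) into valid sub-branches.
  split_branch <- function(idx) {
    if (length(idx) < 2 * min_module_size) return(list(idx))
    d_sub <- dissim[idx, idx]
    h <- hclust(as.dist(d_sub), method = "average")
    if (max(h$height) <= 0) return(list(idx))
    comp <- cutree(h, h = cut_quantile * max(h$height))
    sizes <- table(comp)
    valid <- as.integer(names(sizes)[sizes >= min_module_size])
    if (!length(valid)) return(list(idx))
    if (length(valid) == 1 && sizes[as.character(valid)] == length(idx)) {
      return(list(idx))
    }
    unlist(lapply(valid, function(v) split_branch(idx[comp == v])),
           recursive = FALSE)
  }
  clusters <- split_branch(seq_len(n))
  clusters <- clusters[lengths(clusters) >= min_module_size]

  lab_int <- rep(0L, n)
  for (i in seq_along(clusters)) lab_int[clusters[[i]]] <- i

  if (!is.null(es) && any(lab_int > 0)) {
    # Dissolve incoherent branches: a real module's first PC dominates.
    for (i in seq_along(clusters)) {
      ve <- module_eigengene(es, genes[lab_int == i])$var_explained
      if (ve < min_var_explained) lab_int[lab_int == i] <- 0L
    }
    # kME refinement: membership must be backed by eigengene correlation.
    for (it in seq_len(refine_iter)) {
      mods <- setdiff(unique(lab_int), 0L)
      if (!length(mods)) break
      mes <- sapply(mods, function(i) {
        module_eigengene(es, genes[lab_int == i])$me
      })
      kme <- abs(cor(t(es$values[genes, , drop = FALSE]), mes))
      best <- max.col(kme, ties.method = "first")
      new_lab <- ifelse(kme[cbind(seq_len(n), best)] >= kme_threshold,
                        mods[best], 0L)
      if (all(new_lab == lab_int)) break
      lab_int <- new_lab
      for (i in mods) {                       # a module can shrink away
        if (sum(lab_int == i) < min_module_size) lab_int[lab_int == i] <- 0L
      }
    }
  }

  labels <- assign_module_colors(lab_int)
  names(labels) <- genes
  list(dendro = dend, labels = labels)
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardized expression,
#' sign-aligned so that it correlates non-negatively with the module's mean
#' standardized profile, and scaled to unit variance.
#'
#' @param es An `expr_set` (transformed scale).
#' @param genes Character vector of module member gene IDs.
#' @return A list with `me` (named sample vector, unit variance) and
#'   `var_explained` (fraction of module variance captured).
#' @export
module_eigengene <- function(es, genes) {
  stopifnot(inherits(es, "expr_set"), length(genes) >= 1)
  x <- es$values[genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0       # constant genes contribute nothing
  sv <- svd(xs)
  me <- sv$v[, 1]
  avg <- colMeans(xs)
  if (sd(avg) > 0 && sd(me) > 0 && cor(me, avg) < 0) me <- -me
  if (sd(me) > 0) me <- me / sd(me)
  names(me) <- colnames(es$values)
  var_explained <- if (sum(sv$d^2) > 0) sv$d[1]^2 / sum(sv$d^2) else 0
  list(me = me, var_explained = var_explained)
}

# Eigengenes of every module label (including grey) as samples x modules.
module_eigengenes <- function(es, labels) {
  mods <- unique(labels)
  mes <- sapply(mods, function(mod) {
    module_eigengene(es, names(labels)[labels == mod])$me
  })
  colnames(mes) <- mods
  rownames(mes) <- colnames(es$values)
  mes
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(ME_p, ME_q)` is below `cut_height`, recomputing
#' eigengenes after each merge, until no pair qualifies. The merged module
#' keeps the larger member's name; colors are then re-ranked by size.
#'
#' @param es An `expr_set` (transformed scale).
#' @param labels Named character vector of module colors from
#'   [detect_modules()].
#' @param cut_height Eigengene dissimilarity below which modules merge;
#'   default 0.25.
#' @return A list with `labels` (merged, re-ranked colors) and `eigengenes`
#'   (samples x modules matrix including `"grey"` when present).
#' @export
merge_close_modules <- function(es, labels, cut_height = 0.25) {
  stopifnot(cut_height > 0, cut_height < 1)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    mes <- module_eigengenes(es, labels)[, mods, drop = FALSE]
    d <- 1 - cor(mes)
    diag(d) <- Inf
    if (min(d) >= cut_height) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    p <- mods[idx[1]]; q <- mods[idx[2]]
    big <- if (sum(labels == p) >= sum(labels == q)) p else q
    labels[labels %in% c(p, q)] <- big
  }
  # re-rank color names by final size
  mods <- setdiff(unique(labels), "grey")
  lab_int <- rep(0L, length(labels))
  for (i in seq_along(mods)) lab_int[labels == mods[i]] <- i
  names(lab_int) <- names(labels)
  labels <- assign_module_colors(lab_int)
  list(labels = labels, eigengenes = module_eigengenes(es, labels))
}

# Two-sided p-value of a Pearson correlation via the t transform, n-2 df.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- suppressWarnings(r * sqrt(df / (1 - r^2)))
  p <- 2 * pt(-abs(t), df)
  p[abs(r) >= 1] <- 0
  p
}

#' Per-gene network statistics
#'
#' Gene significance (GS: correlation of expression with the trait), module
#' membership (MM/kME: correlation with the gene's own module eigengene, the
#' grey pseudo-module treated the same way) and total connectivity (kTotal:
#' sum of adjacency to all other genes).
#'
#' @param es An `expr_set` (transformed scale).
#' @param adjacency Adjacency matrix over the same genes.
#' @param labels Named module colors.
#' @param eigengenes Samples x modules eigengene matrix.
#' @param trait Named numeric trait vector over the samples (names are
#'   sample IDs), or a traits tibble with `sample_id` plus one column named
#'   by `trait_name`.
#' @param trait_name Trait column used when `trait` is a data frame;
#'   default `"malate"`.
#' @return A tibble: `gene_id`, `module`, `gs`, `abs_gs`, `mm`, `abs_mm`,
#'   `ktotal`.
#' @export
gene_statistics <- function(es, adjacency, labels, eigengenes, trait,
                            trait_name = "malate") {
  if (is.data.frame(trait)) {
    trait <- setNames(trait[[trait_name]], trait$sample_id)
  }
  trait <- trait[colnames(es$values)]
  if (anyNA(trait)) abort("Trait not defined on all samples")
  if (sd(trait) == 0) abort("Trait is constant; GS undefined")
  genes <- names(labels)
  x <- es$values[genes, , drop = FALSE]
  gs <- apply(x, 1, function(v) if (sd(v) > 0) cor(v, trait) else NA_real_)
  mm <- vapply(genes, function(g) {
    me <- eigengenes[, labels[g]]
    v <- x[g, ]
    if (sd(v) > 0 && sd(me) > 0) cor(v, me) else NA_real_
  }, numeric(1))
  a <- adjacency[genes, genes]
  ktotal <- rowSums(a) - diag(a)
  tibble::tibble(
    gene_id = genes, module = unname(labels),
    gs = unname(gs), abs_gs = abs(unname(gs)),
    mm = unname(mm), abs_mm = abs(unname(mm)),
    ktotal = unname(ktotal)
  )
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each trait, with
#' two-sided p-values from the t transform (n - 2 degrees of freedom).
#'
#' @param eigengenes Samples x modules matrix.
#' @param traits Tibble with `sample_id` and trait columns.
#' @param sig_p Significance cutoff on p; default 0.001.
#' @return A tibble: `module`, `trait`, `r`, `p`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits, sig_p = 0.001) {
  traits <- tibble::as_tibble(traits)
  tvars <- setdiff(names(traits), "sample_id")
  tm <- as.matrix(traits[match(rownames(eigengenes), traits$sample_id),
                         tvars, drop = FALSE])
  n <- nrow(eigengenes)
  if (n < 3) abort("Need >= 3 samples")
  out <- tidyr::expand_grid(module = colnames(eigengenes), trait = tvars)
  out$r <- purrr::map2_dbl(out$module, out$trait,
                           function(m, t) cor(eigengenes[, m], tm[, t]))
  out$p <- cor_pvalue(out$r, n)
  out$significant <- out$p < sig_p
  out
}

#' Fit the full co-expression network model
#'
#' Runs the network pipeline on an expression set (square-root transform,
#' Pearson correlation, unsigned soft-threshold adjacency, TOM, average
#' linkage module detection, eigengene merge) and, when traits are supplied,
#' computes module-trait correlations and per-gene GS/MM/kTotal.
#'
#' @param es An `expr_set` (typically restricted to trait-associated genes).
#' @param traits Optional traits tibble (`sample_id` + trait columns).
#' @param trait_name Trait used for gene significance; default `"malate"`.
#' @param beta Soft-threshold power; default 6.
#' @param min_module_size Default 30.
#' @param merge_cut_height Default 0.25.
#' @param cut_quantile Dendrogram branch cut fraction; default 0.97.
#' @param transform `"sqrt"` (default) or `"none"` if `es` is already on the
#'   analysis scale.
#' @param sig_p Module-trait significance cutoff; default 0.001.
#' @return An object of class `acid_network` with components `params`,
#'   `es` (transformed), `cor`, `adjacency`, `tom`, `dendro`, `labels`,
#'   `eigengenes`, `module_trait` and `gene_stats` (the last two NULL
#'   without traits).
#' @export
build_network <- function(es, traits = NULL, trait_name = "malate",
                          beta = 6, min_module_size = 30,
                          merge_cut_height = 0.25, cut_quantile = 0.97,
                          transform = c("sqrt", "none"), sig_p = 0.001) {
  transform <- match.arg(transform)
  if (transform == "sqrt") es <- sqrt_transform(es)
  cc <- correlation_matrix(es)
  es <- subset_expression(es, gene_ids = rownames(cc))
  adj <- soft_adjacency(cc, beta)
  tom <- topological_overlap(adj)
  det <- detect_modules(1 - tom, min_module_size, cut_quantile, es = es)
  merged <- merge_close_modules(es, det$labels, merge_cut_height)
  fit <- structure(list(
    params = list(beta = beta, min_module_size = min_module_size,
                  merge_cut_height = merge_cut_height,
                  cut_quantile = cut_quantile, trait_name = trait_name,
                  sig_p = sig_p),
    es = es, cor = cc, adjacency = adj, tom = tom,
    dendro = det$dendro, labels = merged$labels,
    eigengenes = merged$eigengenes,
    module_trait = NULL, gene_stats = NULL
  ), class = "acid_network")
  if (!is.null(traits)) {
    traits <- validate_traits(traits, es)
    fit$module_trait <- module_trait_correlation(merged$eigengenes, traits,
                                                 sig_p)
    fit$gene_stats <- gene_statistics(es, adj, merged$labels,
                                      merged$eigengenes, traits, trait_name)
  }
  fit
}

#' @export
print.acid_network <- function(x, ...) {
  mods <- setdiff(unique(x$labels), "grey")
  cat(sprintf("<acid_network> %d genes, %d modules (+%d grey), beta = %g\n",
              length(x$labels), length(mods), sum(x$labels == "grey"),
              x$params$beta))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param x,y Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  expected <- b * cc / choose(n, 2)
  maximum <- (b + cc) / 2
  if (maximum == expected) return(1)
  (a - expected) / (maximum - expected)
}
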