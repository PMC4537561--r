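#' Configuration for the synthetic two-genotype expression study
#'
#' Defines a seeded simulated dataset that emulates a 29-sample, two-group
#' mature-fruit RNA-seq design: co-expression modules planted as latent
#' sample factors, a malate-like trait driven by a subset of module factors,
#' a guide gene with a configured between-group mean difference and fold
#' change, and one planted regulator gene per trait module whose expression
#' tracks the binary sample split of its module's factor.
#'
#' Expression is generated on the log scale and exponentiated, giving
#' lognormal-like RPKM marginals that stay non-negative without truncation.
#' Within a module all member genes share the sample factor with unit
#' loading, so at `noise_sd = 0` members are exact positive scalar multiples
#' of each other (pairwise correlation 1). The first `n_high_fidelity` genes
#' of each module receive half the noise, making them the module's most
#' factor-faithful (hub-like) members.
#'
#' @param n_samples_a,n_samples_b Samples per genotype group; defaults 17 and
#'   12 mirror the usable study design.
#' @param module_sizes Integer vector of planted module sizes.
#' @param n_background Number of unstructured background genes.
#' @param trait_coef Named numeric vector: names are module indices, values
#'   the coefficients linking the module factor to the trait.
#' @param group_shift Between-group difference (in factor SD units) applied
#'   to each trait module's factor, signed so the trait is higher in group A.
#' @param guide_spec List with `module` (index of the guide's module),
#'   `mean_diff` (expected between-group RPKM mean difference) and
#'   `fold_change` (expected between-group fold change, > 1).
#' @param regulator_spec List with `separation` (log-scale expression shift
#'   across the tracked sample split) and `noise_sd`.
#' @param noise_sd Gene-level log-scale noise standard deviation.
#' @param baseline_rpkm Median RPKM of background genes; must be positive.
#' @param trait_noise_sd Noise SD of the latent trait before calibration.
#' @param n_high_fidelity Low-noise (hub-like) genes per module.
#' @param target_group_means Length-2 vector the malate group means are
#'   calibrated to (mg/g FW); defaults to the published 7.58 and 2.16.
#' @param n_candidate_pool Background genes (beyond the planted regulatory
#'   genes) labelled with the transcription-factor/signal-transducer
#'   annotation term.
#' @param n_tf_per_module Weaker regulator-like TF genes planted per trait
#'   module (graded separation, part of the candidate pool but not ground
#'   truth regulators).
#' @param tf_sep_range Range the weak TF separations are drawn from
#'   (log-scale units).
#' @param tf_noise_sd Noise SD of the weak TF genes.
#' @param seed Integer seed; the same configuration gives a bit-identical
#'   dataset.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples_a = 17,
                       n_samples_b = 12,
                       module_sizes = rep(60L, 5),
                       n_background = 300,
                       trait_coef = c("1" = 1, "2" = 0.6, "3" = -0.4),
                       group_shift = 1.5,
                       guide_spec = list(module = 1, mean_diff = 20,
                                         fold_change = 2),
                       regulator_spec = list(separation = 2, noise_sd = 0.2),
                       noise_sd = 0.5,
                       baseline_rpkm = 10,
                       trait_noise_sd = 0.4,
                       n_high_fidelity = 3,
                       target_group_means = c(7.58, 2.16),
                       n_candidate_pool = 40,
                       n_tf_per_module = 0,
                       tf_sep_range = c(0.8, 1.6),
                       tf_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_samples_a = as.integer(n_samples_a),
    n_samples_b = as.integer(n_samples_b),
    module_sizes = as.integer(module_sizes),
    n_background = as.integer(n_background),
    trait_coef = trait_coef, group_shift = group_shift,
    guide_spec = guide_spec, regulator_spec = regulator_spec,
    noise_sd = noise_sd, baseline_rpkm = baseline_rpkm,
    trait_noise_sd = trait_noise_sd,
    n_high_fidelity = as.integer(n_high_fidelity),
    target_group_means = target_group_means,
    n_candidate_pool = as.integer(n_candidate_pool),
    n_tf_per_module = as.integer(n_tf_per_module),
    tf_sep_range = tf_sep_range, tf_noise_sd = tf_noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_samples_a < 1 || cfg$n_samples_b < 1) {
    abort("Sample counts must be >= 1")
  }
  if (!length(cfg$module_sizes)) abort("module_sizes must be non-empty")
  if (any(cfg$module_sizes < 1) || cfg$n_background < 0) {
    abort("Module sizes must be positive and n_background non-negative")
  }
  if (is.null(names(cfg$trait_coef)) || !length(cfg$trait_coef)) {
    abort("trait_coef must be a named vector of module-index coefficients")
  }
  midx <- as.integer(names(cfg$trait_coef))
  if (any(is.na(midx)) || any(midx < 1) || any(midx > length(cfg$module_sizes))) {
    abort("trait_coef names must be valid module indices")
  }
  if (cfg$guide_spec$fold_change <= 1) abort("Guide fold_change must be > 1")
  if (cfg$guide_spec$module < 1 ||
      cfg$guide_spec$module > length(cfg$module_sizes)) {
    abort("guide_spec$module out of range")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$baseline_rpkm <= 0) abort("baseline_rpkm must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# Optimal 1-d two-means split: threshold position minimizing within-group SS.
# Returns a logical vector, TRUE for the high set.
best_binary_split <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(x)
  cs <- cumsum(xs); tot <- cs[n]
  css <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wss <- (css[k] - cs[k]^2 / k) +
    ((css[n] - css[k]) - (tot - cs[k])^2 / (n - k))
  kbest <- which.min(wss)
  high <- rep(FALSE, n)
  high[o[(kbest + 1):n]] <- TRUE
  high
}

#' Simulate a seeded expression/trait/annotation dataset with ground truth
#'
#' @param config A [sim_config()] object.
#' @return A list of class `acid_sim` with elements `expr` (an
#'   [expression_set()]), `traits` (tibble: sample_id, malate, ta, ph),
#'   `annotation` (tibble: gene_id, namespace, term_id, term_name) and
#'   `truth` (planted module labels, guide ID, regulator IDs, trait
#'   coefficients and planted enriched terms).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  n_mod <- length(cfg$module_sizes)
  n <- cfg$n_samples_a + cfg$n_samples_b
  grp <- c(rep("Ma_", cfg$n_samples_a), rep("mama", cfg$n_samples_b))
  sample_id <- c(sprintf("A%02d", seq_len(cfg$n_samples_a)),
                 sprintf("B%02d", seq_len(cfg$n_samples_b)))
  trait_idx <- as.integer(names(cfg$trait_coef))

  # --- latent module factors ------------------------------------------------
  set.seed(derive_seed(cfg$seed, "factors"))
  shift <- numeric(n_mod)
  shift[trait_idx] <- sign(cfg$trait_coef) * cfg$group_shift
  factors <- sapply(seq_len(n_mod), function(m) {
    mu <- ifelse(grp == "Ma_", shift[m] / 2, -shift[m] / 2)
    mu + rnorm(n)
  })
  colnames(factors) <- paste0("module", seq_len(n_mod))

  # --- module member genes (log scale, exponentiated) -----------------------
  set.seed(derive_seed(cfg$seed, "genes"))
  gene_blocks <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    sz <- cfg$module_sizes[m]
    intercepts <- rnorm(sz, 0, 0.5)
    fid <- rep(1, sz)
    fid[seq_len(min(cfg$n_high_fidelity, sz))] <- 0.5
    eps <- matrix(rnorm(sz * n), sz, n)
    logx <- log(cfg$baseline_rpkm) + intercepts +
      matrix(factors[, m], sz, n, byrow = TRUE) +
      eps * cfg$noise_sd * fid
    blk <- exp(logx)
    rownames(blk) <- sprintf("M%d_G%03d", m, seq_len(sz))
    gene_blocks[[m]] <- blk
  }
  bg <- NULL
  if (cfg$n_background > 0) {
    intercepts <- rnorm(cfg$n_background, 0, 0.5)
    eps <- matrix(rnorm(cfg$n_background * n), cfg$n_background, n)
    bg <- exp(log(cfg$baseline_rpkm) + intercepts +
                eps * max(cfg$noise_sd, 0.3))
    rownames(bg) <- sprintf("BG_%04d", seq_len(cfg$n_background))
  }

  # RPKM columns of a real study carry comparable total signal (library-size
  # normalized). The planted genes are a small slice of the transcriptome,
  # so totals are equalized against the large stable mass of the unobserved
  # remainder: with slice fraction q, a column's effective total is
  # tot_j*q + (1-q)*mean(tot), damping compositional shifts without
  # injecting a shared normalization component into every gene.
  q <- 0.1
  base_values <- do.call(rbind, c(gene_blocks, list(bg)))
  tot <- colSums(base_values)
  eff <- q * tot + (1 - q) * mean(tot)
  base_values <- sweep(base_values, 2, mean(eff) / eff, "*")
  for (m in seq_len(n_mod)) {
    gene_blocks[[m]] <- base_values[rownames(gene_blocks[[m]]), , drop = FALSE]
  }
  if (!is.null(bg)) bg <- base_values[rownames(bg), , drop = FALSE]

  # --- guide gene: exact expected group means, residual tracks its module ---
  set.seed(derive_seed(cfg$seed, "guide"))
  gm <- cfg$guide_spec$module
  d <- cfg$guide_spec$mean_diff; fc <- cfg$guide_spec$fold_change
  mean_b <- d / (fc - 1); mean_a <- mean_b * fc
  resid <- factors[, gm] - ifelse(grp == "Ma_", shift[gm] / 2, -shift[gm] / 2)
  s <- 0.3
  guide <- ifelse(grp == "Ma_", mean_a, mean_b) * exp(s * resid - s^2 / 2)
  guide_id <- "GUIDE_1"
  guide <- matrix(guide, 1, n, dimnames = list(guide_id, NULL))

  # --- planted regulators and regulator-like TF pool ------------------------
  # Each regulator steps across the binary sample split that best separates
  # its module, taken from the realized mean member profile on the square
  # root (analysis) scale — the split a clustering of the generated data
  # recovers. Besides one strong regulator per trait module, a pool of
  # weaker TF-like genes tracks the same splits with graded separation,
  # emulating that annotated transcription factors are enriched for
  # regulatory expression patterns of varying strength.
  set.seed(derive_seed(cfg$seed, "regulators"))
  regs <- NULL
  reg_ids <- character(0)
  tf_extra <- NULL
  tf_ids <- character(0)
  if (length(trait_idx)) {
    profiles <- lapply(trait_idx, function(m) {
      colMeans(t(scale(t(sqrt(gene_blocks[[m]])))))
    })
    splits <- lapply(profiles, best_binary_split)
    # Sigmoidal activation: saturated on both sides of the split, graded at
    # the transition, so samples near the boundary take intermediate values.
    activations <- lapply(seq_along(trait_idx), function(i) {
      prof <- profiles[[i]]; high <- splits[[i]]
      mid <- (mean(prof[high]) + mean(prof[!high])) / 2
      width <- 0.15 * (mean(prof[high]) - mean(prof[!high]))
      stats::plogis((prof - mid) / width)
    })
    regs <- t(sapply(seq_along(trait_idx), function(i) {
      exp(log(cfg$baseline_rpkm) +
            cfg$regulator_spec$separation * activations[[i]] +
            rnorm(n, 0, cfg$regulator_spec$noise_sd))
    }))
    reg_ids <- sprintf("REG_M%d", trait_idx)
    rownames(regs) <- reg_ids
    if (cfg$n_tf_per_module > 0) {
      tf_rows <- list()
      for (i in seq_along(trait_idx)) {
        sep <- runif(cfg$n_tf_per_module, cfg$tf_sep_range[1],
                     cfg$tf_sep_range[2])
        for (j in seq_len(cfg$n_tf_per_module)) {
          tf_rows[[length(tf_rows) + 1]] <-
            exp(log(cfg$baseline_rpkm) + sep[j] * activations[[i]] +
                  rnorm(n, 0, cfg$tf_noise_sd))
          tf_ids <- c(tf_ids, sprintf("TF_M%d_%02d", trait_idx[i], j))
        }
      }
      tf_extra <- do.call(rbind, tf_rows)
      rownames(tf_extra) <- tf_ids
    }
  }

  values <- do.call(rbind, c(gene_blocks, list(guide), list(regs),
                             list(tf_extra), list(bg)))
  colnames(values) <- sample_id

  # --- trait model: linear in factors, calibrated to target group means -----
  set.seed(derive_seed(cfg$seed, "trait"))
  raw <- as.numeric(factors[, trait_idx, drop = FALSE] %*% cfg$trait_coef) +
    rnorm(n, 0, cfg$trait_noise_sd)
  e_a <- sum(cfg$trait_coef * shift[trait_idx] / 2)
  e_b <- -e_a
  tg <- cfg$target_group_means
  if (abs(e_a - e_b) > 1e-12) {
    beta <- (tg[1] - tg[2]) / (e_a - e_b)
    alpha <- tg[1] - beta * e_a
  } else {
    beta <- 1; alpha <- mean(tg)
  }
  malate <- pmax(alpha + beta * raw, 0.05)
  ta <- pmax(0.8 * malate + rnorm(n, 0, 0.3), 0.05)
  ph <- pmin(pmax(4.2 - 0.12 * malate + rnorm(n, 0, 0.05), 2.5), 5)
  traits <- tibble::tibble(sample_id = sample_id, malate = malate,
                           ta = ta, ph = ph)

  # --- annotation: one planted term per module + background bins + TF pool --
  set.seed(derive_seed(cfg$seed, "annotation"))
  all_ids <- rownames(values)
  ann <- list()
  planted_terms <- tibble::tibble(module = integer(0), term_id = character(0))
  for (m in seq_len(n_mod)) {
    members <- rownames(gene_blocks[[m]])
    if (m == gm) members <- c(members, guide_id)
    take <- sample(members, ceiling(0.9 * length(members)))
    tid <- sprintf("GO:BP%04d", m)
    ann[[length(ann) + 1]] <- tibble::tibble(
      gene_id = take, namespace = "GO-BP", term_id = tid,
      term_name = sprintf("planted process %d", m))
    planted_terms <- dplyr::bind_rows(
      planted_terms, tibble::tibble(module = m, term_id = tid))
  }
  for (k in 1:5) {
    take <- sample(all_ids, max(3, round(0.08 * length(all_ids))))
    ann[[length(ann) + 1]] <- tibble::tibble(
      gene_id = take, namespace = "MapMan",
      term_id = sprintf("BIN.%d", k),
      term_name = sprintf("background bin %d", k))
  }
  # TF/signal-transducer labels: the planted regulators plus background
  # genes only — annotated regulatory genes are otherwise unrelated to the
  # planted co-expression structure.
  pool_universe <- if (is.null(bg)) setdiff(all_ids, c(reg_ids, tf_ids)) else
    rownames(bg)
  pool <- sample(pool_universe,
                 min(cfg$n_candidate_pool, length(pool_universe)))
  ann[[length(ann) + 1]] <- tibble::tibble(
    gene_id = c(reg_ids, tf_ids, pool), namespace = "GO-MF",
    term_id = "GO:TFST",
    term_name = "transcription factor or signal transducer")
  annotation <- dplyr::bind_rows(ann)

  module_lab <- c(
    rep(seq_len(n_mod), cfg$module_sizes),
    gm,                                    # guide belongs to its module
    rep(0L, length(reg_ids)),              # regulatory genes are extra
    rep(0L, length(tf_ids)),
    rep(0L, if (is.null(bg)) 0 else nrow(bg))
  )
  truth <- list(
    modules = tibble::tibble(gene_id = all_ids, module = module_lab),
    guide_id = guide_id,
    regulators = tibble::tibble(gene_id = reg_ids, module = trait_idx),
    tf_pool = tf_ids,
    trait_coef = cfg$trait_coef,
    planted_terms = planted_terms,
    config = cfg
  )

  expr <- expression_set(
    tibble::as_tibble(cbind(data.frame(gene_id = all_ids), values)),
    tibble::tibble(sample_id = sample_id, group = grp,
                   replicate = as.character(ave(seq_len(n), grp,
                                                FUN = seq_along)))
  )
  structure(list(expr = expr, traits = traits, annotation = annotation,
                 truth = truth),
            class = "acid_sim")
}

#' @export
print.acid_sim <- function(x, ...) {
  cat(sprintf("<acid_sim> %d genes x %d samples, %d planted modules, guide %s\n",
              nrow(x$expr$values), ncol(x$expr$values),
              length(x$truth$config$module_sizes), x$truth$guide_id))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the tab-separated expression, sample-metadata, trait and annotation
#' tables consumed by the pipeline, plus a JSON ground-truth file.
#'
#' @param sim An `acid_sim` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "acid_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    traits = file.path(dir, "traits.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.json")
  )
  expr_tbl <- tibble::as_tibble(cbind(
    data.frame(gene_id = rownames(sim$expr$values)), sim$expr$values))
  readr::write_tsv(expr_tbl, paths["expression"], progress = FALSE)
  readr::write_tsv(sim$expr$samples, paths["samples"], progress = FALSE)
  readr::write_tsv(sim$traits, paths["traits"], progress = FALSE)
  readr::write_tsv(sim$annotation, paths["annotation"], progress = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
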