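#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted co-expression network
#'
#' @param x An `acid_network`.
#' @param ... Unused.
#' @return The per-gene statistics tibble (gene, module, GS, MM, kTotal);
#'   just gene and module when the network was fitted without traits.
#' @export
tidy.acid_network <- function(x, ...) {
  if (!is.null(x$gene_stats)) return(x$gene_stats)
  tibble::tibble(gene_id = names(x$labels), module = unname(x$labels))
}

#' One-row summary of a fitted network
#'
#' @param x An `acid_network`.
#' @param ... Unused.
#' @return A one-row tibble: gene and module counts, the strongest
#'   module-trait correlation and its module, and the kTotal-|GS| r-squared.
#' @export
glance.acid_network <- function(x, ...) {
  mods <- setdiff(unique(x$labels), "grey")
  out <- tibble::tibble(
    n_genes = length(x$labels),
    n_modules = length(mods),
    n_grey = sum(x$labels == "grey"),
    beta = x$params$beta
  )
  if (!is.null(x$module_trait)) {
    mt <- x$module_trait
    mt <- mt[mt$trait == x$params$trait_name & mt$module != "grey", ]
    best <- mt[which.max(abs(mt$r)), ]
    out$top_module <- best$module
    out$top_module_r <- best$r
    out$n_sig_modules <- sum(mt$significant)
  }
  if (!is.null(x$gene_stats)) {
    out$ktotal_gs_r2 <- ktotal_gs_relation(x$gene_stats)$r_squared
  }
  out
}

#' Tidy regulator assignments
#'
#' @param x An `acid_regulators`.
#' @param ... Unused.
#' @return The (candidate, cluster, score, flag) tibble.
#' @export
tidy.acid_regulators <- function(x, ...) x$assignments

#' One-row summary of regulator detection
#'
#' @param x An `acid_regulators`.
#' @param ... Unused.
#' @return A one-row tibble with cluster/candidate/regulator counts and the
#'   control-calibration z and p.
#' @export
glance.acid_regulators <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(unique(x$clusters$cluster_id)),
    n_clustered_genes = nrow(x$clusters),
    n_assignments = nrow(x$assignments),
    n_regulator_pairs = nrow(x$regulators),
    n_regulator_genes = length(unique(x$regulators$gene_id)),
    score_cutoff = attr(x$assignments, "cutoff") %||% NA_real_,
    control_z = x$calibration$z,
    control_p = x$calibration$p
  )
}

#' Plot methods for fitted networks
#'
#' `type = "module_trait"` draws the module-trait correlation heatmap with
#' correlation values and p-values; `type = "ktotal_gs"` draws the
#' whole-network kTotal vs |GS| scatter; `type = "dendrogram"` plots the
#' gene dendrogram colored by module.
#'
#' @param object An `acid_network`.
#' @param type Plot type.
#' @param ... Unused.
#' @return A ggplot (or, for the dendrogram, a base plot drawn as a side
#'   effect).
#' @export
autoplot.acid_network <- function(object,
                                  type = c("module_trait", "ktotal_gs"),
                                  ...) {
  type <- match.arg(type)
  if (type == "module_trait") {
    mt <- object$module_trait
    if (is.null(mt)) abort("Network was fitted without traits")
    ggplot2::ggplot(mt, ggplot2::aes(.data$trait, .data$module,
                                     fill = .data$r)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.2f\n(%.1e)", .data$r, .data$p)), size = 3) +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red", limits = c(-1, 1)) +
      ggplot2::labs(x = NULL, y = NULL, fill = "r",
                    title = "Module-trait correlations")
  } else {
    st <- object$gene_stats
    if (is.null(st)) abort("Network was fitted without traits")
    rel <- ktotal_gs_relation(st)
    ggplot2::ggplot(st, ggplot2::aes(.data$ktotal, .data$abs_gs)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(
        x = "kTotal", y = "|GS|",
        title = sprintf("kTotal vs |GS| (r² = %.3f, p = %.2e)",
                        rel$r_squared, rel$p))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Gene dendrogram with module colors
#'
#' @param fit An `acid_network`.
#' @return Invisibly the fit; draws a base-graphics dendrogram with a module
#'   color bar.
#' @export
plot_module_dendrogram <- function(fit) {
  stopifnot(inherits(fit, "acid_network"))
  op <- graphics::par(mfrow = c(2, 1), mar = c(0, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(fit$dendro, labels = FALSE, hang = -1, main = "Gene dendrogram",
       xlab = "", sub = "")
  ord <- fit$dendro$order
  cols <- unname(fit$labels[fit$dendro$labels[ord]])
  cols[!cols %in% grDevices::colors()] <- "grey"
  pal <- unique(cols)
  graphics::par(mar = c(2, 4, 0, 1))
  graphics::image(matrix(match(cols, pal), ncol = 1), col = pal,
                  axes = FALSE)
  invisible(fit)
}
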