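# Small in-code fixtures shared across the suite.

# A minimal valid expression set: g genes x (na + nb) samples of lognormal
# RPKM with equal column totals unless jitter is requested.
toy_expr_set <- function(g = 10, na = 4, nb = 3, seed = 1, values = NULL) {
  set.seed(seed)
  n <- na + nb
  if (is.null(values)) {
    values <- matrix(exp(rnorm(g * n, log(10), 0.5)), g, n)
  }
  expr <- tibble::as_tibble(cbind(
    data.frame(gene_id = sprintf("g%03d", seq_len(g))), values))
  names(expr)[-1] <- sprintf("s%02d", seq_len(n))
  meta <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                         group = c(rep("A", na), rep("B", nb)),
                         replicate = as.character(seq_len(n)))
  expression_set(expr, meta)
}

# Expression set built from an explicit gene x sample matrix.
es_from_matrix <- function(m, na, nb) {
  g <- nrow(m)
  expr <- tibble::as_tibble(cbind(
    data.frame(gene_id = rownames(m) %||%
                 sprintf("g%03d", seq_len(g))), m))
  names(expr)[-1] <- sprintf("s%02d", seq_len(ncol(m)))
  meta <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(ncol(m))),
                         group = c(rep("A", na), rep("B", nb)))
  expression_set(expr, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent step-up BH oracle (direct implementation of the definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Random symmetric adjacency with unit diagonal, entries in [0, 1].
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# Brute-force TOM by triple loop over shared neighbours.
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# A compact simulation config for fast unit tests (network-scale defaults
# are used only where a test needs them).
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(n_samples_a = 9, n_samples_b = 7,
             module_sizes = c(20L, 20L), n_background = 40,
             trait_coef = c("1" = 1, "2" = 0.5),
             n_candidate_pool = 10, seed = seed, ...)
}
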