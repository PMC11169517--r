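#' Simulate a cluster-structured scRNA-seq-like count matrix
#'
#' Minimal generative model for sparse single-cell counts: cells are split
#' into `k_clusters` balanced groups; every gene has baseline negative-
#' binomial mean `base_mean`, and each cluster up-regulates its own disjoint
#' block of `de_fraction * n_genes` marker genes by `fold_change`. Counts are
#' negative binomial with the given dispersion (`size = 1 / dispersion`),
#' after which each nonzero entry is independently zeroed with probability
#' `dropout_rate`, emulating dropout events from low RNA capture.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param k_clusters number of cell groups (>= 2).
#' @param de_fraction fraction of genes differentially expressed per cluster.
#' @param fold_change mean multiplier on a cluster's marker genes.
#' @param base_mean baseline NB mean.
#' @param dispersion NB dispersion; variance is `mu + dispersion * mu^2`.
#' @param dropout_rate extra zero-inflation probability in `[0, 1]`.
#' @param seed integer seed; identical seeds reproduce the matrix bitwise.
#' @return An [expression_matrix()] carrying the true labels (0-based).
#' @export
simulate_counts <- function(n_cells = 300L, n_genes = 500L, k_clusters = 3L,
                            de_fraction = 0.1, fold_change = 4,
                            base_mean = 2, dispersion = 0.3,
                            dropout_rate = 0.3, seed = 0L) {
  if (k_clusters < 2L) stop("k_clusters must be >= 2")
  if (n_cells < k_clusters) stop("need at least one cell per cluster")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  if (base_mean <= 0 || fold_change <= 0) stop("means must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  labels <- rep(seq_len(k_clusters) - 1L, length.out = n_cells)
  n_de <- floor(de_fraction * n_genes)
  mu <- matrix(base_mean, k_clusters, n_genes)
  for (g in seq_len(k_clusters)) {
    lo <- (g - 1L) * n_de + 1L
    hi <- min(g * n_de, n_genes)
    if (lo <= hi) mu[g, lo:hi] <- base_mean * fold_change
  }
  size <- 1 / dispersion
  counts <- matrix(0, n_cells, n_genes)
  for (i in seq_len(n_cells)) {
    counts[i, ] <- stats::rnbinom(n_genes, size = size, mu = mu[labels[i] + 1L, ])
  }
  if (dropout_rate > 0) {
    nz <- which(counts > 0)
    drop <- nz[stats::runif(length(nz)) < dropout_rate]
    counts[drop] <- 0
  }
  expression_matrix(counts, labels = labels)
}

#' Zero floor(rate * nnz) nonzero entries of an expression matrix
#'
#' Used by the dropout-robustness experiment: exactly `floor(rate * nnz(X))`
#' nonzero entries, chosen uniformly without replacement, are set to zero.
#'
#' @param X an [expression_matrix()].
#' @param rate fraction of nonzero entries to zero, in `[0, 1)`.
#' @param seed integer seed.
#' @return Corrupted [expression_matrix()].
#' @export
apply_dropout <- function(X, rate, seed = 0L) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (rate < 0 || rate >= 1) stop("apply_dropout: rate must lie in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  v <- X$values
  nz <- which(v != 0)
  ndrop <- floor(rate * length(nz))
  if (ndrop > 0) v[sample(nz, ndrop)] <- 0
  expression_matrix(v, X$cell_ids, X$gene_ids, X$labels)
}
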