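#' Dropout-robustness experiment
#'
#' For each rate, zeroes that fraction of the nonzero entries of the raw
#' count matrix ([apply_dropout()]), re-runs preprocessing and the full
#' training pipeline, and records the clustering metrics against the true
#' labels. Quantifies how stable the clustering stays as sparsity grows.
#'
#' @param X a raw (count-scale) [expression_matrix()] with labels.
#' @param rates dropout fractions, default `c(0.2, 0.3, 0.4, 0.5)`.
#' @param config trainer configuration.
#' @param seed seed for the dropout masks (training uses
#'   `config$train$seed`).
#' @return data.frame with columns `rate`, `nmi`, `ari`, `f1`,
#'   `n_clusters_pred`.
#' @export
dropout_experiment <- function(X, rates = c(0.2, 0.3, 0.4, 0.5),
                               config = dcrelm_config("easy"), seed = 0L) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.null(X$labels)) stop("dropout_experiment: X must carry true labels")
  if (any(rates <= 0 | rates >= 1)) stop("rates must lie in (0, 1)")
  rows <- lapply(seq_along(rates), function(i) {
    Xd <- apply_dropout(X, rates[i], seed = seed + i)
    Xp <- standardize(filter_genes(Xd))
    fit <- dcrelm_train(Xp, config = config)
    ev <- evaluate_clustering(X$labels, fit$labels)
    data.frame(rate = rates[i], nmi = ev$nmi, ari = ev$ari, f1 = ev$f1,
               n_clusters_pred = ev$n_clusters_pred)
  })
  do.call(rbind, rows)
}

#' Configure an ablation variant
#'
#' Returns a configuration whose trainer drops one model component:
#' * `full` — the complete model;
#' * `CR` — correlation-reduction losses (sample, feature, propagation)
#'   removed;
#' * `DF` — the graph autoencoder removed; fusion degenerates to the
#'   attribute embedding and the graph-assignment distribution is replaced by
#'   the attribute one in the triplet loss;
#' * `N` — feature corruption disabled (noise sd 0);
#' * `E` — structural distortion disabled: no edge masking, and both views
#'   use the normalized adjacency.
#'
#' @param name one of `"full"`, `"CR"`, `"DF"`, `"N"`, `"E"`.
#' @param config base configuration.
#' @return The configuration with `variant` set.
#' @export
build_variant <- function(name = c("full", "CR", "DF", "N", "E"),
                          config = dcrelm_config("easy")) {
  name <- match.arg(name)
  config$variant <- name
  config
}

#' Run the ablation study
#'
#' Trains every variant on the same data across the given seeds and returns
#' one metrics row per (variant, seed).
#'
#' @param X preprocessed [expression_matrix()] with labels (used for k and
#'   evaluation).
#' @param variants variant names, see [build_variant()].
#' @param seeds integer vector of training seeds.
#' @param config base configuration.
#' @return data.frame with `variant`, `seed`, `nmi`, `ari`, `f1`,
#'   `n_clusters_pred`.
#' @export
ablation_experiment <- function(X, variants = c("full", "CR", "DF", "N", "E"),
                                seeds = 0:2, config = dcrelm_config("easy")) {
  stopifnot(inherits(X, "ExpressionMatrix"), !is.null(X$labels))
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      cfg <- build_variant(v, config)
      cfg$train$seed <- as.integer(s)
      fit <- dcrelm_train(X, config = cfg)
      ev <- evaluate_clustering(X$labels, fit$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = s, nmi = ev$nmi, ari = ev$ari, f1 = ev$f1,
        n_clusters_pred = ev$n_clusters_pred)
    }
  }
  do.call(rbind, rows)
}
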