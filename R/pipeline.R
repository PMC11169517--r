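#' Run the end-to-end clustering pipeline
#'
#' Loads (or simulates) an expression matrix, filters and standardizes it,
#' trains the deep clustering model, evaluates against true labels when
#' available, and writes a self-describing output directory:
#' `labels.tsv` (cell_id, cluster), `losses.tsv` (per-epoch loss
#' components), `metrics.json` (when labels exist) and
#' `resolved-config.yaml`.
#'
#' @param input path to an expression matrix, or an [expression_matrix()],
#'   or `NULL` to simulate with the easy preset.
#' @param out_dir output directory (created if missing).
#' @param k cluster count; defaults to the label count when labels exist.
#' @param config a [dcrelm_config()] list.
#' @param fmt,orientation passed to [load_expression()] for file input.
#' @param truth optional path to a truth TSV (`cell_id`, `label`) used for
#'   evaluation when the matrix itself has no labels.
#' @return The `dcrelm_fit`, invisibly, with `$metrics` attached when
#'   computed.
#' @export
run_pipeline <- function(input, out_dir, k = NULL,
                         config = dcrelm_config(), fmt = NULL,
                         orientation = "cells_by_genes", truth = NULL) {
  if (is.null(input)) {
    X <- simulate_counts(seed = config$train$seed)
  } else if (inherits(input, "ExpressionMatrix")) {
    X <- input
  } else {
    X <- load_expression(input, fmt = fmt, orientation = orientation)
  }
  if (!is.null(truth)) {
    tr <- data.table::fread(truth, data.table = FALSE)
    lab <- tr[[2L]][match(X$cell_ids, as.character(tr[[1L]]))]
    if (anyNA(lab)) stop("run_pipeline: truth file misses some cell ids")
    X$labels <- as.integer(factor(lab)) - 1L
  }
  Xp <- standardize(filter_genes(X))
  fit <- dcrelm_train(Xp, k = k, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(
    data.frame(cell_id = Xp$cell_ids, cluster = fit$labels),
    file.path(out_dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(fit$losses, file.path(out_dir, "losses.tsv"), sep = "\t")
  write_config(fit$config, file.path(out_dir, "resolved-config.yaml"))
  if (!is.null(Xp$labels)) {
    m <- evaluate_clustering(Xp$labels, fit$labels)
    jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    fit$metrics <- m
  }
  invisible(fit)
}
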