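#' Initialize a frozen extreme-learning-machine feature map
#'
#' An ELM here is a single hidden layer with random, never-trained input
#' weights: gene-space vectors are projected through `n_nodes` random affine
#' units and a fixed nonlinearity, turning a sparse high-dimensional
#' expression profile into a dense low-dimensional feature vector. Weights
#' are drawn i.i.d. uniform; with the default `"scaled"` variant the range is
#' `(-sqrt(3/n_genes), sqrt(3/n_genes))` so pre-activations of standardized
#' input have roughly unit variance and a bounded activation stays in its
#' informative regime instead of saturating; `"unit"` draws from (-1, 1).
#' Biases are Uniform(-1, 1). The map is fully determined by
#' `(n_genes, n_nodes, activation, weight_scale, seed)`.
#'
#' @param n_genes number of input genes (columns of the expression matrix).
#' @param n_nodes number of random hidden nodes, i.e. the output width.
#' @param activation `"tanh"` (default), `"sigmoid"`, `"relu"` or
#'   `"identity"`.
#' @param weight_scale `"scaled"` (default) or `"unit"`.
#' @param seed integer RNG seed.
#' @return An object of class `ELMMap` with fields `phi` (n_genes x n_nodes
#'   weights), `zeta` (n_nodes biases), `activation`, `seed`.
#' @export
init_elm <- function(n_genes, n_nodes, activation = c("tanh", "sigmoid",
                                                      "relu", "identity"),
                     weight_scale = c("scaled", "unit"), seed = 0L) {
  activation <- match.arg(activation)
  weight_scale <- match.arg(weight_scale)
  if (!is.numeric(n_nodes) || n_nodes < 1) stop("n_nodes must be >= 1")
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  n_nodes <- as.integer(n_nodes)
  n_genes <- as.integer(n_genes)
  a <- if (weight_scale == "scaled") sqrt(3 / n_genes) else 1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  phi <- matrix(stats::runif(n_genes * n_nodes, -a, a), n_genes, n_nodes)
  zeta <- stats::runif(n_nodes, -1, 1)
  structure(list(phi = phi, zeta = zeta, activation = activation,
                 weight_scale = weight_scale, seed = as.integer(seed)),
            class = "ELMMap")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

activation_fun <- function(name) {
  switch(name,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh = tanh,
    relu = function(x) pmax(x, 0),
    identity = identity,
    stop("unknown activation: ", name))
}

#' Map an expression matrix through an ELM
#'
#' Computes `H[n, i] = act(phi_i . x_n + zeta_i)`: the matrix product of the
#' cell profiles with the frozen random weights, a broadcast bias, and the
#' map's nonlinearity.
#'
#' @param X an [expression_matrix()] or plain numeric matrix with cells as
#'   rows; its gene count must match the map.
#' @param map an [init_elm()] result.
#' @return Dense numeric matrix, cells x `n_nodes`.
#' @export
elm_map <- function(X, map) {
  stopifnot(inherits(map, "ELMMap"))
  v <- if (inherits(X, "ExpressionMatrix")) X$values else as.matrix(X)
  if (ncol(v) != nrow(map$phi))
    stop(sprintf("elm_map: X has %d genes but map expects %d",
                 ncol(v), nrow(map$phi)))
  act <- activation_fun(map$activation)
  h <- act(sweep(v %*% map$phi, 2L, map$zeta, "+"))
  rownames(h) <- if (inherits(X, "ExpressionMatrix")) X$cell_ids else rownames(v)
  h
}
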