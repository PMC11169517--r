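#' Multiplicative Gaussian feature corruption
#'
#' Entrywise product of the feature matrix with a noise matrix drawn i.i.d.
#' from `N(noise_mean, noise_sd^2)` (defaults mean 1, sd 0.1), so the
#' corrupted matrix is unbiased around the original with relative noise
#' proportional to each entry.
#'
#' @param H feature matrix.
#' @param noise_mean Gaussian mean (default 1).
#' @param noise_sd Gaussian standard deviation (default 0.1). When the
#'   `variance` interpretation is wanted, pass `sqrt(v)`.
#' @param seed integer seed; same seed reproduces the corruption bitwise.
#' @return Corrupted matrix of the same shape.
#' @export
corrupt_features <- function(H, noise_mean = 1, noise_sd = 0.1, seed = 0L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  H <- as.matrix(H)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  NO <- matrix(stats::rnorm(length(H), mean = noise_mean, sd = noise_sd),
               nrow(H), ncol(H))
  H * NO
}

#' Build the two distorted views for the siamese encoders
#'
#' View 1 pairs a corrupted copy of `H` with the masked normalized adjacency
#' `A_m`; view 2 pairs an independently corrupted copy with the PPR-diffused
#' adjacency `A_d`. The two corruption seeds should differ, otherwise both
#' views share the same noise and a warning is raised.
#'
#' @param H feature matrix.
#' @param graph a `CellGraph` from [build_cell_graph()].
#' @param seeds integer pair of corruption seeds.
#' @param noise_mean,noise_sd passed to [corrupt_features()].
#' @return A `ViewPair` list: `H1`, `H2`, `G1` (= `A_m`), `G2` (= `A_d`),
#'   `seeds`.
#' @export
make_views <- function(H, graph, seeds = c(1L, 2L), noise_mean = 1,
                       noise_sd = 0.1) {
  stopifnot(inherits(graph, "CellGraph"), length(seeds) == 2L)
  if (seeds[1L] == seeds[2L])
    warning("make_views: identical seeds; both views share the same noise")
  structure(list(
    H1 = corrupt_features(H, noise_mean, noise_sd, seed = seeds[1L]),
    H2 = corrupt_features(H, noise_mean, noise_sd, seed = seeds[2L]),
    G1 = graph$A_m,
    G2 = graph$A_d,
    seeds = as.integer(seeds)),
    class = "ViewPair")
}
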