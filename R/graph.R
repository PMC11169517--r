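cosine_matrix <- function(H) {
  n <- sqrt(rowSums(H^2)) + 1e-12
  Hn <- H / n
  Hn %*% t(Hn)
}

#' Build a cosine k-nearest-neighbour cell graph
#'
#' Each cell selects its `k` most similar cells under cosine similarity in
#' the feature space; the directed selections are symmetrized by union (an
#' edge is kept if either endpoint chose it). The adjacency is binary with a
#' zero diagonal.
#'
#' @param H numeric matrix, cells as rows (typically the ELM output).
#' @param k neighbour count, `1 <= k < nrow(H)`.
#' @return Binary symmetric adjacency matrix.
#' @export
build_knn_graph <- function(H, k = 15L) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (k < 1 || k >= n) stop("build_knn_graph: need 1 <= k < number of cells")
  S <- cosine_matrix(H)
  diag(S) <- -Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

undirected_edges <- function(A) {
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Mask the weakest graph edges
#'
#' Among the undirected edges of `A`, the `floor(drop_fraction * E)` edges
#' with the smallest pairwise cosine similarity (computed on `H`) are marked
#' 0 in the returned mask; every other position, edge or not, is 1. Ties in
#' similarity are broken by lexicographic (i, j) order.
#'
#' @param A symmetric adjacency.
#' @param H feature matrix used for the similarities.
#' @param drop_fraction fraction of edges to remove, in `[0, 1)`; default
#'   0.10.
#' @param seed unused placeholder kept for interface stability (the mask is
#'   deterministic).
#' @return Binary symmetric mask matrix, same shape as `A`.
#' @export
edge_mask <- function(A, H, drop_fraction = 0.10, seed = 0L) {
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  n <- nrow(A)
  MA <- matrix(1, n, n)
  ed <- undirected_edges(A)
  ndrop <- floor(drop_fraction * nrow(ed))
  if (ndrop > 0) {
    S <- cosine_matrix(as.matrix(H))
    sims <- S[ed]
    ord <- order(sims, ed[, 1L], ed[, 2L])
    drop <- ed[ord[seq_len(ndrop)], , drop = FALSE]
    MA[drop] <- 0
    MA[drop[, c(2L, 1L), drop = FALSE]] <- 0
  }
  MA
}

#' Symmetrically normalize a masked adjacency
#'
#' Computes `A_m = D^{-1/2} ((A . MA) + I) D^{-1/2}` where `D` holds the row
#' degrees of the self-looped masked adjacency. A `literal` switch instead
#' applies `D^{-1/2} (.) D^{+1/2}` for auditing the unnormalized variant;
#' the symmetric form is the default because it keeps the spectral radius at
#' 1, which the PPR diffusion requires.
#'
#' @param A symmetric adjacency.
#' @param MA binary mask (defaults to all ones).
#' @param literal use the `D^{+1/2}` right factor instead of `D^{-1/2}`.
#' @return Normalized adjacency matrix.
#' @export
normalize_adjacency <- function(A, MA = NULL, literal = FALSE) {
  n <- nrow(A)
  if (is.null(MA)) MA <- matrix(1, n, n)
  Aw <- A * MA
  diag(Aw) <- diag(Aw) + 1
  d <- rowSums(Aw)
  dl <- 1 / sqrt(d)
  dr <- if (literal) sqrt(d) else dl
  Aw * outer(dl, dr)
}

#' Personalized-PageRank graph diffusion
#'
#' Closed-form PPR: `A_d = tau * (I - (1 - tau) * A_m)^{-1}`, solved as a
#' linear system and verified by its residual. With the symmetric
#' normalization the spectral radius of `(1 - tau) A_m` is below 1, so the
#' system is well posed; `A_d` is a dense, globally diffused view of the
#' graph that tends to the identity as `tau -> 1`.
#'
#' @param A_m normalized adjacency from [normalize_adjacency()].
#' @param tau teleport (restart) probability in (0, 1); default 0.2.
#' @return Diffusion matrix of the same shape.
#' @export
ppr_diffusion <- function(A_m, tau = 0.2) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  n <- nrow(A_m)
  lhs <- diag(n) - (1 - tau) * A_m
  A_d <- tryCatch(tau * solve(lhs),
                  error = function(e) {
                    stop(sprintf(
                      "ppr_diffusion: singular system (rcond ~ %.2e): %s",
                      rcond(lhs), conditionMessage(e)))
                  })
  res <- max(abs(lhs %*% A_d - tau * diag(n)))
  if (res > 1e-8)
    stop(sprintf("ppr_diffusion: residual %.2e exceeds 1e-8", res))
  A_d
}

#' Build the full cell graph bundle
#'
#' Convenience wrapper running [build_knn_graph()], [edge_mask()],
#' [normalize_adjacency()] (masked and unmasked) and [ppr_diffusion()], and
#' returning everything downstream stages need.
#'
#' @param H feature matrix (cells as rows).
#' @param k neighbour count.
#' @param drop_fraction edge-mask fraction.
#' @param tau_ppr PPR teleport probability.
#' @param literal_normalization audit switch, see [normalize_adjacency()].
#' @return A `CellGraph` list: `A`, `MA`, `D`, `A_m` (masked, normalized),
#'   `A_d` (diffused), `A_norm` (unmasked, normalized), `tau_ppr`.
#' @export
build_cell_graph <- function(H, k = 15L, drop_fraction = 0.10, tau_ppr = 0.2,
                             literal_normalization = FALSE) {
  A <- build_knn_graph(H, k = k)
  MA <- edge_mask(A, H, drop_fraction = drop_fraction)
  A_m <- normalize_adjacency(A, MA, literal = literal_normalization)
  A_d <- ppr_diffusion(A_m, tau = tau_ppr)
  A_norm <- normalize_adjacency(A, literal = literal_normalization)
  Aw <- A * MA
  diag(Aw) <- diag(Aw) + 1
  structure(list(A = A, MA = MA, D = rowSums(Aw), A_m = A_m, A_d = A_d,
                 A_norm = A_norm, tau_ppr = tau_ppr),
            class = "CellGraph")
}

#' Export a graph as an edge list
#'
#' @param A adjacency matrix.
#' @param path output TSV with columns i, j, weight (1-based, upper
#'   triangle).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(A, path) {
  ed <- undirected_edges(A)
  df <- data.frame(i = ed[, 1L], j = ed[, 2L], weight = A[ed])
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
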