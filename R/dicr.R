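# Dual information correlation reduction: losses that push the cross-view
# sample and feature correlation matrices toward the identity, de-redundifying
# the latent space, plus a propagation regularizer against oversmoothing.

#' Cross-view sample correlation loss
#'
#' `S_C[i, j]` is the cosine similarity between row i of the view-1 latent and
#' row j of the view-2 latent; the loss is the mean squared deviation of
#' `S_C` from the identity over all `N^2` entries. Minimizing it aligns each
#' cell with itself across views and decorrelates distinct cells.
#'
#' @param H_v1,H_v2 per-view latent embeddings (N x d).
#' @return List with `S_C` and `loss`.
#' @export
sample_correlation_loss <- function(H_v1, H_v2) {
  if (!all(dim(H_v1) == dim(H_v2))) stop("shape mismatch")
  n1 <- sqrt(rowSums(H_v1^2)) + 1e-12
  n2 <- sqrt(rowSums(H_v2^2)) + 1e-12
  S_C <- (H_v1 / n1) %*% t(H_v2 / n2)
  n <- nrow(H_v1)
  list(S_C = S_C, loss = sum((S_C - diag(n))^2) / n^2)
}

#' Group-mean readout
#'
#' Collapses an N x d latent matrix to k x d by averaging the rows of each
#' label group; empty groups receive the global mean row.
#'
#' @param H_v latent matrix.
#' @param labels integer labels in `[0, k)`.
#' @param k group count (defaults to `max(labels) + 1`).
#' @return k x d matrix of group means.
#' @export
readout <- function(H_v, labels, k = NULL) {
  H_v <- as.matrix(H_v)
  labels <- as.integer(labels)
  if (length(labels) != nrow(H_v)) stop("readout: one label per row required")
  if (is.null(k)) k <- max(labels) + 1L
  if (any(labels < 0L | labels >= k)) stop("readout: labels out of [0, k)")
  out <- matrix(NA_real_, k, ncol(H_v))
  gmean <- colMeans(H_v)
  for (g in seq_len(k) - 1L) {
    idx <- which(labels == g)
    out[g + 1L, ] <- if (length(idx)) colMeans(H_v[idx, , drop = FALSE]) else gmean
  }
  out
}

#' Cross-view feature correlation loss
#'
#' `S_F[i, j]` is the cosine similarity between column j of the view-1
#' readout and column i of the view-2 readout (the printed transpose
#' convention, pinned by a unit test); the loss is the mean squared deviation
#' from the d x d identity.
#'
#' @param R_out1,R_out2 k x d readout matrices.
#' @return List with `S_F` and `loss`.
#' @export
feature_correlation_loss <- function(R_out1, R_out2) {
  if (!all(dim(R_out1) == dim(R_out2))) stop("shape mismatch")
  c1 <- sqrt(colSums(R_out1^2)) + 1e-12
  c2 <- sqrt(colSums(R_out2^2)) + 1e-12
  C1 <- sweep(R_out1, 2L, c1, "/")
  C2 <- sweep(R_out2, 2L, c2, "/")
  S_F <- t(C2) %*% C1  # S_F[i, j] = <col_i(view2), col_j(view1)>
  d <- ncol(R_out1)
  list(S_F = S_F, loss = sum((S_F - diag(d))^2) / d^2)
}

kl_rows <- function(p, q) rowSums(ifelse(p > 0, p * (log(p) - log(q)), 0))

#' Propagation (oversmoothing) regularizer
#'
#' Jensen-Shannon divergence, averaged over cells, between the row-softmax of
#' the latent matrix and the row-softmax of its one-step graph propagation.
#' Natural log, so the value lies in `[0, ln 2]`; zero when propagation
#' leaves the latent distributionally unchanged.
#'
#' @param H_latent fused latent matrix.
#' @param A_m normalized adjacency.
#' @return Scalar divergence.
#' @export
propagation_reg <- function(H_latent, A_m) {
  p <- row_softmax(as.matrix(H_latent))
  q <- row_softmax(A_m %*% as.matrix(H_latent))
  m <- 0.5 * (p + q)
  mean(0.5 * kl_rows(p, m) + 0.5 * kl_rows(q, m))
}

#' Fuse the two view latents
#'
#' Entrywise average `H = (H_v1 + H_v2) / 2`.
#'
#' @param H_v1,H_v2 per-view latent matrices of equal shape.
#' @return Fused latent matrix.
#' @export
fuse_latent <- function(H_v1, H_v2) {
  if (!all(dim(H_v1) == dim(H_v2))) stop("fuse_latent: shape mismatch")
  0.5 * (H_v1 + H_v2)
}
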