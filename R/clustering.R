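#' Student-t soft cluster assignment
#'
#' DEC-style kernel: `q_ij` is proportional to
#' `(1 + ||z_i - mu_j||^2 / nu)^{-(nu + 1) / 2}`, normalized over clusters,
#' so each row of `Q` is a probability vector that decays with distance to
#' the centre.
#'
#' @param Z N x d embedding.
#' @param mu k x d cluster centres.
#' @param nu Student-t degrees of freedom (default 1).
#' @return N x k row-stochastic soft assignment matrix.
#' @export
soft_assign <- function(Z, mu, nu = 1) {
  Z <- as.matrix(Z)
  mu <- as.matrix(mu)
  if (nrow(mu) < 1L) stop("soft_assign: need at least one centre")
  if (ncol(Z) != ncol(mu)) stop("soft_assign: embedding width mismatch")
  d2 <- outer(rowSums(Z^2), rowSums(mu^2), "+") - 2 * Z %*% t(mu)
  d2[d2 < 0] <- 0
  K <- (1 + d2 / nu)^(-(nu + 1) / 2)
  K / rowSums(K)
}

#' Sharpened target distribution
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with `f_j = sum_i q_ij`
#' the soft cluster frequency. Squaring sharpens confident assignments while
#' the frequency division discourages large clusters from absorbing
#' everything.
#'
#' @param Q row-stochastic soft assignment.
#' @return Row-stochastic target of the same shape.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  w <- sweep(Q^2, 2L, colSums(Q), "/")
  w / rowSums(w)
}

#' Triplet self-supervised KL loss
#'
#' KL divergence of the equal mixture of the three assignment distributions
#' (fused, attribute-only, graph-only) from the shared target:
#' `sum_ij p_ij log(p_ij / ((q_ij + q'_ij + q''_ij) / 3))`.
#'
#' @param P target distribution.
#' @param Q,Q1,Q2 the three row-stochastic assignments.
#' @return Nonnegative scalar, zero when the mixture equals the target.
#' @export
triplet_kl_loss <- function(P, Q, Q1, Q2) {
  for (m in list(Q, Q1, Q2))
    if (!all(dim(m) == dim(P))) stop("triplet_kl_loss: shape mismatch")
  mix <- (Q + Q1 + Q2) / 3
  sum(ifelse(P > 0, P * (log(P) - log(mix)), 0))
}

#' Total training objective
#'
#' `T = (T_AE + T_IGAE) + (T_C + T_F + epsilon * T_R) + lambda * T_KL`:
#' reconstruction, correlation reduction, and clustering blocks.
#'
#' @param parts named list or vector with `t_ae`, `t_igae`, `t_c`, `t_f`,
#'   `t_r`, `t_kl`.
#' @param weights list with `epsilon` and `lambda` (and `gamma`, already
#'   folded into `t_igae`).
#' @return Scalar total loss.
#' @export
total_loss <- function(parts, weights = list(epsilon = 0.01, lambda = 10)) {
  parts <- as.list(parts)
  need <- c("t_ae", "t_igae", "t_c", "t_f", "t_r", "t_kl")
  miss <- setdiff(need, names(parts))
  if (length(miss)) stop("total_loss: missing parts: ", paste(miss, collapse = ", "))
  for (nm in need)
    if (!is.finite(parts[[nm]])) stop("total_loss: non-finite part: ", nm)
  parts$t_ae + parts$t_igae + parts$t_c + parts$t_f +
    weights$epsilon * parts$t_r + weights$lambda * parts$t_kl
}

#' Hard labels from a soft assignment
#'
#' Row argmax with ties broken by the lowest column index; labels are
#' 0-based cluster ids.
#'
#' @param Q row-stochastic assignment matrix.
#' @return Integer vector of cluster labels.
#' @export
predict_labels <- function(Q) {
  max.col(as.matrix(Q), ties.method = "first") - 1L
}
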