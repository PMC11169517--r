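row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

xavier <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize autoencoder parameters
#'
#' Builds the weight/bias matrices for the attribute autoencoder (AE) and the
#' improved graph autoencoder (IGAE). Encoders map the ELM feature width
#' `m_tilde` through the given hidden widths down to the latent width `d`;
#' decoders mirror the encoders back to `m_tilde`. Weights are Glorot-uniform;
#' the fusion gate `beta` starts at 0 so global structure is blended in only
#' as training opens it.
#'
#' @param m_tilde input feature width (ELM nodes).
#' @param ae_hidden integer vector of AE encoder hidden widths.
#' @param igae_hidden integer vector of IGAE encoder hidden widths.
#' @param d latent embedding width.
#' @param seed integer seed.
#' @return Named list of parameter matrices (`ae_enc_W*`, `ae_enc_b*`,
#'   `ae_dec_W*`, `ae_dec_b*`, `ig_enc_W*`, `ig_dec_W*`, `beta`).
#' @export
init_autoencoder_params <- function(m_tilde, ae_hidden = c(512L, 256L),
                                    igae_hidden = 256L, d = 20L, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  pars <- list()
  widths <- c(m_tilde, ae_hidden, d)
  for (i in seq_len(length(widths) - 1L)) {
    pars[[paste0("ae_enc_W", i)]] <- xavier(widths[i], widths[i + 1L])
    pars[[paste0("ae_enc_b", i)]] <- matrix(0, 1L, widths[i + 1L])
  }
  dwidths <- rev(widths)
  for (i in seq_len(length(dwidths) - 1L)) {
    pars[[paste0("ae_dec_W", i)]] <- xavier(dwidths[i], dwidths[i + 1L])
    pars[[paste0("ae_dec_b", i)]] <- matrix(0, 1L, dwidths[i + 1L])
  }
  gwidths <- c(m_tilde, igae_hidden, d)
  for (i in seq_len(length(gwidths) - 1L)) {
    pars[[paste0("ig_enc_W", i)]] <- xavier(gwidths[i], gwidths[i + 1L])
  }
  gdwidths <- rev(gwidths)
  for (i in seq_len(length(gdwidths) - 1L)) {
    pars[[paste0("ig_dec_W", i)]] <- xavier(gdwidths[i], gdwidths[i + 1L])
  }
  pars$beta <- matrix(0, 1L, 1L)
  pars
}

#' Attribute autoencoder forward pass
#'
#' A plain feed-forward stack `relu(Z W + b)` per layer. By default every
#' layer applies ReLU; with `linear_last = TRUE` the final layer of the stack
#' is left linear (the trainer's default for both the latent and the
#' reconstruction so that neither is gradient-dead at zero).
#'
#' @param Z input matrix (view features for encoding, fused latent for
#'   decoding).
#' @param W list of weight matrices.
#' @param b list of 1-row bias matrices.
#' @param linear_last leave the last layer linear instead of ReLU.
#' @return Output matrix of the stack.
#' @export
ae_forward <- function(Z, W, b, linear_last = FALSE) {
  stopifnot(length(W) == length(b))
  Z <- as.matrix(Z)
  for (i in seq_along(W)) {
    if (ncol(Z) != nrow(W[[i]]))
      stop(sprintf("ae_forward: layer %d expects width %d, got %d",
                   i, nrow(W[[i]]), ncol(Z)))
    Z <- sweep(Z %*% W[[i]], 2L, b[[i]][1L, ], "+")
    if (!(linear_last && i == length(W))) Z[Z < 0] <- 0
  }
  Z
}

#' Improved graph autoencoder forward pass
#'
#' Each layer propagates over the graph before the weight and nonlinearity:
#' `sigma(G Z W)`. View 1 uses the masked normalized adjacency, view 2 the
#' PPR-diffused one; the decoder always propagates with the normalized
#' adjacency.
#'
#' @param Z input matrix.
#' @param G graph operator (N x N).
#' @param W list of weight matrices.
#' @param activation `"lrelu"` (LeakyReLU, slope 0.2; default) or
#'   `"identity"`.
#' @param linear_last leave the last layer linear.
#' @return Output matrix.
#' @export
igae_forward <- function(Z, G, W, activation = c("lrelu", "identity"),
                         linear_last = FALSE) {
  activation <- match.arg(activation)
  Z <- as.matrix(Z)
  for (i in seq_along(W)) {
    if (ncol(Z) != nrow(W[[i]]))
      stop(sprintf("igae_forward: layer %d expects width %d, got %d",
                   i, nrow(W[[i]]), ncol(Z)))
    Z <- G %*% Z %*% W[[i]]
    if (!(linear_last && i == length(W)) && activation == "lrelu")
      Z <- ifelse(Z > 0, Z, 0.2 * Z)
  }
  Z
}

#' Attribute reconstruction loss
#'
#' Sum of squared entrywise differences between the decoded matrix and the
#' ELM feature matrix.
#'
#' @param H_hat decoded matrix.
#' @param H target feature matrix.
#' @return Nonnegative scalar; zero iff the reconstruction is exact.
#' @export
ae_loss <- function(H_hat, H) {
  if (!all(dim(H_hat) == dim(H))) stop("ae_loss: shape mismatch")
  sum((H_hat - H)^2)
}

#' Graph autoencoder mixed loss
#'
#' `T_m + gamma * T_n` with `T_m = ||A_norm H - H_hat||_F^2 / (2N)` (the
#' propagated-attribute residual) and `T_n = ||A_norm - A_hat||_F^2 / (2N)`
#' (the adjacency residual).
#'
#' @param H_hat decoded feature matrix.
#' @param A_hat reconstructed adjacency from [reconstruct_adjacency()].
#' @param H feature matrix.
#' @param A_norm unmasked normalized adjacency.
#' @param gamma adjacency-term weight (default 0.1).
#' @return List with `loss`, `t_m`, `t_n`.
#' @export
igae_loss <- function(H_hat, A_hat, H, A_norm, gamma = 0.1) {
  if (!all(dim(H_hat) == dim(H))) stop("igae_loss: feature shape mismatch")
  if (!all(dim(A_hat) == dim(A_norm))) stop("igae_loss: adjacency shape mismatch")
  n <- nrow(H)
  t_m <- sum((A_norm %*% H - H_hat)^2) / (2 * n)
  t_n <- sum((A_norm - A_hat)^2) / (2 * n)
  list(loss = t_m + gamma * t_n, t_m = t_m, t_n = t_n)
}

#' Decode an adjacency from a latent embedding
#'
#' Inner-product graph decoder: `logistic(Z Z^T)`, symmetric with entries in
#' (0, 1).
#'
#' @param Z latent embedding.
#' @return Reconstructed adjacency matrix.
#' @export
reconstruct_adjacency <- function(Z) {
  Z <- as.matrix(Z)
  1 / (1 + exp(-(Z %*% t(Z))))
}

#' Dynamic attribute/structure fusion
#'
#' Averages the two views of each encoder, convexly combines attribute and
#' graph embeddings (`H_I = tau H_AE + (1 - tau) H_IGAE`), enhances locally
#' through the graph (`H_L = A_m H_I`), computes the row-softmax
#' self-correlation `S` of `H_L`, enhances globally (`H_G = S H_L`) and gates
#' the result (`H_star = beta H_G + H_L`).
#'
#' @param H_AE_v1,H_AE_v2 per-view attribute embeddings.
#' @param H_IGAE_v1,H_IGAE_v2 per-view graph embeddings.
#' @param A_m masked normalized adjacency.
#' @param beta scalar gate on the global term.
#' @param tau_fuse attribute/structure balance in `[0, 1]`.
#' @return A `FusionState` list: `H_AE`, `H_IGAE`, `H_I`, `H_L`, `S`, `H_G`,
#'   `H_star`, `beta`, `tau_fuse`.
#' @export
dynamic_fuse <- function(H_AE_v1, H_AE_v2, H_IGAE_v1, H_IGAE_v2, A_m,
                         beta = 0, tau_fuse = 0.5) {
  if (tau_fuse < 0 || tau_fuse > 1) stop("tau_fuse must lie in [0, 1]")
  dims <- dim(H_AE_v1)
  for (m in list(H_AE_v2, H_IGAE_v1, H_IGAE_v2))
    if (!all(dim(m) == dims)) stop("dynamic_fuse: embedding width mismatch")
  H_AE <- 0.5 * (H_AE_v1 + H_AE_v2)
  H_IGAE <- 0.5 * (H_IGAE_v1 + H_IGAE_v2)
  H_I <- tau_fuse * H_AE + (1 - tau_fuse) * H_IGAE
  H_L <- A_m %*% H_I
  S <- row_softmax(H_L %*% t(H_L))
  H_G <- S %*% H_L
  H_star <- as.numeric(beta) * H_G + H_L
  structure(list(H_AE = H_AE, H_IGAE = H_IGAE, H_I = H_I, H_L = H_L, S = S,
                 H_G = H_G, H_star = H_star, beta = as.numeric(beta),
                 tau_fuse = tau_fuse),
            class = "FusionState")
}
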