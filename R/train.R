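# End-to-end training of the fused autoencoder clustering network. The whole
# forward pass is expressed on the autograd tape (R/autograd.R); one epoch is
# forward + backward + one Adam step on every learnable matrix, including the
# cluster centres during the self-supervised phase.

layer_count <- function(params, prefix) {
  sum(grepl(paste0("^", prefix, "\\d+$"), names(params)))
}

# Forward pass on a tape. `raw` holds plain matrices (corrupted views, graph
# operators, ELM features, precomputed A_norm %*% H); `pn` the parameter
# nodes; `opt` the phase switches and hyperparameters. Returns the loss nodes
# and key representation nodes.
net_forward <- function(tape, pn, raw, opt) {
  cn <- function(x) ag_const(tape, x)
  n <- nrow(raw$H)
  H1 <- cn(raw$H1); H2 <- cn(raw$H2)
  G1 <- cn(raw$G1); G2 <- cn(raw$G2)
  Am <- cn(raw$A_m)
  Hn <- cn(raw$H)

  enc_ae <- function(Z) {
    L <- opt$n_ae_enc
    for (i in seq_len(L)) {
      Z <- ag_add_bias(tape, ag_mm(tape, Z, pn[[paste0("ae_enc_W", i)]]),
                       pn[[paste0("ae_enc_b", i)]])
      if (i < L) Z <- ag_relu(tape, Z)
    }
    Z
  }
  dec_ae <- function(Z) {
    L <- opt$n_ae_dec
    for (i in seq_len(L)) {
      Z <- ag_add_bias(tape, ag_mm(tape, Z, pn[[paste0("ae_dec_W", i)]]),
                       pn[[paste0("ae_dec_b", i)]])
      if (i < L) Z <- ag_relu(tape, Z)
    }
    Z
  }
  enc_ig <- function(Z, G) {
    L <- opt$n_ig_enc
    for (i in seq_len(L)) {
      Z <- ag_mm(tape, ag_mm(tape, G, Z), pn[[paste0("ig_enc_W", i)]])
      if (i < L) Z <- ag_lrelu(tape, Z, 0.2)
    }
    Z
  }
  dec_ig <- function(Z, G) {
    L <- opt$n_ig_dec
    for (i in seq_len(L)) {
      Z <- ag_mm(tape, ag_mm(tape, G, Z), pn[[paste0("ig_dec_W", i)]])
      if (i < L) Z <- ag_lrelu(tape, Z, 0.2)
    }
    Z
  }
  sumsq <- function(a) ag_sum(tape, ag_mul(tape, a, a))
  avg2 <- function(a, b) ag_affine(tape, ag_add(tape, a, b), 0.5)

  Z_ae1 <- enc_ae(H1); Z_ae2 <- enc_ae(H2)
  H_AE <- avg2(Z_ae1, Z_ae2)
  if (opt$use_igae) {
    Z_ig1 <- enc_ig(H1, G1); Z_ig2 <- enc_ig(H2, G2)
    H_IG <- avg2(Z_ig1, Z_ig2)
    H_I <- ag_add(tape, ag_affine(tape, H_AE, opt$tau),
                  ag_affine(tape, H_IG, 1 - opt$tau))
  } else {
    H_I <- H_AE
  }
  H_L <- ag_mm(tape, Am, H_I)
  S <- ag_row_softmax(tape, ag_mm(tape, H_L, ag_t(tape, H_L)))
  H_G <- ag_mm(tape, S, H_L)
  H_star <- ag_add(tape, ag_scalar_mul(tape, pn$beta, H_G), H_L)

  Hhat_AE <- dec_ae(H_star)
  t_ae <- sumsq(ag_sub(tape, Hhat_AE, Hn))
  total <- t_ae
  t_igae <- NULL
  if (opt$use_igae) {
    Hhat_IG <- dec_ig(H_star, Am)
    Ahat <- ag_sigmoid(tape, ag_mm(tape, H_star, ag_t(tape, H_star)))
    t_m <- ag_affine(tape, sumsq(ag_sub(tape, cn(raw$A_normH), Hhat_IG)),
                     1 / (2 * n))
    t_n <- ag_affine(tape, sumsq(ag_sub(tape, cn(raw$A_norm), Ahat)),
                     1 / (2 * n))
    t_igae <- ag_add(tape, t_m, ag_affine(tape, t_n, opt$gamma))
    total <- ag_add(tape, total, t_igae)
  }

  # per-view fused latents feeding the correlation-reduction block
  if (opt$use_igae) {
    Hv1 <- ag_add(tape, ag_affine(tape, Z_ae1, opt$tau),
                  ag_affine(tape, Z_ig1, 1 - opt$tau))
    Hv2 <- ag_add(tape, ag_affine(tape, Z_ae2, opt$tau),
                  ag_affine(tape, Z_ig2, 1 - opt$tau))
  } else {
    Hv1 <- Z_ae1; Hv2 <- Z_ae2
  }
  H_lat <- avg2(Hv1, Hv2)

  t_c <- t_f <- t_r <- NULL
  if (opt$use_dicr && opt$dicr_on) {
    R1 <- ag_row_normalize(tape, Hv1)
    R2 <- ag_row_normalize(tape, Hv2)
    SC <- ag_mm(tape, R1, ag_t(tape, R2))
    t_c <- ag_affine(tape, sumsq(ag_sub(tape, SC, cn(diag(n)))), 1 / n^2)

    klab <- opt$k
    Mlab <- matrix(0, klab, n)
    for (g in seq_len(klab) - 1L) {
      idx <- which(opt$labels == g)
      if (length(idx)) Mlab[g + 1L, idx] <- 1 / length(idx)
      else Mlab[g + 1L, ] <- 1 / n
    }
    Rt1 <- ag_mm(tape, cn(Mlab), Hv1)
    Rt2 <- ag_mm(tape, cn(Mlab), Hv2)
    C1 <- ag_col_normalize(tape, Rt1)
    C2 <- ag_col_normalize(tape, Rt2)
    SF <- ag_mm(tape, ag_t(tape, C2), C1)
    d <- ncol(Hv1$value)
    t_f <- ag_affine(tape, sumsq(ag_sub(tape, SF, cn(diag(d)))), 1 / d^2)

    p <- ag_row_softmax(tape, H_lat)
    q <- ag_row_softmax(tape, ag_mm(tape, Am, H_lat))
    m <- avg2(p, q)
    klp <- ag_sum(tape, ag_mul(tape, p, ag_sub(tape, ag_log(tape, p),
                                               ag_log(tape, m))))
    klq <- ag_sum(tape, ag_mul(tape, q, ag_sub(tape, ag_log(tape, q),
                                               ag_log(tape, m))))
    t_r <- ag_affine(tape, ag_add(tape, klp, klq), 0.5 / n)
    total <- ag_add(tape, total, t_c)
    total <- ag_add(tape, total, t_f)
    total <- ag_add(tape, total, ag_affine(tape, t_r, opt$epsilon))
  }

  Qn <- Q1n <- Q2n <- t_kl <- NULL
  if (opt$clustering_on) {
    assign_node <- function(Z) {
      A2 <- ag_rowsums(tape, ag_mul(tape, Z, Z))
      M2 <- ag_rowsums(tape, ag_mul(tape, pn$mu, pn$mu))
      cross <- ag_mm(tape, Z, ag_t(tape, pn$mu))
      D2 <- ag_add(tape, ag_outer_add(tape, A2, M2),
                   ag_affine(tape, cross, -2))
      K <- ag_pow(tape, ag_affine(tape, D2, 1 / opt$nu, 1),
                  -(opt$nu + 1) / 2)
      ag_mul_col(tape, K, ag_pow(tape, ag_rowsums(tape, K), -1))
    }
    Qn <- assign_node(H_star)
    Q1n <- assign_node(H_AE)
    Q2n <- if (opt$use_igae) assign_node(H_IG) else Q1n
    P <- opt$P
    c0 <- sum(ifelse(P > 0, P * log(P), 0))
    mix <- ag_affine(tape, ag_add(tape, ag_add(tape, Qn, Q1n), Q2n), 1 / 3)
    t_kl <- ag_sub(tape, cn(matrix(c0, 1L, 1L)),
                   ag_sum(tape, ag_mul(tape, cn(P), ag_log(tape, mix))))
    total <- ag_add(tape, total, ag_affine(tape, t_kl, opt$lambda))
  }

  list(total = total, t_ae = t_ae, t_igae = t_igae, t_c = t_c, t_f = t_f,
       t_r = t_r, t_kl = t_kl, H_star = H_star, H_AE = H_AE,
       H_IG = if (opt$use_igae) H_IG else NULL, H_lat = H_lat,
       Q = Qn, Q1 = Q1n, Q2 = Q2n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_val <- function(nd) if (is.null(nd)) NA_real_ else nd$value[1L]

safe_kmeans <- function(Z, k, nstart = 10L) {
  tryCatch(stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100L),
           error = function(e) {
             Zj <- Z + matrix(stats::rnorm(length(Z), sd = 1e-6),
                              nrow(Z), ncol(Z))
             stats::kmeans(Zj, centers = k, nstart = nstart, iter.max = 100L)
           })
}

#' Train the full deep clustering model
#'
#' Runs the complete pipeline on a preprocessed expression matrix: ELM random
#' feature mapping, cell-graph construction with edge masking and PPR
#' diffusion, siamese view corruption, and epochs of joint training of the
#' attribute and graph autoencoders with dynamic fusion, dual
#' correlation-reduction losses and the triplet Student-t self-supervised
#' clustering objective. Training has two phases: a reconstruction-only
#' warm-up, after which the cluster centres are initialized by k-means on the
#' fused embedding and the correlation-reduction and clustering losses are
#' switched on. Every source of randomness derives from `config$train$seed`,
#' so identical configurations reproduce identical labels.
#'
#' @param X an [expression_matrix()], already filtered and standardized.
#' @param k number of clusters; defaults to `config$train$k`, or to the
#'   number of distinct labels carried by `X`.
#' @param config a [dcrelm_config()] list. `config$variant` selects an
#'   ablation variant (see [build_variant()]).
#' @return A `dcrelm_fit` list: `labels` (0-based), `Q`, `Q1`, `Q2`, `P`,
#'   `mu`, `H_star`, `H_latent`, `losses` (per-epoch data.frame), `graph`,
#'   `map`, `params`, `config`, `k`.
#' @export
dcrelm_train <- function(X, k = NULL, config = dcrelm_config()) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.null(k)) k <- config$train$k
  if (is.null(k) && !is.null(X$labels)) k <- length(unique(X$labels))
  if (is.null(k)) stop("dcrelm_train: supply k or an X with labels")
  k <- as.integer(k)
  n <- nrow(X$values)
  if (k > n) stop("dcrelm_train: k exceeds the number of cells")
  variant <- config$variant %||% "full"
  if (!variant %in% c("full", "CR", "DF", "N", "E"))
    stop("unknown variant: ", variant)
  seed <- as.integer(config$train$seed)

  old_rng <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_rng), add = TRUE)

  use_igae <- variant != "DF"
  use_dicr <- variant != "CR"
  noise_sd <- if (variant == "N") 0 else config$aug$noise_sd
  drop_frac <- if (variant == "E") 0 else config$graph$drop_fraction

  map <- init_elm(ncol(X$values), config$elm$n_nodes,
                  config$elm$activation,
                  weight_scale = config$elm$weight_scale %||% "scaled",
                  seed = seed)
  H <- elm_map(X, map)
  graph <- build_cell_graph(H, k = min(config$graph$k, n - 1L),
                            drop_fraction = drop_frac,
                            tau_ppr = config$graph$tau_ppr,
                            literal_normalization =
                              config$graph$literal_normalization)
  if (variant == "E") graph$A_d <- graph$A_m

  params <- init_autoencoder_params(ncol(H), config$ae$layers,
                                    config$igae$layers, config$latent$d,
                                    seed = seed + 1L)
  if (!use_igae) params <- params[!grepl("^ig_", names(params))]
  # start the AE decoder at the feature means so early epochs learn structure,
  # not the offset
  bias_last <- paste0("ae_dec_b", layer_count(params, "ae_dec_W"))
  params[[bias_last]] <- matrix(colMeans(H), 1L)
  opt_base <- list(
    n_ae_enc = layer_count(params, "ae_enc_W"),
    n_ae_dec = layer_count(params, "ae_dec_W"),
    n_ig_enc = layer_count(params, "ig_enc_W"),
    n_ig_dec = layer_count(params, "ig_dec_W"),
    tau = config$fusion$tau, gamma = config$fusion$gamma,
    epsilon = config$loss$epsilon, lambda = config$loss$lambda,
    nu = config$train$nu, use_igae = use_igae, use_dicr = use_dicr,
    k = k, dicr_on = FALSE, clustering_on = FALSE, labels = NULL, P = NULL)

  epochs <- as.integer(config$train$epochs)
  warmup <- min(as.integer(config$train$warmup), epochs)
  set.seed(seed + 2L)
  noise_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * epochs + 2L),
                        nrow = 2L)

  raw <- list(H = H, G1 = graph$A_m, G2 = graph$A_d, A_m = graph$A_m,
              A_norm = graph$A_norm, A_normH = graph$A_norm %*% H)
  clean_raw <- raw
  clean_raw$H1 <- H
  clean_raw$H2 <- H

  forward_values <- function(opt) {
    tape <- ag_tape()
    pn <- lapply(params, function(p) ag_const(tape, p))
    net_forward(tape, pn, clean_raw, opt)
  }

  state <- adam_state(params, lr = config$train$lr)
  losses <- vector("list", epochs)
  labels <- NULL
  P <- NULL
  Q_prev <- NULL

  for (epoch in seq_len(epochs)) {
    in_full <- epoch > warmup
    if (noise_sd > 0 && (config$aug$resample_each_epoch || epoch == 1L)) {
      raw$H1 <- corrupt_features(H, config$aug$noise_mean, noise_sd,
                                 seed = noise_seeds[1L, epoch])
      raw$H2 <- corrupt_features(H, config$aug$noise_mean, noise_sd,
                                 seed = noise_seeds[2L, epoch])
    } else if (noise_sd == 0 && is.null(raw$H1)) {
      raw$H1 <- H
      raw$H2 <- H
    }

    opt <- opt_base
    opt$dicr_on <- in_full
    opt$clustering_on <- in_full
    if (in_full) {
      if ((epoch - warmup - 1L) %% max(1L, config$train$p_refresh) == 0L &&
          !is.null(Q_prev))
        P <- target_distribution(Q_prev)
      opt$labels <- labels
      opt$P <- P
    }

    tape <- ag_tape()
    pn <- lapply(params, function(p) ag_const(tape, p))
    nodes <- net_forward(tape, pn, raw, opt)
    if (!is.finite(nodes$total$value[1L]))
      stop(sprintf("dcrelm_train: loss diverged (non-finite) at epoch %d",
                   epoch))
    ag_backward(tape, nodes$total)
    grads <- lapply(pn, function(nd) nd$grad)
    st <- adam_step(state, params, grads)
    state <- st$state
    params <- st$params

    losses[[epoch]] <- data.frame(
      epoch = epoch, t_ae = node_val(nodes$t_ae),
      t_igae = node_val(nodes$t_igae), t_c = node_val(nodes$t_c),
      t_f = node_val(nodes$t_f), t_r = node_val(nodes$t_r),
      t_kl = node_val(nodes$t_kl), total = node_val(nodes$total))

    if (in_full) Q_prev <- nodes$Q$value

    if (epoch == warmup || (epoch == epochs && !in_full)) {
      # phase switch: k-means on the clean fused embedding initializes the
      # centres, the pseudo-labels and the first target distribution
      cl_opt <- opt_base
      vals <- forward_values(cl_opt)
      Hs <- vals$H_star$value
      set.seed(seed + 3L)
      km <- safe_kmeans(Hs, k, nstart = 10L)
      params$mu <- km$centers
      labels <- km$cluster - 1L
      Q_prev <- soft_assign(Hs, params$mu, nu = config$train$nu)
      P <- target_distribution(Q_prev)
      state <- adam_state(params, lr = config$train$lr)
    } else if (in_full) {
      labels <- predict_labels(Q_prev)
    }
  }

  # inference pass with noise off and final parameters
  fin_opt <- opt_base
  fin_opt$dicr_on <- FALSE
  fin_opt$clustering_on <- TRUE
  fin_opt$P <- P %||% target_distribution(Q_prev)
  fin <- forward_values(fin_opt)
  Q <- fin$Q$value
  structure(list(
    labels = predict_labels(Q), Q = Q, Q1 = fin$Q1$value, Q2 = fin$Q2$value,
    P = target_distribution(Q), mu = params$mu, H_star = fin$H_star$value,
    H_latent = fin$H_lat$value, losses = do.call(rbind, losses),
    graph = graph, map = map, params = params, config = config, k = k),
    class = "dcrelm_fit")
}

#' @export
print.dcrelm_fit <- function(x, ...) {
  cat(sprintf("dcrelm_fit: %d cells, k = %d, %d epochs (final loss %.4g)\n",
              nrow(x$Q), x$k, nrow(x$losses),
              x$losses$total[nrow(x$losses)]))
  invisible(x)
}
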