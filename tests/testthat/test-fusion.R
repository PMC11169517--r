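test_that("AE forward matches per-neuron arithmetic and the ReLU contract", {
  # identity-initialized single layer passes nonnegative input through
  W <- list(diag(3))
  b <- list(matrix(0, 1, 3))
  Zp <- matrix(c(1, 2, 0, 3, 4, 5), 2, 3)
  expect_equal(ae_forward(Zp, W, b), Zp)
  # negative inputs clipped by ReLU
  Zn <- matrix(c(-1, 2, -3, 4, -5, 6), 2, 3)
  expect_equal(ae_forward(Zn, W, b), pmax(Zn, 0))
  expect_equal(ae_forward(Zn, W, b, linear_last = TRUE), Zn)
  # loop oracle on a 3x4 input
  set.seed(12)
  W1 <- matrix(rnorm(8), 4, 2)
  b1 <- matrix(rnorm(2), 1, 2)
  X <- matrix(rnorm(12), 3, 4)
  out <- ae_forward(X, list(W1), list(b1))
  for (n in 1:3) for (j in 1:2)
    expect_equal(out[n, j], max(0, sum(X[n, ] * W1[, j]) + b1[1, j]))
  expect_error(ae_forward(X, list(matrix(0, 3, 2)), list(b1)), "width")
})

test_that("IGAE forward propagates over the graph before the weights", {
  set.seed(13)
  Z <- matrix(rnorm(8), 2, 4)
  W <- list(diag(4))
  G <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  # identity weights, linear layer: output is G Z exactly
  expect_equal(igae_forward(Z, G, W, linear_last = TRUE), G %*% Z)
  # G = I reduces to a dense layer
  W2 <- list(matrix(rnorm(12), 4, 3))
  expect_equal(igae_forward(Z, diag(2), W2),
               {v <- Z %*% W2[[1]]; ifelse(v > 0, v, 0.2 * v)})
  # two-node graph, hand 2x2 weights
  Zh <- matrix(c(1, 2, 3, 4), 2, 2)
  Wh <- matrix(c(1, 0, 1, 1), 2, 2)
  got <- igae_forward(Zh, G, list(Wh), activation = "identity")
  expect_equal(got, (G %*% Zh) %*% Wh)
})

test_that("reconstruction losses vanish exactly at their optimum", {
  set.seed(14)
  H <- matrix(rnorm(12), 3, 4)
  expect_equal(ae_loss(H, H), 0)
  D <- matrix(c(1, -1, 1, -1, 1, -1), 2, 3)
  expect_equal(ae_loss(D, matrix(0, 2, 3)), 6)
  # loop oracle
  A <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(16), 4, 4)
  acc <- 0
  for (i in 1:4) for (j in 1:4) acc <- acc + (A[i, j] - B[i, j])^2
  expect_equal(ae_loss(A, B), acc)

  A_norm <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  Hh <- matrix(rnorm(6), 2, 3)
  perfect <- igae_loss(A_norm %*% Hh, A_norm, Hh, A_norm, gamma = 0.1)
  expect_equal(perfect$loss, 0)
  # gamma = 0 leaves only the attribute term; unit residual scales as d/(2N)
  res <- igae_loss(A_norm %*% Hh + 1, A_norm, Hh, A_norm, gamma = 0)
  expect_equal(res$loss, res$t_m)
  expect_equal(res$t_m, (2 * 3) / (2 * 2))
})

test_that("adjacency decoder is a symmetric logistic inner product", {
  expect_true(all(reconstruct_adjacency(matrix(0, 3, 2)) == 0.5))
  set.seed(15)
  Z <- matrix(rnorm(10), 5, 2)
  Ah <- reconstruct_adjacency(Z)
  expect_equal(Ah, t(Ah))
  expect_true(all(Ah > 0 & Ah < 1))
  z <- matrix(c(0.7, -1.2), 2, 1)
  expect_equal(reconstruct_adjacency(z)[1, 2], plogis(0.7 * -1.2))
})

test_that("dynamic fusion follows the local/global enhancement chain", {
  set.seed(16)
  n <- 4; d <- 3
  A1 <- matrix(rnorm(n * d), n, d); A2 <- matrix(rnorm(n * d), n, d)
  G1 <- matrix(rnorm(n * d), n, d); G2 <- matrix(rnorm(n * d), n, d)
  Am <- normalize_adjacency(build_knn_graph(matrix(rnorm(n * 5), n, 5), 2))
  fs <- dynamic_fuse(A1, A2, G1, G2, Am, beta = 0.3, tau_fuse = 0.5)
  expect_equal(rowSums(fs$S), rep(1, n), tolerance = 1e-6)
  expect_equal(fs$H_star, 0.3 * fs$H_G + fs$H_L)
  # endpoint of the convex combination
  fs1 <- dynamic_fuse(A1, A2, G1, G2, Am, tau_fuse = 1)
  expect_equal(fs1$H_I, 0.5 * (A1 + A2))
  # closed gate
  fs0 <- dynamic_fuse(A1, A2, G1, G2, Am, beta = 0)
  expect_equal(fs0$H_star, fs0$H_L)
  # hand softmax for orthonormal H_L: identity graph keeps H_I
  fsI <- dynamic_fuse(diag(2), diag(2), diag(2), diag(2), diag(2), beta = 1)
  e <- exp(1)
  Sh <- matrix(c(e, 1, 1, e) / (e + 1), 2, 2)
  expect_equal(fsI$S, Sh, tolerance = 1e-12)
  expect_equal(fsI$H_G, Sh %*% diag(2))
})

test_that("dynamic fusion is permutation-equivariant", {
  set.seed(17)
  n <- 6; d <- 4
  mats <- replicate(4, matrix(rnorm(n * d), n, d), simplify = FALSE)
  Am <- normalize_adjacency(build_knn_graph(matrix(rnorm(n * 5), n, 5), 2))
  fs <- dynamic_fuse(mats[[1]], mats[[2]], mats[[3]], mats[[4]], Am,
                     beta = 0.7)
  perm <- sample(n)
  fsp <- dynamic_fuse(mats[[1]][perm, ], mats[[2]][perm, ],
                      mats[[3]][perm, ], mats[[4]][perm, ],
                      Am[perm, perm], beta = 0.7)
  expect_equal(fsp$H_star, fs$H_star[perm, ], tolerance = 1e-10)
})
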