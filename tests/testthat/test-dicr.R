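test_that("sample correlation loss measures cross-view misalignment", {
  # aligned orthogonal rows
  H <- diag(3)
  r <- sample_correlation_loss(H, H)
  expect_equal(r$S_C, diag(3), tolerance = 1e-8)
  expect_equal(r$loss, 0, tolerance = 1e-8)
  # swapped orthonormal rows: S_C is the swap matrix, loss 1
  H1 <- diag(2)
  H2 <- H1[c(2, 1), ]
  r2 <- sample_correlation_loss(H1, H2)
  expect_equal(r2$S_C, matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-8)
  expect_equal(r2$loss, 1, tolerance = 1e-8)
  # cosine scale invariance
  set.seed(18)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  base <- sample_correlation_loss(A, B)
  A5 <- A; A5[2, ] <- 5 * A5[2, ]
  expect_equal(sample_correlation_loss(A5, B)$S_C, base$S_C, tolerance = 1e-12)
})

test_that("readout pools rows by group with empty-group fallback", {
  set.seed(19)
  H <- matrix(rnorm(8), 4, 2)
  expect_equal(readout(H, rep(0L, 4), k = 1), t(colMeans(H)), ignore_attr = TRUE)
  # singletons reproduce the rows
  expect_equal(readout(H, 0:3, k = 4), H, ignore_attr = TRUE)
  # hand 4x2 example with k = 2
  lab <- c(0L, 0L, 1L, 1L)
  R <- readout(H, lab, k = 2)
  expect_equal(R[1, ], colMeans(H[1:2, ]))
  expect_equal(R[2, ], colMeans(H[3:4, ]))
  # empty group gets the global mean
  R3 <- readout(H, lab, k = 3)
  expect_equal(R3[3, ], colMeans(H))
  expect_error(readout(H, c(0L, 0L, 1L, 5L), k = 2), "labels")
})

test_that("feature correlation loss uses the column-transpose convention", {
  R <- diag(3)
  r <- feature_correlation_loss(R, R)
  expect_equal(r$S_F, diag(3), tolerance = 1e-8)
  expect_equal(r$loss, 0, tolerance = 1e-8)
  # swapped view-2 columns, d = 2: loss 1
  R1 <- diag(2)
  R2 <- R1[, c(2, 1)]
  expect_equal(feature_correlation_loss(R1, R2)$loss, 1, tolerance = 1e-8)
  # orientation pin: S_F[i, j] = cos(col_j(view1), col_i(view2))
  R1 <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)  # col1=(1,0,0), col2=(1,1,1)
  R2 <- matrix(c(0, 1, 0, 1, 0, 0), 3, 2)  # col1=(0,1,0), col2=(1,0,0)
  got <- feature_correlation_loss(R1, R2)$S_F
  expect_equal(got[2, 1], 1, tolerance = 1e-8)          # col1(v1) . col2(v2)
  expect_equal(got[1, 2], 1 / sqrt(3), tolerance = 1e-8) # col2(v1) . col1(v2)
  expect_equal(got[1, 1], 0)                             # col1(v1) . col1(v2)
  expect_equal(got[2, 2], 1 / sqrt(3), tolerance = 1e-8) # col2(v1) . col2(v2)
  # column scale invariance
  R1s <- R1; R1s[, 2] <- 7 * R1s[, 2]
  expect_equal(feature_correlation_loss(R1s, R2)$S_F, got, tolerance = 1e-8)
})

test_that("minimizing the sample correlation loss aligns a free embedding", {
  # gradient descent on a free view-2 embedding against a fixed orthonormal
  # view 1 (width >= rows so the identity correlation target is attainable)
  set.seed(20)
  H1 <- diag(5)[1:4, ]
  H2 <- matrix(rnorm(20, sd = 0.5), 4, 5)
  lr <- 20
  for (it in 1:800) {
    g <- num_grad(function(x) sample_correlation_loss(H1, x)$loss, H2, h = 1e-5)
    H2 <- H2 - lr * g
  }
  expect_lt(sample_correlation_loss(H1, H2)$loss, 1e-4)
})

test_that("propagation regularizer is a bounded JSD, zero on identity graphs", {
  set.seed(21)
  H <- matrix(rnorm(15), 5, 3)
  expect_equal(propagation_reg(H, diag(5)), 0)
  A <- matrix(runif(25), 5, 5)
  v <- propagation_reg(H, A)
  expect_gte(v, 0)
  expect_lte(v, log(2) + 1e-9)
  # two-row hand check against scalar KL arithmetic
  H2 <- matrix(c(1, 0, 0, 1), 2, 2)
  Am <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  p <- exp(H2) / rowSums(exp(H2))
  q <- exp(Am %*% H2) / rowSums(exp(Am %*% H2))
  m <- (p + q) / 2
  kl <- function(a, b) rowSums(a * log(a / b))
  expect_equal(propagation_reg(H2, Am),
               mean(0.5 * kl(p, m) + 0.5 * kl(q, m)))
})

test_that("latent fusion is the entrywise average", {
  set.seed(22)
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(fuse_latent(A, A), A)
  expect_equal(fuse_latent(A, -A), A * 0)
  B <- matrix(rnorm(12), 3, 4)
  out <- fuse_latent(A, B)
  for (i in 1:3) for (j in 1:4)
    expect_equal(out[i, j], (A[i, j] + B[i, j]) / 2)
  expect_error(fuse_latent(A, matrix(0, 2, 2)), "shape")
})
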