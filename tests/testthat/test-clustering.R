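test_that("soft assignment follows the Student-t kernel", {
  Z <- matrix(c(0, 1), 2, 1)
  expect_true(all(soft_assign(Z, matrix(0.5, 1, 1)) == 1))
  # equidistant from two centres
  mu <- matrix(c(-1, 1), 2, 1)
  expect_equal(soft_assign(matrix(0, 1, 1), mu)[1, ], c(0.5, 0.5))
  # nu = 1, squared distances (0, 1): kernel (1, 0.5) -> (2/3, 1/3)
  q <- soft_assign(matrix(0, 1, 1), matrix(c(0, 1), 2, 1), nu = 1)
  expect_equal(q[1, ], c(2 / 3, 1 / 3))
  # rows stochastic, monotone in distance
  set.seed(23)
  Q <- soft_assign(matrix(rnorm(40), 10, 4), matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(Q), rep(1, 10), tolerance = 1e-12)
  expect_error(soft_assign(matrix(0, 2, 2), matrix(0, 0, 2)), "centre")
})

test_that("target distribution sharpens and fixes the printed example", {
  Q <- matrix(c(0.8, 0.6, 0.2, 0.4), 2, 2)
  P <- target_distribution(Q)
  # hand computation with column masses f = (1.4, 0.6)
  w11 <- 0.64 / 1.4; w12 <- 0.04 / 0.6
  expect_equal(P[1, 1], w11 / (w11 + w12), tolerance = 1e-4)
  expect_equal(round(P[1, 1], 4), 0.8727)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  # uniform stays uniform
  U <- matrix(1 / 3, 4, 3)
  expect_equal(target_distribution(U), U)
  # single sample: P = Q
  q1 <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(target_distribution(q1), q1)
})

test_that("target sharpening holds over random stochastic rows", {
  set.seed(24)
  Q <- matrix(rexp(1e4 * 3), 1e4, 3)
  Q <- Q / rowSums(Q)
  P <- target_distribution(Q)
  expect_true(all(apply(P, 1, max) >= apply(Q, 1, max) - 1e-9))
  expect_equal(rowSums(P), rep(1, 1e4), tolerance = 1e-9)
})

test_that("triplet KL loss is a KL against the assignment mixture", {
  P <- matrix(c(0.6, 0.3, 0.4, 0.7), 2, 2)
  expect_equal(triplet_kl_loss(P, P, P, P), 0)
  # one-hot target vs (0.5, 0.5) mixture: ln 2
  P1 <- matrix(c(1, 0), 1, 2)
  U <- matrix(0.5, 1, 2)
  expect_equal(triplet_kl_loss(P1, U, U, U), log(2))
  # loop oracle on random stochastic 5x3 matrices
  set.seed(25)
  rs <- function() {
    m <- matrix(rexp(15), 5, 3)
    m / rowSums(m)
  }
  Pr <- rs(); Qa <- rs(); Qb <- rs(); Qc <- rs()
  acc <- 0
  for (i in 1:5) for (j in 1:3) {
    mix <- (Qa[i, j] + Qb[i, j] + Qc[i, j]) / 3
    acc <- acc + Pr[i, j] * log(Pr[i, j] / mix)
  }
  expect_equal(triplet_kl_loss(Pr, Qa, Qb, Qc), acc)
  expect_gte(triplet_kl_loss(Pr, Qa, Qb, Qc), -1e-9)
  expect_error(triplet_kl_loss(Pr, Qa[1:2, ], Qb, Qc), "shape")
})

test_that("total objective is the stated weighted sum", {
  parts <- list(t_ae = 1, t_igae = 1, t_c = 1, t_f = 1, t_r = 1, t_kl = 1)
  expect_equal(total_loss(parts, list(epsilon = 0.5, lambda = 2)), 6.5)
  expect_equal(total_loss(lapply(parts, function(x) 0),
                          list(epsilon = 1, lambda = 1)), 0)
  expect_equal(total_loss(parts, list(epsilon = 0, lambda = 0)), 4)
  parts$t_c <- NaN
  expect_error(total_loss(parts, list(epsilon = 1, lambda = 1)), "t_c")
})

test_that("label prediction is argmax with first-index ties", {
  Q <- rbind(c(0, 1, 0), c(1, 0, 0))
  expect_equal(predict_labels(Q), c(1L, 0L))
  expect_equal(predict_labels(matrix(c(0.5, 0.5), 1, 2)), 0L)
  set.seed(26)
  Qr <- matrix(runif(60), 20, 3)
  expect_equal(predict_labels(Qr),
               apply(Qr, 1, which.max) - 1L)
})

test_that("loss terms are nonnegative on random inputs", {
  set.seed(27)
  for (r in 1:200) {
    n <- sample(2:6, 1); d <- sample(2:5, 1)
    A <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(n * d), n, d)
    expect_gte(ae_loss(A, B), 0)
    expect_gte(sample_correlation_loss(A, B)$loss, 0)
    expect_gte(feature_correlation_loss(A, B)$loss, 0)
    G <- matrix(runif(n * n), n, n)
    expect_gte(propagation_reg(A, G), 0)
    rs <- function() {
      m <- matrix(rexp(n * d), n, d)
      m / rowSums(m)
    }
    expect_gte(triplet_kl_loss(rs(), rs(), rs(), rs()), -1e-9)
  }
})
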