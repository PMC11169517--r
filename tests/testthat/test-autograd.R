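# The training engine relies on the in-package reverse-mode autodiff; its
# gradients are pinned here against central finite differences.

ag <- function(name) get(name, envir = asNamespace("dcrelm"))

test_that("every autodiff primitive matches finite differences", {
  ag_tape <- ag("ag_tape"); ag_const <- ag("ag_const")
  ag_backward <- ag("ag_backward")
  set.seed(31)
  X <- matrix(rnorm(12, sd = 0.7), 3, 4)

  cases <- list(
    mm = function(tp, x) ag("ag_mm")(tp, x, ag_const(tp, matrix(rnorm(8), 4, 2))),
    add_bias = function(tp, x) ag("ag_add_bias")(tp, x, ag_const(tp, matrix(rnorm(4), 1, 4))),
    lrelu = function(tp, x) ag("ag_lrelu")(tp, x, 0.2),
    sigmoid = function(tp, x) ag("ag_sigmoid")(tp, x),
    tanh = function(tp, x) ag("ag_tanh")(tp, x),
    softmax = function(tp, x) ag("ag_row_softmax")(tp, x),
    rownorm = function(tp, x) ag("ag_row_normalize")(tp, x),
    colnorm = function(tp, x) ag("ag_col_normalize")(tp, x),
    pow = function(tp, x) ag("ag_pow")(tp, ag("ag_affine")(tp, ag("ag_mul")(tp, x, x), 1, 1), -1),
    logexp = function(tp, x) ag("ag_log")(tp, ag("ag_exp")(tp, x)),
    rowsums = function(tp, x) ag("ag_rowsums")(tp, x)
  )
  set.seed(32)
  for (nm in names(cases)) {
    set.seed(33)  # same downstream weights for analytic and numeric passes
    fval <- function(xm) {
      set.seed(33)
      tp <- ag_tape()
      xn <- ag_const(tp, xm)
      out <- cases[[nm]](tp, xn)
      s <- ag("ag_sum")(tp, ag("ag_mul")(tp, out, out))
      list(tape = tp, node = xn, loss = s)
    }
    r <- fval(X)
    ag_backward(r$tape, r$loss)
    gnum <- num_grad(function(xm) fval(xm)$loss$value[1], X)
    expect_equal(r$node$grad, gnum, tolerance = 1e-5,
                 label = paste("gradient of", nm))
  }
})

test_that("composite network gradients match finite differences", {
  ag_tape <- ag("ag_tape"); ag_const <- ag("ag_const")
  set.seed(34)
  W <- matrix(rnorm(8, sd = 0.5), 4, 2)
  mu <- matrix(rnorm(4), 2, 2)
  G <- matrix(runif(9), 3, 3); G <- G / rowSums(G)
  P <- matrix(runif(6), 3, 2); P <- P / rowSums(P)
  X <- matrix(rnorm(12), 3, 4)
  build <- function(Wm, mum) {
    tp <- ag_tape()
    Wn <- ag_const(tp, Wm); mun <- ag_const(tp, mum)
    Xn <- ag_const(tp, X)
    Z <- ag("ag_relu")(tp, ag("ag_mm")(tp, Xn, Wn))
    # student-t assignment + KL to a fixed target
    A2 <- ag("ag_rowsums")(tp, ag("ag_mul")(tp, Z, Z))
    M2 <- ag("ag_rowsums")(tp, ag("ag_mul")(tp, mun, mun))
    cross <- ag("ag_mm")(tp, Z, ag("ag_t")(tp, mun))
    D2 <- ag("ag_add")(tp, ag("ag_outer_add")(tp, A2, M2),
                       ag("ag_affine")(tp, cross, -2))
    K <- ag("ag_pow")(tp, ag("ag_affine")(tp, D2, 1, 1), -1)
    Q <- ag("ag_mul_col")(tp, K, ag("ag_pow")(tp, ag("ag_rowsums")(tp, K), -1))
    kl <- ag("ag_sum")(tp, ag("ag_mul")(tp, ag_const(tp, P),
                                        ag("ag_log")(tp, Q)))
    # JSD-style piece through the graph
    p <- ag("ag_row_softmax")(tp, Z)
    q <- ag("ag_row_softmax")(tp, ag("ag_mm")(tp, ag_const(tp, G), Z))
    m <- ag("ag_affine")(tp, ag("ag_add")(tp, p, q), 0.5)
    klp <- ag("ag_sum")(tp, ag("ag_mul")(tp, p,
             ag("ag_sub")(tp, ag("ag_log")(tp, p), ag("ag_log")(tp, m))))
    loss <- ag("ag_add")(tp, kl, klp)
    list(tape = tp, loss = loss, Wn = Wn, mun = mun)
  }
  r <- build(W, mu)
  ag("ag_backward")(r$tape, r$loss)
  gW <- num_grad(function(x) build(x, mu)$loss$value[1], W)
  gmu <- num_grad(function(x) build(W, x)$loss$value[1], mu)
  expect_equal(r$Wn$grad, gW, tolerance = 1e-5)
  expect_equal(r$mun$grad, gmu, tolerance = 1e-5)
})

test_that("autograd loss values equal the plain-numeric module functions", {
  # dual route: the tape-based losses used in training vs the exported
  # numeric implementations
  set.seed(35)
  n <- 5; d <- 3
  H1 <- matrix(rnorm(n * d), n, d)
  H2 <- matrix(rnorm(n * d), n, d)
  G <- matrix(runif(n * n), n, n); G <- G / rowSums(G)
  tp <- ag("ag_tape")()
  c1 <- ag("ag_const")(tp, H1); c2 <- ag("ag_const")(tp, H2)
  R1 <- ag("ag_row_normalize")(tp, c1)
  R2 <- ag("ag_row_normalize")(tp, c2)
  SC <- ag("ag_mm")(tp, R1, ag("ag_t")(tp, R2))
  diffn <- ag("ag_sub")(tp, SC, ag("ag_const")(tp, diag(n)))
  tc <- ag("ag_affine")(tp, ag("ag_sum")(tp, ag("ag_mul")(tp, diffn, diffn)),
                        1 / n^2)
  expect_equal(tc$value[1], sample_correlation_loss(H1, H2)$loss,
               tolerance = 1e-12)

  lat <- ag("ag_affine")(tp, ag("ag_add")(tp, c1, c2), 0.5)
  p <- ag("ag_row_softmax")(tp, lat)
  q <- ag("ag_row_softmax")(tp, ag("ag_mm")(tp, ag("ag_const")(tp, G), lat))
  m <- ag("ag_affine")(tp, ag("ag_add")(tp, p, q), 0.5)
  klp <- ag("ag_sum")(tp, ag("ag_mul")(tp, p,
           ag("ag_sub")(tp, ag("ag_log")(tp, p), ag("ag_log")(tp, m))))
  klq <- ag("ag_sum")(tp, ag("ag_mul")(tp, q,
           ag("ag_sub")(tp, ag("ag_log")(tp, q), ag("ag_log")(tp, m))))
  tr <- ag("ag_affine")(tp, ag("ag_add")(tp, klp, klq), 0.5 / n)
  expect_equal(tr$value[1], propagation_reg(fuse_latent(H1, H2), G),
               tolerance = 1e-12)
})
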