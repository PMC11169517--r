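# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every node value is a numeric matrix (losses are 1x1). Nodes are recorded on
# a tape in creation order, which is a valid topological order because the
# graph is built forward; backward() walks the tape in reverse and each node's
# backfn scatters its accumulated gradient into its parents. The engine covers
# exactly the primitives the clustering network needs; gradients are verified
# against central finite differences in the test suite.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ag_const <- function(tape, x) ag_node(tape, as.matrix(x))

# Parameters are constants whose gradient the optimizer reads back.
ag_param <- ag_const

ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

ag_mm <- function(tape, a, b) {
  ag_node(tape, a$value %*% b$value, function(g) {
    ag_acc(a, g %*% t(b$value))
    ag_acc(b, t(a$value) %*% g)
  })
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

ag_sub <- function(tape, a, b) {
  ag_node(tape, a$value - b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, -g)
  })
}

ag_mul <- function(tape, a, b) {
  ag_node(tape, a$value * b$value, function(g) {
    ag_acc(a, g * b$value)
    ag_acc(b, g * a$value)
  })
}

# elementwise a * s + c with fixed scalars s, c
ag_affine <- function(tape, a, s = 1, c = 0) {
  ag_node(tape, a$value * s + c, function(g) ag_acc(a, g * s))
}

# X scaled by a learnable 1x1 node
ag_scalar_mul <- function(tape, s, x) {
  ag_node(tape, s$value[1L] * x$value, function(g) {
    ag_acc(s, matrix(sum(g * x$value), 1L, 1L))
    ag_acc(x, s$value[1L] * g)
  })
}

# add a 1 x k bias row to every row of a (n x k)
ag_add_bias <- function(tape, a, b) {
  ag_node(tape, sweep(a$value, 2L, b$value[1L, ], "+"), function(g) {
    ag_acc(a, g)
    ag_acc(b, matrix(colSums(g), 1L))
  })
}

ag_t <- function(tape, a) {
  ag_node(tape, t(a$value), function(g) ag_acc(a, t(g)))
}

ag_relu <- function(tape, a) {
  v <- a$value
  v[v < 0] <- 0
  ag_node(tape, v, function(g) ag_acc(a, g * (a$value > 0)))
}

ag_lrelu <- function(tape, a, alpha = 0.2) {
  v <- a$value
  neg <- v < 0
  v[neg] <- alpha * v[neg]
  ag_node(tape, v, function(g) {
    slope <- ifelse(a$value > 0, 1, alpha)
    ag_acc(a, g * slope)
  })
}

ag_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  nd <- ag_node(tape, v, function(g) ag_acc(a, g * v * (1 - v)))
  nd
}

ag_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ag_node(tape, v, function(g) ag_acc(a, g * (1 - v^2)))
}

ag_exp <- function(tape, a) {
  v <- exp(a$value)
  ag_node(tape, v, function(g) ag_acc(a, g * v))
}

# log with a positivity floor; callers only pass strictly positive values
ag_log <- function(tape, a, eps = 1e-300) {
  v <- pmax(a$value, eps)
  ag_node(tape, log(v), function(g) ag_acc(a, g / v))
}

# elementwise power; defined for strictly positive base when p is fractional
ag_pow <- function(tape, a, p) {
  v <- a$value^p
  ag_node(tape, v, function(g) ag_acc(a, g * p * a$value^(p - 1)))
}

ag_sum <- function(tape, a) {
  dims <- dim(a$value)
  ag_node(tape, matrix(sum(a$value), 1L, 1L), function(g) {
    ag_acc(a, matrix(g[1L], dims[1L], dims[2L]))
  })
}

ag_rowsums <- function(tape, a) {
  k <- ncol(a$value)
  ag_node(tape, matrix(rowSums(a$value), ncol = 1L), function(g) {
    ag_acc(a, matrix(g, nrow(a$value), k))
  })
}

# multiply every row i of a by column vector c[i]
ag_mul_col <- function(tape, a, cv) {
  ag_node(tape, a$value * cv$value[, 1L], function(g) {
    ag_acc(a, g * cv$value[, 1L])
    ag_acc(cv, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

# outer sum: value[i, j] = a[i] + b[j]  (a: n x 1, b: k x 1)
ag_outer_add <- function(tape, a, b) {
  ag_node(tape, outer(a$value[, 1L], b$value[, 1L], "+"), function(g) {
    ag_acc(a, matrix(rowSums(g), ncol = 1L))
    ag_acc(b, matrix(colSums(g), ncol = 1L))
  })
}

# numerically stable softmax over each row
ag_row_softmax <- function(tape, a) {
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ag_node(tape, s, function(g) {
    ag_acc(a, s * (g - rowSums(g * s)))
  })
}

# rows rescaled to unit Euclidean norm (guarded for zero rows)
ag_row_normalize <- function(tape, a, eps = 1e-12) {
  x <- a$value
  r <- sqrt(rowSums(x^2))
  s <- r + eps
  y <- x / s
  ag_node(tape, y, function(g) {
    rg <- pmax(r, eps)
    proj <- rowSums(g * x) / (s^2 * rg)
    ag_acc(a, g / s - x * proj)
  })
}

ag_col_normalize <- function(tape, a, eps = 1e-12) {
  x <- a$value
  r <- sqrt(colSums(x^2))
  s <- r + eps
  y <- sweep(x, 2L, s, "/")
  ag_node(tape, y, function(g) {
    rg <- pmax(r, eps)
    proj <- colSums(g * x) / (s^2 * rg)
    ag_acc(a, sweep(g, 2L, s, "/") - sweep(x, 2L, proj, "*"))
  })
}

# ---- Adam optimizer over a named list of parameter matrices ----

adam_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = lapply(params, function(p) p * 0),
             v = lapply(params, function(p) p * 0))
  st
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
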