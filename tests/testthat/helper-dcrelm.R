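# Shared fixtures and independent oracles used across the suite.

rand_expr <- function(n = 10, m = 8, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(round(runif(n * m) * 10), n, m))
}

# Brute-force clustering metrics, written independently of R/metrics.R:
# entropy/contingency arithmetic and O(N^2) pair enumeration.

bf_nmi <- function(t, p) {
  t <- as.integer(factor(t)); p <- as.integer(factor(p))
  n <- length(t)
  mi <- 0
  for (a in unique(t)) for (b in unique(p)) {
    nij <- sum(t == a & p == b)
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (sum(t == a) * sum(p == b)))
  }
  ent <- function(x) {
    ps <- table(x) / length(x)
    -sum(ps * log(ps))
  }
  d <- (ent(t) + ent(p)) / 2
  if (d == 0) 1 else mi / d
}

bf_ari <- function(t, p) {
  n <- length(t)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- t[i] == t[j]; sp <- p[i] == p[j]
    if (st && sp) s11 <- s11 + 1
    else if (!st && !sp) s00 <- s00 + 1
    else if (st) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(if (s11 == exp_idx) 1 else 0)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) for (sub in all_perms(n - 1L)) {
    v <- integer(n); v[i] <- n; v[-i] <- sub
    out[[length(out) + 1L]] <- v
  }
  out
}

# Overlap-maximizing matched macro-F1 by exhaustive permutation search.
# Returns the F1 values of every matching that attains the maximum total
# overlap (ties are possible; the Hungarian implementation picks one).
bf_f1_set <- function(t, p) {
  t <- as.integer(factor(t)); p <- as.integer(factor(p))
  kt <- max(t); kp <- max(p); kk <- max(kt, kp)
  best_ov <- -1
  f1s_at_best <- numeric(0)
  for (perm in all_perms(kk)) {
    # perm[c]: predicted cluster matched to true class c (may be a dummy > kp)
    ov <- 0
    f1s <- numeric(kt)
    for (cc in seq_len(kt)) {
      j <- perm[cc]
      tp <- if (j <= kp) sum(t == cc & p == j) else 0
      ov <- ov + tp
      szt <- sum(t == cc)
      szp <- if (j <= kp) sum(p == j) else 0
      f1s[cc] <- if (tp == 0) 0 else 2 * tp / (szt + szp)
    }
    if (ov > best_ov) {
      best_ov <- ov
      f1s_at_best <- mean(f1s)
    } else if (ov == best_ov) {
      f1s_at_best <- c(f1s_at_best, mean(f1s))
    }
  }
  list(overlap = best_ov, f1s = f1s_at_best)
}

# Central finite-difference gradient of a scalar-valued function of a matrix.
num_grad <- function(fn, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + h
    x2 <- x; x2[i] <- x2[i] - h
    g[i] <- (fn(x1) - fn(x2)) / (2 * h)
  }
  g
}
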