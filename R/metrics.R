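# Clustering agreement metrics. All three are invariant to relabeling of
# cluster ids; they are cross-checked in the tests against brute-force
# pair-enumeration / entropy implementations.

check_pair <- function(a, b, min_len = 1L) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) < min_len) stop("need at least ", min_len, " samples")
  list(a = as.integer(factor(a)), b = as.integer(factor(b)))
}

#' Normalized mutual information
#'
#' Mutual information between the two labelings normalized by the arithmetic
#' mean of their entropies (natural log). 1 for identical partitions, 0 when
#' one labeling carries no information about the other.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return Value in `[0, 1]`.
#' @export
nmi <- function(labels_true, labels_pred) {
  lb <- check_pair(labels_true, labels_pred)
  n <- length(lb$a)
  tab <- table(lb$a, lb$b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(p_j)) {
    if (pij[i, j] > 0)
      mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * p_j[j]))
  }
  h1 <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  h2 <- -sum(ifelse(p_j > 0, p_j * log(p_j), 0))
  denom <- (h1 + h2) / 2
  # both partitions trivial (single cluster each) => identical
  if (denom == 0) return(1)
  unname(mi / denom)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance: 1 for identical partitions
#' (up to label permutation), around 0 for random ones, can be negative.
#'
#' @param labels_true,labels_pred equal-length label vectors (>= 2 samples).
#' @return Value in `[-1, 1]`.
#' @export
ari <- function(labels_true, labels_pred) {
  lb <- check_pair(labels_true, labels_pred, min_len = 2L)
  tab <- table(lb$a, lb$b)
  n <- length(lb$a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expected <- sum_a * sum_b / tot
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  unname((sum_ij - expected) / (max_index - expected))
}

# Munkres assignment on a square cost matrix; returns the column assigned to
# each row. O(n^3); cluster counts here are small.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  # columns are offset by one on the tape (index 1 is the dummy)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) assign[p[j]] <- j - 2L
  assign
}

#' Hungarian-matched macro F1
#'
#' Builds the contingency table between true classes and predicted clusters,
#' finds the overlap-maximizing one-to-one matching by the Hungarian
#' algorithm (padding with empty dummies when counts differ), computes a
#' binary F1 for each true class against its matched cluster, and returns
#' the macro average over true classes. A true class with no matched
#' non-empty cluster contributes 0.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return Value in `[0, 1]`.
#' @export
clustering_f1 <- function(labels_true, labels_pred) {
  lb <- check_pair(labels_true, labels_pred)
  tab <- unclass(table(lb$a, lb$b))
  kt <- nrow(tab)
  kp <- ncol(tab)
  kk <- max(kt, kp)
  overlap <- matrix(0, kk, kk)
  overlap[seq_len(kt), seq_len(kp)] <- tab
  match_col <- hungarian(-overlap) + 1L  # maximize overlap
  f1s <- numeric(kt)
  for (cidx in seq_len(kt)) {
    j <- match_col[cidx]
    tp <- if (j <= kp) overlap[cidx, j] else 0
    sz_true <- sum(tab[cidx, ])
    sz_pred <- if (j <= kp) sum(tab[, j]) else 0
    f1s[cidx] <- if (tp == 0) 0 else 2 * tp / (sz_true + sz_pred)
  }
  mean(f1s)
}

#' Evaluate a predicted clustering against truth
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return An `EvalResult` list with `nmi`, `ari`, `f1`, `n_clusters_pred`.
#' @export
evaluate_clustering <- function(labels_true, labels_pred) {
  list(nmi = nmi(labels_true, labels_pred),
       ari = ari(labels_true, labels_pred),
       f1 = clustering_f1(labels_true, labels_pred),
       n_clusters_pred = length(unique(labels_pred)))
}
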