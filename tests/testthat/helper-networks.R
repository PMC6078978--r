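# Shared fixture builders: small random and structured networks, all
# generated in code under explicit seeds.

rand_network <- function(n, seed, density = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n)
  if (density < 1) A[matrix(stats::runif(n * n), n) > density] <- 0
  W <- (A + t(A)) / 2
  diag(W) <- 0
  ids <- sprintf("n%03d", 1:n)  # zero-padded: lexicographic == numeric order
  dimnames(W) <- list(ids, ids)
  W
}

# Flat two-block network: within-block weight 1, between-block 0.
two_block_flat <- function(sizes = c(3, 3)) {
  lab <- rep(seq_along(sizes), sizes)
  W <- outer(lab, lab, function(a, b) as.numeric(a == b))
  dimnames(W) <- list(sprintf("n%d", seq_along(lab)), sprintf("n%d", seq_along(lab)))
  list(W = W, labels = lab)
}

# Build the doubly stochastic operator for a random network.
rand_operator <- function(n, seed, k = max(2, n %/% 3)) {
  localized_dsm(knn_transition(rand_network(n, seed), k))
}

expect_dsm <- function(M, tol = 1e-8) {
  expect_true(all(M >= -1e-12))
  expect_lt(max(abs(rowSums(M) - 1)), tol)
  expect_lt(max(abs(colSums(M) - 1)), tol)
  expect_lt(max(abs(M - t(M))), 1e-10)
}

# Independent brute-force oracles -------------------------------------------

# Top-k-and-normalize transition oracle: scan row i, pick i plus the k-1
# heaviest other entries (ascending-index tie-break), normalize.
oracle_knn_transition <- function(W, k) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in 1:n) {
    w <- W[i, ]
    pool <- setdiff(seq_len(n), i)
    pool <- pool[order(-w[pool], pool)]
    nb <- c(i, utils::head(pool, k - 1))
    s <- sum(w[nb])
    if (s > 0) for (j in nb) P[i, j] <- w[j] / s else P[i, i] <- 1
  }
  P
}

# Direct triple-loop summation of T[i,j] = sum_k P[i,k] P[j,k] / colsum_k.
oracle_localized_dsm <- function(P) {
  n <- nrow(P)
  cs <- colSums(P)
  Tm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    acc <- 0
    for (k in 1:n) if (cs[k] > 0) acc <- acc + P[i, k] * P[j, k] / cs[k]
    Tm[i, j] <- acc
  }
  Tm
}

# Entrywise double-sum diffusion step (the expanded form of the matrix
# update): W'[i,j] = alpha sum_k sum_l T[i,k] W[k,l] T[l,j] + (1-alpha) T[i,j].
oracle_diffusion_step <- function(T_op, W, alpha) {
  n <- nrow(T_op)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    acc <- 0
    for (k in 1:n) for (l in 1:n)
      acc <- acc + T_op[i, k] * W[k, l] * T_op[l, j]
    out[i, j] <- alpha * acc + (1 - alpha) * T_op[i, j]
  }
  out
}

# Contingency-table NMI from first principles (independent of nmi()).
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0; ha <- 0; hb <- 0
  for (x in ua) {
    px <- sum(a == x) / n
    ha <- ha - px * log(px)
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (px * sum(b == y) / n))
    }
  }
  for (y in ub) {
    py <- sum(b == y) / n
    hb <- hb - py * log(py)
  }
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

# Exhaustive positive-negative pair enumeration AUROC.
oracle_auroc <- function(scores, pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
  wins / (length(pos) * length(neg))
}
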