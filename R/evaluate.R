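#' Random walk with restart propagation
#'
#' Scores every node by its visitation probability under a weighted random
#' walk that restarts at the seed nodes with probability `restart_prob` at
#' each step. The stationary distribution of
#' `s <- (1 - r) * t(P) s + r * u` is found by power iteration, where `P` is
#' the row-normalized walk matrix of the network and `u` is uniform over the
#' seeds. Zero-degree nodes are restart-only: a walk arriving there teleports
#' back to the seeds. This is the standard propagation scheme used to spread
#' gene-function associations from annotated genes to the rest of an
#' interaction network.
#'
#' @param W symmetric non-negative weight matrix.
#' @param seeds non-empty node subset (character ids or integer indices).
#' @param restart_prob restart probability in (0, 1); default 0.5.
#' @param tol L1 convergence threshold of the power iteration.
#' @param max_iter iteration cap.
#' @return an `ne_propagation` list: `scores` (named, non-negative, sums to
#'   1), `restart_prob`, `seeds`, `iterations`, `residual` (L1 fixed-point
#'   residual).
#' @export
rwr_propagate <- function(W, seeds, restart_prob = 0.5,
                          tol = 1e-10, max_iter = 10000) {
  W <- as_weighted_network(W)
  if (length(seeds) == 0) stop_parameter("seed set must be non-empty")
  if (restart_prob <= 0 || restart_prob >= 1)
    stop_parameter("restart_prob must lie in (0, 1), got %g", restart_prob)
  n <- nrow(W)
  deg <- rowSums(W)
  if (all(deg == 0))
    stop_validation("network has no positive-degree node; nothing to propagate")
  idx <- resolve_nodes(seeds, W, "seed set")
  u <- numeric(n)
  u[idx] <- 1 / length(idx)
  # Row-normalized walk matrix; zero-degree rows restart to the seeds.
  P <- W / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- rep(u, each = sum(deg == 0))
  Pt <- t(P)
  r <- restart_prob
  s <- u
  res <- Inf
  iter <- 0L
  for (t in seq_len(max_iter)) {
    sn <- (1 - r) * as.vector(Pt %*% s) + r * u
    res <- sum(abs(sn - s))
    s <- sn
    iter <- t
    if (res < tol) break
  }
  s <- pmax(s, 0)
  s <- s / sum(s)
  names(s) <- node_ids(W)
  residual <- sum(abs((1 - r) * as.vector(Pt %*% s) + r * u - s))
  structure(
    list(scores = s, restart_prob = r, seeds = node_ids(W)[idx],
         iterations = iter, residual = residual),
    class = "ne_propagation")
}

#' @export
print.ne_propagation <- function(x, ...) {
  cat(sprintf("Random walk with restart (r = %g, %d seeds, %d nodes)\n",
              x$restart_prob, length(x$seeds), length(x$scores)))
  cat(sprintf("  converged in %d iterations (fixed-point L1 residual %.3g)\n",
              x$iterations, x$residual))
  invisible(x)
}

# Align two label vectors on a common node set; names, when present on both,
# define the correspondence.
align_labels <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop_validation("label vectors cover different node sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop_validation("label vectors differ in length (%d vs %d)",
                    length(a), length(b))
  }
  list(a = as.vector(a), b = as.vector(b))
}

#' Normalized mutual information between two partitions
#'
#' `I(a; b) / sqrt(H(a) H(b))` (natural log) from the joint contingency
#' table, in [0, 1]; 1 means the partitions match up to relabelling.
#' Conventions: `0 log 0 = 0`; two single-cluster partitions score 1; if
#' exactly one partition is a single cluster the mutual information is 0 and
#' so is the score. `normalization = "arithmetic"` switches to
#' `2 I / (H(a) + H(b))`, the other common variant.
#'
#' @param a,b integer (or factor) community labels; if both are named the
#'   names define node correspondence.
#' @param normalization `"geometric"` (default) or `"arithmetic"`.
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b, normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  al <- align_labels(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  denom <- if (normalization == "geometric") sqrt(ha * hb) else (ha + hb) / 2
  min(1, max(0, mi / denom))
}

#' Retrieval (identification) accuracy of a similarity network
#'
#' Treats every node as a query, ranks all other nodes by descending edge
#' weight to the query (ties broken by ascending node index), and averages
#' the fraction of the `top_m` retrievals that share the query's class
#' label. This is the standard identification-accuracy metric for
#' fine-grained retrieval on a similarity network.
#'
#' @param W symmetric non-negative weight matrix.
#' @param labels per-node class labels (named by node id, or positional).
#' @param top_m number of retrievals per query, `1 <= top_m <= n - 1`.
#' @return mean retrieval accuracy in [0, 1].
#' @export
retrieval_accuracy <- function(W, labels, top_m) {
  W <- as_weighted_network(W)
  n <- nrow(W)
  if (top_m < 1 || top_m > n - 1)
    stop_parameter("top_m must be in 1..%d, got %d", n - 1, top_m)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), node_ids(W)))
      stop_validation("label names do not match network node ids")
    labels <- labels[node_ids(W)]
  } else if (length(labels) != n) {
    stop_validation("need %d labels, got %d", n, length(labels))
  }
  labels <- as.vector(labels)
  acc <- vapply(seq_len(n), function(i) {
    w <- W[i, ]
    w[i] <- -Inf
    top <- order(-w, seq_len(n))[seq_len(top_m)]
    mean(labels[top] == labels[i])
  }, numeric(1))
  mean(acc)
}

#' Edge density of a node subset
#'
#' Sum of edge weights among the members divided by the number of possible
#' member pairs `m (m - 1) / 2`. Used to rank function-associated
#' subnetworks by internal connectivity in a denoised network.
#'
#' @param W symmetric non-negative weight matrix.
#' @param members node subset of size >= 2 (ids or indices).
#' @return the weighted edge density.
#' @export
subnetwork_edge_density <- function(W, members) {
  W <- as_weighted_network(W)
  idx <- resolve_nodes(members, W, "member set")
  m <- length(idx)
  if (m < 2) stop_parameter("member set needs at least 2 nodes, got %d", m)
  sub <- W[idx, idx]
  sum(sub[upper.tri(sub)]) / (m * (m - 1) / 2)
}

#' Rank-based AUROC of node scores
#'
#' Mann-Whitney estimator with midrank tie handling: the probability that a
#' uniformly drawn positive outranks a uniformly drawn negative, counting
#' ties as half. With `negatives = NULL` every non-positive node is a
#' negative, matching the gene-function evaluation setting.
#'
#' @param scores named (or positional) numeric node scores.
#' @param positives node subset of true positives (ids or indices).
#' @param negatives node subset of negatives; default: all non-positives.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, positives, negatives = NULL) {
  nm <- names(scores)
  to_idx <- function(set, what) {
    if (is.character(set)) {
      if (is.null(nm)) stop_validation("%s given as ids but scores unnamed", what)
      i <- match(set, nm)
      if (anyNA(i)) stop_validation("%s contains unknown ids", what)
      i
    } else as.integer(set)
  }
  pos <- to_idx(positives, "positive set")
  neg <- if (is.null(negatives)) setdiff(seq_along(scores), pos)
         else to_idx(negatives, "negative set")
  if (length(pos) == 0 || length(neg) == 0)
    stop_parameter("both positive and negative sets must be non-empty")
  if (length(intersect(pos, neg)) > 0)
    stop_parameter("positive and negative sets must be disjoint")
  x <- scores[c(pos, neg)]
  rk <- rank(x, ties.method = "average")
  np <- length(pos); nn <- length(neg)
  (sum(rk[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Leave-one-out cross-validation of network propagation
#'
#' For each positive node in turn, reseeds the random walk with restart on
#' the remaining positives and asks how well the held-out positive is ranked
#' against sampled negative nodes. The per-fold hit is the midrank fraction
#' of negatives scored below the held-out node; the mean over folds is a
#' leave-one-out AUROC. Deterministic given `seed`.
#'
#' @param W symmetric non-negative weight matrix.
#' @param positives node subset with >= 2 members.
#' @param restart_prob restart probability of the walk.
#' @param n_negatives negatives sampled per fold (capped at the available
#'   pool); `Inf` uses all non-positives.
#' @param seed integer seed for the negative sampling.
#' @return list with `auroc` (mean over folds) and `fold_auroc` (per
#'   held-out positive).
#' @export
rwr_loo_auroc <- function(W, positives, restart_prob = 0.5,
                          n_negatives = 50, seed = 1) {
  W <- as_weighted_network(W)
  pos <- resolve_nodes(positives, W, "positive set")
  if (length(pos) < 2)
    stop_parameter("leave-one-out needs >= 2 positives, got %d", length(pos))
  pool <- setdiff(seq_len(nrow(W)), pos)
  if (length(pool) == 0) stop_parameter("no negative nodes available")
  folds <- numeric(length(pos))
  with_preserved_rng(seed, {
    for (f in seq_along(pos)) {
      held <- pos[f]
      neg <- if (is.finite(n_negatives) && n_negatives < length(pool))
        sample(pool, n_negatives) else pool
      prop <- rwr_propagate(W, seeds = pos[-f], restart_prob = restart_prob)
      s <- prop$scores
      folds[f] <- mean((s[neg] < s[held]) + 0.5 * (s[neg] == s[held]))
    }
  })
  list(auroc = mean(folds), fold_auroc = folds)
}

#' Detect communities with Louvain modularity optimization
#'
#' Thin wrapper around [igraph::cluster_louvain()] on the weighted,
#' undirected graph of the matrix (diagonal dropped). Louvain is the
#' off-the-shelf community detector used to read topological domains and
#' modules out of raw and denoised networks.
#'
#' @param W symmetric non-negative weight matrix.
#' @param seed integer seed (Louvain's node sweep uses the R RNG).
#' @return named integer membership vector.
#' @export
detect_communities <- function(W, seed = 1) {
  W <- as_weighted_network(W)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_preserved_rng(seed, igraph::membership(igraph::cluster_louvain(g)))
  out <- as.integer(memb)
  names(out) <- node_ids(W)
  out
}

# Run `expr` under a locally seeded RNG without disturbing the caller's
# global RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
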