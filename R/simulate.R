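#' Generate a noisy block-structured similarity network
#'
#' Plants `n_blocks` communities and draws a symmetric weight matrix whose
#' entries are `max(0, base + noise)`: `base` is `within_weight` for pairs
#' in the same block and `between_weight` otherwise, and the noise is
#' i.i.d. Gaussian on the upper triangle, mirrored for symmetry. True
#' within-block edges are then independently zeroed with probability
#' `dropout`. The two corruption channels reproduce the failure modes seen
#' in measured biological networks: noise tails create superficially strong
#' spurious edges, dropout hides real connections. The diagonal is zero and
#' the output is exactly symmetric and reproducible given `seed`.
#'
#' Defaults (`n = 200`, 4 blocks, within 1.0, between 0.3, noise sd 0.5,
#' dropout 0.2) give a regime where Louvain community detection on the raw
#' network is imperfect, leaving headroom for denoising to show an effect.
#'
#' @param n node count.
#' @param n_blocks number of planted communities.
#' @param block_sizes optional explicit sizes summing to `n`; default as
#'   balanced as possible.
#' @param within_weight mean similarity inside a block.
#' @param between_weight mean similarity across blocks; must be smaller
#'   than `within_weight` and non-negative.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param dropout probability of zeroing a true within-block edge, in [0, 1).
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @return list with `network` (n x n matrix, node ids `n001...`) and
#'   `labels` (named integer block memberships).
#' @examples
#' sim <- generate_block_network(n = 40, n_blocks = 2, seed = 7)
#' table(sim$labels)
#' @export
generate_block_network <- function(n, n_blocks,
                                   block_sizes = NULL,
                                   within_weight = 1.0,
                                   between_weight = 0.3,
                                   noise_sd = 0.5,
                                   dropout = 0.2,
                                   seed = 1) {
  if (n < 1) stop_parameter("n must be >= 1")
  if (n_blocks < 1 || n_blocks > n)
    stop_parameter("n_blocks must be in 1..%d, got %d", n, n_blocks)
  if (is.null(block_sizes)) {
    block_sizes <- rep(n %/% n_blocks, n_blocks)
    extra <- n %% n_blocks
    if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1L
  }
  if (sum(block_sizes) != n)
    stop_parameter("block sizes sum to %d, expected n = %d", sum(block_sizes), n)
  if (any(block_sizes < 1)) stop_parameter("every block needs >= 1 node")
  check_noise_spec(within_weight, between_weight, noise_sd, dropout)

  labels <- rep(seq_len(n_blocks), times = block_sizes)
  W <- with_preserved_rng(seed, {
    base <- matrix(between_weight, n, n)
    same <- outer(labels, labels, "==")
    base[same] <- within_weight
    noisy_symmetric(base, noise_sd, dropout_mask = same, dropout = dropout)
  })
  ids <- sprintf("n%0*d", nchar(n), seq_len(n))
  dimnames(W) <- list(ids, ids)
  names(labels) <- ids
  list(network = W, labels = labels)
}

check_noise_spec <- function(within_weight, between_weight, noise_sd, dropout) {
  if (!(within_weight > between_weight))
    stop_parameter("within_weight (%g) must exceed between_weight (%g)",
                   within_weight, between_weight)
  if (between_weight < 0) stop_parameter("between_weight must be >= 0")
  if (noise_sd < 0) stop_parameter("noise_sd must be >= 0")
  if (dropout < 0 || dropout >= 1)
    stop_parameter("dropout must lie in [0, 1), got %g", dropout)
  invisible(TRUE)
}

# Symmetric noise + truncation at zero + within-structure dropout, acting on
# the upper triangle and mirrored. `dropout_mask` marks the "true" edges
# eligible for dropout. Diagonal forced to zero.
noisy_symmetric <- function(base, noise_sd, dropout_mask, dropout) {
  n <- nrow(base)
  W <- base
  up <- upper.tri(W)
  if (noise_sd > 0) W[up] <- W[up] + stats::rnorm(sum(up), 0, noise_sd)
  W[up] <- pmax(0, W[up])
  if (dropout > 0) {
    drop_here <- up & dropout_mask
    W[drop_here] <- W[drop_here] *
      (stats::runif(sum(drop_here)) >= dropout)
  }
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

#' Generate a two-level hierarchical block network
#'
#' Nested planted structure mimicking hierarchically organized contact
#' maps: every super-block splits into `sub_blocks_per_block` sub-blocks,
#' and expected weights come in three tiers — `within_weight` inside a
#' sub-block, the midpoint `(within_weight + between_weight)/2` between
#' sub-blocks of the same super-block, and `between_weight` across
#' super-blocks. Noise and dropout act as in [generate_block_network()],
#' with dropout applied to the finest (within-sub-block) edges.
#'
#' @inheritParams generate_block_network
#' @param sub_blocks_per_block number of sub-blocks per super-block, >= 2.
#' @return list with `network`, `super_labels` and `sub_labels` (both named
#'   integer vectors).
#' @export
generate_hierarchical_block_network <- function(n, n_blocks,
                                                sub_blocks_per_block = 2,
                                                within_weight = 1.0,
                                                between_weight = 0.3,
                                                noise_sd = 0.5,
                                                dropout = 0.2,
                                                seed = 1) {
  if (sub_blocks_per_block < 2)
    stop_parameter("sub_blocks_per_block must be >= 2, got %d",
                   sub_blocks_per_block)
  if (n_blocks < 1) stop_parameter("n_blocks must be >= 1")
  n_sub <- n_blocks * sub_blocks_per_block
  if (n < n_sub)
    stop_validation("n = %d too small to subdivide %d blocks into %d sub-blocks",
                    n, n_blocks, sub_blocks_per_block)
  check_noise_spec(within_weight, between_weight, noise_sd, dropout)

  sub_sizes <- rep(n %/% n_sub, n_sub)
  extra <- n %% n_sub
  if (extra > 0) sub_sizes[seq_len(extra)] <- sub_sizes[seq_len(extra)] + 1L
  sub_labels <- rep(seq_len(n_sub), times = sub_sizes)
  super_labels <- (sub_labels - 1L) %/% sub_blocks_per_block + 1L
  mid_weight <- (within_weight + between_weight) / 2

  W <- with_preserved_rng(seed, {
    base <- matrix(between_weight, n, n)
    same_super <- outer(super_labels, super_labels, "==")
    same_sub <- outer(sub_labels, sub_labels, "==")
    base[same_super] <- mid_weight
    base[same_sub] <- within_weight
    noisy_symmetric(base, noise_sd, dropout_mask = same_sub, dropout = dropout)
  })
  ids <- sprintf("n%0*d", nchar(n), seq_len(n))
  dimnames(W) <- list(ids, ids)
  names(sub_labels) <- ids
  names(super_labels) <- ids
  list(network = W, super_labels = super_labels, sub_labels = sub_labels)
}
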