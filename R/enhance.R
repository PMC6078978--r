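#' KNN-truncated transition matrix
#'
#' Builds the row-stochastic transition matrix `P` over each node's
#' k-nearest-neighbour set. The neighbourhood of node i always contains i
#' itself plus the k-1 strongest remaining edges of row i (ties broken by
#' ascending node index for determinism). Rows whose neighbourhood carries
#' zero total weight are made self-absorbing (`P[i, i] = 1`) so isolated
#' nodes stay isolated and the downstream doubly stochastic construction
#' remains well defined.
#'
#' @param W symmetric non-negative weight matrix (validated via
#'   [as_weighted_network()]).
#' @param k neighbourhood size, counting the node itself; `1 <= k <= n`.
#' @return n x n matrix `P` with row sums 1 and at most `k` nonzeros per
#'   row; attributes `k` and `neighborhoods` (list of index vectors).
#' @export
knn_transition <- function(W, k) {
  W <- as_weighted_network(W)
  n <- nrow(W)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n)
    stop_parameter("k must be an integer in 1..%d, got %s", n, format(k))
  P <- matrix(0, n, n, dimnames = dimnames(W))
  nbhd <- vector("list", n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    ord <- order(-w, seq_len(n))
    others <- ord[ord != i]
    nb <- sort(c(i, others[seq_len(k - 1L)]))
    s <- sum(w[nb])
    if (s > 0) P[i, nb] <- w[nb] / s else P[i, i] <- 1
    nbhd[[i]] <- nb
  }
  attr(P, "k") <- k
  attr(P, "neighborhoods") <- nbhd
  P
}

#' Localized doubly stochastic operator
#'
#' Second construction step: `T[i, j] = sum_k P[i, k] P[j, k] / colsum_k(P)`,
#' with the convention 0/0 -> 0 for all-zero columns. For any row-stochastic
#' `P` the result is a symmetric doubly stochastic matrix (DSM): entries are
#' non-negative and every row and column sums to 1 (column sums telescope to
#' the row sums of P). This operator drives the diffusion; its spectrum lies
#' in [-1, 1] and eigenvalue 1 has multiplicity equal to the number of
#' connected components of the KNN graph.
#'
#' @param P row-stochastic matrix from [knn_transition()].
#' @return symmetric doubly stochastic n x n matrix.
#' @export
localized_dsm <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop_validation("P must be a square matrix")
  cs <- colSums(P)
  scal <- ifelse(cs > 0, 1 / cs, 0)
  Tm <- tcrossprod(P, sweep(P, 2, scal, "*"))
  Tm <- (Tm + t(Tm)) / 2
  dimnames(Tm) <- dimnames(P)
  Tm
}

#' Eigenvalue map of the converged diffusion
#'
#' The diffusion preserves the eigenvectors of the doubly stochastic
#' operator and maps each eigenvalue `lam` to
#' `f(lam) = (1 - alpha) * lam / (1 - alpha * lam^2)`. Since
#' `1 - alpha * lam^2 >= 1 - alpha > 0` for `|lam| <= 1` and
#' `0 < alpha < 1`, the map is finite on the whole spectrum; 0 and 1 are
#' fixed points, and on (0, 1) the map shrinks, with smaller eigenvalues
#' shrunk at a higher rate — this is what widens the top eigengap.
#'
#' @param lam numeric vector of eigenvalues in `[-1, 1]` (a roundoff slack
#'   of 1e-9 is tolerated, values are clipped).
#' @param alpha regularization weight in (0, 1).
#' @return mapped eigenvalues, same length as `lam`.
#' @export
map_eigenvalue <- function(lam, alpha) {
  check_alpha(alpha)
  if (any(abs(lam) > 1 + 1e-9))
    ne_stop("ne_parameter_error",
            "eigenvalue outside [-1, 1]: %g", lam[which.max(abs(lam))])
  lam <- pmin(1, pmax(-1, lam))
  (1 - alpha) * lam / (1 - alpha * lam^2)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop_parameter("alpha must lie strictly in (0, 1), got %s", format(alpha))
  invisible(alpha)
}

new_diffusion_result <- function(denoised, iterations, residuals, mode,
                                 converged = TRUE, dsm_history = NULL) {
  structure(
    list(denoised = denoised,
         iterations = iterations,
         residuals = residuals,
         mode = mode,
         converged = converged,
         dsm_check = dsm_deviation(denoised),
         dsm_history = dsm_history),
    class = "ne_diffusion")
}

# Max deviation of any row or column sum from 1.
dsm_deviation <- function(M) {
  max(abs(c(rowSums(M), colSums(M)) - 1))
}

#' @export
print.ne_diffusion <- function(x, ...) {
  cat(sprintf("Network diffusion result (%s mode)\n", x$mode))
  cat(sprintf("  nodes: %d\n", nrow(x$denoised)))
  cat(sprintf("  iterations: %d%s\n", x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  row/col-sum deviation from 1: %.3g\n", x$dsm_check))
  invisible(x)
}

#' Iterative diffusion over the doubly stochastic operator
#'
#' Iterates `W[t+1] = alpha * T W[t] T + (1 - alpha) * T` until the relative
#' Frobenius change drops below `tol` or `max_iter` is reached. The update is
#' a contraction with factor at most `alpha` in the fixed-point error, so the
#' limit is unique and independent of the start `W0`. The default start
#' `W0 = T` keeps every iterate a symmetric DSM.
#'
#' @param T_op symmetric doubly stochastic operator from [localized_dsm()].
#' @param alpha regularization weight in (0, 1); larger alpha weights the
#'   diffused signal more, smaller alpha stays closer to the local operator.
#' @param tol convergence threshold on the relative Frobenius change.
#' @param max_iter iteration cap; hitting it raises a non-convergence
#'   warning, never an error, and the last iterate is returned.
#' @param W0 optional symmetric start matrix (defaults to `T_op`).
#' @param track_dsm if `TRUE`, record each iterate's max row/column-sum
#'   deviation from 1 in `dsm_history`.
#' @return an `ne_diffusion` list: `denoised`, `iterations`, `residuals`,
#'   `mode`, `converged`, `dsm_check`, `dsm_history`.
#' @export
diffuse_iterative <- function(T_op, alpha = 0.9, tol = 1e-6, max_iter = 100,
                              W0 = NULL, track_dsm = FALSE) {
  check_alpha(alpha)
  if (tol <= 0) stop_parameter("tol must be positive")
  if (max_iter < 1) stop_parameter("max_iter must be >= 1")
  if (is.null(W0)) {
    W <- T_op
  } else {
    if (!identical(dim(W0), dim(T_op)))
      stop_validation("W0 dimension %dx%d does not match operator %dx%d",
                      nrow(W0), ncol(W0), nrow(T_op), ncol(T_op))
    W <- (W0 + t(W0)) / 2
  }
  residuals <- numeric(0)
  dsm_history <- if (track_dsm) dsm_deviation(W) else NULL
  res <- Inf
  iter <- 0L
  for (t in seq_len(max_iter)) {
    Wn <- alpha * (T_op %*% W %*% T_op) + (1 - alpha) * T_op
    res <- norm(Wn - W, "F") / max(norm(W, "F"), .Machine$double.eps)
    residuals <- c(residuals, res)
    if (track_dsm) dsm_history <- c(dsm_history, dsm_deviation(Wn))
    W <- Wn
    iter <- t
    if (res < tol) break
  }
  converged <- res < tol
  if (!converged)
    warn_ne("ne_nonconvergence_warning",
            "diffusion did not reach tol %g in %d iterations (last change %g)",
            tol, max_iter, res)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(T_op)
  new_diffusion_result(W, iter, residuals, "iterative", converged, dsm_history)
}

#' Closed-form solution of the diffusion
#'
#' The fixed point of the iterative update has the same eigenvectors as the
#' operator, with each eigenvalue mapped through [map_eigenvalue()]. This
#' computes the symmetric eigendecomposition `T = V L V'` and returns
#' `W* = V f(L) V'`, symmetrized to absorb floating-point asymmetry.
#' Eigenvalues are clipped to [-1, 1] before mapping to guard |lam| = 1 + eps
#' roundoff.
#'
#' @inheritParams diffuse_iterative
#' @return an `ne_diffusion` result with `iterations = 0`.
#' @export
diffuse_closed_form <- function(T_op, alpha = 0.9) {
  check_alpha(alpha)
  eig <- tryCatch(eigen(T_op, symmetric = TRUE),
                  error = function(e) stop_numerical(
                    "eigendecomposition failed: %s", conditionMessage(e)))
  lam <- pmin(1, pmax(-1, eig$values))
  W <- eig$vectors %*% (map_eigenvalue(lam, alpha) * t(eig$vectors))
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(T_op)
  new_diffusion_result(W, 0L, numeric(0), "closed_form")
}

#' Map a denoised network back to the input weight scale
#'
#' The converged diffusion output is doubly stochastic, so all node degrees
#' equal 1. When downstream analysis needs the original scale, the input
#' degrees `d[i] = sum_j W[i, j]` (recorded before enhancement) are restored
#' by the symmetric scaling `D^{1/2} W* D^{1/2}`. Zero-degree nodes keep
#' zero rows and columns. The contract is symmetry and restoration of the
#' total weight scale, not exact row-sum equality. The alternative
#' `method = "row_scale"` applies `D W*` and re-symmetrizes as
#' `(D W* + W* D)/2`.
#'
#' @param W_star denoised matrix (or an `ne_diffusion` result).
#' @param W_input the original weight matrix whose degrees set the scale.
#' @param method `"sqrt_degree"` (default) or `"row_scale"`.
#' @return rescaled symmetric matrix.
#' @export
rescale_to_input_degrees <- function(W_star, W_input,
                                     method = c("sqrt_degree", "row_scale")) {
  method <- match.arg(method)
  if (inherits(W_star, "ne_diffusion")) W_star <- W_star$denoised
  if (!identical(dim(W_star), dim(W_input)))
    stop_validation("denoised %dx%d and input %dx%d dimensions differ",
                    nrow(W_star), ncol(W_star), nrow(W_input), ncol(W_input))
  d <- rowSums(W_input)
  out <- if (method == "sqrt_degree") {
    s <- sqrt(d)
    s * W_star * rep(s, each = nrow(W_star))
  } else {
    DW <- d * W_star
    (DW + t(DW)) / 2
  }
  dimnames(out) <- dimnames(W_star)
  out
}

default_k <- function(n) max(1L, min(n, min(20L, max(2L, as.integer(ceiling(n / 10))))))

#' Enhance (denoise) a weighted network
#'
#' Full pipeline: build the KNN transition matrix, form the localized doubly
#' stochastic operator, run the diffusion (closed form by default, exact and
#' fast; iterative as an option), optionally rescale to the input degree
#' scale, then zero the diagonal (self-edges are not reported) and clip
#' vanishing negative roundoff to 0. Node ids are preserved in order.
#' Because the operator is built from row-normalized quantities, the
#' pre-rescale output is invariant to multiplying the input by any positive
#' constant.
#'
#' @param W symmetric non-negative weight matrix.
#' @param alpha regularization weight in (0, 1); default 0.9.
#' @param k KNN size (counting the node itself); default
#'   `min(20, max(2, ceiling(n/10)))`, capped at n.
#' @param mode `"closed_form"` (default) or `"iterative"`.
#' @param tol,max_iter iterative-mode convergence controls.
#' @param rescale if `TRUE`, map the result back to the input degree scale.
#' @param rescale_method passed to [rescale_to_input_degrees()].
#' @param details if `TRUE`, return a list with the denoised network plus
#'   the intermediate operator and diffusion result.
#' @return the denoised weight matrix (or a detail list).
#' @examples
#' sim <- generate_block_network(n = 60, n_blocks = 3, seed = 1)
#' W_hat <- enhance(sim$network, alpha = 0.9, k = 10)
#' @export
enhance <- function(W, alpha = 0.9, k = NULL,
                    mode = c("closed_form", "iterative"),
                    tol = 1e-6, max_iter = 100,
                    rescale = FALSE,
                    rescale_method = c("sqrt_degree", "row_scale"),
                    details = FALSE) {
  mode <- match.arg(mode)
  W <- as_weighted_network(W)
  n <- nrow(W)
  if (is.null(k)) k <- default_k(n)
  P <- knn_transition(W, k)
  T_op <- localized_dsm(P)
  diff_res <- if (mode == "closed_form") {
    diffuse_closed_form(T_op, alpha)
  } else {
    diffuse_iterative(T_op, alpha, tol = tol, max_iter = max_iter)
  }
  out <- diff_res$denoised
  if (rescale) out <- rescale_to_input_degrees(out, W, match.arg(rescale_method))
  diag(out) <- 0
  if (min(out) < -1e-9)
    stop_numerical("enhanced network has a negative entry %g beyond roundoff",
                   min(out))
  out[out < 0] <- 0
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(W)
  if (details) {
    list(network = out, operator = T_op, transition = P,
         diffusion = diff_res, k = attr(P, "k"), alpha = alpha)
  } else {
    out
  }
}
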