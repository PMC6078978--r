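#' Eigengap of a symmetric matrix
#'
#' Difference between consecutive eigenvalues of the descending-sorted
#' spectrum; `index = 1` is the top gap `lambda_1 - lambda_2`. Large top
#' gaps are associated with cleanly separable community structure, and the
#' diffusion is designed to widen them.
#'
#' @param M symmetric numeric matrix.
#' @param index gap position, `1 <= index <= n - 1`.
#' @return the gap `lambda_index - lambda_{index+1}`.
#' @export
eigengap <- function(M, index) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop_validation("eigengap needs a square matrix")
  n <- nrow(M)
  if (index < 1 || index >= n)
    stop_parameter("eigengap index must be in 1..%d, got %d", n - 1, index)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[index] - ev[index + 1]
}

# Split descending eigenvalue vectors into clusters whose internal gaps are
# below `gap_tol`; individual eigenvectors are not identifiable inside such a
# cluster, so drift is measured on the invariant subspace instead. When a
# second spectrum is given (the mapped eigenvalues, whose gaps the map can
# contract), a split requires separation in both spectra.
eigenvalue_clusters <- function(values, gap_tol = 1e-6, values2 = NULL) {
  n <- length(values)
  if (n == 0) return(list())
  sep <- -diff(values) > gap_tol
  if (!is.null(values2)) sep <- sep & (-diff(values2) > gap_tol)
  breaks <- which(sep)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  Map(seq.int, starts, ends)
}

# Worst-case 1 - min singular value of V1'V2 across matched eigenvalue
# clusters: 0 when the two bases span identical invariant subspaces.
subspace_drift <- function(V1, V2, clusters) {
  drift <- 0
  for (cl in clusters) {
    sv <- svd(crossprod(V1[, cl, drop = FALSE], V2[, cl, drop = FALSE]))$d
    drift <- max(drift, 1 - min(sv))
  }
  drift
}

#' Spectral report: before/after eigenstructure of an enhancement
#'
#' Certifies, on a concrete network, the theoretical behaviour of the
#' diffusion: the denoised matrix `W*` shares the operator's eigenvectors,
#' its eigenvalues are the [map_eigenvalue()] images of the operator's, the
#' multiplicity of eigenvalue 1 (one per connected component) is unchanged,
#' and gaps between large eigenvalues grow. Eigenvalue clusters separated by
#' less than `gap_tol` are compared as invariant subspaces via principal
#' angles, since individual eigenvectors are not identifiable there.
#'
#' @param T_op the doubly stochastic operator before diffusion.
#' @param W_star the denoised matrix.
#' @param alpha regularization weight used for the diffusion.
#' @param gap_tol eigenvalue separation below which eigenvectors are
#'   compared as subspaces.
#' @return an `ne_spectral_report` list: sorted eigenvalues and consecutive
#'   gaps before and after, `component_count` (multiplicity of eigenvalue 1
#'   within 1e-8), `max_eigenvector_drift`, and `max_fmap_deviation`
#'   (worst absolute difference between the eigenvalues of `W*` and the
#'   mapped eigenvalues of the operator).
#' @export
spectral_report <- function(T_op, W_star, alpha, gap_tol = 1e-6) {
  check_alpha(alpha)
  if (!identical(dim(T_op), dim(W_star)))
    stop_validation("operator %dx%d and W* %dx%d dimensions differ",
                    nrow(T_op), ncol(T_op), nrow(W_star), ncol(W_star))
  eb <- eigen(T_op, symmetric = TRUE)
  ea <- eigen(W_star, symmetric = TRUE)
  values_before <- eb$values
  values_after <- ea$values
  if (any(abs(values_before) > 1 + 1e-9))
    stop_numerical("operator eigenvalue outside [-1, 1]: %g",
                   values_before[which.max(abs(values_before))])
  mapped <- map_eigenvalue(values_before, alpha)
  # f is monotone on [0,1] but not on [-1,1]; compare after sorting both.
  fmap_dev <- max(abs(sort(values_after) - sort(mapped)))
  clusters <- eigenvalue_clusters(values_before, gap_tol, values2 = mapped)
  drift <- subspace_drift(eb$vectors, ea$vectors, clusters)
  structure(
    list(eigenvalues_before = values_before,
         eigenvalues_after = values_after,
         eigengaps_before = -diff(values_before),
         eigengaps_after = -diff(values_after),
         component_count = sum(abs(values_before - 1) <= 1e-8),
         max_eigenvector_drift = drift,
         max_fmap_deviation = fmap_dev,
         alpha = alpha),
    class = "ne_spectral_report")
}

#' @export
print.ne_spectral_report <- function(x, top = 5, ...) {
  n <- length(x$eigenvalues_before)
  top <- min(top, n)
  cat(sprintf("Spectral report (alpha = %g, n = %d)\n", x$alpha, n))
  cat("  top eigenvalues before:", sprintf("%.4f", x$eigenvalues_before[1:top]), "\n")
  cat("  top eigenvalues after: ", sprintf("%.4f", x$eigenvalues_after[1:top]), "\n")
  cat(sprintf("  components (eigenvalue-1 multiplicity): %d\n", x$component_count))
  cat(sprintf("  max eigenvector drift: %.3g\n", x$max_eigenvector_drift))
  cat(sprintf("  max |eig(W*) - f(eig(T))|: %.3g\n", x$max_fmap_deviation))
  invisible(x)
}
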