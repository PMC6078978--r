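# Condition helpers. Every user-facing failure is classed so the CLI can map
# it to an exit code: validation/parse -> 2, numerical -> 3, non-convergence
# is a warning class, not an error.

ne_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ne_error")))
}

stop_validation <- function(fmt, ...) ne_stop("ne_validation_error", fmt, ...)
stop_parameter  <- function(fmt, ...) ne_stop("ne_parameter_error", fmt, ...)
stop_numerical  <- function(fmt, ...) ne_stop("ne_numerical_error", fmt, ...)

warn_ne <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "ne_warning")))
}

#' Validate (and lightly repair) a weighted network matrix
#'
#' A weighted network is a square, symmetric, non-negative numeric matrix.
#' Node identifiers are carried in the dimnames; when absent, `n1 ... nN`
#' are assigned. Asymmetry up to `sym_tol` is absorbed by averaging
#' `(W + t(W))/2`; larger asymmetry triggers a warning before averaging.
#' Negative entries and non-finite values are hard errors, because the
#' doubly stochastic construction requires a non-negative matrix.
#'
#' @param W square numeric matrix of non-negative edge weights.
#' @param sym_tol maximum entrywise asymmetry accepted silently.
#' @return the validated matrix, symmetrized, with node ids in dimnames.
#' @export
as_weighted_network <- function(W, sym_tol = 1e-6) {
  if (inherits(W, "Matrix")) W <- as.matrix(W)
  if (!is.matrix(W) || !is.numeric(W))
    stop_validation("network must be a numeric matrix, got %s", class(W)[1])
  if (nrow(W) != ncol(W))
    stop_validation("network matrix must be square, got %d x %d", nrow(W), ncol(W))
  if (any(!is.finite(W)))
    stop_validation("network contains NaN/Inf at %d entries", sum(!is.finite(W)))
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_validation("network has %d negative entries; first at (%d, %d) = %g",
                    nrow(neg), neg[1, 1], neg[1, 2], W[neg[1, 1], neg[1, 2]])
  asym <- max(abs(W - t(W)))
  if (asym > sym_tol)
    warn_ne("ne_asymmetry_warning",
            "input asymmetry %g exceeds %g; symmetrizing as (W + t(W))/2",
            asym, sym_tol)
  W <- (W + t(W)) / 2
  ids <- rownames(W)
  if (is.null(ids)) ids <- sprintf("n%d", seq_len(nrow(W)))
  if (anyDuplicated(ids))
    stop_validation("duplicated node identifiers: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(W) <- list(ids, ids)
  W
}

node_ids <- function(W) rownames(W)

# Resolve a node subset given as character ids or integer indices to indices.
resolve_nodes <- function(nodes, W, what = "node set") {
  n <- nrow(W)
  if (is.character(nodes)) {
    idx <- match(nodes, node_ids(W))
    if (anyNA(idx))
      stop_validation("%s contains unknown node ids: %s", what,
                      paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1 | idx > n))
      stop_parameter("%s indices out of range 1..%d", what, n)
  }
  if (anyDuplicated(idx))
    stop_parameter("%s contains duplicated nodes", what)
  idx
}
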