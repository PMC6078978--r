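#' Read a weighted network from file
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{`edgelist`}{tab-separated `node_a  node_b  weight` rows, one
#'     undirected edge per row; duplicate pairs (in either orientation) are
#'     summed; node ids are sorted lexicographically for a deterministic
#'     ordering.}
#'   \item{`dense`}{tab-separated matrix with a header row and a leading
#'     column of node ids; ragged rows are a parse error.}
#'   \item{`mtx`}{MatrixMarket coordinate format, 1-based indices, read via
#'     the Matrix package; node ids are synthesized as `n1..nN` since the
#'     format carries none.}
#' }
#' All readers symmetrize the result as `(W + t(W))/2`, warning when the
#' asymmetry exceeds 1e-6; negative weights are a hard error reported with
#' the offending line.
#'
#' @param path file to read.
#' @param format one of `"edgelist"`, `"dense"`, `"mtx"`.
#' @param delimiter field separator for the text dialects (default TAB).
#' @return weight matrix with node ids in dimnames.
#' @export
read_network <- function(path, format = c("edgelist", "dense", "mtx"),
                         delimiter = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  switch(format,
         edgelist = read_edgelist(path, delimiter),
         dense = read_dense(path, delimiter),
         mtx = read_mtx(path))
}

read_edgelist <- function(path, delimiter) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_validation("empty edge list: %s", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop_validation("parse error in %s line %d: expected 3 fields, got %d",
                    path, bad[1], length(parts[[bad[1]]]))
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (anyNA(w))
    stop_validation("parse error in %s line %d: non-numeric weight",
                    path, which(is.na(w))[1])
  if (any(w < 0))
    stop_validation("negative weight in %s line %d", path, which(w < 0)[1])
  ids <- sort(unique(c(a, b)))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(a, ids)
  ib <- match(b, ids)
  for (e in seq_along(w)) {
    if (ia[e] == ib[e]) {
      W[ia[e], ia[e]] <- W[ia[e], ia[e]] + w[e]
    } else {
      W[ia[e], ib[e]] <- W[ia[e], ib[e]] + w[e]
      W[ib[e], ia[e]] <- W[ib[e], ia[e]] + w[e]
    }
  }
  as_weighted_network(W)
}

read_dense <- function(path, delimiter) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_validation("parse error in %s: %s",
                                        path, conditionMessage(e)))
  W <- as.matrix(df)
  if (!is.numeric(W)) stop_validation("non-numeric entries in %s", path)
  if (nrow(W) != ncol(W))
    stop_validation("dense matrix in %s is %d x %d, expected square",
                    path, nrow(W), ncol(W))
  if (!identical(rownames(W), colnames(W)))
    stop_validation("row and column ids disagree in %s", path)
  as_weighted_network(W)
}

read_mtx <- function(path) {
  M <- tryCatch(Matrix::readMM(path),
                error = function(e) stop_validation(
                  "MatrixMarket parse error in %s: %s", path,
                  conditionMessage(e)))
  W <- as.matrix(M)
  dimnames(W) <- NULL
  as_weighted_network(W)
}

#' Write a weighted network to file
#'
#' Inverse of [read_network()], same three dialects. Edge-list output emits
#' each undirected edge once (`i < j`, lexicographic id order) with 10
#' significant digits, omitting zero-weight pairs; self-loops (diagonal
#' entries) are written as `id id w`. Sparse outputs (`edgelist`, `mtx`)
#' treat weights below 1e-12 as exact zeros — the enhanced operator is
#' sparse up to roundoff — while `dense` keeps full precision.
#'
#' @param W weight matrix with node ids in dimnames.
#' @param path destination file.
#' @param format one of `"edgelist"`, `"dense"`, `"mtx"`.
#' @param delimiter field separator for the text dialects.
#' @return `path`, invisibly.
#' @export
write_network <- function(W, path, format = c("edgelist", "dense", "mtx"),
                          delimiter = "\t") {
  format <- match.arg(format)
  W <- as_weighted_network(W)
  switch(format,
         edgelist = write_edgelist(W, path, delimiter),
         dense = write_dense(W, path, delimiter),
         mtx = write_mtx(W, path))
  invisible(path)
}

write_edgelist <- function(W, path, delimiter) {
  W[abs(W) < 1e-12] <- 0
  ids <- node_ids(W)
  keep <- which(upper.tri(W, diag = TRUE) & W != 0, arr.ind = TRUE)
  lines <- if (nrow(keep) > 0) {
    ord <- order(keep[, 1], keep[, 2])
    keep <- keep[ord, , drop = FALSE]
    paste(ids[keep[, 1]], ids[keep[, 2]],
          sprintf("%.10g", W[keep]), sep = delimiter)
  } else character(0)
  writeLines(lines, path)
}

write_dense <- function(W, path, delimiter) {
  utils::write.table(W, path, sep = delimiter, quote = FALSE,
                     row.names = TRUE, col.names = NA)
}

write_mtx <- function(W, path) {
  W[abs(W) < 1e-12] <- 0
  Matrix::writeMM(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                  path)
}

#' Read node labels from a two-column TSV (`node_id  label`)
#'
#' @param path file with one `id<TAB>label` pair per line.
#' @return named integer label vector (labels coerced via factor when not
#'   already integer).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (anyDuplicated(df$id))
    stop_validation("duplicated node ids in %s", path)
  lab <- df$label
  if (!is.integer(lab)) lab <- as.integer(factor(lab))
  names(lab) <- df$id
  lab
}

#' Write node labels as a two-column TSV
#'
#' @param labels named label vector.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (is.null(names(labels)))
    stop_validation("labels must be named by node id")
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}
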