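#' Cosine distance between two co-occurrence vectors
#'
#' `1 - (A . B) / (||A|| ||B||)`: zero for proportional non-negative vectors,
#' 1 for orthogonal ones, at most 2. Insensitive to overall frequency scale.
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return the cosine distance, a scalar in `[0, 2]`.
#' @examples
#' cosine_distance(c(1, 0, 9), c(0, 10, 90)) # ~0.012
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for zero-norm vectors")
  1 - sum(a * b) / (na * nb)
}

#' Per-column value ranges of a co-occurrence matrix
#'
#' Maximum and minimum of each column over all word rows (zeros included),
#' used to scale the numeric-overlap distance.
#'
#' @param m a matrix, a sparse `Matrix`, or a `cooccurrence_matrix`.
#' @return list with numeric vectors `max`, `min`, `range` (per column).
#' @export
column_ranges <- function(m) {
  if (inherits(m, "cooccurrence_matrix")) m <- m$counts
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    nnz <- diff(m@p)
    nr <- nrow(m)
    j <- rep.int(seq_len(ncol(m)), nnz)
    mx <- rep(0, ncol(m)); mn <- rep(0, ncol(m))
    if (length(m@x) > 0) {
      mx_nz <- vapply(split(m@x, j), max, numeric(1))
      mn_nz <- vapply(split(m@x, j), min, numeric(1))
      idx <- as.integer(names(mx_nz))
      mx[idx] <- pmax(mx_nz, ifelse(nnz[idx] < nr, 0, -Inf))
      mn[idx] <- pmin(mn_nz, ifelse(nnz[idx] < nr, 0, Inf))
    }
  } else {
    m <- as.matrix(m)
    mx <- apply(m, 2, max)
    mn <- apply(m, 2, min)
  }
  list(max = mx, min = mn, range = mx - mn)
}

#' Numeric-overlap distance between two co-occurrence vectors
#'
#' Sum over columns of `|A_i - B_i| / (max(i) - min(i))`, where the per-column
#' maxima and minima are taken over all rows of the current matrix. A column
#' with zero range contributes 0. Unlike cosine, this distance is sensitive to
#' absolute frequency differences.
#'
#' @param a,b numeric vectors of equal length.
#' @param ranges result of [column_ranges()] over the matrix the vectors
#'   belong to.
#' @return non-negative scalar; 0 iff `a == b` on all columns with range > 0.
#' @examples
#' rng <- column_ranges(rbind(c(1, 0, 9), c(0, 10, 90), c(50, 30, 2)))
#' numeric_overlap_distance(c(1, 0, 9), c(0, 10, 90), rng)
#' @export
numeric_overlap_distance <- function(a, b, ranges) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(ranges$range) != length(a))
    stop("column ranges do not match vector length")
  r <- ranges$range
  term <- ifelse(r > 0, abs(a - b) / r, 0)
  sum(term)
}

# Full pairwise distance matrix between the rows of a co-occurrence matrix.
# cosine: via sparse cross-product; numeric_overlap: columns scaled by 1/range
# (zero-range columns dropped to a zero factor), then sparse pairwise L1.
pairwise_distances <- function(matrix, metric = c("cosine", "numeric_overlap")) {
  metric <- match.arg(metric)
  m <- matrix$counts
  if (metric == "cosine") {
    norms <- sqrt(Matrix::rowSums(m^2))
    if (any(norms == 0)) stop("cosine distance undefined for zero rows")
    s <- as.matrix(Matrix::tcrossprod(m))
    d <- 1 - s / outer(norms, norms)
    d[d < 0] <- 0 # rounding guard
    diag(d) <- 0
  } else {
    rng <- column_ranges(m)
    scale <- ifelse(rng$range > 0, 1 / rng$range, 0)
    ms <- m %*% Matrix::Diagonal(x = scale)
    ms <- methods::as(ms, "CsparseMatrix")
    d <- pairwise_l1_sparse(ms)
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
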