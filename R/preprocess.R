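# Quality control, library-size log-normalization, and low-rank embeddings.

#' Embedding container
#'
#' A tagged n x d point set: the space sketchers and Hausdorff metrics
#' operate in.
#'
#' @param points Numeric `n x d` matrix with finite entries.
#' @param representation One of `"pca"`, `"coords"`, `"smoothed_pca"`.
#' @param row_ids Character identifiers aligned to the source dataset.
#' @return An object of class `st_embedding`.
#' @export
st_embedding <- function(points, representation = c("pca", "coords", "smoothed_pca"),
                         row_ids = NULL) {
  representation <- match.arg(representation)
  points <- as.matrix(points)
  if (ncol(points) < 1L) stop("embedding must have at least one dimension", call. = FALSE)
  if (!all(is.finite(points))) stop("embedding entries must be finite", call. = FALSE)
  if (is.null(row_ids)) row_ids <- rownames(points)
  if (is.null(row_ids)) row_ids <- paste0("cell", seq_len(nrow(points)))
  if (length(row_ids) != nrow(points)) {
    stop("`row_ids` must match the number of rows", call. = FALSE)
  }
  rownames(points) <- row_ids
  structure(list(points = points, representation = representation,
                 row_ids = as.character(row_ids)),
            class = "st_embedding")
}

#' @export
print.st_embedding <- function(x, ...) {
  cat(sprintf("st_embedding (%s): %d points x %d dims\n",
              x$representation, nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Quality-control filter on total counts
#'
#' Drops a cell iff (i) its total counts fall below `min_counts`, or (ii) its
#' total deviates from the mean total by more than `mad_multiplier` times the
#' mean absolute deviation about the mean, both statistics computed on the
#' cells passing rule (i). The outlier rule is two-sided; the low tail is in
#' practice handled by the minimum-count rule.
#'
#' @param dataset An `st_dataset`.
#' @param min_counts Minimum total counts to retain a cell (default 100).
#' @param mad_multiplier Outlier threshold in units of the mean absolute
#'   deviation (default 5).
#' @return List with `dataset` (filtered, input order preserved) and `keep`
#'   (logical mask aligned with the input rows).
#' @export
qc_filter <- function(dataset, min_counts = 100, mad_multiplier = 5) {
  stopifnot(is(dataset, "st_dataset"))
  totals <- unname(Matrix::rowSums(dataset$counts))
  pass_min <- totals >= min_counts
  keep <- pass_min
  if (any(pass_min)) {
    mu <- mean(totals[pass_min])
    mad_stat <- mean(abs(totals[pass_min] - mu))
    keep <- pass_min & (abs(totals - mu) <= mad_multiplier * mad_stat)
  }
  if (!any(keep)) {
    stop(sprintf(
      "qc_filter removed every cell (%d below %g counts, %d flagged as outliers)",
      sum(!pass_min), min_counts, sum(pass_min & !keep)), call. = FALSE)
  }
  list(dataset = subset_cells(dataset, which(keep)), keep = keep)
}

#' Library-size scaled log-normalization
#'
#' Maps entry (i, j) to `log(1 + scale_target * counts[i, j] / total_i)`.
#' Zeros map to zeros, so sparsity is preserved; the result is invariant to
#' per-cell rescaling of counts.
#'
#' @param counts Sparse or dense n x g count matrix with strictly positive
#'   row totals.
#' @param scale_target Target library size (default 10000).
#' @return Sparse normalized matrix with the same dimensions and dimnames.
#' @export
lognormalize <- function(counts, scale_target = 1e4) {
  if (!is(counts, "CsparseMatrix")) {
    counts <- as(as(as(as.matrix(counts), "dMatrix"), "generalMatrix"),
                 "CsparseMatrix")
  }
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) {
    stop("lognormalize: zero-total cell encountered; run qc_filter first",
         call. = FALSE)
  }
  out <- counts
  # column-compressed storage: recover row index of each nonzero
  ri <- out@i + 1L
  out@x <- log1p(scale_target * out@x / totals[ri])
  out
}

#' Principal component embedding
#'
#' Truncated PCA of a (normalized) expression matrix: rows are centred by
#' the column means and the leading `d` right singular directions are
#' extracted with a seeded randomized SVD (exact for small problems, where
#' the sampled subspace spans the full column space).
#'
#' @param X Numeric or sparse n x g matrix.
#' @param d Number of components (default 20); must satisfy
#'   `d <= min(n, g)`.
#' @param seed Integer seed for the randomized solver.
#' @return List with `embedding` (an `st_embedding` of scores, representation
#'   `"pca"`), `loadings` (g x d), `center` (length-g column means), and
#'   `sdev` (component standard deviations, nonincreasing).
#' @export
pca_embedding <- function(X, d = 20L, seed = 1L) {
  d <- as.integer(d)
  n <- nrow(X)
  g <- ncol(X)
  if (d < 1L || d > min(n, g)) {
    stop("invalid rank: `d` must satisfy 1 <= d <= min(n, g)", call. = FALSE)
  }
  ctr <- as.numeric(Matrix::colSums(X) / n)
  dec <- rsvd_centered(X, center = ctr, rank = d, seed = seed,
                       oversampling = 10L, power_iterations = 3L)
  scores <- dec$U %*% diag(dec$singular_values, d, d)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(d))
  loadings <- dec$V
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(d))
  list(embedding = st_embedding(scores, "pca"),
       loadings = loadings,
       center = ctr,
       singular_values = dec$singular_values,
       sdev = dec$singular_values / sqrt(max(1, n - 1)))
}

#' Randomized truncated SVD
#'
#' Range-finder randomized SVD with Gaussian test matrix, oversampling, and
#' QR-stabilized power iterations. When `rank + oversampling >= min(n, g)`
#' the sampled subspace spans the full column space and the decomposition is
#' exact (up to floating point).
#'
#' @param X Numeric or sparse n x g matrix.
#' @param rank Target rank (<= min(n, g)).
#' @param seed Integer seed.
#' @param oversampling Extra sampled directions (default 10).
#' @param power_iterations Subspace power iterations (default 2); >= 2 is
#'   recommended for slowly decaying spectra.
#' @return An object of class `basis_decomposition`: list with `U` (n x rank,
#'   orthonormal columns), `singular_values` (nonincreasing), `V` (g x rank).
#' @export
randomized_svd <- function(X, rank, seed = 1L, oversampling = 10L,
                           power_iterations = 2L) {
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(X))) {
    stop("invalid rank: must satisfy 1 <= rank <= min(n, g)", call. = FALSE)
  }
  rsvd_centered(X, center = NULL, rank = rank, seed = seed,
                oversampling = as.integer(oversampling),
                power_iterations = as.integer(power_iterations))
}

#' @export
print.basis_decomposition <- function(x, ...) {
  cat(sprintf("basis_decomposition: rank %d, singular values [%.4g .. %.4g]\n",
              length(x$singular_values),
              max(x$singular_values), min(x$singular_values)))
  invisible(x)
}

# Randomized SVD of X (optionally implicitly column-centred, so sparse X is
# never densified). center = NULL means no centring.
rsvd_centered <- function(X, center, rank, seed, oversampling, power_iterations) {
  n <- nrow(X)
  g <- ncol(X)
  r2 <- min(rank + oversampling, n, g)
  # implicit centring: (X - 1 c^T) M = X M - 1 (c^T M)
  mult <- function(M) {
    Y <- as.matrix(X %*% M)
    if (!is.null(center)) Y <- Y - tcrossprod(rep(1, n), crossprod(M, center))
    Y
  }
  tmult <- function(M) { # t(Xc) %*% M = t(X) M - c (1^T M)
    Y <- as.matrix(Matrix::crossprod(X, M))
    if (!is.null(center)) Y <- Y - tcrossprod(center, colSums(M))
    Y
  }
  Omega <- with_seed(seed, matrix(rnorm(g * r2), g, r2))
  Q <- qr.Q(qr(mult(Omega)))
  for (i in seq_len(power_iterations)) {
    Q <- qr.Q(qr(tmult(Q)))
    Q <- qr.Q(qr(mult(Q)))
  }
  B <- t(tmult(Q)) # r2 x g
  sv <- svd(B, nu = rank, nv = rank)
  U <- Q %*% sv$u
  structure(list(U = U[, seq_len(rank), drop = FALSE],
                 singular_values = sv$d[seq_len(rank)],
                 V = sv$v[, seq_len(rank), drop = FALSE]),
            class = "basis_decomposition")
}
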