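# Spatial weights matrix W and smoothed embeddings/bases: the mechanism for
# injecting tissue location into expression-space sketchers.

#' Build a k-nearest-neighbour spatial weights matrix
#'
#' Constructs a sparse row-stochastic n x n matrix whose row i averages over
#' cell i's k nearest spatial neighbours (plus itself when `self_included`).
#' The uniform kernel weights neighbours equally; the gaussian kernel weights
#' them by `exp(-d^2 / sigma_i^2)` with `sigma_i` the distance to the k-th
#' neighbour. Multiplying an embedding by W smooths it across the tissue.
#'
#' @param coords `n x 2` coordinate matrix.
#' @param k_neighbors Neighbourhood size (default 15); must be `< n`.
#' @param kernel `"uniform"` or `"gaussian"`.
#' @param self_included Include each cell in its own neighbourhood
#'   (default TRUE).
#' @return An object of class `spatial_weights`: list with sparse matrix `W`
#'   (rows sum to 1), `k_neighbors`, `kernel`, `self_included`.
#' @export
build_spatial_weights <- function(coords, k_neighbors = 15L,
                                  kernel = c("uniform", "gaussian"),
                                  self_included = TRUE) {
  kernel <- match.arg(kernel)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L || k_neighbors >= n) {
    stop("`k_neighbors` must satisfy 1 <= k < n", call. = FALSE)
  }
  nn <- knn_search(coords, k = k_neighbors)
  if (self_included) {
    idx <- cbind(seq_len(n), nn$idx)
    dst <- cbind(0, nn$dist)
  } else {
    idx <- nn$idx
    dst <- nn$dist
  }
  w <- if (kernel == "uniform") {
    matrix(1, nrow(idx), ncol(idx))
  } else {
    sigma <- nn$dist[, k_neighbors]
    sigma[sigma == 0] <- .Machine$double.eps
    exp(-(dst / sigma)^2)
  }
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), ncol(idx)),
    j = as.integer(idx),
    x = as.numeric(w),
    dims = c(n, n))
  W <- Matrix::Diagonal(n, 1 / Matrix::rowSums(W)) %*% W
  structure(list(W = as(W, "CsparseMatrix"), k_neighbors = k_neighbors,
                 kernel = kernel, self_included = self_included),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d x %d, k = %d, %s kernel, self %sincluded\n",
              nrow(x$W), ncol(x$W), x$k_neighbors, x$kernel,
              if (x$self_included) "" else "not "))
  invisible(x)
}

#' Smooth a basis by the spatial weights matrix
#'
#' Returns the spatially smoothed basis `W U`. No re-orthonormalization is
#' applied: the smoothed columns are generally not orthonormal, and the
#' spatially aware leverage scores are taken from the raw row norms of the
#' smoothed basis.
#'
#' @param weights A `spatial_weights` object (or a plain n x n matrix).
#' @param U An `n x r` matrix, row-aligned with the weights.
#' @return The dense `n x r` matrix `W U`.
#' @export
smooth_basis <- function(weights, U) {
  W <- if (is(weights, "spatial_weights")) weights$W else weights
  U <- as.matrix(U)
  if (nrow(U) != ncol(W)) {
    stop("dimension mismatch: W and U must be row-aligned", call. = FALSE)
  }
  out <- as.matrix(W %*% U)
  dimnames(out) <- dimnames(U)
  out
}

#' Spatially smoothed embedding
#'
#' Applies one pass of neighbourhood averaging to an embedding's points and
#' retags the representation as `"smoothed_pca"`. Additional passes compose:
#' smoothing twice with W equals applying W squared once.
#'
#' @param dataset The source `st_dataset` (used for row alignment checks).
#' @param embedding An `st_embedding` (typically the PCA representation).
#' @param weights A `spatial_weights` built on the same cells.
#' @param passes Number of smoothing passes (default 1).
#' @return An `st_embedding` with representation `"smoothed_pca"`.
#' @export
smoothed_embedding <- function(dataset, embedding, weights, passes = 1L) {
  stopifnot(is(embedding, "st_embedding"), is(weights, "spatial_weights"))
  pts <- embedding$points
  if (!is.null(dataset)) {
    stopifnot(is(dataset, "st_dataset"))
    if (!identical(dataset$ids, embedding$row_ids)) {
      stop("embedding rows are not aligned with the dataset", call. = FALSE)
    }
  }
  if (nrow(pts) != nrow(weights$W)) {
    stop("dimension mismatch between embedding and weights", call. = FALSE)
  }
  for (i in seq_len(passes)) pts <- smooth_basis(weights, pts)
  st_embedding(pts, "smoothed_pca", row_ids = embedding$row_ids)
}
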