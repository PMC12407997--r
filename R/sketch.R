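# Sketching designs: uniform, leverage-score (exact, randomized-projection
# approximate, and spatially smoothed), minimax (grid-covering / Hausdorff),
# and maximin (greedy farthest-first) selection.

new_sketch <- function(indices, method, representation, fraction, seed, n) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("sketch indices must be unique", call. = FALSE)
  if (any(indices < 1L) || any(indices > n)) {
    stop("sketch indices out of range", call. = FALSE)
  }
  structure(list(indices = indices, method = method,
                 representation = representation,
                 fraction = fraction, seed = as.integer(seed), n = as.integer(n)),
            class = "st_sketch")
}

#' @export
print.st_sketch <- function(x, ...) {
  cat(sprintf("st_sketch: %d of %d cells (fraction %.4g), method %s on %s, seed %d\n",
              length(x$indices), x$n, x$fraction, x$method,
              x$representation, x$seed))
  invisible(x)
}

sketch_size <- function(n, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  max(1L, as.integer(floor(fraction * n)))
}

#' Uniform random sketch
#'
#' Selects `max(1, floor(fraction * n))` distinct indices without replacement
#' with equal probabilities.
#'
#' @param n Population size.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return An `st_sketch`.
#' @export
uniform_sketch <- function(n, fraction, seed = 1L) {
  n <- as.integer(n)
  k <- sketch_size(n, fraction)
  idx <- with_seed(seed, sample.int(n, k))
  new_sketch(sort(idx), "uniform", "index", fraction, seed, n)
}

#' Exact leverage scores from an orthonormal basis
#'
#' The leverage score of row i is the squared Euclidean norm of the i-th row
#' of a (column-orthonormal) basis U — the i-th diagonal entry of the hat
#' matrix. For orthonormal U the scores sum to the basis rank. When
#' `smoothed = TRUE` the input is a spatially smoothed basis whose raw row
#' norms are used as-is (the sum identity no longer holds).
#'
#' @param U An n x r matrix; column-orthonormal unless `smoothed = TRUE`.
#' @param smoothed Logical flag recording that U is a smoothed basis.
#' @return An object of class `leverage_scores`: list with `scores`
#'   (length-n, nonnegative), `basis_rank`, `smoothed`.
#' @export
leverage_scores_exact <- function(U, smoothed = FALSE) {
  U <- as.matrix(U)
  structure(list(scores = rowSums(U^2), basis_rank = ncol(U),
                 smoothed = isTRUE(smoothed)),
            class = "leverage_scores")
}

#' @export
print.leverage_scores <- function(x, ...) {
  cat(sprintf("leverage_scores: n = %d, basis rank %d%s, sum %.4g\n",
              length(x$scores), x$basis_rank,
              if (x$smoothed) " (smoothed)" else "", sum(x$scores)))
  invisible(x)
}

#' Approximate leverage scores by random projection + QR
#'
#' Projects X against a seeded Gaussian test matrix with
#' `rank + oversampling` columns, orthonormalizes the projection by QR, and
#' takes squared row norms of the orthonormal factor — the randomized
#' leverage-score approximation used for large cell-by-gene matrices.
#'
#' @param X Numeric or sparse n x g matrix.
#' @param rank Target rank (<= min(n, g)).
#' @param seed Integer seed.
#' @param oversampling Extra projection columns (default 10).
#' @return A `leverage_scores` object; scores sum to the orthonormal factor's
#'   column count.
#' @export
leverage_scores_approx <- function(X, rank, seed = 1L, oversampling = 10L) {
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(X))) {
    stop("invalid rank: must satisfy 1 <= rank <= min(n, g)", call. = FALSE)
  }
  r2 <- min(rank + as.integer(oversampling), nrow(X), ncol(X))
  Omega <- with_seed(seed, matrix(rnorm(ncol(X) * r2), ncol(X), r2))
  qry <- qr(as.matrix(X %*% Omega))
  # rank-revealing truncation: on (numerically) low-rank input the trailing
  # QR columns are noise and would corrupt the scores
  Q <- qr.Q(qry)[, seq_len(qry$rank), drop = FALSE]
  structure(list(scores = rowSums(Q^2), basis_rank = ncol(Q),
                 smoothed = FALSE),
            class = "leverage_scores")
}

#' Weighted sampling without replacement
#'
#' Draws `k` distinct indices with probability proportional to the scores
#' via sequential renormalized draws.
#'
#' @param scores A `leverage_scores` object or a nonnegative numeric vector.
#' @param k Number of draws; must not exceed the number of strictly positive
#'   scores.
#' @param seed Integer seed.
#' @return Integer vector of `k` distinct indices (ascending order).
#' @export
probability_sample <- function(scores, k, seed = 1L) {
  if (is(scores, "leverage_scores")) scores <- scores$scores
  scores <- as.numeric(scores)
  if (any(scores < 0) || !all(is.finite(scores))) {
    stop("scores must be finite and nonnegative", call. = FALSE)
  }
  k <- as.integer(k)
  support <- sum(scores > 0)
  if (k > support) {
    stop(sprintf("infeasible sample: k = %d exceeds the %d strictly positive scores",
                 k, support), call. = FALSE)
  }
  sort(with_seed(seed, sample.int(length(scores), k, prob = scores)))
}

#' Minimax (Hausdorff-coverage) sketch
#'
#' Grid-covering selection: a binary search over the lattice cell width
#' finds the coarsest width whose occupied hypercubes still number at least
#' `k`; `k` occupied cells are then chosen uniformly without replacement
#' (all of them when counts allow) and one uniformly random member is taken
#' from each. Spreading the sketch across occupied cells bounds the maximum
#' distance from any point to the sketch — the minimax/Hausdorff design
#' objective. If even the finest width yields fewer than `k` occupied cells
#' (duplicate points), the sketch is completed farthest-first.
#'
#' @param embedding An `st_embedding` or numeric matrix of points.
#' @param k Sketch size (<= n).
#' @param seed Integer seed.
#' @param iterations Binary-search iterations over the cell width
#'   (default 30).
#' @return An `st_sketch` with method `"minimax"`.
#' @export
minimax_sketch <- function(embedding, k, seed = 1L, iterations = 30L) {
  pts <- if (is(embedding, "st_embedding")) embedding$points else as.matrix(embedding)
  rep_tag <- if (is(embedding, "st_embedding")) embedding$representation else "pca"
  n <- nrow(pts)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n", call. = FALSE)
  if (k == n) {
    return(new_sketch(seq_len(n), "minimax", rep_tag, k / n, seed, n))
  }
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  diag_len <- sqrt(sum((hi - lo)^2))
  if (diag_len == 0) { # all points identical: coverage is trivial
    idx <- with_seed(seed, sample.int(n, k))
    return(new_sketch(sort(idx), "minimax", rep_tag, k / n, seed, n))
  }
  cell_key <- function(width) {
    bins <- floor(sweep(sweep(pts, 2, lo), 2, width, "/"))
    do.call(paste, c(as.data.frame(bins), sep = "_"))
  }
  # occupied-cell count decreases with width. Stage 1: largest width whose
  # occupied count is still >= k (that count is the minimal one >= k
  # reachable on the search grid). Stage 2: ties in the count are resolved
  # toward the smallest width attaining it, so cells stay compact and
  # well-separated clusters land in distinct cells.
  w_lo <- 0
  w_hi <- diag_len
  best <- NULL
  for (it in seq_len(iterations)) {
    mid <- (w_lo + w_hi) / 2
    if (mid <= 0) break
    key <- cell_key(mid)
    occ <- length(unique(key))
    if (occ >= k) {
      best <- key
      w_lo <- mid
    } else {
      w_hi <- mid
    }
  }
  if (is.null(best)) best <- cell_key(diag_len / 2^iterations)
  occ_star <- length(unique(best))
  s_lo <- 0
  s_hi <- w_lo
  for (it in seq_len(iterations)) {
    mid <- (s_lo + s_hi) / 2
    if (mid <= 0) break
    key <- cell_key(mid)
    if (length(unique(key)) <= occ_star) {
      best <- key
      s_hi <- mid
    } else {
      s_lo <- mid
    }
  }
  cells <- split(seq_len(n), best)
  occ <- length(cells)
  idx <- with_seed(seed, {
    if (occ >= k) {
      chosen <- if (occ == k) seq_len(occ) else sample.int(occ, k)
      vapply(cells[chosen], function(m) {
        if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
      }, integer(1))
    } else {
      # duplicate-heavy degenerate case: one per occupied cell, then
      # farthest-first completion
      base <- vapply(cells, function(m) {
        if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
      }, integer(1))
      farthest_first_complete(pts, base, k)
    }
  })
  new_sketch(sort(unname(idx)), "minimax", rep_tag, k / n, seed, n)
}

# Extend `current` indices to size k by greedy farthest-first additions.
farthest_first_complete <- function(pts, current, k) {
  n <- nrow(pts)
  mind <- rep(Inf, n)
  for (j in current) {
    mind <- pmin(mind, sqrt(cross_dist2(pts, pts[j, , drop = FALSE]))[, 1])
  }
  sel <- as.integer(current)
  while (length(sel) < k) {
    j <- which.max(mind) # ties: lowest index
    sel <- c(sel, j)
    mind <- pmin(mind, sqrt(cross_dist2(pts, pts[j, , drop = FALSE]))[, 1])
  }
  sel
}

#' Maximin (farthest-first) sketch
#'
#' Greedy farthest-first traversal: the first point is chosen uniformly at
#' random; each subsequent point maximizes the minimum distance to the
#' current sketch (ties broken by lowest index). This greedily maximizes the
#' minimum pairwise distance within the sketch — the maximin design — and is
#' a classical 2-approximation of the optimum.
#'
#' @param embedding An `st_embedding` or numeric matrix of points.
#' @param k Sketch size (<= n).
#' @param seed Integer seed (consumed by the starting point only).
#' @return An `st_sketch` with method `"maximin"`.
#' @export
maximin_sketch <- function(embedding, k, seed = 1L) {
  pts <- if (is(embedding, "st_embedding")) embedding$points else as.matrix(embedding)
  rep_tag <- if (is(embedding, "st_embedding")) embedding$representation else "pca"
  n <- nrow(pts)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n", call. = FALSE)
  start <- with_seed(seed, sample.int(n, 1L))
  sel <- farthest_first_complete(pts, start, k)
  new_sketch(sort(sel), "maximin", rep_tag, k / n, seed, n)
}

#' Sketch minimum pairwise distance
#'
#' The maximin design objective: the smallest pairwise distance among the
#' sketched points.
#'
#' @param pts Numeric matrix of all points.
#' @param indices Sketch indices.
#' @return The minimum pairwise distance (Inf for singleton sketches).
#' @export
min_pairwise_distance <- function(pts, indices) {
  if (length(indices) < 2L) return(Inf)
  min(dist(as.matrix(pts)[indices, , drop = FALSE]))
}

# Valid (method, representation) combinations for the dispatcher.
sketch_table <- function() {
  rbind(
    data.frame(method = "uniform", representation = "index"),
    data.frame(method = "leverage", representation = c("counts", "pca")),
    data.frame(method = "leverage_smoothed", representation = "smoothed_pca"),
    data.frame(method = "minimax", representation = c("pca", "coords", "smoothed_pca")),
    data.frame(method = "maximin", representation = c("pca", "coords", "smoothed_pca")))
}

#' Prepare shared sketching context
#'
#' Computes, once per dataset, everything the sketchers and metrics share:
#' the log-normalized matrix, the full-data PCA (scores, loadings, centre),
#' the coordinate embedding, the spatial weights, the randomized-SVD basis
#' U, and its spatially smoothed counterpart `W U`.
#'
#' @param dataset A QC-filtered `st_dataset`.
#' @param pcs Number of PCA components (default 20).
#' @param k_neighbors Spatial neighbourhood size for W (default 15).
#' @param kernel Spatial kernel (default `"uniform"`).
#' @param scale_target Normalization library size (default 10000).
#' @param seed Integer seed for the randomized solvers.
#' @return An object of class `sketch_context`.
#' @export
prepare_context <- function(dataset, pcs = 20L, k_neighbors = 15L,
                            kernel = "uniform", scale_target = 1e4,
                            seed = 1L) {
  stopifnot(is(dataset, "st_dataset"))
  seeds <- derive_seeds(seed, 2L)
  norm <- lognormalize(dataset$counts, scale_target)
  d <- min(pcs, nrow(norm), ncol(norm))
  pca <- pca_embedding(norm, d = d, seed = seeds[1])
  weights <- build_spatial_weights(dataset$coords, k_neighbors, kernel)
  U <- pca$embedding$points %*%
    diag(1 / pmax(pca$singular_values, .Machine$double.eps), d, d)
  U_smooth <- smooth_basis(weights, U)
  coords_emb <- st_embedding(dataset$coords, "coords", row_ids = dataset$ids)
  smooth_emb <- smoothed_embedding(dataset, pca$embedding, weights)
  structure(list(dataset = dataset, normalized = norm, pca = pca,
                 coords = coords_emb, smoothed_pca = smooth_emb,
                 weights = weights, U = U, U_smoothed = U_smooth,
                 seed = seed),
            class = "sketch_context")
}

#' @export
print.sketch_context <- function(x, ...) {
  cat(sprintf("sketch_context: %d cells, %d PCs, W with k = %d\n",
              nrow(x$normalized), ncol(x$pca$embedding$points),
              x$weights$k_neighbors))
  invisible(x)
}

#' Draw a sketch of a dataset
#'
#' Dispatches to the sketching designs over the requested input
#' representation. Valid combinations: uniform on the cell index; leverage
#' on `"counts"` (randomized-projection scores on the normalized
#' cell-by-gene matrix) or `"pca"` (exact scores on the orthonormal basis U);
#' `"leverage_smoothed"` on `"smoothed_pca"` (raw row norms of the smoothed
#' basis `W U` — the spatially aware variant); minimax and maximin on
#' `"pca"`, `"coords"`, or `"smoothed_pca"`. Uniform sampling over the
#' coordinate representation is disallowed as it is equivalent to plain
#' uniform sampling.
#'
#' @param dataset The `st_dataset` being sketched.
#' @param method One of `"uniform"`, `"leverage"`, `"leverage_smoothed"`,
#'   `"minimax"`, `"maximin"`.
#' @param representation One of `"index"`, `"counts"`, `"pca"`,
#'   `"coords"`, `"smoothed_pca"`.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @param context A [prepare_context()] object for the dataset.
#' @return An `st_sketch` carrying its provenance.
#' @export
sketch <- function(dataset, method, representation, fraction, seed = 1L,
                   context) {
  stopifnot(is(context, "sketch_context"))
  tab <- sketch_table()
  ok <- any(tab$method == method & tab$representation == representation)
  if (!ok) {
    valid <- paste(sprintf("%s x %s", tab$method, tab$representation),
                   collapse = ", ")
    stop(sprintf("unsupported configuration %s x %s; valid pairs: %s",
                 method, representation, valid), call. = FALSE)
  }
  n <- nrow(dataset$counts)
  k <- sketch_size(n, fraction)
  emb <- switch(representation,
                pca = context$pca$embedding,
                coords = context$coords,
                smoothed_pca = context$smoothed_pca,
                NULL)
  out <- switch(method,
    uniform = uniform_sketch(n, fraction, seed),
    leverage = {
      sc <- if (representation == "counts") {
        leverage_scores_approx(context$normalized,
                               rank = ncol(context$U), seed = seed)
      } else {
        leverage_scores_exact(context$U)
      }
      new_sketch(probability_sample(sc, k, seed), "leverage",
                 representation, fraction, seed, n)
    },
    leverage_smoothed = {
      sc <- leverage_scores_exact(context$U_smoothed, smoothed = TRUE)
      new_sketch(probability_sample(sc, k, seed), "leverage_smoothed",
                 representation, fraction, seed, n)
    },
    minimax = minimax_sketch(emb, k, seed),
    maximin = maximin_sketch(emb, k, seed))
  out$representation <- representation
  out$fraction <- fraction
  out
}
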