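# Evaluation framework: robust (partial) Hausdorff distances, graph-based
# clustering + adjusted Rand index, principal-component projection drift,
# kNN neighbourhood-composition distortion, and the rank-sum overall
# spatial score.

#' Directed partial (robust) Hausdorff distance
#'
#' Computes the nearest-sketch-neighbour distance for every point of the
#' full set and returns its q-quantile (the ceiling(q n)-th order statistic).
#' `q = 1` gives the classic directed Hausdorff maximum; quantiles below 1
#' make the statistic robust to outlying points.
#'
#' @param full_points Numeric n x d matrix (the full dataset in some
#'   embedding).
#' @param sketch_points Numeric m x d matrix (the sketch, same space).
#' @param q Quantile in (0, 1], default 1.
#' @return Nonnegative scalar.
#' @export
partial_hausdorff <- function(full_points, sketch_points, q = 1) {
  sketch_points <- as.matrix(sketch_points)
  full_points <- as.matrix(full_points)
  if (nrow(sketch_points) < 1L) {
    stop("sketch must contain at least one point", call. = FALSE)
  }
  if (!is.numeric(q) || q <= 0 || q > 1) {
    stop("`q` must lie in (0, 1]", call. = FALSE)
  }
  d <- nn1_dist(full_points, sketch_points)
  sort(d, partial = ceiling(q * length(d)))[ceiling(q * length(d))]
}

#' Graph-based clustering for ARI evaluation
#'
#' Builds a shared-nearest-neighbour graph (kNN, Jaccard edge weights over
#' shared neighbour sets) on the embedding and partitions it by seeded
#' modularity optimization (multilevel/Louvain) at the given resolution —
#' the standard graph-clustering recipe for expression embeddings.
#'
#' @param embedding An `st_embedding` or numeric matrix.
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Integer seed.
#' @param k Neighbourhood size for the SNN graph (default 15, capped at
#'   n - 1).
#' @return Integer cluster labels, length n.
#' @export
cluster_for_ari <- function(embedding, resolution = 1, seed = 1L, k = 15L) {
  pts <- if (is(embedding, "st_embedding")) embedding$points else as.matrix(embedding)
  n <- nrow(pts)
  if (n < 2L) stop("clustering needs at least two points", call. = FALSE)
  k <- min(as.integer(k), n - 1L)
  nn <- knn_search(pts, k = k)
  # adjacency including self so Jaccard is over (k+1)-sets
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k + 1L),
    j = c(seq_len(n), as.integer(nn$idx)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  s <- shared@x[keep]
  jac <- s / (2 * (k + 1L) - s)
  ok <- jac >= 1 / 15 # prune weak SNN edges (standard cutoff)
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  out <- integer(n)
  out[as.integer(igraph::V(g)$name)] <- as.integer(memb)
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed by pair
#' counting from the contingency table. 1 means identical partitions (up to
#' label names), values near 0 arise for independent labelings, and the
#' index can be negative for worse-than-chance agreement.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' PCA projection difference
#'
#' Measures drift of the principal subspace under sketching: the sketch's
#' rows are projected (i) onto components learned from the full dataset and
#' (ii) onto a fresh d-component PCA fitted on the sketch alone. Sketch
#' components are sign-aligned to the full ones by the sign of the
#' per-column correlation, and the mean over cells of the Euclidean distance
#' between the aligned projections is returned. Lower values indicate more
#' consistent low-dimensional structure.
#'
#' @param full_loadings g x d loading matrix learned from the full dataset.
#' @param full_center Length-g centring vector of the full-data PCA.
#' @param sketch_matrix m x g normalized expression matrix of the sketched
#'   cells (m > d).
#' @param d Number of components to compare (default `ncol(full_loadings)`).
#' @param seed Integer seed for the sketch-side randomized PCA.
#' @return Nonnegative scalar.
#' @export
pca_projection_difference <- function(full_loadings, full_center, sketch_matrix,
                                      d = ncol(full_loadings), seed = 1L) {
  d <- as.integer(d)
  m <- nrow(sketch_matrix)
  if (m <= d) stop("insufficient rank: sketch must have more rows than components",
                   call. = FALSE)
  proj_full <- as.matrix(sketch_matrix %*% full_loadings[, seq_len(d), drop = FALSE]) -
    tcrossprod(rep(1, m), crossprod(full_loadings[, seq_len(d), drop = FALSE],
                                    full_center))
  sk <- pca_embedding(sketch_matrix, d = d, seed = seed)
  proj_sketch <- sk$embedding$points
  for (j in seq_len(d)) {
    s <- suppressWarnings(cor(proj_full[, j], proj_sketch[, j]))
    if (!is.na(s) && s < 0) proj_sketch[, j] <- -proj_sketch[, j]
  }
  mean(sqrt(rowSums((proj_full - proj_sketch)^2)))
}

#' k-nearest-neighbour label composition
#'
#' For each query cell, the label-frequency vector over its k nearest
#' spatial neighbours within a stated population (the query itself is
#' excluded when it belongs to the population). Rows sum to 1.
#'
#' @param coords n x 2 coordinate matrix for the whole dataset.
#' @param labels Length-n label vector.
#' @param query_points Integer indices of the query cells.
#' @param k Neighbourhood size; must be smaller than the population.
#' @param population Integer indices of the population searched (default:
#'   all cells).
#' @return Matrix `length(query_points) x nlevels(labels)` of proportions.
#' @export
neighborhood_composition <- function(coords, labels, query_points, k,
                                     population = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  population <- as.integer(population)
  query_points <- as.integer(query_points)
  k <- as.integer(k)
  if (k >= length(population)) {
    stop("`k` must be smaller than the population size", call. = FALSE)
  }
  ref <- coords[population, , drop = FALSE]
  qry <- coords[query_points, , drop = FALSE]
  # exclude self-matches by searching one extra neighbour and dropping any
  # hit that is the query itself
  nn <- knn_search(ref, qry, k = min(k + 1L, length(population)))
  lev <- levels(labels)
  out <- matrix(0, length(query_points), length(lev),
                dimnames = list(NULL, lev))
  pop_pos <- match(query_points, population)
  for (i in seq_along(query_points)) {
    hits <- nn$idx[i, ]
    if (!is.na(pop_pos[i])) hits <- hits[hits != pop_pos[i]]
    hits <- hits[seq_len(k)]
    out[i, ] <- tabulate(labels[population[hits]], length(lev)) / k
  }
  out
}

#' Local neighbourhood distortion (composition MSE)
#'
#' For each sketched cell, compares its kNN label-composition vector
#' computed in the full population against the one computed within the
#' sketch population (same k), and returns the mean over sketched cells of
#' the mean squared difference across label categories. 0 means the sketch
#' preserves local tissue composition exactly; the value is bounded above
#' by 2.
#'
#' @param dataset A labelled `st_dataset`.
#' @param sketch An `st_sketch` (size must exceed `k`).
#' @param k Neighbourhood size (default 20).
#' @return Nonnegative scalar.
#' @export
neighborhood_mse <- function(dataset, sketch, k = 20L) {
  stopifnot(is(dataset, "st_dataset"))
  if (is.null(dataset$labels)) {
    stop("neighborhood_mse requires per-cell labels", call. = FALSE)
  }
  idx <- if (is(sketch, "st_sketch")) sketch$indices else as.integer(sketch)
  k <- as.integer(k)
  if (length(idx) <= k) {
    stop("sketch must contain more than `k` cells", call. = FALSE)
  }
  full_comp <- neighborhood_composition(dataset$coords, dataset$labels, idx, k)
  sk_comp <- neighborhood_composition(dataset$coords, dataset$labels, idx, k,
                                      population = idx)
  mean(rowMeans((full_comp - sk_comp)^2))
}

#' Rank-sum overall spatial score
#'
#' Ranks each benchmark condition (method x representation) on every metric
#' at one sampling fraction — replicate values are averaged first, ties get
#' average ranks, rank 1 is best (highest ARI; lowest for every other
#' metric) — and sums the three spatial-metric ranks (ARI, coordinate-space
#' Hausdorff, neighbourhood MSE) into an overall spatial score, lower =
#' better.
#'
#' @param records Long-form data frame of metric records with columns
#'   `method`, `representation`, `fraction`, `replicate`, `metric`, `value`.
#' @param fraction Sampling fraction to score (default: the single fraction
#'   present).
#' @return An object of class `rank_table`: a data frame of per-metric ranks
#'   plus `overall_spatial_score`.
#' @export
rank_sum_score <- function(records, fraction = NULL) {
  req <- c("method", "representation", "fraction", "replicate", "metric", "value")
  if (!all(req %in% names(records))) {
    stop("records must contain columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(fraction)) {
    fraction <- unique(records$fraction)
    if (length(fraction) != 1L) {
      stop("specify `fraction`: records contain several sampling fractions",
           call. = FALSE)
    }
  }
  rec <- records[records$fraction == fraction, , drop = FALSE]
  spatial_metrics <- c("ari", "hausdorff_coord", "neighborhood_mse")
  agg <- aggregate(value ~ method + representation + metric, data = rec, FUN = mean)
  wide <- reshape(agg, idvar = c("method", "representation"),
                  timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  present <- setdiff(names(wide), c("method", "representation"))
  missing_sp <- setdiff(spatial_metrics, present)
  if (length(missing_sp)) {
    stop("missing spatial metric(s) for ranking: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  ranks <- wide[, c("method", "representation")]
  for (mname in present) {
    v <- wide[[mname]]
    if (any(is.na(v))) {
      stop(sprintf("metric %s missing for some condition", mname), call. = FALSE)
    }
    # rank 1 = best: ARI is better-high, all distances/errors better-low
    ranks[[paste0("rank_", mname)]] <-
      if (mname == "ari") rank(-v) else rank(v)
  }
  ranks$overall_spatial_score <- ranks$rank_ari + ranks$rank_hausdorff_coord +
    ranks$rank_neighborhood_mse
  ranks <- ranks[order(ranks$overall_spatial_score), ]
  rownames(ranks) <- NULL
  attr(ranks, "fraction") <- fraction
  class(ranks) <- c("rank_table", "data.frame")
  ranks
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table at sampling fraction %.4g (lower score = better)\n",
              attr(x, "fraction")))
  print.data.frame(x, ...)
  invisible(x)
}
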