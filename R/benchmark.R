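# Benchmark orchestrator: runs the full method x representation x fraction x
# replicate matrix over a dataset and aggregates the rank-sum summary.

#' Benchmark configuration
#'
#' @param conditions Data frame with columns `method` and `representation`
#'   listing the conditions to run; defaults to the full set of valid pairs.
#' @param fractions Sampling fractions in (0, 1] (default
#'   `c(0.01, 0.05, 0.1, 0.2)`).
#' @param replicates Replicate draws per condition and fraction (default 10).
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @param score_fraction Fraction at which the rank table is computed
#'   (default 0.1; must be one of `fractions`).
#' @param hausdorff_q Quantile of the robust Hausdorff distance
#'   (default 0.99).
#' @param knn_k Neighbourhood size for composition MSE (default 20).
#' @param pcs PCA components (default 20).
#' @param k_neighbors Spatial-weights neighbourhood size (default 15).
#' @param cluster_resolution Modularity resolution for ARI clusterings
#'   (default 1).
#' @param min_counts,mad_multiplier QC-filter parameters passed to
#'   [qc_filter()].
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(conditions = NULL,
                             fractions = c(0.01, 0.05, 0.1, 0.2),
                             replicates = 10L,
                             base_seed = 1L,
                             score_fraction = 0.1,
                             hausdorff_q = 0.99,
                             knn_k = 20L,
                             pcs = 20L,
                             k_neighbors = 15L,
                             cluster_resolution = 1,
                             min_counts = 100,
                             mad_multiplier = 5) {
  if (is.null(conditions)) conditions <- sketch_table()
  tab <- sketch_table()
  for (i in seq_len(nrow(conditions))) {
    ok <- any(tab$method == conditions$method[i] &
              tab$representation == conditions$representation[i])
    if (!ok) {
      stop(sprintf("invalid condition %s x %s", conditions$method[i],
                   conditions$representation[i]), call. = FALSE)
    }
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (!score_fraction %in% fractions) {
    stop("`score_fraction` must be one of `fractions`", call. = FALSE)
  }
  structure(list(conditions = conditions, fractions = fractions,
                 replicates = replicates, base_seed = as.integer(base_seed),
                 score_fraction = score_fraction, hausdorff_q = hausdorff_q,
                 knn_k = as.integer(knn_k), pcs = as.integer(pcs),
                 k_neighbors = as.integer(k_neighbors),
                 cluster_resolution = cluster_resolution,
                 min_counts = min_counts, mad_multiplier = mad_multiplier),
            class = "benchmark_config")
}

#' @export
print.benchmark_config <- function(x, ...) {
  cat(sprintf("benchmark_config: %d conditions x %d fractions x %d replicates, base seed %d\n",
              nrow(x$conditions), length(x$fractions), x$replicates, x$base_seed))
  invisible(x)
}

# Evaluate all five metrics for one sketch. `reference` is the label vector
# used for ARI (ground truth or cached full-data clustering).
evaluate_sketch <- function(context, sk, reference, cfg, seed) {
  ds <- context$dataset
  idx <- sk$indices
  pca_pts <- context$pca$embedding$points
  coord_pts <- ds$coords
  sub_seeds <- derive_seeds(seed, 2L)
  h_expr <- partial_hausdorff(pca_pts, pca_pts[idx, , drop = FALSE],
                              q = cfg$hausdorff_q)
  h_coord <- partial_hausdorff(coord_pts, coord_pts[idx, , drop = FALSE],
                               q = cfg$hausdorff_q)
  # sketch-derived clusters: fresh PCA of the sketch's own normalized counts
  sk_norm <- context$normalized[idx, , drop = FALSE]
  d_use <- min(cfg$pcs, length(idx) - 1L, ncol(sk_norm))
  sk_pca <- pca_embedding(sk_norm, d = d_use, seed = sub_seeds[1])
  sk_clust <- cluster_for_ari(sk_pca$embedding,
                              resolution = cfg$cluster_resolution,
                              seed = sub_seeds[1])
  ari <- adjusted_rand_index(sk_clust, reference[idx])
  pca_diff <- pca_projection_difference(context$pca$loadings,
                                        context$pca$center,
                                        sk_norm, d = d_use,
                                        seed = sub_seeds[2])
  nmse <- if (length(idx) > cfg$knn_k) {
    neighborhood_mse(ds, sk, k = cfg$knn_k)
  } else {
    NA_real_
  }
  c(hausdorff_expr = h_expr, hausdorff_coord = h_coord, ari = ari,
    pca_diff = pca_diff, neighborhood_mse = nmse)
}

#' Run the sketching benchmark
#'
#' The full pipeline: QC filtering, normalization, PCA, spatial weights, and
#' smoothed embeddings are computed once and shared; every (method,
#' representation, fraction, replicate) cell then draws one sketch and
#' produces all five metric records. Replicate r uses seed
#' `base_seed + r`. ARI is computed against ground-truth labels when the
#' dataset carries them, otherwise against a seeded full-data graph
#' clustering computed once. On gridded (lattice) coordinate layouts,
#' coordinate-representation conditions are skipped with a warning, as
#' coordinate sketching there is akin to uniform sampling.
#'
#' @param dataset An `st_dataset`.
#' @param cfg A [benchmark_config()].
#' @return An object of class `st_benchmark`: list with `records` (long-form
#'   data frame of metric values), `ranks` (the [rank_sum_score()] table at
#'   `score_fraction`), `reference` (the ARI reference labels), `context`,
#'   and `cfg`.
#' @export
run_benchmark <- function(dataset, cfg = benchmark_config()) {
  stopifnot(is(dataset, "st_dataset"), is(cfg, "benchmark_config"))
  qc <- qc_filter(dataset, min_counts = cfg$min_counts,
                  mad_multiplier = cfg$mad_multiplier)
  ds <- qc$dataset
  context <- prepare_context(ds, pcs = cfg$pcs, k_neighbors = cfg$k_neighbors,
                             seed = cfg$base_seed)
  conditions <- cfg$conditions
  if (is_grid_layout(ds$coords)) {
    drop <- conditions$representation == "coords"
    if (any(drop)) {
      warning("skipping coordinate-representation conditions on a gridded layout ",
              "(akin to uniform sampling)", call. = FALSE)
      conditions <- conditions[!drop, , drop = FALSE]
    }
  }
  reference <- if (!is.null(ds$labels)) {
    as.integer(as.factor(ds$labels))
  } else {
    cluster_for_ari(context$pca$embedding, resolution = cfg$cluster_resolution,
                    seed = cfg$base_seed)
  }
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    m <- conditions$method[ci]
    rep_tag <- conditions$representation[ci]
    for (f in cfg$fractions) {
      for (r in seq_len(cfg$replicates)) {
        seed_r <- cfg$base_seed + r
        sk <- sketch(ds, m, rep_tag, f, seed = seed_r, context = context)
        vals <- evaluate_sketch(context, sk, reference, cfg, seed_r)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, representation = rep_tag, fraction = f, replicate = r,
          metric = names(vals), value = as.numeric(vals))
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  ranks <- rank_sum_score(records, fraction = cfg$score_fraction)
  structure(list(records = records, ranks = ranks, reference = reference,
                 context = context, cfg = cfg),
            class = "st_benchmark")
}

# Heuristic lattice detector: both coordinate axes take few distinct values
# with constant spacing.
is_grid_layout <- function(coords) {
  on_lattice <- function(v) {
    u <- sort(unique(round(v, 9)))
    if (length(u) < 2L) return(TRUE)
    if (length(u) > ceiling(sqrt(length(v))) + 1L) return(FALSE)
    gaps <- diff(u)
    max(gaps) - min(gaps) < 1e-9 * max(abs(u), 1)
  }
  on_lattice(coords[, 1]) && on_lattice(coords[, 2])
}

#' @export
print.st_benchmark <- function(x, ...) {
  cat(sprintf("st_benchmark: %d metric records (%d conditions, %d fractions, %d replicates)\n",
              nrow(x$records), nrow(x$ranks), length(x$cfg$fractions),
              x$cfg$replicates))
  cat(sprintf("rank table at fraction %.4g:\n", x$cfg$score_fraction))
  print(x$ranks)
  invisible(x)
}

#' @export
summary.st_benchmark <- function(object, ...) {
  agg <- aggregate(value ~ method + representation + fraction + metric,
                   data = object$records, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg
}

#' Plot benchmark metric trajectories
#'
#' One panel per metric: mean metric value against sampling fraction, one
#' line per condition.
#'
#' @param x An `st_benchmark`.
#' @param ... Passed to `matplot`.
#' @export
plot.st_benchmark <- function(x, ...) {
  agg <- summary(x)
  agg$cond <- paste(agg$method, agg$representation, sep = ":")
  metrics <- unique(agg$metric)
  op <- graphics::par(mfrow = c(ceiling(length(metrics) / 2), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  conds <- unique(agg$cond)
  for (mname in metrics) {
    sub <- agg[agg$metric == mname, ]
    wide <- reshape(sub[, c("cond", "fraction", "mean_value")],
                    idvar = "fraction", timevar = "cond", direction = "wide")
    wide <- wide[order(wide$fraction), ]
    graphics::matplot(wide$fraction, as.matrix(wide[, -1, drop = FALSE]),
                      type = "b", pch = 19, lty = 1, xlab = "sampling fraction",
                      ylab = mname, main = mname, ...)
  }
  graphics::legend("topright", legend = conds, col = seq_along(conds),
                   lty = 1, pch = 19, cex = 0.6, bty = "n")
  invisible(x)
}
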