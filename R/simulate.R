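# Synthetic spatial-transcriptomics generator: gridded (Visium-like) or
# scattered (Xenium-like) geometries, striped/radial/mosaic domain layouts,
# and zero-inflated negative-binomial counts with class-specific fold changes.

#' Simulation configuration
#'
#' Parameters of the built-in spatial transcriptomics simulator. Defaults
#' emulate an imaging-ST count regime with six separable spatial domains.
#'
#' @param n_locations Number of cells/locations (default 100000).
#' @param n_genes Number of genes (default 500).
#' @param layout Spatial geometry: `"grid"` (regular lattice, Visium-like) or
#'   `"random"` (uniformly scattered, Xenium-like).
#' @param pattern Domain layout: `"stripes"` (vertical bands), `"radial"`
#'   (equal-population annuli), or `"complex"` (Voronoi mosaic of random seeds).
#' @param n_classes Number of domain classes; labelled `"A"`, `"B"`, ...
#' @param n_signal_genes_per_class Genes upregulated in each class (disjoint
#'   blocks across classes).
#' @param baseline_log_mean Natural-log mean of the per-gene LogNormal
#'   baseline expression.
#' @param baseline_log_sd Natural-log sd of the baseline expression (>= 0).
#' @param dispersion Negative-binomial size parameter (> 0); the count
#'   variance is `mu + mu^2 / dispersion`.
#' @param zero_inflation Probability in `[0, 1]` that a count is
#'   independently replaced by zero.
#' @param logfc_per_class Log fold change applied to each class's signal
#'   genes in cells of that class; one value per class. Defaults to distinct
#'   values evenly spanning `log(2)` to `log(8)`.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_locations = 100000L,
                       n_genes = 500L,
                       layout = c("grid", "random"),
                       pattern = c("stripes", "radial", "complex"),
                       n_classes = 6L,
                       n_signal_genes_per_class = 25L,
                       baseline_log_mean = log(0.5),
                       baseline_log_sd = 1,
                       dispersion = 2,
                       zero_inflation = 0.2,
                       logfc_per_class = NULL,
                       seed = 1L) {
  layout <- match.arg(layout)
  pattern <- match.arg(pattern)
  n_locations <- as.integer(n_locations)
  n_genes <- as.integer(n_genes)
  n_classes <- as.integer(n_classes)
  n_signal_genes_per_class <- as.integer(n_signal_genes_per_class)
  if (n_locations < 1L) stop("`n_locations` must be positive", call. = FALSE)
  if (n_genes < 1L) stop("`n_genes` must be positive", call. = FALSE)
  if (n_classes < 2L) stop("`n_classes` must be at least 2", call. = FALSE)
  if (n_signal_genes_per_class < 1L ||
      n_signal_genes_per_class * n_classes > n_genes) {
    stop("signal gene blocks must fit: n_signal_genes_per_class * n_classes <= n_genes",
         call. = FALSE)
  }
  if (baseline_log_sd < 0) stop("`baseline_log_sd` must be >= 0", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (zero_inflation < 0 || zero_inflation > 1) {
    stop("`zero_inflation` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(logfc_per_class)) {
    logfc_per_class <- log(seq(2, 8, length.out = n_classes))
  }
  if (length(logfc_per_class) != n_classes) {
    stop("`logfc_per_class` must have one value per class", call. = FALSE)
  }
  structure(list(n_locations = n_locations, n_genes = n_genes,
                 layout = layout, pattern = pattern, n_classes = n_classes,
                 n_signal_genes_per_class = n_signal_genes_per_class,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, zero_inflation = zero_inflation,
                 logfc_per_class = as.numeric(logfc_per_class),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d locations x %d genes, %s layout, %s pattern, %d classes\n",
              x$n_locations, x$n_genes, x$layout, x$pattern, x$n_classes))
  cat(sprintf("  signal genes/class %d, dispersion %.3g, zero inflation %.3g, seed %d\n",
              x$n_signal_genes_per_class, x$dispersion, x$zero_inflation, x$seed))
  invisible(x)
}

#' Generate spatial coordinates
#'
#' `"grid"` lays points on the most-square integer lattice with
#' `ceiling(sqrt(n))` columns at unit spacing, truncated to exactly `n`
#' points. `"random"` scatters `n` points uniformly on a square of side
#' `sqrt(n)`, keeping point density ~1 regardless of `n`.
#'
#' @param layout `"grid"` or `"random"`.
#' @param n Number of points (>= 1).
#' @param seed Integer seed (only the random layout consumes randomness).
#' @return An `n x 2` coordinate matrix.
#' @export
generate_coordinates <- function(layout = c("grid", "random"), n, seed = 1L) {
  layout <- match.arg(layout)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (layout == "grid") {
    ncols <- ceiling(sqrt(n))
    i <- seq_len(n) - 1L
    coords <- cbind(x = as.numeric(i %% ncols), y = as.numeric(i %/% ncols))
  } else {
    side <- sqrt(n)
    coords <- with_seed(seed, cbind(x = runif(n) * side, y = runif(n) * side))
  }
  coords
}

#' Assign spatial domain labels
#'
#' Partitions the tissue into `n_classes` spatial domains: `"stripes"` cuts
#' the x-range into equal-width vertical bands; `"radial"` forms
#' equal-population concentric annuli about the coordinate centroid;
#' `"complex"` builds a Voronoi mosaic from randomly placed seed points
#' (three per class, so every class owns at least one seed).
#'
#' @param coords `n x 2` coordinate matrix.
#' @param pattern `"stripes"`, `"radial"`, or `"complex"`.
#' @param n_classes Number of domain classes (>= 2).
#' @param seed Integer seed (consumed by the complex pattern only).
#' @return A factor of length `n` with levels `"A"`, `"B"`, ...; every class
#'   is non-empty.
#' @export
assign_domain_labels <- function(coords, pattern = c("stripes", "radial", "complex"),
                                 n_classes = 6L, seed = 1L) {
  pattern <- match.arg(pattern)
  coords <- as.matrix(coords)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be at least 2", call. = FALSE)
  n <- nrow(coords)
  if (nrow(unique(coords)) < n_classes) {
    stop("infeasible layout: fewer distinct coordinates than classes", call. = FALSE)
  }
  lev <- LETTERS[seq_len(n_classes)]
  cls <- switch(pattern,
    stripes = {
      x <- coords[, 1]
      rng <- range(x)
      if (rng[1] == rng[2]) stop("infeasible layout: degenerate x-range", call. = FALSE)
      band <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_classes) + 1L
      pmin(band, n_classes)
    },
    radial = {
      ctr <- colMeans(coords)
      d <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2)
      # equal-population annuli: rank distances (index-ordered ties) into
      # n_classes consecutive blocks
      r <- rank(d, ties.method = "first")
      as.integer(ceiling(r * n_classes / n))
    },
    complex = {
      m <- 3L  # Voronoi seeds per class
      rng_x <- range(coords[, 1])
      rng_y <- range(coords[, 2])
      seeds <- with_seed(seed, cbind(
        runif(n_classes * m, rng_x[1], rng_x[2]),
        runif(n_classes * m, rng_y[1], rng_y[2])))
      seed_class <- rep(seq_len(n_classes), times = m)
      nearest <- knn_search(seeds, coords, k = 1L)$idx[, 1]
      assigned <- seed_class[nearest]
      # guarantee non-empty classes: hand each empty class the point closest
      # to its first seed
      for (c in seq_len(n_classes)) {
        if (!any(assigned == c)) {
          s <- seeds[which(seed_class == c)[1], , drop = FALSE]
          assigned[which.min(cross_dist2(coords, s))] <- c
        }
      }
      assigned
    })
  labels <- factor(lev[cls], levels = lev)
  if (any(tabulate(labels, n_classes) == 0L)) {
    stop("infeasible layout: an empty class was produced", call. = FALSE)
  }
  labels
}

#' Simulate zero-inflated negative-binomial counts
#'
#' Each gene g draws a baseline mean `mu_g ~ LogNormal(baseline_log_mean,
#' baseline_log_sd)`. Each class owns a disjoint block of
#' `n_signal_genes_per_class` signal genes whose mean is multiplied by
#' `exp(logfc)` in cells of that class; all other genes are noise genes at
#' baseline. Counts are NB(mu, size = dispersion) and then independently
#' zeroed with probability `zero_inflation`.
#'
#' @param labels Factor of cell labels drawn from the configuration's class
#'   set (`"A"`, `"B"`, ...).
#' @param cfg A [sim_config()] (its `n_locations` is ignored in favour of
#'   `length(labels)`).
#' @return A sparse `length(labels) x n_genes` count matrix.
#' @export
simulate_counts <- function(labels, cfg) {
  stopifnot(is(cfg, "sim_config"))
  labels <- as.factor(labels)
  lev <- LETTERS[seq_len(cfg$n_classes)]
  if (!all(levels(labels) %in% lev)) {
    stop("unknown class label: labels must come from the configuration's classes",
         call. = FALSE)
  }
  labels <- factor(labels, levels = lev)
  n <- length(labels)
  g <- cfg$n_genes
  s <- cfg$n_signal_genes_per_class
  class_idx <- as.integer(labels)
  # gene -> owning class (0 = noise gene)
  gene_class <- integer(g)
  gene_class[seq_len(cfg$n_classes * s)] <- rep(seq_len(cfg$n_classes), each = s)
  seeds <- derive_seeds(cfg$seed, 2L)
  mu_g <- with_seed(seeds[1], rlnorm(g, cfg$baseline_log_mean, cfg$baseline_log_sd))
  with_seed(seeds[2], {
    ii <- vector("list", g)
    xx <- vector("list", g)
    for (j in seq_len(g)) {
      mu <- rep(mu_g[j], n)
      oc <- gene_class[j]
      if (oc > 0L) {
        hit <- class_idx == oc
        mu[hit] <- mu[hit] * exp(cfg$logfc_per_class[oc])
      }
      cnt <- rnbinom(n, size = cfg$dispersion, mu = mu)
      if (cfg$zero_inflation > 0) {
        cnt[runif(n) < cfg$zero_inflation] <- 0L
      }
      nz <- which(cnt > 0L)
      ii[[j]] <- nz
      xx[[j]] <- cnt[nz]
    }
    Matrix::sparseMatrix(
      i = unlist(ii, use.names = FALSE),
      j = rep.int(seq_len(g), lengths(ii)),
      x = as.numeric(unlist(xx, use.names = FALSE)),
      dims = c(n, g),
      dimnames = list(NULL, paste0("gene", seq_len(g))))
  })
}

#' Build a complete simulated dataset
#'
#' Composes [generate_coordinates()], [assign_domain_labels()] and
#' [simulate_counts()] using independent random streams derived from
#' `cfg$seed`; the ground-truth labels are stored on the dataset.
#'
#' @param cfg A [sim_config()].
#' @return An `st_dataset` with the configuration attached as attribute
#'   `"config"`.
#' @export
#' @examples
#' d <- make_dataset(sim_config(n_locations = 200, n_genes = 30,
#'                              layout = "random", pattern = "stripes",
#'                              n_signal_genes_per_class = 5, seed = 7))
#' d
make_dataset <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 3L)
  coords <- generate_coordinates(cfg$layout, cfg$n_locations, seed = seeds[1])
  labels <- assign_domain_labels(coords, cfg$pattern, cfg$n_classes, seed = seeds[2])
  counts <- simulate_counts(labels, modifyList_config(cfg, seed = seeds[3]))
  out <- st_dataset(counts, coords, labels = labels)
  attr(out, "config") <- cfg
  out
}

# replace fields of a sim_config while keeping validation
modifyList_config <- function(cfg, ...) {
  new <- utils::modifyList(unclass(cfg), list(...))
  do.call(sim_config, new)
}
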