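# Internal numerical utilities shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations never
#' perturb the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive `n` independent child seeds from a parent seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Squared Euclidean cross-distance matrix between rows of `a` (m x d) and
# rows of `b` (p x d), computed via the expanded inner product.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Distance from each row of `query` to its nearest row of `ref`.
# Chunked so the cross-distance block stays bounded in memory.
nn1_dist <- function(query, ref, chunk = 2048L) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  n <- nrow(query)
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- cross_dist2(query[idx, , drop = FALSE], ref)
    # max.col on the negated matrix is a fast per-row argmin
    j <- max.col(-d2, ties.method = "first")
    out[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
  }
  out
}

#' Exact k-nearest-neighbour search
#'
#' Returns, for each row of `query`, the indices of its `k` nearest rows of
#' `ref` (Euclidean distance, ties broken by lowest index). When `query` and
#' `ref` are the same object each point is excluded from its own neighbour
#' list. Two-dimensional inputs at large n are routed through an exact
#' grid-bucket search; everything else uses chunked brute force.
#'
#' @param ref Numeric matrix of reference points (n x d).
#' @param query Numeric matrix of query points; defaults to `ref`.
#' @param k Number of neighbours to return.
#' @return List with integer matrix `idx` (nrow(query) x k) and numeric
#'   matrix `dist` of the corresponding distances.
#' @keywords internal
#' @noRd
knn_search <- function(ref, query = NULL, k) {
  ref <- as.matrix(ref)
  self_query <- is.null(query)
  query <- if (self_query) ref else as.matrix(query)
  n_ref <- nrow(ref)
  k <- as.integer(k)
  max_k <- if (self_query) n_ref - 1L else n_ref
  if (k < 1L || k > max_k) {
    stop("`k` must be between 1 and the number of available neighbours",
         call. = FALSE)
  }
  if (ncol(ref) == 2L && nrow(query) > 20000L) {
    return(knn_grid_2d(ref, query, k, self_query))
  }
  knn_brute(ref, query, k, self_query)
}

knn_brute <- function(ref, query, k, self_query, chunk = 1024L) {
  nq <- nrow(query)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  starts <- seq(1L, nq, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nq)
    d2 <- cross_dist2(query[rows, , drop = FALSE], ref)
    if (self_query) d2[cbind(seq_along(rows), rows)] <- Inf
    for (i in seq_along(rows)) {
      o <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(d2[i, o])
    }
  }
  list(idx = idx, dist = dst)
}

# Exact 2-D kNN via uniform grid buckets with ring expansion. Correct because
# a query's k-th candidate distance is compared against the guaranteed-covered
# radius of the searched ring before acceptance.
knn_grid_2d <- function(ref, query, k, self_query) {
  n_ref <- nrow(ref)
  nq <- nrow(query)
  rng_x <- range(ref[, 1], query[, 1])
  rng_y <- range(ref[, 2], query[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1], .Machine$double.eps)
  # aim for ~2k points per 3x3 block so one ring usually suffices
  ncell <- max(1L, as.integer(floor(sqrt(n_ref * 9 / (2 * k)))))
  h <- span / ncell
  cell_of <- function(xy) {
    cx <- pmin(ncell - 1L, pmax(0L, as.integer(floor((xy[, 1] - rng_x[1]) / h))))
    cy <- pmin(ncell - 1L, pmax(0L, as.integer(floor((xy[, 2] - rng_y[1]) / h))))
    list(cx = cx, cy = cy, id = cx * ncell + cy)
  }
  rc <- cell_of(ref)
  qc <- cell_of(query)
  ref_by_cell <- split(seq_len(n_ref), rc$id)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  q_groups <- split(seq_len(nq), qc$id)
  for (grp in q_groups) {
    gx <- qc$cx[grp[1]]
    gy <- qc$cy[grp[1]]
    ring <- 1L
    repeat {
      xs <- max(0L, gx - ring):min(ncell - 1L, gx + ring)
      ys <- max(0L, gy - ring):min(ncell - 1L, gy + ring)
      ids <- as.character(outer(xs * ncell, ys, "+"))
      cand <- unlist(ref_by_cell[ids], use.names = FALSE)
      need <- k + as.integer(self_query)
      # radius guaranteed fully covered by this ring of cells
      covered <- ring * h
      if (length(cand) >= need) {
        d2 <- cross_dist2(query[grp, , drop = FALSE],
                          ref[cand, , drop = FALSE])
        if (self_query) {
          hit <- match(grp, cand)
          ok <- !is.na(hit)
          if (any(ok)) d2[cbind(which(ok), hit[ok])] <- Inf
        }
        kth <- numeric(length(grp))
        ord <- vector("list", length(grp))
        for (i in seq_along(grp)) {
          o <- order(d2[i, ], cand)[seq_len(k)]
          ord[[i]] <- o
          kth[i] <- sqrt(d2[i, o[k]])
        }
        if (all(kth <= covered) || ring >= 2L * ncell) {
          for (i in seq_along(grp)) {
            idx[grp[i], ] <- cand[ord[[i]]]
            dst[grp[i], ] <- sqrt(d2[i, ord[[i]]])
          }
          break
        }
      } else if (ring >= 2L * ncell) {
        stop("grid kNN failed to gather enough candidates", call. = FALSE)
      }
      ring <- ring + 1L
    }
  }
  list(idx = idx, dist = dst)
}
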