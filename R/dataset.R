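#' Spatial transcriptomics dataset container
#'
#' Bundles a cells/locations-by-genes count matrix with 2-D spatial
#' coordinates, optional per-cell domain/cell-type labels, and unique cell
#' identifiers. This is the universal input consumed by preprocessing,
#' sketching, and evaluation.
#'
#' @param counts Matrix of non-negative integer counts, cells as rows. Dense
#'   matrices are converted to sparse `dgCMatrix` storage.
#' @param coords Numeric matrix or data frame with two columns (x, y), one
#'   row per cell, in consistent units.
#' @param labels Optional factor/character vector of per-cell labels.
#' @param ids Optional character vector of unique cell identifiers; defaults
#'   to the rownames of `counts` or `cell1..celln`.
#' @return An object of class `st_dataset`: a list with elements `counts`
#'   (sparse matrix), `coords` (n x 2 matrix), `labels` (factor or NULL) and
#'   `ids` (character).
#' @export
#' @examples
#' counts <- matrix(rpois(60, 5), nrow = 10)
#' coords <- cbind(runif(10), runif(10))
#' st_dataset(counts, coords)
st_dataset <- function(counts, coords, labels = NULL, ids = NULL) {
  if (!is(counts, "sparseMatrix")) {
    counts <- as(as(as(as.matrix(counts), "dMatrix"), "generalMatrix"),
                 "CsparseMatrix")
  } else {
    counts <- as(counts, "CsparseMatrix")
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(counts)
  if (ncol(coords) != 2L) stop("`coords` must have exactly two columns", call. = FALSE)
  if (nrow(coords) != n) stop("`coords` must have one row per cell", call. = FALSE)
  if (any(counts@x < 0) || any(counts@x != floor(counts@x))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- rownames(counts)
    if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must have one entry per cell", call. = FALSE)
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != n) stop("`labels` must have one entry per cell", call. = FALSE)
  }
  rownames(counts) <- ids
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  structure(list(counts = counts, coords = coords, labels = labels, ids = ids),
            class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d cells/locations x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels (%d classes): %s\n", length(tab),
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  } else {
    cat("labels: none\n")
  }
  cat(sprintf("coordinate ranges: x [%.3g, %.3g], y [%.3g, %.3g]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

#' Subset an st_dataset by cell indices
#'
#' @param x An `st_dataset`.
#' @param i Integer, logical, or character (id) index of cells to keep.
#' @param ... Ignored.
#' @return The subsetted `st_dataset`, rows in the order of `i`.
#' @export
subset_cells <- function(x, i, ...) {
  stopifnot(is(x, "st_dataset"))
  if (is.character(i)) i <- match(i, x$ids)
  st_dataset(x$counts[i, , drop = FALSE], x$coords[i, , drop = FALSE],
             labels = if (!is.null(x$labels)) x$labels[i] else NULL,
             ids = x$ids[i])
}

#' Write an st_dataset to a directory
#'
#' Emits the plain-text dataset layout used throughout the package:
#' `counts.mtx` (Matrix Market, cells as rows), `coords.csv` (id,x,y),
#' `labels.csv` (id,label; only when labels exist), and `config.json` when a
#' simulation configuration is attached.
#'
#' @param x An `st_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_st_dataset <- function(x, dir) {
  stopifnot(is(x, "st_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "counts.mtx"))
  write.csv(data.frame(id = x$ids, x = x$coords[, 1], y = x$coords[, 2]),
            file.path(dir, "coords.csv"), row.names = FALSE)
  if (!is.null(x$labels)) {
    write.csv(data.frame(id = x$ids, label = as.character(x$labels)),
              file.path(dir, "labels.csv"), row.names = FALSE)
  }
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an st_dataset from a directory
#'
#' @param dir Directory written by [write_st_dataset()] (or following the
#'   same layout: `counts.mtx`, `coords.csv`, optional `labels.csv`).
#' @return An `st_dataset`.
#' @export
read_st_dataset <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  coords <- read.csv(file.path(dir, "coords.csv"))
  labels <- NULL
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    lab <- read.csv(lab_path)
    labels <- lab$label[match(coords$id, lab$id)]
  }
  st_dataset(counts, as.matrix(coords[, c("x", "y")]), labels = labels,
             ids = coords$id)
}
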