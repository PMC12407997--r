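test_that("grid coordinates form the most-square unit lattice, truncated to n", {
  expect_equal(generate_coordinates("grid", 4),
               cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
               ignore_attr = FALSE)
  c7 <- generate_coordinates("grid", 7)
  expect_equal(nrow(c7), 7)
  expect_equal(max(c7[, 1]), 2)  # ceiling(sqrt(7)) = 3 columns -> x in 0..2
  expect_true(all(c7 == floor(c7)))
  expect_error(generate_coordinates("grid", 0), "positive")
})

test_that("random coordinates are deterministic per seed and uniform on the square", {
  a <- generate_coordinates("random", 5000, seed = 1)
  b <- generate_coordinates("random", 5000, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_coordinates("random", 5000, seed = 2)))
  side <- sqrt(5000)
  expect_true(all(a >= 0 & a <= side))
  # mean of U(0, side) is side/2 with sd side/sqrt(12)
  se <- side / sqrt(12) / sqrt(5000)
  expect_lt(abs(mean(a[, 1]) - side / 2), 3 * se)
  expect_lt(abs(mean(a[, 2]) - side / 2), 3 * se)
})

test_that("stripe labels depend only on x; radial labels only on centroid distance", {
  coords <- generate_coordinates("random", 2000, seed = 3)
  lab <- assign_domain_labels(coords, "stripes", n_classes = 6)
  # same x band -> same label, regardless of y
  band <- pmin(floor((coords[, 1] - min(coords[, 1])) /
                       diff(range(coords[, 1])) * 6) + 1, 6)
  expect_true(all(tapply(as.integer(lab), band, function(v) length(unique(v))) == 1))

  rad <- assign_domain_labels(coords, "radial", n_classes = 6)
  ctr <- colMeans(coords)
  d <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  # annuli are monotone in distance: sorting by distance sorts the labels
  expect_true(!is.unsorted(as.integer(rad)[order(d)]))
  # equal-population annuli
  expect_true(max(abs(table(rad) - 2000 / 6)) <= 1)
})

test_that("complex pattern produces all classes non-empty and is seed-deterministic", {
  coords <- generate_coordinates("random", 10000, seed = 5)
  lab <- assign_domain_labels(coords, "complex", n_classes = 6, seed = 7)
  expect_identical(levels(lab), LETTERS[1:6])
  expect_true(all(table(lab) >= 1))
  expect_identical(lab, assign_domain_labels(coords, "complex", 6, seed = 7))
})

test_that("stripes and radial layouts are class-balanced within 20%", {
  for (layout in c("grid", "random")) {
    coords <- generate_coordinates(layout, 10000, seed = 2)
    for (pattern in c("stripes", "radial")) {
      tab <- table(assign_domain_labels(coords, pattern, 6))
      expect_true(all(abs(tab - 10000 / 6) <= 0.2 * 10000 / 6),
                  info = paste(layout, pattern))
    }
  }
})

test_that("degenerate zero inflation empties the count matrix", {
  cfg <- sim_config(n_locations = 50, n_genes = 20, n_classes = 2,
                    n_signal_genes_per_class = 5, zero_inflation = 1, seed = 1)
  lab <- factor(rep(c("A", "B"), 25))
  expect_equal(sum(simulate_counts(lab, cfg)), 0)
})

test_that("equal log-fold changes leave no detectable class difference in gene means", {
  n_per <- 5000
  cfg <- sim_config(n_locations = 2 * n_per, n_genes = 30, n_classes = 2,
                    n_signal_genes_per_class = 5, zero_inflation = 0,
                    logfc_per_class = c(log(3), log(3)), seed = 8)
  lab <- factor(rep(c("A", "B"), each = n_per))
  counts <- as.matrix(simulate_counts(lab, cfg))
  # noise genes (not owned by either class) must agree between classes
  noise <- 11:30
  for (j in noise[1:5]) {
    a <- counts[lab == "A", j]
    b <- counts[lab == "B", j]
    se <- sqrt(var(a) / n_per + var(b) / n_per)
    expect_lt(abs(mean(a) - mean(b)), 4 * max(se, 1e-12))
  }
})

test_that("a log(4) fold change lifts signal-gene means four-fold", {
  n_per <- 5000
  cfg <- sim_config(n_locations = 2 * n_per, n_genes = 30, n_classes = 2,
                    n_signal_genes_per_class = 5, zero_inflation = 0,
                    baseline_log_mean = log(2), baseline_log_sd = 0.3,
                    logfc_per_class = c(log(4), 0), seed = 9)
  lab <- factor(rep(c("A", "B"), each = n_per))
  counts <- as.matrix(simulate_counts(lab, cfg))
  sig <- 1:5  # class A's signal block
  ratio <- colMeans(counts[lab == "A", sig]) / colMeans(counts[lab == "B", sig])
  expect_true(all(abs(ratio - 4) < 0.4))
})

test_that("simulate_counts rejects labels outside the configured class set", {
  cfg <- sim_config(n_locations = 10, n_genes = 10, n_classes = 2,
                    n_signal_genes_per_class = 2, seed = 1)
  expect_error(simulate_counts(factor(c("A", "Z")), cfg), "unknown class")
})

test_that("make_dataset composes the generators deterministically", {
  cfg <- sim_config(n_locations = 100, n_genes = 20, n_classes = 4,
                    n_signal_genes_per_class = 5, layout = "random",
                    pattern = "radial", seed = 33)
  d1 <- make_dataset(cfg)
  expect_s3_class(d1, "st_dataset")
  expect_equal(dim(d1$counts), c(100, 20))
  expect_equal(dim(d1$coords), c(100, 2))
  expect_equal(length(d1$labels), 100)
  d2 <- make_dataset(cfg)
  expect_equal(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$coords, d2$coords)
  expect_identical(d1$labels, d2$labels)
})

test_that("the default configuration matches the simulated-dataset design", {
  cfg <- sim_config()
  expect_equal(cfg$n_locations, 100000L)
  expect_equal(cfg$n_genes, 500L)
  expect_equal(cfg$n_classes, 6L)
  expect_equal(length(cfg$logfc_per_class), 6L)
  expect_true(all(diff(cfg$logfc_per_class) > 0))
})

test_that("dataset round-trips through the directory writer", {
  d <- make_dataset(sim_config(n_locations = 80, n_genes = 15, n_classes = 3,
                               n_signal_genes_per_class = 4,
                               layout = "random", seed = 12))
  dir <- tempfile("stds")
  write_st_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c("counts.mtx", "coords.csv",
                                               "labels.csv", "config.json")))))
  d2 <- read_st_dataset(dir)
  expect_equal(as.matrix(d2$counts), unname(as.matrix(d$counts)),
               ignore_attr = TRUE)
  expect_equal(unname(d2$coords), unname(d$coords))
  expect_equal(as.character(d2$labels), as.character(d$labels))
})
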