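# Shared fixtures, built in code at test time.

# A small scattered dataset with stripe domains; cached per session because
# several files reuse it.
small_stripe_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_locations = 600, n_genes = 60, layout = "random",
                        pattern = "stripes", n_classes = 3,
                        n_signal_genes_per_class = 10, seed = 101)
      cache <<- make_dataset(cfg)
    }
    cache
  }
})

# Dense random matrix with reproducible entries.
rand_matrix <- function(n, g, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * g), n, g)
}

# Brute-force directed partial Hausdorff: full pairwise distances, NN per
# full point, order statistic. Independent of the package's chunked search.
brute_hausdorff <- function(full, sk, q = 1) {
  full <- as.matrix(full); sk <- as.matrix(sk)
  d <- apply(full, 1, function(p) {
    min(sqrt(colSums((t(sk) - p)^2)))
  })
  sort(d)[ceiling(q * length(d))]
}

# Brute-force pair-counting ARI: iterate over all unordered pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  s00 <- s11 <- s01 <- s10 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (same_a) s10 <- s10 + 1
    else if (same_b) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  n2 <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / n2
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(m + 1L)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}
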