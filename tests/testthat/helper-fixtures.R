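# Shared fixtures, all built in code.

# tiny deterministic count matrix
toy_counts <- function() {
  count_matrix(matrix(c(5L, 0L, 3L, 7L), 2, 2,
                      dimnames = list(c("hsa-miR-141", "hsa-miR-200c"),
                                      c("S1", "S2"))))
}

# a standardized pair with one strong planted block and Gaussian noise;
# returns the pair plus the planted index sets
block_pair <- function(m = 100, n = 60, rows = 1:10, cols = 1:8,
                       effect = 5, seed = 42) {
  set.seed(seed)
  e <- matrix(rnorm(m * n), m, n,
              dimnames = list(sprintf("g%03d", 1:m), sprintf("s%03d", 1:n)))
  e[rows, cols] <- e[rows, cols] + effect
  list(pair = standardize(e), rows = rownames(e)[rows], cols = colnames(e)[cols])
}

# the standard recovery benchmark instance, preprocessed
benchmark_fit_input <- function(seed) {
  sim <- generate_counts(planted_benchmark_design(seed = seed))
  prep <- suppressMessages(preprocess_counts(sim$counts, sim$family_map))
  list(sim = sim, prep = prep)
}

# a small hand-made bicluster set over a fixed universe
tiny_bicluster_set <- function() {
  b1 <- new_bicluster(row_scores = c(g1 = 1, g2 = -0.5),
                      col_scores = c(s1 = 1, s2 = 0.25),
                      iterations = 3L, basin_count = 4L)
  b2 <- new_bicluster(row_scores = c(g3 = -1),
                      col_scores = c(s3 = 1),
                      iterations = 7L, basin_count = 2L)
  bicluster_set(list(b1, b2), row_ids = paste0("g", 1:4),
                col_ids = paste0("s", 1:4),
                params = list(th_r = 3.5, th_c = 1, n_seeds = 10, seed = 99))
}

# exhaustive two-sided Fisher oracle: enumerate the hypergeometric
# distribution with the table's margins via choose(); independent of
# stats::fisher.test and of the package implementation
fisher_oracle_p <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  r1 <- n11 + n10
  c1 <- n11 + n01
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), numeric(1))
  p_obs <- probs[ks == n11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
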