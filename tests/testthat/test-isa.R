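test_that("seed generation is sparse, uniform and reproducible", {
  expect_identical(generate_seeds(5, 3, sparsity = 5, seed = 1),
                   rep(list(rep(1L, 5)), 3))        # forced all-ones
  s1 <- generate_seeds(100, 100, sparsity = 2, seed = 9)
  s2 <- generate_seeds(100, 100, sparsity = 2, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, sum, integer(1)) == 2L))
  expect_true(all(vapply(s1, function(v) all(v %in% 0:1), logical(1))))
  expect_error(generate_seeds(5, 1, sparsity = 6), "between 1 and m")
})

test_that("z-score thresholding matches direct arithmetic", {
  v <- c(0, 0, 0, 10)
  sd_pop <- sqrt(mean((v - mean(v))^2))            # 4.330127
  out <- threshold_scores(v, 1.0)
  expect_equal(out[4], (10 - 2.5) / sd_pop, tolerance = 1e-12)   # ~1.732
  expect_equal(out[1:3], rep(0, 3))
  # th = 0 keeps every entry with nonzero z
  all_kept <- threshold_scores(c(1, 2, 3, 4), 0)
  expect_true(all(all_kept != 0))
  expect_error(threshold_scores(c(5, 5, 5), 1),
               class = "mirmod_degenerate_error")
  expect_error(threshold_scores(3, 1), ">= 2 entries")
})

test_that("thresholding support shrinks monotonically in th", {
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(50)
    ths <- sort(runif(3, 0, 3))
    sup <- lapply(ths, function(th) which(threshold_scores(v, th) != 0))
    expect_true(all(sup[[2]] %in% sup[[1]]))
    expect_true(all(sup[[3]] %in% sup[[2]]))
  }
})

test_that("the ISA iteration converges onto a planted block", {
  bp <- block_pair()
  seed <- integer(100)
  seed[c(2, 7)] <- 1L                               # inside the planted rows
  bc <- isa_iterate(bp$pair, seed, th_r = 2, th_c = 2)
  expect_s3_class(bc, "bicluster")
  expect_setequal(names(bc$row_scores), bp$rows)
  expect_setequal(names(bc$col_scores), bp$cols)
  expect_equal(max(abs(bc$row_scores)), 1)
  expect_equal(max(abs(bc$col_scores)), 1)

  # oracle: the planted supports are a fixed point of one hand-computed
  # thresholded iteration (independent arithmetic, no package calls)
  er <- bp$pair$E_rows; ec <- bp$pair$E_cols
  zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  r01 <- as.numeric(rownames(er) %in% names(bc$row_scores))
  cz <- zs(drop(t(er) %*% r01)); cz[abs(cz) <= 2] <- 0
  rz <- zs(drop(ec %*% cz)); rz[abs(rz) <= 2] <- 0
  expect_setequal(colnames(er)[cz != 0], names(bc$col_scores))
  expect_setequal(rownames(er)[rz != 0], names(bc$row_scores))
})

test_that("a seed in pure noise with a huge row threshold dies out", {
  set.seed(5)
  e <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
  sp <- standardize(e)
  seed <- integer(50); seed[c(3, 4)] <- 1L
  expect_null(isa_iterate(sp, seed, th_r = 6, th_c = 1))
  expect_error(isa_iterate(sp, integer(10), 1, 1), "does not match row count")
})

test_that("duplicate fixed points merge and accumulate basins", {
  b <- new_bicluster(c(g1 = 1, g2 = 0.5), c(s1 = 1), basin_count = 1L)
  merged <- merge_fixed_points(list(b, b), cor_merge = 0.9,
                               row_ids = paste0("g", 1:3),
                               col_ids = paste0("s", 1:2))
  expect_length(merged$biclusters, 1)
  expect_equal(merged$biclusters[[1]]$basin_count, 2L)
  other <- new_bicluster(c(g3 = -1), c(s2 = 1), basin_count = 1L)
  kept <- merge_fixed_points(list(b, other), cor_merge = 0.9,
                             row_ids = paste0("g", 1:3),
                             col_ids = paste0("s", 1:2))
  expect_length(kept$biclusters, 2)
})

test_that("a single planted block yields exactly one bicluster from 100 seeds", {
  bp <- block_pair()
  fit <- suppressMessages(run_isa(bp$pair, th_r = 2, th_c = 2, seed = 13))
  expect_length(fit, 1)
  expect_setequal(names(fit$biclusters[[1]]$row_scores), bp$rows)
  expect_gt(fit$biclusters[[1]]$basin_count, 1)
})

test_that("runs are reproducible from the seed and record their parameters", {
  bp <- block_pair()
  f1 <- suppressMessages(run_isa(bp$pair, th_r = 2, th_c = 2, seed = 4))
  f2 <- suppressMessages(run_isa(bp$pair, th_r = 2, th_c = 2, seed = 4))
  expect_equal(f1$biclusters, f2$biclusters)
  expect_equal(f1$params$th_r, 2)
  expect_equal(f1$params$seed, 4)
  expect_true(f1$params$n_converged <= f1$params$n_seeds)
})

test_that("membership matrices embed scores densely and stay bounded", {
  bs <- tiny_bicluster_set()
  mm <- membership_matrices(bs)
  expect_equal(dim(mm$row_membership), c(4L, 2L))
  expect_equal(mm$row_membership["g3", "BC2"], -1)
  expect_equal(mm$row_membership["g4", "BC1"], 0)
  expect_true(all(abs(mm$row_membership) <= 1))
  expect_true(all(abs(mm$col_membership) <= 1))
  # column restricted to support equals the stored scores
  b1 <- bs$biclusters[[1]]
  expect_equal(mm$row_membership[names(b1$row_scores), "BC1"], b1$row_scores)
  empty <- bicluster_set(list(), row_ids = "g1", col_ids = "s1")
  mm0 <- membership_matrices(empty)
  expect_equal(ncol(mm0$row_membership), 0L)
  stray <- bicluster_set(list(b1), row_ids = names(b1$row_scores),
                         col_ids = names(b1$col_scores))
  expect_error(membership_matrices(stray, all_row_ids = "g1",
                                   all_col_ids = names(b1$col_scores)),
               "unknown ids")
})

test_that("biclusters may overlap when overlapping modules are planted", {
  d <- planted_design(
    m = 200, n = 150,
    modules = list(list(rows = 1:10, cols = 1:15, sign = 1, f = 4),
                   list(rows = 7:16, cols = 40:55, sign = 1, f = 4)),
    baseline_sdlog = 0.1, library_total_range = c(1e4, 5e5),
    dispersion = 0.05, seed = 8)
  sim <- generate_counts(d)
  prep <- suppressMessages(preprocess_counts(sim$counts, sim$family_map))
  fit <- suppressMessages(run_isa(prep$pair, seed = 8))
  expect_gte(length(fit), 2)
  mm <- membership_matrices(fit)$row_membership
  shared <- rowSums(mm != 0) >= 2
  overlap_ids <- sprintf("sf-hsa-mir-%03d", 7:10)
  expect_gt(sum(shared[overlap_ids]), 0)
})
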