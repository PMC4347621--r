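test_that("matching a set against itself is the identity", {
  bs <- tiny_bicluster_set()
  mr <- match_biclusters(bs, bs)
  expect_equal(mr$relevance, 1)
  expect_equal(mr$recovery, 1)
  expect_true(all(diag(mr$jaccard) == 1))
})

test_that("support Jaccard follows set arithmetic", {
  a <- bicluster_set(list(new_bicluster(c(g1 = 1, g2 = 1), c(s1 = 1))),
                     row_ids = paste0("g", 1:3), col_ids = "s1")
  b <- bicluster_set(list(new_bicluster(c(g2 = 1, g3 = 1), c(s1 = 1))),
                     row_ids = paste0("g", 1:3), col_ids = "s1")
  mr <- match_biclusters(a, b)
  expect_equal(mr$jaccard[1, 1], 2 / 4)    # {g2,s1} over {g1,g2,g3,s1}
  disj <- bicluster_set(list(new_bicluster(c(g3 = 1), c(s1 = 1))),
                        row_ids = paste0("g", 1:3), col_ids = "s1")
  only_rows_differ <- match_biclusters(
    bicluster_set(list(new_bicluster(c(g1 = 1), c(s1 = 1))),
                  row_ids = paste0("g", 1:3), col_ids = c("s1", "s2")),
    bicluster_set(list(new_bicluster(c(g3 = 1), c(s2 = 1))),
                  row_ids = paste0("g", 1:3), col_ids = c("s1", "s2")))
  expect_equal(only_rows_differ$jaccard[1, 1], 0)
  expect_warning(mr0 <- match_biclusters(
    bicluster_set(list(), row_ids = "g1", col_ids = "s1"), disj), "empty")
  expect_equal(mr0$relevance, 0)
  expect_equal(mr0$recovery, 0)
})

test_that("relevance and recovery are permutation invariant and nest", {
  bs <- tiny_bicluster_set()
  flipped <- bicluster_set(rev(bs$biclusters), bs$row_ids, bs$col_ids)
  mr <- match_biclusters(bs, flipped)
  expect_equal(mr$relevance, 1)
  expect_equal(mr$recovery, 1)
  # B = A plus an extra bicluster: relevance stays 1, recovery drops
  extra <- new_bicluster(c(g4 = 1), c(s4 = 1))
  bigger <- bicluster_set(c(bs$biclusters, list(extra)), bs$row_ids, bs$col_ids)
  mr2 <- match_biclusters(bs, bigger)
  expect_equal(mr2$relevance, 1)
  expect_lt(mr2$recovery, 1)
})

test_that("a single run is trivially stable", {
  bp <- block_pair(m = 60, n = 40, rows = 1:8, cols = 1:6)
  st <- stability_analysis(bp$pair, n_runs = 1, seed = 2,
                           th_r = 2, th_c = 2, n_seeds = 30)
  expect_true(st$stable)
  expect_equal(st$n_runs, 1)
  expect_true(is.na(st$min_jaccard))
})

test_that("repeated reseeding on a planted block is stable", {
  bp <- block_pair(m = 60, n = 40, rows = 1:8, cols = 1:6)
  st <- stability_analysis(bp$pair, n_runs = 4, seed = 2,
                           th_r = 2, th_c = 2, n_seeds = 30)
  expect_true(st$stable)
  expect_equal(unname(st$counts), rep(1L, 4))
  expect_equal(st$min_jaccard, 1)
})

test_that("Fisher association matches the hypergeometric enumeration", {
  # bicluster membership = exactly the 5 TNBC samples of a balanced cohort
  meta <- cohort_metadata(data.frame(
    sample_id = sprintf("S%02d", 1:10),
    er_status = rep(c("negative", "positive"), each = 5),
    pr_status = rep(c("negative", "positive"), each = 5),
    her2_status = rep(c("negative", "positive"), each = 5),
    histology = "IDC",
    molecular_subtype = rep(c("Basal", "LuminalA"), each = 5)))
  bs <- bicluster_set(
    list(new_bicluster(c(g1 = 1), setNames(rep(1, 5), sprintf("S%02d", 1:5)))),
    row_ids = "g1", col_ids = meta$sample_id)
  at <- annotation_association(bs, meta)
  tn <- at[at$characteristic == "tnbc" & at$level == "yes", ]
  expect_equal(tn$n_in_has, 5)
  expect_equal(tn$n_out_lacks, 5)
  expect_equal(tn$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(tn$p_value, fisher_oracle_p(5, 0, 0, 5), tolerance = 1e-12)
  expect_true(tn$or_corrected)               # empty cells: corrected OR
  expect_equal(tn$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  expect_true(all(at$q_value >= at$p_value - 1e-12))
  expect_true(all(na.omit(at$q_value) <= 1))
})

test_that("independent annotations give odds ratios around 1", {
  set.seed(31)
  ids <- sprintf("S%03d", 1:400)
  meta <- cohort_metadata(data.frame(
    sample_id = ids,
    er_status = sample(c("positive", "negative"), 400, replace = TRUE),
    pr_status = sample(c("positive", "negative"), 400, replace = TRUE),
    her2_status = sample(c("positive", "negative"), 400, replace = TRUE),
    histology = sample(c("IDC", "DCIS"), 400, replace = TRUE),
    molecular_subtype = "Basal"))
  members <- sample(ids, 150)
  bs <- bicluster_set(list(new_bicluster(c(g1 = 1), setNames(rep(1, 150), members))),
                      row_ids = "g1", col_ids = ids)
  at <- annotation_association(bs, meta)
  ors <- at$odds_ratio[at$characteristic %in% c("er_status", "pr_status", "her2_status")]
  expect_true(all(abs(log(ors)) < log(2)))   # no spurious strong enrichment
  expect_gt(min(at$p_value[at$characteristic == "er_status"]), 0.001)
})

test_that("biclusters without annotated samples yield NA statistics", {
  meta <- cohort_metadata(data.frame(
    sample_id = c("S1", "S2"), er_status = c("positive", "negative"),
    pr_status = "negative", her2_status = "negative",
    histology = "IDC", molecular_subtype = "Basal"))
  bs <- bicluster_set(list(new_bicluster(c(g1 = 1), c(S9 = 1))),
                      row_ids = "g1", col_ids = c("S1", "S2", "S9"))
  at <- annotation_association(bs, meta)
  expect_true(all(is.na(at$p_value)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(at, p)
  expect_match(readLines(p, n = 1), "^# extension")
})
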