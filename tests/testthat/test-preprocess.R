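test_that("library filter keeps totals at or above the cut and is idempotent", {
  cm <- count_matrix(matrix(c(4999L, 0L, 5000L, 0L, 1L, 2000L), 2, 3,
                            dimnames = list(c("a", "b"), c("L1", "L2", "L3"))))
  expect_message(out <- filter_libraries(cm), "dropped 2/3")
  expect_identical(colnames(out), "L2")           # 4999 dropped, 5000 kept
  expect_identical(rownames(out), c("a", "b"))
  expect_identical(attr(out, "dropped_samples"), c("L1", "L3"))
  again <- filter_libraries(out)
  expect_identical(unclass(again)[, , drop = FALSE], unclass(out)[, , drop = FALSE])
  expect_identical(colnames(filter_libraries(cm, min_reads = 0)), colnames(cm))
  cm2 <- count_matrix(matrix(c(2000L, 7500L, 5001L), 1, 3,
                             dimnames = list("a", c("L1", "L2", "L3"))))
  expect_identical(ncol(suppressMessages(filter_libraries(cm2))), 2L)
  expect_error(filter_libraries(cm, min_reads = 1e7), "all libraries fall below")
})

test_that("read frequencies are percent shares summing to 100", {
  cm <- count_matrix(matrix(c(2L, 3L, 5L, 1L, 1L, 2L), 3, 2,
                            dimnames = list(c("a", "b", "c"), c("L1", "L2"))))
  rf <- to_read_frequencies(cm)
  expect_equal(rf[, "L1"], c(a = 20, b = 30, c = 50))
  expect_equal(unname(colSums(rf)), c(100, 100))
  single <- count_matrix(matrix(7L, 1, 1, dimnames = list("a", "L1")))
  expect_equal(as.numeric(to_read_frequencies(single)), 100)
  quarters <- count_matrix(matrix(rep(1L, 4), 4, 1,
                                  dimnames = list(letters[1:4], "L1")))
  expect_equal(unname(to_read_frequencies(quarters)[, 1]), rep(25, 4))
  zero <- count_matrix(matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("L1", "L2"))))
  expect_error(to_read_frequencies(zero), "zero total reads.*L2")
})

test_that("family condensation sums member frequencies and conserves totals", {
  fm <- rbind(m1 = c(10, 20), m2 = c(5, 5), m3 = c(85, 75))
  colnames(fm) <- c("L1", "L2")
  map <- c(m1 = "f", m2 = "f", m3 = "g")
  out <- condense_families(fm, map)
  expect_equal(out["f", ], c(L1 = 15, L2 = 25))
  expect_equal(unname(colSums(out)), unname(colSums(fm)))
  # singleton families: identity up to renaming
  map1 <- setNames(paste0("sf-", rownames(fm)), rownames(fm))
  out1 <- condense_families(fm, map1)
  expect_equal(unname(out1[order(sub("sf-", "", rownames(out1))), ]),
               unname(fm[order(rownames(fm)), ]))
  expect_error(condense_families(fm, map[-1]), "missing from family map: m1")
})

test_that("standardization matches direct arithmetic and drops constants", {
  fm <- rbind(x = c(1, 2, 3), y = c(4, 4, 4), z = c(9, 1, 5))
  colnames(fm) <- c("L1", "L2", "L3")
  expect_message(sp <- standardize(fm), "constant rows: y")
  expect_identical(sp$dropped_rows, "y")
  # row (1,2,3) with population SD sqrt(2/3)
  expect_equal(unname(sp$E_rows["x", ]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(sp$E_rows))), 1e-9)
  expect_lt(max(abs(apply(sp$E_rows, 1, function(r) sqrt(mean((r - mean(r))^2))) - 1)), 1e-9)
  expect_lt(max(abs(colMeans(sp$E_cols))), 1e-9)
  expect_error(standardize(fm[1, , drop = FALSE]), "at least 2 rows")
  expect_error(standardize(rbind(c(1, 1), c(2, 2))), "non-degenerate")
})

test_that("normalization is invariant to row order and per-library scaling", {
  set.seed(11)
  cm <- count_matrix(matrix(rpois(60, 50) + 1L, 10, 6,
                            dimnames = list(sprintf("m%02d", 1:10),
                                            sprintf("L%d", 1:6))))
  rf <- to_read_frequencies(cm)
  # rf is scale-free per library
  scaled <- cm
  scaled[, 2] <- scaled[, 2] * 7L
  expect_equal(to_read_frequencies(count_matrix(scaled)), rf)
  # standardize commutes with row permutation
  perm <- sample(nrow(rf))
  sp1 <- standardize(rf)
  sp2 <- standardize(rf[perm, ])
  expect_equal(sp2$E_rows[rownames(sp1$E_rows), ], sp1$E_rows)
  expect_equal(sp2$E_cols[rownames(sp1$E_cols), ], sp1$E_cols)
})

test_that("the preprocessing chain reports stage dimensions", {
  sim <- generate_counts(planted_design(m = 40, n = 20, seed = 5,
                                        mirnas_per_family = 3))
  expect_gt(nrow(sim$counts), 40)  # families split into member miRNAs
  prep <- suppressMessages(preprocess_counts(sim$counts, sim$family_map,
                                             min_reads = 1000))
  expect_equal(nrow(prep$rf), 40)  # condensed back to families
  expect_equal(unname(colSums(prep$rf)), rep(100, ncol(prep$rf)),
               tolerance = 1e-9)
  expect_named(prep$stages, c("input", "filtered", "condensed", "standardized"))
})
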