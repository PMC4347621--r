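#' Match two bicluster sets by support Jaccard
#'
#' Similarity between two biclusters is the Jaccard index of their supports,
#' taken on the union of row and column supports (row and sample ids live in
#' disjoint namespaces).  Working on supports rather than scores makes ISA
#' results comparable with sign-free external biclusterings.  Besides the
#' full pairwise matrix, a greedy one-to-one assignment (descending Jaccard,
#' each bicluster used once) is reported; `relevance` is the mean best-match
#' Jaccard of `a`'s biclusters into `b`, `recovery` the mean best-match of
#' `b` into `a`.
#'
#' @param a,b `bicluster_set`s over the same id universes.
#' @return object of class `match_result`: list with `jaccard` (matrix
#'   `length(a)` x `length(b)`), `assignment` (data.frame `a`, `b`,
#'   `jaccard`), `relevance`, `recovery`.
#' @export
match_biclusters <- function(a, b) {
  ka <- length(a$biclusters); kb <- length(b$biclusters)
  if (ka == 0 || kb == 0) {
    warning("empty bicluster set; relevance and recovery set to 0")
    return(structure(list(jaccard = matrix(numeric(0), ka, kb),
                          assignment = data.frame(a = integer(), b = integer(),
                                                  jaccard = numeric()),
                          relevance = 0, recovery = 0),
                     class = "match_result"))
  }
  sup_a <- lapply(a$biclusters, tag_support)
  sup_b <- lapply(b$biclusters, tag_support)
  jac <- matrix(0, ka, kb, dimnames = list(paste0("A", seq_len(ka)),
                                           paste0("B", seq_len(kb))))
  for (i in seq_len(ka))
    for (j in seq_len(kb))
      jac[i, j] <- length(intersect(sup_a[[i]], sup_b[[j]])) /
        length(union(sup_a[[i]], sup_b[[j]]))

  ord <- order(-jac)
  used_a <- logical(ka); used_b <- logical(kb)
  pairs <- list()
  for (idx in ord) {
    i <- ((idx - 1) %% ka) + 1
    j <- ((idx - 1) %/% ka) + 1
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j, jaccard = jac[i, j])
      if (all(used_a) || all(used_b)) break
    }
  }
  structure(list(jaccard = jac,
                 assignment = do.call(rbind, pairs),
                 relevance = mean(apply(jac, 1, max)),
                 recovery = mean(apply(jac, 2, max))),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("bicluster match: %d vs %d; relevance %.3f, recovery %.3f\n",
              nrow(x$jaccard), ncol(x$jaccard), x$relevance, x$recovery))
  if (nrow(x$assignment))
    print(x$assignment, row.names = FALSE)
  invisible(x)
}

#' Stability of ISA results across random initializations
#'
#' Re-runs [run_isa()] `n_runs` times with per-run RNG seeds derived
#' deterministically from a master seed, then compares every run with the
#' first, order-invariantly (the order in which fixed points are found is
#' arbitrary).  The result is flagged stable when every run yields the same
#' number of biclusters and every greedily matched pair agrees at Jaccard
#' `>= jaccard_threshold`.
#'
#' @param sp a `standardized_pair`.
#' @param n_runs number of independent runs, default 10.
#' @param seed master seed; run `i` uses `seed + i`.
#' @param jaccard_threshold per-pair agreement threshold, default 0.95.
#' @param ... ISA parameters passed to [run_isa()] (held fixed across runs).
#' @return object of class `stability_report`: per-run bicluster counts,
#'   all matched Jaccard values against run 1, their min/mean, and `stable`.
#' @export
stability_analysis <- function(sp, n_runs = 10, seed = 1,
                               jaccard_threshold = 0.95, ...) {
  runs <- lapply(seq_len(n_runs), function(i)
    suppressMessages(run_isa(sp, ..., seed = seed + i)))
  counts <- vapply(runs, length, integer(1))
  jaccards <- numeric(0)
  stable <- TRUE
  if (n_runs > 1) {
    for (i in 2:n_runs) {
      if (counts[i] != counts[1]) { stable <- FALSE }
      if (counts[i] == 0 || counts[1] == 0) {
        if (counts[i] != counts[1]) jaccards <- c(jaccards, 0)
        next
      }
      mr <- suppressWarnings(match_biclusters(runs[[1]], runs[[i]]))
      jaccards <- c(jaccards, mr$assignment$jaccard)
      if (nrow(mr$assignment) < max(counts[1], counts[i]) ||
          any(mr$assignment$jaccard < jaccard_threshold))
        stable <- FALSE
    }
  }
  structure(list(n_runs = n_runs, counts = counts, jaccards = jaccards,
                 min_jaccard = if (length(jaccards)) min(jaccards) else NA_real_,
                 mean_jaccard = if (length(jaccards)) mean(jaccards) else NA_real_,
                 jaccard_threshold = jaccard_threshold,
                 stable = stable, seed = seed, runs = runs),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability over %d runs: %s\n", x$n_runs,
              if (x$stable) "STABLE" else "not stable"))
  cat("  biclusters per run:", paste(x$counts, collapse = " "), "\n")
  if (length(x$jaccards))
    cat(sprintf("  matched Jaccard vs run 1: min %.3f mean %.3f (threshold %.2f)\n",
                x$min_jaccard, x$mean_jaccard, x$jaccard_threshold))
  invisible(x)
}

# annotation characteristics tested, with the levels whose membership defines
# "has annotation"; unknown / unannotated samples are excluded per level
.association_levels <- function(meta) {
  tnbc <- ifelse(meta$er_status == "negative" & meta$pr_status == "negative" &
                   meta$her2_status == "negative", "yes",
                 ifelse(meta$er_status == "positive" | meta$pr_status == "positive" |
                          meta$her2_status == "positive", "no", "unknown"))
  list(
    er_status = list(values = meta$er_status, levels = c("positive", "negative"),
                     known = meta$er_status != "unknown"),
    pr_status = list(values = meta$pr_status, levels = c("positive", "negative"),
                     known = meta$pr_status != "unknown"),
    her2_status = list(values = meta$her2_status, levels = c("positive", "negative"),
                       known = meta$her2_status != "unknown"),
    tnbc = list(values = tnbc, levels = c("yes"), known = tnbc != "unknown"),
    histology = list(values = meta$histology,
                     levels = intersect(.histology_levels, unique(meta$histology)),
                     known = rep(TRUE, nrow(meta))),
    molecular_subtype = list(values = meta$molecular_subtype,
                             levels = setdiff(intersect(.subtype_levels,
                                                        unique(meta$molecular_subtype)),
                                              "NA"),
                             known = meta$molecular_subtype != "NA"))
}

#' Bicluster-phenotype association table
#'
#' For every (bicluster, annotation level) pair, builds the 2x2 table of
#' sample membership against annotation among samples with known status,
#' tests it with a two-sided Fisher exact test, and adjusts all p-values by
#' Benjamini-Hochberg.  The odds ratio is the sample cross-product ratio; a
#' 0.5 continuity correction is applied (and flagged) when any cell is
#' empty.  The BH-adjusted testing layer is an extension over a purely
#' visual membership analysis and the output header says so.
#'
#' @param bs a `bicluster_set`.
#' @param meta cohort metadata (see [cohort_metadata()]); only samples in
#'   the bicluster universe are used.
#' @return data.frame of class `association_table` with columns `bicluster`,
#'   `characteristic`, `level`, the four cell counts, `odds_ratio`,
#'   `or_corrected`, `p_value`, `q_value`.
#' @export
annotation_association <- function(bs, meta) {
  meta <- cohort_metadata(meta)
  meta <- meta[meta$sample_id %in% bs$col_ids, , drop = FALSE]
  if (!nrow(meta)) stop("no annotated samples overlap the bicluster universe")
  specs <- .association_levels(meta)
  rows <- list()
  for (k in seq_along(bs$biclusters)) {
    members <- names(bs$biclusters[[k]]$col_scores)
    for (ch in names(specs)) {
      spc <- specs[[ch]]
      ann <- meta[spc$known, , drop = FALSE]
      vals <- spc$values[spc$known]
      for (lev in spc$levels) {
        inb <- ann$sample_id %in% members
        has <- vals == lev
        n11 <- sum(inb & has); n10 <- sum(inb & !has)
        n01 <- sum(!inb & has); n00 <- sum(!inb & !has)
        if (sum(inb) == 0 || nrow(ann) == 0) {
          orv <- NA_real_; pv <- NA_real_; corrected <- NA
        } else {
          tab <- matrix(c(n11, n10, n01, n00), 2, byrow = TRUE)
          pv <- .fisher_p(n11, n10, n01, n00)
          corrected <- any(tab == 0)
          orv <- if (corrected)
            ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
          else (n11 * n00) / (n10 * n01)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          bicluster = paste0("BC", k), characteristic = ch, level = lev,
          n_in_has = n11, n_in_lacks = n10, n_out_has = n01, n_out_lacks = n00,
          odds_ratio = orv, or_corrected = corrected, p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("association_table", "data.frame")
  attr(out, "note") <-
    "extension: BH-adjusted two-sided Fisher exact enrichment of sample annotations"
  out
}

# two-sided Fisher exact p for the 2x2 table [[n11, n10], [n01, n00]]
.fisher_p <- function(n11, n10, n01, n00) {
  stats::fisher.test(matrix(c(n11, n10, n01, n00), 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

#' Write an association table as TSV (with its extension note as a header)
#' @param at an `association_table`.
#' @param path destination path.
#' @export
write_association_table <- function(at, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(at, "note")), con)
  utils::write.table(at, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
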