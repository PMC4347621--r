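#' Drop under-sequenced libraries
#'
#' Keeps the sample columns whose total miRNA read count reaches `min_reads`.
#' The 5,000-read default is the conventional cut for replicate-merged miRNA
#' libraries; the boundary is inclusive (a library with exactly `min_reads`
#' reads is kept).  Dropped sample ids are reported via `message()` and
#' attached as attribute `"dropped_samples"`.
#'
#' @param cm count matrix (miRNAs x samples).
#' @param min_reads minimum library total, default 5000.
#' @return the filtered count matrix; errors if no library survives.
#' @export
filter_libraries <- function(cm, min_reads = 5000) {
  totals <- colSums(cm)
  keep <- totals >= min_reads
  if (!any(keep))
    stop("all libraries fall below ", min_reads, " total reads; nothing to analyse")
  dropped <- colnames(cm)[!keep]
  if (length(dropped))
    mirmod_log("filter", "dropped %d/%d libraries below %d reads: %s",
               length(dropped), ncol(cm), min_reads, paste(dropped, collapse = ", "))
  out <- cm[, keep, drop = FALSE]
  attr(out, "dropped_samples") <- dropped
  out
}

#' Convert counts to relative-percent read frequencies
#'
#' `rf(i, j) = 100 * count(i, j) / total(j)`: each miRNA's share of its
#' library, in percent, so every column sums to 100 and libraries of very
#' different depth become comparable.
#'
#' @param cm count matrix with strictly positive column totals (run
#'   [filter_libraries()] first).
#' @return numeric frequency matrix, same dimnames as `cm`.
#' @export
to_read_frequencies <- function(cm) {
  totals <- colSums(cm)
  zero <- totals == 0
  if (any(zero))
    stop("zero total reads in library: ", paste(colnames(cm)[zero], collapse = ", "))
  sweep(cm, 2, totals, "/") * 100
}

#' Condense miRNA read frequencies into sequence families
#'
#' Sums member read frequencies per family and sample.  Read frequencies are
#' additive shares of a library, so summation preserves the 100% column total;
#' averaging would not.
#'
#' @param fm frequency matrix (miRNA rows).
#' @param map named character vector miRNA id -> family id; every row of `fm`
#'   must be mapped (unmapped rows are an error, never silently dropped).
#' @return frequency matrix with one row per family.
#' @export
condense_families <- function(fm, map) {
  missing <- setdiff(rownames(fm), names(map))
  if (length(missing))
    stop("miRNAs missing from family map: ", paste(missing, collapse = ", "))
  fam <- map[rownames(fm)]
  out <- rowsum(fm, group = fam, reorder = FALSE)
  # rowsum returns in group order of appearance; keep it deterministic
  out[order(rownames(out)), , drop = FALSE]
}

#' Doubly standardize an expression matrix for ISA
#'
#' Returns the two standardized variants the ISA iteration needs: `E_rows`
#' with every row at mean 0 / SD 1 (population SD), used to score samples,
#' and `E_cols` with every column at mean 0 / SD 1, used to score rows.
#' Zero-variance rows and columns carry no contrast and are removed from both
#' matrices; their ids are recorded in `dropped_rows` / `dropped_cols`.
#'
#' @param fm numeric matrix with at least 2 informative rows and columns.
#' @return object of class `standardized_pair`: list with `E_rows`, `E_cols`,
#'   `dropped_rows`, `dropped_cols`.
#' @export
standardize <- function(fm) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2 || ncol(fm) < 2)
    stop("standardization needs at least 2 rows and 2 columns")
  row_sd <- apply(fm, 1, sd_pop)
  col_sd <- apply(fm, 2, sd_pop)
  dropped_rows <- rownames(fm)[row_sd == 0]
  dropped_cols <- colnames(fm)[col_sd == 0]
  keep <- fm[row_sd > 0, col_sd > 0, drop = FALSE]
  if (nrow(keep) < 2 || ncol(keep) < 2)
    stop("fewer than 2 non-degenerate rows or columns after dropping zero variance")
  if (length(dropped_rows))
    mirmod_log("standardize", "dropped constant rows: %s",
               paste(dropped_rows, collapse = ", "))
  if (length(dropped_cols))
    mirmod_log("standardize", "dropped constant columns: %s",
               paste(dropped_cols, collapse = ", "))
  e_rows <- t(apply(keep, 1, function(x) (x - mean(x)) / sd_pop(x)))
  e_cols <- apply(keep, 2, function(x) (x - mean(x)) / sd_pop(x))
  dimnames(e_rows) <- dimnames(keep)
  dimnames(e_cols) <- dimnames(keep)
  structure(list(E_rows = e_rows, E_cols = e_cols,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols),
            class = "standardized_pair")
}

#' @export
print.standardized_pair <- function(x, ...) {
  cat(sprintf("Standardized expression pair: %d rows x %d samples\n",
              nrow(x$E_rows), ncol(x$E_rows)))
  if (length(x$dropped_rows))
    cat("  dropped constant rows:", length(x$dropped_rows), "\n")
  if (length(x$dropped_cols))
    cat("  dropped constant columns:", length(x$dropped_cols), "\n")
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' filter -> read frequencies -> family condensation -> standardization, the
#' order in which the corresponding steps are applied to real cohorts.
#'
#' @param cm raw count matrix.
#' @param map optional family map; `NULL` skips condensation.
#' @param min_reads library-size cut, see [filter_libraries()].
#' @return list with `counts` (filtered), `rf` (frequency matrix, condensed if
#'   a map was given), `pair` (standardized pair), and per-stage dimensions in
#'   `stages`.
#' @export
preprocess_counts <- function(cm, map = NULL, min_reads = 5000) {
  stages <- list(input = dim(cm))
  cm <- filter_libraries(cm, min_reads)
  stages$filtered <- dim(cm)
  rf <- to_read_frequencies(cm)
  if (!is.null(map)) {
    rf <- condense_families(rf, map)
    stages$condensed <- dim(rf)
  }
  pair <- standardize(rf)
  stages$standardized <- dim(pair$E_rows)
  mirmod_log("preprocess", "rows at each stage: %s",
             paste(vapply(stages, function(d) paste(d, collapse = "x"), ""),
                   collapse = " -> "))
  list(counts = cm, rf = rf, pair = pair, stages = stages)
}
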