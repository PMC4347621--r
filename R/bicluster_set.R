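#' Construct a single bicluster
#'
#' A bicluster couples a signed sparse score vector over miRNA (or family)
#' ids with one over sample ids.  Scores live in `[-1, +1]`, reach `|1|`
#' somewhere on each side, and their sign encodes correlation direction:
#' members of opposite sign are anti-correlated across the bicluster.
#'
#' @param row_scores,col_scores named numeric vectors over the member ids
#'   (support only, no zeros).
#' @param iterations iterations the ISA run took to converge (NA for
#'   externally supplied or ground-truth biclusters).
#' @param basin_count number of seeds that converged to this fixed point.
#' @return object of class `bicluster`.
#' @export
new_bicluster <- function(row_scores, col_scores, iterations = NA_integer_,
                          basin_count = 1L) {
  for (v in list(row_scores, col_scores)) {
    if (!length(v) || is.null(names(v)) || any(!nzchar(names(v))))
      stop("bicluster scores must be non-empty named vectors")
    if (any(!is.finite(v)) || any(abs(v) > 1 + 1e-12))
      stop("bicluster scores must be finite and within [-1, +1]")
    if (any(v == 0)) stop("bicluster score vectors carry the support only; zeros not allowed")
  }
  structure(list(row_scores = row_scores, col_scores = col_scores,
                 iterations = as.integer(iterations),
                 basin_count = as.integer(basin_count)),
            class = "bicluster")
}

#' Construct a bicluster set
#'
#' @param biclusters list of `bicluster` objects.
#' @param row_ids,col_ids the id universes the supports live in.
#' @param params optional named list of run parameters.
#' @return object of class `bicluster_set`.
#' @export
bicluster_set <- function(biclusters, row_ids, col_ids, params = list()) {
  for (b in biclusters) {
    if (!inherits(b, "bicluster")) stop("all members must be bicluster objects")
    bad_r <- setdiff(names(b$row_scores), row_ids)
    bad_c <- setdiff(names(b$col_scores), col_ids)
    if (length(bad_r) || length(bad_c))
      stop("bicluster ids outside the universe: ",
           paste(c(bad_r, bad_c), collapse = ", "))
  }
  structure(list(biclusters = biclusters, row_ids = row_ids,
                 col_ids = col_ids, params = params),
            class = "bicluster_set")
}

#' Number of biclusters in a set
#' @param x a `bicluster_set`.
#' @export
length.bicluster_set <- function(x) length(x$biclusters)

#' Dense membership matrices of a bicluster set
#'
#' Embeds each bicluster's sparse score vectors into dense matrices over the
#' full id universes: `row_membership` (miRNAs x biclusters) and
#' `col_membership` (samples x biclusters).  Zero means non-membership;
#' column `k` restricted to its support equals bicluster `k`'s scores.
#'
#' @param bs a `bicluster_set`.
#' @param all_row_ids,all_col_ids id universes; default those stored in `bs`.
#' @return list with `row_membership` and `col_membership`.
#' @export
membership_matrices <- function(bs, all_row_ids = bs$row_ids,
                                all_col_ids = bs$col_ids) {
  k <- length(bs$biclusters)
  rm <- matrix(0, length(all_row_ids), max(k, 0),
               dimnames = list(all_row_ids,
                               if (k) paste0("BC", seq_len(k)) else NULL))
  cm <- matrix(0, length(all_col_ids), max(k, 0),
               dimnames = list(all_col_ids,
                               if (k) paste0("BC", seq_len(k)) else NULL))
  for (i in seq_len(k)) {
    b <- bs$biclusters[[i]]
    bad <- c(setdiff(names(b$row_scores), all_row_ids),
             setdiff(names(b$col_scores), all_col_ids))
    if (length(bad))
      stop("bicluster ", i, " references unknown ids: ", paste(bad, collapse = ", "))
    rm[names(b$row_scores), i] <- b$row_scores
    cm[names(b$col_scores), i] <- b$col_scores
  }
  list(row_membership = rm, col_membership = cm)
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d rows x %d samples (basin %d, %s iterations)\n",
              length(x$row_scores), length(x$col_scores), x$basin_count,
              ifelse(is.na(x$iterations), "?", x$iterations)))
  invisible(x)
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("ISA bicluster set: %d bicluster(s) over %d rows x %d samples\n",
              length(x$biclusters), length(x$row_ids), length(x$col_ids)))
  if (length(x$params))
    cat(sprintf("  parameters: th_r=%s th_c=%s n_seeds=%s seed=%s\n",
                x$params$th_r, x$params$th_c, x$params$n_seeds,
                ifelse(is.null(x$params$seed), "none", x$params$seed)))
  for (i in seq_along(x$biclusters)) {
    b <- x$biclusters[[i]]
    cat(sprintf("  BC%d: %d rows, %d samples, basin %d\n", i,
                length(b$row_scores), length(b$col_scores), b$basin_count))
  }
  invisible(x)
}

#' Summarize a bicluster set
#' @param object a `bicluster_set`.
#' @param ... unused.
#' @return data.frame with one row per bicluster: sizes, basin count, top
#'   row members by absolute score.
#' @export
summary.bicluster_set <- function(object, ...) {
  df <- do.call(rbind, lapply(seq_along(object$biclusters), function(i) {
    b <- object$biclusters[[i]]
    top <- names(sort(abs(b$row_scores), decreasing = TRUE))
    data.frame(bicluster = paste0("BC", i),
               n_rows = length(b$row_scores),
               n_samples = length(b$col_scores),
               basin_count = b$basin_count,
               iterations = b$iterations,
               top_rows = paste(utils::head(top, 4), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(bicluster = character(), n_rows = integer(),
                     n_samples = integer(), basin_count = integer(),
                     iterations = integer(), top_rows = character())
  class(df) <- c("summary.bicluster_set", "data.frame")
  df
}

#' Membership matrices as model coefficients
#' @param object a `bicluster_set`.
#' @param ... unused.
#' @export
coef.bicluster_set <- function(object, ...) membership_matrices(object)

#' Heatmap of sample memberships
#'
#' Base-graphics view of the samples x biclusters membership matrix on a
#' diverging scale centred at 0; samples belonging to no bicluster are
#' omitted, as in the usual cohort visualization.
#'
#' @param x a `bicluster_set`.
#' @param ... passed to [graphics::image()].
#' @export
plot.bicluster_set <- function(x, ...) {
  mm <- membership_matrices(x)$col_membership
  if (!ncol(mm)) {
    plot.new()
    graphics::title("empty bicluster set")
    return(invisible(x))
  }
  keep <- rowSums(mm != 0) > 0
  mm <- mm[keep, , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(x = seq_len(ncol(mm)), y = seq_len(nrow(mm)), z = t(mm),
                  zlim = c(-1, 1), col = pal, xlab = "bicluster",
                  ylab = "sample", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(mm)), labels = colnames(mm))
  graphics::box()
  invisible(x)
}
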