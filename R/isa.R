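#' Generate random sparse binary seed vectors
#'
#' Each seed is a 0/1 vector of length `m` with exactly `sparsity` ones at
#' positions drawn uniformly without replacement.  Seeds select the initial
#' row (miRNA) set from which the ISA iteration starts.
#'
#' @param m number of rows of the expression matrix.
#' @param n_seeds number of seeds.
#' @param sparsity number of 1-entries per seed, `1 <= sparsity <= m`.
#' @param seed optional RNG seed; the seed list is fully determined by it.
#' @return list of integer 0/1 vectors.
#' @export
generate_seeds <- function(m, n_seeds, sparsity = 2, seed = NULL) {
  if (sparsity < 1 || sparsity > m)
    stop("sparsity must be between 1 and m = ", m)
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_seeds), function(i) {
    v <- integer(m)
    v[sample.int(m, sparsity)] <- 1L
    v
  })
}

#' Z-score threshold a score vector
#'
#' Standardizes `v` to `z = (v - mean) / SD` (population SD) and keeps the
#' entries with `|z| > th`, zeroing the rest.  The thresholding is two-sided
#' and the signed z value is retained, so anti-correlated members enter a
#' bicluster with negative scores.  Strict inequality at the boundary.
#'
#' @param v numeric vector, length >= 2.
#' @param th non-negative threshold in SD units.
#' @return vector of the same length (and names) with sub-threshold entries
#'   set to 0; all-zero if nothing passes.  A zero-variance `v` raises a
#'   classed condition (`mirmod_degenerate_error`); the ISA driver discards
#'   the offending seed.
#' @export
threshold_scores <- function(v, th) {
  if (length(v) < 2) stop("score vector needs >= 2 entries")
  if (th < 0) stop("threshold must be non-negative")
  s <- sd_pop(v)
  if (s == 0) degenerate_vector_error("zero-variance score vector")
  z <- (v - mean(v)) / s
  z[abs(z) <= th] <- 0
  z
}

# One ISA half-cycle: sample scores from the row-standardized matrix, then
# row scores from the column-standardized matrix.  Returns NULL when the seed
# dies (degenerate or all-zero intermediate vector).
.isa_step <- function(sp, r, th_r, th_c) {
  tryCatch({
    c_new <- threshold_scores(drop(crossprod(sp$E_rows, r)), th_c)
    if (all(c_new == 0)) return(NULL)
    r_new <- threshold_scores(drop(sp$E_cols %*% c_new), th_r)
    if (all(r_new == 0)) return(NULL)
    list(r = r_new, c = c_new)
  }, mirmod_degenerate_error = function(e) NULL)
}

#' Run the ISA iteration from one seed
#'
#' Alternates thresholded matrix products
#' `c_i = threshold(E_rows' r_{i-1}, th_c)` and
#' `r_i = threshold(E_cols c_i, th_r)` until consecutive score vectors agree
#' at Pearson correlation `>= 1 - eps` in both dimensions.  The converged
#' signature is then refined from its binarized row support until the support
#' map reaches an exact fixed point, so a reported bicluster's supports
#' reproduce themselves under one further iteration.  Scores are scaled to
#' unit max-norm per side; the sign is canonicalized so the sample-score sum
#' is non-negative (a fixed point and its global sign flip are the same
#' bicluster).
#'
#' @param sp a `standardized_pair` from [standardize()].
#' @param seed 0/1 seed vector of length `nrow(sp$E_rows)`.
#' @param th_r,th_c row and sample z-score thresholds.
#' @param eps convergence slack: converged when Pearson `>= 1 - eps`.
#' @param max_iter iteration cap.
#' @return a `bicluster` (list with named `row_scores`, `col_scores` on their
#'   supports, `iterations`, `basin_count = 1`), or `NULL` if the seed does
#'   not converge.
#' @export
isa_iterate <- function(sp, seed, th_r, th_c, eps = 0.01, max_iter = 100) {
  m <- nrow(sp$E_rows)
  if (length(seed) != m)
    stop("seed length ", length(seed), " does not match row count ", m)
  r_prev <- as.numeric(seed)
  c_prev <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    st <- .isa_step(sp, r_prev, th_r, th_c)
    if (is.null(st)) return(NULL)
    if (!is.null(c_prev) &&
        safe_cor(st$r, r_prev) >= 1 - eps &&
        safe_cor(st$c, c_prev) >= 1 - eps) {
      converged <- TRUE
      r_prev <- st$r
      c_prev <- st$c
      break
    }
    r_prev <- st$r
    c_prev <- st$c
  }
  if (!converged) return(NULL)

  # support polishing: iterate the binarized-support map to an exact fixed
  # point (seeds whose support map cycles are dropped as non-converged)
  r01 <- as.numeric(r_prev != 0)
  final <- NULL
  for (k in seq_len(30)) {
    st <- .isa_step(sp, r01, th_r, th_c)
    if (is.null(st)) return(NULL)
    r01_new <- as.numeric(st$r != 0)
    it <- it + 1
    if (identical(r01_new, r01)) {
      final <- st
      break
    }
    r01 <- r01_new
  }
  if (is.null(final)) return(NULL)

  r <- final$r / max(abs(final$r))
  cc <- final$c / max(abs(final$c))
  if (sum(cc) < 0) {   # canonical orientation
    r <- -r
    cc <- -cc
  }
  names(r) <- rownames(sp$E_rows)
  names(cc) <- colnames(sp$E_rows)
  new_bicluster(row_scores = r[r != 0], col_scores = cc[cc != 0],
                iterations = it, basin_count = 1L)
}

#' Deduplicate converged fixed points
#'
#' Two fixed points are duplicates when the Pearson correlations of their
#' dense row-score vectors and of their dense column-score vectors both
#' exceed `cor_merge`.  Duplicates collapse onto the member with the largest
#' accumulated basin count (ties: first found); basin counts add up.
#'
#' @param candidates list of `bicluster` objects from one run.
#' @param cor_merge duplicate-correlation threshold, default 0.9.
#' @param row_ids,col_ids the id universes used for dense embedding.
#' @return a `bicluster_set` (without run parameters; [run_isa()] fills them).
#' @export
merge_fixed_points <- function(candidates, cor_merge = 0.9, row_ids, col_ids) {
  reps <- list()
  dense <- function(scores, ids) {
    v <- stats::setNames(numeric(length(ids)), ids)
    v[names(scores)] <- scores
    v
  }
  for (cand in candidates) {
    cr <- dense(cand$row_scores, row_ids)
    cc <- dense(cand$col_scores, col_ids)
    hit <- 0L
    for (i in seq_along(reps)) {
      if (safe_cor(cr, reps[[i]]$dr) > cor_merge &&
          safe_cor(cc, reps[[i]]$dc) > cor_merge) {
        hit <- i
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- list(bc = cand, dr = cr, dc = cc,
                                        basin = cand$basin_count)
    } else {
      rep_i <- reps[[hit]]
      if (cand$basin_count > rep_i$basin) {     # keep the larger basin's scores
        rep_i$bc <- cand
        rep_i$dr <- cr
        rep_i$dc <- cc
      }
      rep_i$basin <- rep_i$basin + cand$basin_count
      reps[[hit]] <- rep_i
    }
  }
  bcs <- lapply(reps, function(x) {
    x$bc$basin_count <- x$basin
    x$bc
  })
  bicluster_set(bcs, row_ids = row_ids, col_ids = col_ids)
}

#' Robustness of a bicluster on a standardized pair
#'
#' The signal strength of a fixed point: the bilinear form of its score
#' vectors through the standardized matrices, normalized by the score norms,
#' averaged over the two standardization directions.  Coherent modules score
#' high; fixed points carried by a single noisy row score like noise.
#'
#' @param bc a `bicluster`.
#' @param sp the `standardized_pair` the bicluster was fitted on.
#' @return non-negative robustness score.
#' @export
robustness_score <- function(bc, sp) {
  r <- stats::setNames(numeric(nrow(sp$E_rows)), rownames(sp$E_rows))
  cc <- stats::setNames(numeric(ncol(sp$E_rows)), colnames(sp$E_rows))
  r[names(bc$row_scores)] <- bc$row_scores
  cc[names(bc$col_scores)] <- bc$col_scores
  nrm <- sqrt(sum(r^2)) * sqrt(sum(cc^2))
  (abs(drop(r %*% sp$E_cols %*% cc)) + abs(drop(r %*% sp$E_rows %*% cc))) / (2 * nrm)
}

# Permute the standardized pair coherently: every row of the row-standardized
# matrix is shuffled independently (which destroys column alignment, i.e. the
# biclusters, while keeping each row's value distribution), then the column
# side is re-standardized from the shuffled matrix so the pair stays
# consistent.  Noise-intrinsic fixed points (e.g. a single extreme row
# reinforcing itself) survive this permutation and therefore calibrate the
# robustness filter.
.permute_pair <- function(sp) {
  er <- t(apply(sp$E_rows, 1, sample))
  dimnames(er) <- dimnames(sp$E_rows)
  ec <- apply(er, 2, function(x) (x - mean(x)) / sd_pop(x))
  dimnames(ec) <- dimnames(sp$E_rows)
  structure(list(E_rows = er, E_cols = ec,
                 dropped_rows = sp$dropped_rows, dropped_cols = sp$dropped_cols),
            class = "standardized_pair")
}

#' Fit ISA biclusters to an expression matrix
#'
#' The main fitting function: runs the Iterative Signature Algorithm from
#' `n_seeds` random sparse seeds, discards non-converging seeds, merges
#' duplicate fixed points and returns the resulting transcription modules as
#' a classed set with soft signed memberships in `[-1, +1]`.
#'
#' The two thresholds are the key tuning parameters: high `th_r` demands very
#' coherent miRNA sets, high `th_c` very coherent sample sets; lowering
#' either grows the biclusters.  The defaults `th_r = 3.5`, `th_c = 1.0` suit
#' percent read-frequency profiles of miRNA families over tumour cohorts.
#'
#' @param x a `standardized_pair`, or a numeric matrix which is passed
#'   through [standardize()] first.
#' @param th_r,th_c row (miRNA) and column (sample) z-score thresholds.
#' @param n_seeds number of random seeds, default 100.
#' @param sparsity ones per seed, default 2.
#' @param eps Pearson convergence slack, default 0.01.
#' @param max_iter per-seed iteration cap, default 100.
#' @param cor_merge duplicate-merge correlation, default 0.9.
#' @param filter_robust drop fixed points whose [robustness_score()] does
#'   not exceed the maximum observed when the same seeds are run on
#'   permuted matrices (default `TRUE`).  Random expression matrices have
#'   genuine ISA fixed points (any single row reinforces itself); the
#'   permutation null separates those from real modules.
#' @param n_perm number of matrix permutations used to calibrate the
#'   robustness null, default 3; the threshold is the maximum robustness
#'   over all of them, times `rob_margin`.
#' @param rob_margin safety factor on the permutation-null maximum, default
#'   1.25.  The null maximum is itself a finite-sample estimate; the margin
#'   absorbs its sampling error.  Real modules score several-fold above the
#'   noise edge, so the margin does not cost sensitivity.
#' @param min_basin minimum number of seeds that must reach a fixed point
#'   for it to be reported, default 2.  A fixed point reached from a single
#'   seed out of `n_seeds` is by definition not reproducible under
#'   reseeding; requiring two independent attainments is the within-run
#'   analogue of the cross-run stability protocol.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @return object of class `bicluster_set`; empty (with a warning) when no
#'   seed converges.
#' @seealso [membership_matrices()], [match_biclusters()],
#'   [stability_analysis()]
#' @examples
#' sim <- generate_counts(planted_benchmark_design(seed = 1))
#' prep <- preprocess_counts(sim$counts, sim$family_map)
#' fit <- run_isa(prep$pair, seed = 1)
#' fit
#' @export
run_isa <- function(x, th_r = 3.5, th_c = 1.0, n_seeds = 100, sparsity = 2,
                    eps = 0.01, max_iter = 100, cor_merge = 0.9,
                    filter_robust = TRUE, n_perm = 3, rob_margin = 1.25,
                    min_basin = 2, seed = NULL) {
  sp <- if (inherits(x, "standardized_pair")) x else standardize(x)
  m <- nrow(sp$E_rows)
  seeds <- generate_seeds(m, n_seeds, sparsity, seed = seed)
  collect <- function(pair) {
    cands <- list()
    for (s in seeds) {
      bc <- isa_iterate(pair, s, th_r, th_c, eps = eps, max_iter = max_iter)
      if (!is.null(bc)) cands[[length(cands) + 1L]] <- bc
    }
    cands
  }
  cands <- collect(sp)
  params <- list(th_r = th_r, th_c = th_c, n_seeds = n_seeds,
                 sparsity = sparsity, eps = eps, max_iter = max_iter,
                 cor_merge = cor_merge, filter_robust = filter_robust,
                 n_perm = n_perm, rob_margin = rob_margin,
                 min_basin = min_basin, seed = seed,
                 n_converged = length(cands))
  empty <- function() {
    bs <- bicluster_set(list(), row_ids = rownames(sp$E_rows),
                        col_ids = colnames(sp$E_rows))
    bs$params <- params
    bs
  }
  if (!length(cands)) {
    warning("no seed converged; returning an empty bicluster set")
    return(empty())
  }
  bs <- merge_fixed_points(cands, cor_merge = cor_merge,
                           row_ids = rownames(sp$E_rows),
                           col_ids = colnames(sp$E_rows))
  bs$biclusters <- Filter(function(b) b$basin_count >= min_basin, bs$biclusters)
  if (!length(bs$biclusters)) {
    warning("no fixed point was reached from at least min_basin seeds")
    return(empty())
  }
  if (filter_robust) {
    rob_null <- 0
    for (p in seq_len(n_perm)) {
      perm <- .permute_pair(sp)
      null_cands <- collect(perm)
      if (length(null_cands))
        rob_null <- max(rob_null,
                        vapply(null_cands, robustness_score, numeric(1), sp = perm))
    }
    rob <- vapply(bs$biclusters, robustness_score, numeric(1), sp = sp)
    keep <- rob > rob_margin * rob_null
    params$robustness_threshold <- rob_margin * rob_null
    mirmod_log("isa", "robustness filter: %d/%d modules above null max %.2f",
               sum(keep), length(keep), rob_null)
    bs$biclusters <- bs$biclusters[keep]
    if (!length(bs$biclusters)) {
      warning("no bicluster survived the robustness filter")
      return(empty())
    }
  }
  ord <- order(-vapply(bs$biclusters, function(b) b$basin_count, numeric(1)))
  bs$biclusters <- bs$biclusters[ord]
  bs$params <- params
  mirmod_log("isa", "%d/%d seeds converged onto %d biclusters",
             length(cands), n_seeds, length(bs$biclusters))
  bs
}
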