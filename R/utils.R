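# Internal numeric helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Population standard deviation (denominator n).  Both the standardization of
# the expression matrix and the z-score thresholding inside the ISA iteration
# use the population form; ISA only needs the two to be consistent.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Pearson correlation that is defined for every pair of equal-length vectors:
# identical vectors correlate at 1 even when constant; a constant vector
# against anything else correlates at 0.
safe_cor <- function(a, b) {
  if (isTRUE(all.equal(a, b, tolerance = 0))) return(1)
  sa <- sd_pop(a)
  sb <- sd_pop(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

# Classed error for a zero-variance score vector; callers inside the ISA loop
# catch it and discard the seed.
degenerate_vector_error <- function(msg) {
  stop(structure(
    class = c("mirmod_degenerate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

mirmod_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Tagged support universe: row and column ids live in one namespace so Jaccard
# on the union of both supports cannot collide.
tag_support <- function(bc) {
  c(paste0("r|", names(bc$row_scores)), paste0("c|", names(bc$col_scores)))
}
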