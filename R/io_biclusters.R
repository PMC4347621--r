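#' Write a bicluster set to its structured-text dialect
#'
#' Line-oriented, diff-able format: a magic header, `#%param` lines carrying
#' the run parameters, `#%rows` / `#%cols` lines carrying the id universes,
#' then one block per bicluster opened by `>k<TAB>iterations<TAB>basin_count`
#' followed by `R<TAB>id<TAB>score` and `C<TAB>id<TAB>score` member lines.
#' Scores are serialized to 12 significant digits, so write-read round-trips
#' are identities for all practical purposes.  This dialect is also the
#' ingestion route for externally produced biclusterings (e.g. SAMBA output
#' re-expressed as blocks with unit scores).
#'
#' @param bs a `bicluster_set`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(bs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) {
    if (is.null(x)) "NULL"
    else if (is.numeric(x)) sprintf("%.12g", x)
    else as.character(x)
  }
  writeLines("#%mirmodules-biclusters 1", con)
  for (nm in names(bs$params))
    writeLines(paste("#%param", nm, fmt(bs$params[[nm]]), sep = "\t"), con)
  writeLines(paste0("#%rows\t", paste(bs$row_ids, collapse = "\t")), con)
  writeLines(paste0("#%cols\t", paste(bs$col_ids, collapse = "\t")), con)
  for (k in seq_along(bs$biclusters)) {
    b <- bs$biclusters[[k]]
    writeLines(sprintf(">%d\t%s\t%d", k,
                       ifelse(is.na(b$iterations), "NA", b$iterations),
                       b$basin_count), con)
    for (i in seq_along(b$row_scores))
      writeLines(sprintf("R\t%s\t%.12g", names(b$row_scores)[i], b$row_scores[i]), con)
    for (i in seq_along(b$col_scores))
      writeLines(sprintf("C\t%s\t%.12g", names(b$col_scores)[i], b$col_scores[i]), con)
  }
  invisible(path)
}

#' Read a bicluster set from its structured-text dialect
#'
#' Strictly validates the format (magic line, block structure, finite scores
#' within `[-1, +1]`); errors cite the offending line number.
#'
#' @param path file path written by [write_biclusters()] (or hand-authored
#'   in the same dialect for external results).
#' @return a `bicluster_set`.
#' @export
read_biclusters <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) stop(sprintf("%s:%d: %s", path, i, why))
  if (!length(lines) || lines[1] != "#%mirmodules-biclusters 1")
    bad(1, "missing '#%mirmodules-biclusters 1' header")
  params <- list()
  row_ids <- col_ids <- NULL
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (!length(cur$r) || !length(cur$c))
      bad(cur$line, "bicluster block with an empty row or column support")
    blocks[[length(blocks) + 1L]] <<- cur
  }
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) && !identical(x, "NA")) NULL else v
  }
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "#%param") {
      if (length(f) != 3) bad(i, "malformed #%param line")
      v <- num(f[3])
      params[[f[2]]] <- if (is.null(v)) f[3] else v
    } else if (f[1] == "#%rows") {
      row_ids <- f[-1]
    } else if (f[1] == "#%cols") {
      col_ids <- f[-1]
    } else if (startsWith(f[1], ">")) {
      flush()
      if (length(f) != 3) bad(i, "bicluster header needs '>k\\titerations\\tbasin'")
      cur <- list(line = i, iterations = suppressWarnings(as.integer(f[2])),
                  basin = suppressWarnings(as.integer(f[3])),
                  r = numeric(), c = numeric())
      if (is.na(cur$basin)) bad(i, "non-integer basin count")
    } else if (f[1] %in% c("R", "C")) {
      if (is.null(cur)) bad(i, "member line outside a bicluster block")
      if (length(f) != 3) bad(i, "member line needs 'R|C\\tid\\tscore'")
      sc <- suppressWarnings(as.numeric(f[3]))
      if (is.na(sc) || !is.finite(sc)) bad(i, "non-numeric score")
      if (abs(sc) > 1) bad(i, sprintf("score %s outside [-1, +1]", f[3]))
      if (sc == 0) bad(i, "zero score in a support line")
      if (f[1] == "R") cur$r[f[2]] <- sc else cur$c[f[2]] <- sc
    } else {
      bad(i, sprintf("unrecognized record '%s'", f[1]))
    }
  }
  flush()
  if (is.null(row_ids) || is.null(col_ids))
    bad(length(lines), "missing #%rows / #%cols universe lines")
  bcs <- lapply(blocks, function(bl)
    new_bicluster(bl$r, bl$c, iterations = bl$iterations, basin_count = bl$basin))
  bicluster_set(bcs, row_ids = row_ids, col_ids = col_ids, params = params)
}
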