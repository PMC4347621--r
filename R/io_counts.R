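#' Construct and validate a miRNA read-count matrix
#'
#' A count matrix is an ordinary integer matrix with miRNAs (or sequence
#' families) as rows and sample libraries as columns; `dimnames` carry the
#' identifiers.  Identifiers are compared case-sensitively after stripping
#' surrounding whitespace, since miRNA nomenclature is case-meaningful.
#'
#' @param values numeric matrix of non-negative integers.
#' @param mirna_ids,sample_ids character vectors of unique row / column ids;
#'   defaults taken from `dimnames(values)`.
#' @return an integer matrix with validated dimnames.
#' @export
count_matrix <- function(values, mirna_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  mirna_ids <- trimws(as.character(mirna_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(mirna_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lists do not match matrix dimensions")
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA ids: ",
         paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0 | values != round(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("invalid count at row '%s', column '%s': %s",
                 mirna_ids[i], sample_ids[j], format(values[i, j])))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(mirna_ids, sample_ids)
  values
}

#' Read a read-count matrix from tab-separated text
#'
#' The file must have one header row of identifiers and one leading identifier
#' column.  The on-disk orientation is declared explicitly; internally the
#' matrix is always stored miRNA x sample.
#'
#' @param path file path.
#' @param orientation `"mirna_rows"` if disk rows are miRNAs (default),
#'   `"sample_rows"` if disk rows are samples.
#' @return integer count matrix, miRNAs x samples.
#' @export
read_count_matrix <- function(path, orientation = c("mirna_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count matrix file needs an id column and >=1 data column: ", path)
  row_ids <- trimws(tab[[1]])
  col_ids <- trimws(colnames(tab)[-1])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop(sprintf("%s: non-integer or negative count at row '%s', column '%s': '%s'",
                 path, row_ids[i], col_ids[j], vals[i, j]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "sample_rows") num <- t(num)
  count_matrix(num)
}

#' Write a count matrix as tab-separated text
#'
#' @param cm count matrix (miRNAs x samples).
#' @param path destination path.
#' @param orientation on-disk orientation, as in [read_count_matrix()].
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, orientation = c("mirna_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "sample_rows") t(cm) else cm
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- if (orientation == "sample_rows") "sample" else "mirna"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-to-sequence-family map
#'
#' Two-column tab-separated text: miRNA id, family id (families conventionally
#' carry an `sf-` prefix).  Every miRNA must map to exactly one family; listing
#' a miRNA twice with different families is an error.
#'
#' @param path file path.
#' @return named character vector: `map[mirna_id] == family_id`.
#' @export
read_family_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("family map needs two tab-separated columns: ", path)
  mir <- trimws(tab[[1]])
  fam <- trimws(tab[[2]])
  # tolerate an optional header line
  if (nrow(tab) && grepl("family", fam[1], ignore.case = TRUE) &&
      grepl("mir", mir[1], ignore.case = TRUE)) {
    mir <- mir[-1]; fam <- fam[-1]
  }
  family_map(stats::setNames(fam, mir))
}

#' Construct/validate a family map from a named character vector
#' @param mapping named character vector, names = miRNA ids, values = family ids.
#' @export
family_map <- function(mapping) {
  mir <- names(mapping)
  if (is.null(mir)) stop("family map must be a named character vector")
  dup <- duplicated(mir)
  if (any(dup)) {
    conflict <- vapply(unique(mir[dup]), function(id) {
      length(unique(mapping[mir == id])) > 1
    }, logical(1))
    if (any(conflict))
      stop("conflicting family assignment for: ",
           paste(unique(mir[dup])[conflict], collapse = ", "))
    mapping <- mapping[!dup]
  }
  stats::setNames(as.character(mapping), names(mapping))
}

#' Write a family map
#' @param map named character vector as returned by [read_family_map()].
#' @param path destination path.
#' @export
write_family_map <- function(map, path) {
  utils::write.table(data.frame(mirna = names(map), family = unname(map)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.status_levels <- c("positive", "negative", "unknown")
.histology_levels <- c("IDC", "DCIS", "Normal", "Metaplastic", "CellLine", "Other")
.subtype_levels <- c("Basal", "LuminalA", "LuminalB", "Her2", "Normal", "NA")

#' Validate a cohort metadata table
#'
#' Per-sample annotations: immunohistochemical receptor statuses (ER, PR,
#' Her2), histology class and molecular subtype.  The literal subtype "NA"
#' marks samples without subtype information; it is kept as a category so the
#' cohort composition can be reported, but association tests exclude it.
#'
#' @param meta data.frame with columns `sample_id`, `er_status`, `pr_status`,
#'   `her2_status`, `histology`, `molecular_subtype`.
#' @return the validated data.frame (character columns).
#' @export
cohort_metadata <- function(meta) {
  need <- c("sample_id", "er_status", "pr_status", "her2_status",
            "histology", "molecular_subtype")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("cohort metadata missing columns: ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (cc in need) meta[[cc]] <- trimws(as.character(meta[[cc]]))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in cohort metadata")
  for (cc in c("er_status", "pr_status", "her2_status")) {
    bad <- setdiff(unique(meta[[cc]]), .status_levels)
    if (length(bad)) stop(cc, ": invalid values ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(meta$histology), .histology_levels)
  if (length(bad)) stop("histology: invalid values ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$molecular_subtype), .subtype_levels)
  if (length(bad)) stop("molecular_subtype: invalid values ", paste(bad, collapse = ", "))
  rownames(meta) <- NULL
  meta[need]
}

#' Read / write cohort metadata TSV
#' @param path file path.
#' @rdname cohort_io
#' @export
read_cohort_metadata <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = NULL)
  cohort_metadata(tab)
}

#' @param meta validated cohort metadata data.frame.
#' @rdname cohort_io
#' @export
write_cohort_metadata <- function(meta, path) {
  utils::write.table(cohort_metadata(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
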