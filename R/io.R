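#' Write an expression matrix as GCT 1.2
#'
#' @param mat numeric matrix, probes in rows, samples in columns; dimnames
#'   required.
#' @param path output file.
#' @export
write_gct <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(mat), ncol(mat), sep = "\t"), con)
  df <- data.frame(Name = rownames(mat), Description = "na", mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GCT 1.2 expression matrix
#'
#' @param path GCT file with a `#1.2` version line and a rows/columns
#'   dimension line; row ids in `Name`, annotations in `Description`.
#' @return numeric matrix (probes x samples).
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || trimws(header[1]) != "#1.2") {
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(header[2], "\t", fixed = TRUE)[[1]])
  df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  got <- c(nrow(df), ncol(df) - 2L)
  if (!identical(got, dims[1:2])) {
    stop(sprintf("GCT dimension header mismatch in %s: declared %d x %d, found %d x %d",
                 path, dims[1], dims[2], got[1], got[2]), call. = FALSE)
  }
  .as_expression_matrix(df[, -(1:2), drop = FALSE], df[[1]], path,
                        sample_ids = colnames(df)[-(1:2)])
}

#' Write an expression matrix as plain TSV (first column = probe id)
#' @param mat probes x samples matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a plain TSV expression matrix (first column = probe id)
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .as_expression_matrix(df[, -1, drop = FALSE], df[[1]], path,
                        sample_ids = colnames(df)[-1])
}

# `[.data.frame` silently uniquifies duplicated column names, so sample ids
# must be taken from the unsubsetted header
.as_expression_matrix <- function(df, row_ids, path, sample_ids = colnames(df)) {
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(df) <- sample_ids
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric expression value in %s at row %d, column '%s'",
                   path, bad, colnames(df)[j]), call. = FALSE)
    }
  }
  mat <- as.matrix(df)
  rownames(mat) <- row_ids
  if (any(!is.finite(mat))) {
    stop("non-finite expression values in ", path, call. = FALSE)
  }
  mat
}

#' Read one expression batch from GCT or TSV
#'
#' @param path file path.
#' @param batch_id batch identifier (platform x experiment); defaults to
#'   the file name without extension.
#' @param format `"gct"`, `"tsv"`, or `"auto"` (by file extension).
#' @return an `expression_batch` (list: `batch_id`, `expr`).
#' @export
read_expression <- function(path, batch_id = NULL, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  mat <- if (format == "gct") read_gct(path) else read_matrix_tsv(path)
  if (is.null(batch_id)) batch_id <- sub("\\.[^.]+$", "", basename(path))
  structure(list(batch_id = batch_id, expr = mat), class = "expression_batch")
}

#' Read a probe-to-gene map TSV (columns probe_id, gene_symbol)
#' @param path TSV file.
#' @return data.frame with `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% colnames(df))) {
    stop("probe map must have columns probe_id and gene_symbol: ", path,
         call. = FALSE)
  }
  df[need]
}

#' Read a clinical metadata TSV
#' @param path TSV with at least sample_id, time, event; optionally arm,
#'   coo, expr_group and expression columns.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df))) {
    stop("clinical table must have columns sample_id, time, event: ", path,
         call. = FALSE)
  }
  if (any(df$time < 0, na.rm = TRUE)) stop("negative survival time in ", path, call. = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a drug-gene interaction TSV (columns gene, drug, source)
#' @param path TSV file.
#' @return data.frame with gene, drug, source (and any extra columns).
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "drug", "source")
  if (!all(need %in% colnames(df))) {
    stop("interaction table must have columns gene, drug, source: ", path,
         call. = FALSE)
  }
  if (any(!nzchar(df$gene)) || any(!nzchar(df$drug))) {
    stop("malformed interaction row (empty gene or drug) in ", path, call. = FALSE)
  }
  df
}
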