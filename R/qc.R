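#' Content digests for expression profiles
#'
#' MD5 digest of a canonical fixed-precision serialization of each sample's
#' expression vector, so byte-identical uploads of the same array collapse
#' to one fingerprint regardless of file container.
#'
#' @param mat probes x samples numeric matrix.
#' @return named character vector of hex digests, one per sample.
#' @export
sample_digests <- function(mat) {
  if (any(!is.finite(mat))) {
    bad <- colnames(mat)[colSums(!is.finite(mat)) > 0][1]
    stop("unreadable (non-finite) content for sample: ", bad, call. = FALSE)
  }
  tmp <- tempfile("digest")
  on.exit(unlink(tmp))
  out <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    writeLines(sprintf("%.6f", mat[, j]), tmp)
    out[j] <- unname(tools::md5sum(tmp))
  }
  stats::setNames(out, colnames(mat))
}

#' Remove duplicate samples by content fingerprint
#'
#' Samples whose canonical content digests coincide are collapsed to the
#' first occurrence in stable column order; re-running on the result is a
#' no-op.
#'
#' @param batches list of `expression_batch` objects (or a single one).
#' @return list with `batches` (duplicates dropped), `report` (data.frame:
#'   sample_id, batch, digest, kept, kept_as — the representative a
#'   removed duplicate maps to).
#' @export
deduplicate <- function(batches) {
  if (inherits(batches, "expression_batch")) batches <- list(batches)
  rows <- lapply(batches, function(b) {
    data.frame(sample_id = colnames(b$expr), batch = b$batch_id,
               digest = sample_digests(b$expr), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  report <- do.call(rbind, rows)
  first <- !duplicated(report$digest)
  rep_of <- stats::setNames(report$sample_id[first], report$digest[first])
  report$kept <- first
  report$kept_as <- ifelse(first, NA_character_, unname(rep_of[report$digest]))
  kept_ids <- report$sample_id[report$kept]
  out <- lapply(batches, function(b) {
    keep <- colnames(b$expr) %in% kept_ids
    b$expr <- b$expr[, keep, drop = FALSE]
    b
  })
  list(batches = out, report = report)
}

#' Pearson correlation matrix between samples
#'
#' @param mat probes x samples matrix (>= 2 probes, >= 2 samples).
#' @return samples x samples symmetric correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation_matrix <- function(mat) {
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    stop("need at least 2 samples and 2 probes", call. = FALSE)
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(mat)
  (R + t(R)) / 2
}

#' PCqc scores: correlation of each sample with the leading PC
#'
#' The first principal component of the sample correlation matrix of a
#' normalized expression batch almost always captures a near-constant
#' pattern shared by all good-quality arrays; arrays that correlate poorly
#' with it are degraded. The component's sign is fixed so its mean loading
#' is nonnegative. By default (`method = "profile"`) a sample's score is
#' the Pearson correlation of its raw expression profile with the
#' PC-weighted meta-profile (the pattern the component describes in gene
#' space). `method = "corr_rows"` instead correlates the sample's row of
#' the correlation matrix with the leading eigenvector; this variant is
#' unstable on perfectly homogeneous batches, where the eigenvector is
#' near-constant and the correlation is driven by numerical noise, so it
#' is not the default.
#'
#' @param R sample correlation matrix from [sample_correlation_matrix()].
#' @param mat the probes x samples matrix (required for
#'   `method = "profile"`).
#' @param method score definition, see above.
#' @return list: `scores` (named, per sample), `pc1_variance_fraction`,
#'   `pcqc` (the leading eigenvector).
#' @export
pcqc_scores <- function(R, mat = NULL, method = c("profile", "corr_rows")) {
  method <- match.arg(method)
  eig <- eigen(R, symmetric = TRUE)
  if (any(!is.finite(eig$values))) stop("eigen-decomposition failed", call. = FALSE)
  v <- eig$vectors[, 1]
  if (mean(v) < 0) v <- -v
  frac <- eig$values[1] / sum(eig$values)
  scores <- if (method == "corr_rows") {
    s <- suppressWarnings(drop(stats::cor(R, v)))
    # a constant row arises only when a sample correlates identically with
    # every sample (rank-one matrix): it conforms perfectly to the pattern
    s[!is.finite(s)] <- 1
    s
  } else {
    if (is.null(mat)) stop("method = 'profile' needs the expression matrix", call. = FALSE)
    meta_profile <- drop(mat %*% v)
    drop(stats::cor(mat, meta_profile))
  }
  list(scores = stats::setNames(scores, colnames(R)),
       pc1_variance_fraction = frac, pcqc = v)
}

#' Partition samples by PCqc score threshold
#'
#' A sample is removed iff its score is strictly below the threshold
#' (score exactly at the threshold is kept).
#'
#' @param scores named numeric vector of PCqc correlations in `[-1, 1]`.
#' @param threshold removal cutoff (default 0.8).
#' @return list with `kept` and `removed` sample id vectors and the
#'   threshold.
#' @export
filter_outliers <- function(scores, threshold = 0.8) {
  stopifnot(all(scores >= -1 - 1e-9 & scores <= 1 + 1e-9))
  removed <- names(scores)[scores < threshold]
  list(kept = setdiff(names(scores), removed), removed = removed,
       threshold = threshold)
}

#' Run sample QC on a batch
#'
#' @param batch an `expression_batch`.
#' @param threshold PCqc removal cutoff.
#' @param method score definition, see [pcqc_scores()].
#' @return list: `batch` (outliers dropped), `report` (data.frame:
#'   sample_id, batch, digest, pcqc_correlation, kept),
#'   `pc1_variance_fraction`, `threshold`.
#' @export
qc_batch <- function(batch, threshold = 0.8, method = "profile") {
  R <- sample_correlation_matrix(batch$expr)
  pc <- pcqc_scores(R, batch$expr, method = method)
  part <- filter_outliers(pc$scores, threshold)
  report <- data.frame(
    sample_id = colnames(batch$expr), batch = batch$batch_id,
    digest = sample_digests(batch$expr),
    pcqc_correlation = unname(pc$scores[colnames(batch$expr)]),
    kept = colnames(batch$expr) %in% part$kept,
    stringsAsFactors = FALSE)
  batch$expr <- batch$expr[, part$kept, drop = FALSE]
  list(batch = batch, report = report,
       pc1_variance_fraction = pc$pc1_variance_fraction, threshold = threshold)
}
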