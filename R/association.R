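#' Collapse probe-level rows to gene level by the mean
#'
#' @param mat probes x samples matrix.
#' @param probe_map data.frame with `probe_id`, `gene_symbol`.
#' @param genes genes to collapse (default: all genes with probes present
#'   in `mat`).
#' @return genes x samples matrix of per-sample arithmetic means over each
#'   gene's probes.
#' @export
collapse_probes <- function(mat, probe_map, genes = NULL) {
  pm <- probe_map[probe_map$probe_id %in% rownames(mat), , drop = FALSE]
  if (is.null(genes)) genes <- unique(pm$gene_symbol)
  missing <- setdiff(genes, pm$gene_symbol)
  if (length(missing)) {
    stop("gene(s) with no probes in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pm <- pm[pm$gene_symbol %in% genes, , drop = FALSE]
  sums <- rowsum(mat[pm$probe_id, , drop = FALSE], group = pm$gene_symbol)
  counts <- as.vector(table(pm$gene_symbol)[rownames(sums)])
  out <- sums / counts
  out[genes, , drop = FALSE]
}

#' Seed profile of a batch (probes collapsed by the mean)
#'
#' @param batch an `expression_batch`.
#' @param probe_map probe-to-gene map.
#' @param seed_gene seed gene symbol.
#' @return named numeric vector over the batch's samples.
#' @export
seed_profile <- function(batch, probe_map, seed_gene) {
  drop(collapse_probes(batch$expr, probe_map, seed_gene))
}

#' Fisher z transform of a Pearson correlation
#'
#' `z = atanh(r)` with standard error `1 / sqrt(n - 3)`; correlations of
#' exactly +/-1 are clipped to +/-(1 - 1e-12) so degenerate inputs keep a
#' finite statistic.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n sample size(s), `n >= 4`.
#' @return list with `z` and `se`.
#' @export
fisher_z <- function(r, n) {
  if (any(n < 4)) stop("fisher_z needs n >= 4", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  list(z = atanh(r), se = 1 / sqrt(n - 3))
}

#' Per-batch Pearson association of every probe with the seed profile
#'
#' @param mat probes x samples matrix (QC-passed).
#' @param seed numeric seed profile aligned to the matrix columns.
#' @return data.frame: `probe_id`, `r`, `n`, `z`, `se`; probes with zero
#'   within-batch variance get `NA` (missing for this batch).
#' @export
batch_correlations <- function(mat, seed) {
  n <- ncol(mat)
  if (length(seed) != n) stop("seed profile not aligned to batch samples", call. = FALSE)
  if (n < 4) stop("need at least 4 samples per batch", call. = FALSE)
  if (stats::sd(seed) == 0) stop("seed profile has zero variance", call. = FALSE)
  sds <- matrixStats_rowSds(mat)
  r <- rep(NA_real_, nrow(mat))
  ok <- sds > 0
  if (any(ok)) r[ok] <- drop(stats::cor(t(mat[ok, , drop = FALSE]), seed))
  fz <- fisher_z(ifelse(ok, r, 0), n)
  data.frame(probe_id = rownames(mat), r = r, n = n,
             z = ifelse(ok, fz$z, NA_real_),
             se = ifelse(ok, fz$se, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

# row standard deviations without extra dependencies
matrixStats_rowSds <- function(mat) {
  m <- rowMeans(mat)
  sqrt(rowSums((mat - m)^2) / (ncol(mat) - 1))
}

#' Fixed-effect inverse-variance combination of Fisher-z estimates
#'
#' Weights `w_i = 1/se_i^2`; pooled `zbar = sum(w z)/sum(w)`, pooled
#' `se = 1/sqrt(sum(w))`, test statistic `zbar/se`, two-sided normal p.
#'
#' @param z per-batch Fisher-z estimates (NAs dropped: complete-case).
#' @param se matching standard errors.
#' @return list: `zbar`, `se`, `statistic`, `p`, `k` (batches used).
#' @export
meta_fixed_effect <- function(z, se) {
  keep <- is.finite(z) & is.finite(se)
  z <- z[keep]; se <- se[keep]
  if (!length(z)) stop("no batch with finite z and se", call. = FALSE)
  w <- 1 / se^2
  zbar <- sum(w * z) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  stat <- zbar / se_pooled
  list(zbar = zbar, se = se_pooled, statistic = stat,
       p = 2 * stats::pnorm(-abs(stat)), k = length(z))
}

#' Seed-gene association meta-analysis across batches
#'
#' For every probe, computes the per-batch Pearson correlation with the
#' collapsed seed profile, Fisher-transforms, and pools across batches by
#' the fixed-effect inverse-variance model. Probes absent or constant in a
#' batch contribute nothing to that batch's sums (platforms differ in
#' probe content). The back-transformed pooled correlation `tanh(zbar)` is
#' reported alongside the statistic.
#'
#' @param batches list of QC-passed `expression_batch` objects.
#' @param probe_map probe-to-gene map covering all probes.
#' @param seed_gene seed gene symbol (must have probes in every batch).
#' @return data.frame of class `meta_association`: `probe_id`,
#'   `gene_symbol`, `is_seed`, per-batch `r.<batch>` / `n.<batch>`,
#'   `zbar`, `se`, `statistic`, `p`, `r_pooled`, `rank` (1 = strongest
#'   positive association; ties broken by gene symbol then probe id).
#' @export
meta_associate <- function(batches, probe_map, seed_gene) {
  probes <- unique(unlist(lapply(batches, function(b) rownames(b$expr))))
  probes <- probes[probes %in% probe_map$probe_id]
  tab <- data.frame(probe_id = probes,
                    gene_symbol = probe_map$gene_symbol[match(probes, probe_map$probe_id)],
                    stringsAsFactors = FALSE)
  W <- WZ <- stats::setNames(numeric(length(probes)), probes)
  used <- stats::setNames(integer(length(probes)), probes)
  for (b in batches) {
    seed <- seed_profile(b, probe_map, seed_gene)
    ba <- batch_correlations(b$expr, seed)
    tab[[paste0("r.", b$batch_id)]] <- ba$r[match(probes, ba$probe_id)]
    tab[[paste0("n.", b$batch_id)]] <- ifelse(probes %in% ba$probe_id, ba$n[1], NA_integer_)
    ok <- is.finite(ba$z)
    w <- 1 / ba$se[ok]^2
    idx <- ba$probe_id[ok]
    W[idx] <- W[idx] + w
    WZ[idx] <- WZ[idx] + w * ba$z[ok]
    used[idx] <- used[idx] + 1L
  }
  if (any(used == 0)) {
    tab <- tab[used[tab$probe_id] > 0, , drop = FALSE]
  }
  zbar <- WZ[tab$probe_id] / W[tab$probe_id]
  se <- 1 / sqrt(W[tab$probe_id])
  tab$zbar <- unname(zbar)
  tab$se <- unname(se)
  tab$statistic <- tab$zbar / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$statistic))
  tab$r_pooled <- tanh(tab$zbar)
  tab$is_seed <- tab$gene_symbol == seed_gene
  ord <- order(-tab$statistic, tab$gene_symbol, tab$probe_id)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("meta_association", "data.frame")
  tab
}

#' Rank probes and slice the top-k associations
#'
#' Probes are ordered by the meta statistic, descending (strongest
#' positive association first; ties broken by gene symbol then probe id
#' for determinism). The seed gene's own probes trivially attain r = 1 and
#' are excluded from the top-k slice by default.
#'
#' @param tab a `meta_association` table.
#' @param k slice size (default 500).
#' @param exclude_seed drop the seed gene's probes from the slice.
#' @return list: `table` (ranked, full), `top` (the slice),
#'   `n_unique_genes` (distinct symbols in the slice).
#' @export
rank_genes <- function(tab, k = 500, exclude_seed = TRUE) {
  stopifnot(nrow(tab) > 0)
  pool <- if (exclude_seed) tab[!tab$is_seed, , drop = FALSE] else tab
  if (k > nrow(pool)) stop("k exceeds the number of rankable probes", call. = FALSE)
  pool <- pool[order(pool$rank), , drop = FALSE]
  top <- pool[seq_len(k), , drop = FALSE]
  list(table = tab, top = top,
       n_unique_genes = length(unique(top$gene_symbol)))
}
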