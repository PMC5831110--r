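#' Permutation null distribution of the meta statistic
#'
#' For each of `B` permutations the seed profile is shuffled independently
#' within every batch — destroying any gene-seed association while keeping
#' batch structure and the gene-gene covariance intact — and the full
#' inverse-variance meta statistic is recomputed for every probe.
#'
#' @param batches list of QC-passed `expression_batch` objects.
#' @param probe_map probe-to-gene map.
#' @param seed_gene seed gene symbol.
#' @param B number of permutations (>= 1).
#' @param rng_seed integer seed for the shuffles.
#' @return list of class `permutation_null`: `stats` (B x probes matrix of
#'   null meta statistics), `B`, `rng_seed`.
#' @export
permute_null <- function(batches, probe_map, seed_gene, B = 1000, rng_seed = 1L) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  probes <- unique(unlist(lapply(batches, function(b) rownames(b$expr))))
  probes <- probes[probes %in% probe_map$probe_id]
  W <- stats::setNames(numeric(length(probes)), probes)
  SWZ <- matrix(0, length(probes), B, dimnames = list(probes, NULL))
  with_rng(rng_seed, {
    for (b in batches) {
      seed <- seed_profile(b, probe_map, seed_gene)
      n <- length(seed)
      perm <- permute_seed_matrix(seed, B)
      bp <- intersect(rownames(b$expr), probes)
      mat <- b$expr[bp, , drop = FALSE]
      sds <- matrixStats_rowSds(mat)
      ok <- sds > 0
      if (!any(ok)) next
      # probes x B matrix of Pearson r against each shuffled seed
      r <- stats::cor(t(mat[ok, , drop = FALSE]), perm)
      r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
      z <- atanh(r)
      w <- n - 3
      idx <- bp[ok]
      W[idx] <- W[idx] + w
      SWZ[idx, ] <- SWZ[idx, ] + w * z
    }
  })
  keep <- W > 0
  null_stats <- t(SWZ[keep, , drop = FALSE] / sqrt(W[keep]))
  structure(list(stats = null_stats, B = B, rng_seed = rng_seed),
            class = "permutation_null")
}

# n x B matrix whose columns are independent uniform shuffles of the
# batch's seed profile (each column a multiset-identical rearrangement)
permute_seed_matrix <- function(seed, B) {
  n <- length(seed)
  perm <- matrix(0, n, B)
  for (j in seq_len(B)) perm[, j] <- seed[sample.int(n)]
  perm
}

#' Multivariate permutation selection controlling the false discovery
#' proportion
#'
#' Candidate thresholds are the observed statistics. For threshold `t`,
#' `R(t)` is the observed count of statistics `>= t` and `V_b(t)` the
#' count of null statistics `>= t` in permutation `b`; the
#' `ceiling(confidence * B)`-th order statistic of the `V_b(t)` is a
#' confidence bound `V*(t)` on the number of false discoveries. The
#' selection threshold `t*` is the smallest candidate with
#' `V*(t) <= gamma * R(t)` — i.e. the largest rejection set whose
#' false-discovery proportion is bounded by `gamma` at the stated
#' confidence. No qualifying threshold gives an empty selection.
#'
#' @param observed named vector of observed meta statistics (by probe or
#'   gene).
#' @param null a `permutation_null` on the same universe.
#' @param gamma target false discovery rate (default 0.01).
#' @param confidence confidence level of the FDP bound (default 0.99).
#' @param two_sided rank on `|statistic|` instead of the signed statistic.
#' @return list of class `fdr_selection`: `selected` (ids), `threshold`,
#'   `gamma`, `confidence`, `B`, and `table` (id, statistic, selected).
#' @export
select_significant <- function(observed, null, gamma = 0.01, confidence = 0.99,
                               two_sided = FALSE) {
  stopifnot(gamma > 0, gamma < 1, confidence > 0, confidence < 1)
  if (is.null(names(observed))) stop("observed statistics must be named", call. = FALSE)
  nullmat <- null$stats
  if (!all(names(observed) %in% colnames(nullmat))) {
    stop("observed and null statistics cover different universes", call. = FALSE)
  }
  nullmat <- nullmat[, names(observed), drop = FALSE]
  obs <- observed
  if (two_sided) {
    obs <- abs(obs)
    nullmat <- abs(nullmat)
  }
  B <- nrow(nullmat)
  thresholds <- sort(unique(unname(obs)), decreasing = TRUE)
  R <- vapply(thresholds, function(t) sum(obs >= t), integer(1))
  # V[b, i] = number of null statistics >= thresholds[i] in permutation b
  nnull <- ncol(nullmat)
  V <- matrix(0L, B, length(thresholds))
  for (b in seq_len(B)) {
    srt <- sort(nullmat[b, ])
    # count of null values < t, via findInterval on the open left side
    below <- findInterval(thresholds, srt, left.open = TRUE)
    V[b, ] <- nnull - below
  }
  ord_idx <- ceiling(confidence * B)
  Vstar <- apply(V, 2, function(col) sort(col)[ord_idx])
  ok <- Vstar <= gamma * R
  if (!any(ok)) {
    tstar <- Inf
    selected <- character(0)
  } else {
    tstar <- thresholds[max(which(ok))]   # smallest qualifying threshold
    selected <- names(obs)[obs >= tstar]
  }
  tab <- data.frame(id = names(obs), statistic = unname(observed),
                    selected = names(obs) %in% selected,
                    stringsAsFactors = FALSE)
  structure(list(selected = selected, threshold = tstar, gamma = gamma,
                 confidence = confidence, B = B, rng_seed = null$rng_seed,
                 table = tab),
            class = "fdr_selection")
}
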