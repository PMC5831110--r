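#' Configuration for the synthetic expression compendium generator
#'
#' Builds and validates the parameter set for [generate_compendium()]. The
#' defaults describe the study conditions every downstream stage is tested
#' under: a compendium of three batches of 400 arrays each, 2000 genes with
#' one to three probes per gene, a planted module of 50 genes correlated
#' with the seed gene at Pearson correlations between 0.5 and 0.9, a
#' dominant shared baseline component (so the first principal component of
#' each batch's sample correlation matrix carries roughly 80-90% of the
#' variance, as is typical of normalized microarray compendia), moderate
#' per-batch shifts, and six low-quality pure-noise arrays.
#'
#' @param n_batches number of meta-analysis batches.
#' @param samples_per_batch integer vector (recycled to `n_batches`) of
#'   array counts per batch.
#' @param n_genes total number of genes, including the seed gene and the
#'   planted module.
#' @param probes_per_gene integer vector of admissible probe counts; each
#'   gene draws its probe count uniformly from this set.
#' @param seed_gene symbol used for the seed gene.
#' @param module_size number of genes truly co-expressed with the seed.
#' @param module_correlations vector of target Pearson correlations in
#'   (-1, 1), recycled to `module_size`.
#' @param common_factor_sd standard deviation of the shared baseline
#'   pattern (log2-like units). Zero switches the shared component off.
#' @param batch_shift_sd standard deviation of per-gene, per-batch shifts.
#' @param noise_sd standard deviation of independent measurement noise.
#' @param n_outliers number of arrays (across the whole compendium)
#'   replaced by pure noise, emulating failed hybridizations.
#' @param rng_seed integer seed; identical seeds give identical compendia.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_batches = 3,
                       samples_per_batch = 400,
                       n_genes = 2000,
                       probes_per_gene = 1:3,
                       seed_gene = "MS4A1",
                       module_size = 50,
                       module_correlations = seq(0.5, 0.9, length.out = max(module_size, 1L)),
                       common_factor_sd = 2,
                       batch_shift_sd = 0.5,
                       noise_sd = 0.8,
                       n_outliers = 6,
                       rng_seed = 1L) {
  if (!is.numeric(n_batches) || n_batches < 1) stop_field("n_batches", "must be >= 1")
  samples_per_batch <- rep_len(as.integer(samples_per_batch), n_batches)
  if (any(samples_per_batch < 4)) stop_field("samples_per_batch", "each batch needs >= 4 samples")
  if (!is.numeric(n_genes) || n_genes < 2) stop_field("n_genes", "must be >= 2")
  if (any(probes_per_gene < 1)) stop_field("probes_per_gene", "probe counts must be >= 1")
  if (module_size >= n_genes) stop_field("module_size", "must be < n_genes")
  if (module_size > 0) {
    module_correlations <- rep_len(module_correlations, module_size)
    if (any(abs(module_correlations) >= 1)) {
      stop_field("module_correlations", "must lie strictly inside (-1, 1)")
    }
  } else {
    module_correlations <- numeric(0)
  }
  if (common_factor_sd < 0) stop_field("common_factor_sd", "must be >= 0")
  if (batch_shift_sd < 0) stop_field("batch_shift_sd", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  if (n_outliers < 0 || n_outliers >= sum(samples_per_batch)) {
    stop_field("n_outliers", "must be >= 0 and smaller than the total sample count")
  }
  structure(list(
    n_batches = as.integer(n_batches),
    samples_per_batch = samples_per_batch,
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    seed_gene = seed_gene,
    module_size = as.integer(module_size),
    module_correlations = module_correlations,
    common_factor_sd = common_factor_sd,
    batch_shift_sd = batch_shift_sd,
    noise_sd = noise_sd,
    n_outliers = as.integer(n_outliers),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# sd of the per-sample strength of the shared baseline pattern; small, so
# the pattern stays near-constant across arrays (the "PCqc" phenomenon)
.sample_factor_sd <- 0.05
# sd of per-probe additive offsets around their gene's signal
.probe_offset_sd <- 0.3
# log2-scale grand mean of the baseline
.baseline_mean <- 8

#' Generate a synthetic multi-batch expression compendium
#'
#' Simulates probe-level log2-scale expression for several batches with a
#' known ground truth. Per batch, a gene's value is
#' `baseline + f_s * (baseline pattern) + batch shift + noise`, where the
#' baseline pattern (sd `common_factor_sd`) is shared by all arrays with a
#' per-sample strength `f_s ~ N(1, 0.05^2)`: this is the near-constant
#' dominant component that the first PC of the sample correlation matrix
#' picks up. The seed gene varies through its own unit-variance biological
#' signal, and each planted module gene is that signal scaled by its target
#' correlation `r` plus independent `N(0, 1 - r^2)` noise, so its
#' within-batch population correlation with the seed is exactly `r`
#' (negative `r` flips the sign of the loading). Genes outside the module
#' do not load on the seed signal and have exactly zero population
#' correlation with it. Outlier arrays are replaced by pure noise with no
#' shared component. Probes of a gene differ by a constant additive offset
#' only, which preserves every probe's correlation structure.
#'
#' @param config a [sim_config()].
#' @return A list with `batches` (list of `expression_batch` objects, each
#'   with `batch_id`, probes-by-samples `expr` matrix), `probe_map`
#'   (data.frame `probe_id`, `gene_symbol`), and `truth` (list:
#'   `associated_genes` data.frame of gene/correlation, `outlier_samples`,
#'   `batch_assignments`, `seed_gene`).
#' @export
generate_compendium <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_rng(config$rng_seed, {
    G <- config$n_genes
    genes <- sprintf("G%04d", seq_len(G))
    genes[1] <- config$seed_gene
    module_idx <- if (config$module_size > 0) 1L + seq_len(config$module_size) else integer(0)

    n_probes_per_gene <- if (length(config$probes_per_gene) == 1L) {
      rep(config$probes_per_gene, G)
    } else {
      sample(config$probes_per_gene, G, replace = TRUE)
    }
    probe_gene <- rep(genes, n_probes_per_gene)
    probe_id <- paste0(probe_gene, "_at",
                       unlist(lapply(n_probes_per_gene, seq_len), use.names = FALSE))
    probe_offset <- rnorm(length(probe_id), 0, .probe_offset_sd)
    probe_map <- data.frame(probe_id = probe_id, gene_symbol = probe_gene,
                            stringsAsFactors = FALSE)

    baseline_dev <- rnorm(G, 0, config$common_factor_sd)  # shared pattern
    mu <- .baseline_mean + baseline_dev
    # seed and module genes carry their own signal, not the shared pattern
    baseline_dev[c(1L, module_idx)] <- 0

    all_samples <- character(0)
    batch_of <- character(0)
    batches <- vector("list", config$n_batches)
    gene_mats <- vector("list", config$n_batches)
    for (k in seq_len(config$n_batches)) {
      n <- config$samples_per_batch[k]
      bid <- sprintf("batch%02d", k)
      s_ids <- sprintf("%s_S%03d", bid, seq_len(n))
      f <- 1 + rnorm(n, 0, .sample_factor_sd)
      u <- rnorm(n)                         # seed's biological signal
      shift <- if (config$batch_shift_sd > 0) rnorm(G, 0, config$batch_shift_sd) else numeric(G)

      X <- .baseline_mean + shift + outer(baseline_dev, f) +
        matrix(rnorm(G * n, 0, config$noise_sd), G, n)
      X[1, ] <- mu[1] + shift[1] + u
      if (length(module_idx)) {
        r <- config$module_correlations
        X[module_idx, ] <- mu[module_idx] + shift[module_idx] +
          outer(r, u) + matrix(rnorm(length(module_idx) * n), ncol = n) *
          sqrt(1 - r^2)
      }
      dimnames(X) <- list(genes, s_ids)
      gene_mats[[k]] <- X
      all_samples <- c(all_samples, s_ids)
      batch_of <- c(batch_of, rep(bid, n))
    }

    outliers <- character(0)
    if (config$n_outliers > 0) {
      outliers <- sort(sample(all_samples, config$n_outliers))
      out_sd <- sqrt(config$common_factor_sd^2 + config$noise_sd^2)
      for (k in seq_len(config$n_batches)) {
        hit <- intersect(outliers, colnames(gene_mats[[k]]))
        for (s in hit) {
          gene_mats[[k]][, s] <- rnorm(G, .baseline_mean, out_sd)
        }
      }
    }

    probe_row_of_gene <- match(probe_gene, genes)
    for (k in seq_len(config$n_batches)) {
      P <- gene_mats[[k]][probe_row_of_gene, , drop = FALSE] + probe_offset
      rownames(P) <- probe_id
      batches[[k]] <- structure(
        list(batch_id = sprintf("batch%02d", k), expr = P),
        class = "expression_batch")
    }

    truth <- list(
      seed_gene = config$seed_gene,
      associated_genes = data.frame(
        gene_symbol = genes[module_idx],
        correlation = config$module_correlations,
        stringsAsFactors = FALSE),
      outlier_samples = outliers,
      batch_assignments = stats::setNames(batch_of, all_samples)
    )
    list(batches = batches, probe_map = probe_map, truth = truth)
  })
}

#' Configuration for simulated clinical metadata
#'
#' @param n_patients number of patients.
#' @param coo_probs probabilities for cell-of-origin labels
#'   ABC / GCB / unclassified; the default echoes the composition of large
#'   published DLBCL compendia.
#' @param arm_probs named probabilities for treatment arms.
#' @param baseline_hazard exponential event rate (per month) for the
#'   reference patient.
#' @param log_hazard_effects named numeric vector of log hazard ratios; a
#'   patient's hazard multiplies `exp(effect)` for every label (expression
#'   group, arm, cell-of-origin) that appears in this vector.
#' @param censoring_rate rate of the independent exponential censoring
#'   process.
#' @param rng_seed integer seed.
#' @return list of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(n_patients = 500,
                                coo_probs = c(ABC = 0.352, GCB = 0.493, unclassified = 0.155),
                                arm_probs = c(CHOP = 0.3, `R-CHOP` = 0.7),
                                baseline_hazard = 0.02,
                                log_hazard_effects = c(high = 0),
                                censoring_rate = 0.01,
                                rng_seed = 1L) {
  if (n_patients < 1) stop_field("n_patients", "must be >= 1")
  if (abs(sum(coo_probs) - 1) > 1e-9) stop_field("coo_probs", "must sum to 1")
  if (abs(sum(arm_probs) - 1) > 1e-9) stop_field("arm_probs", "must sum to 1")
  if (baseline_hazard <= 0) stop_field("baseline_hazard", "must be > 0")
  if (censoring_rate <= 0) stop_field("censoring_rate", "must be > 0")
  structure(list(
    n_patients = as.integer(n_patients), coo_probs = coo_probs,
    arm_probs = arm_probs, baseline_hazard = baseline_hazard,
    log_hazard_effects = log_hazard_effects, censoring_rate = censoring_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "clinical_sim_config")
}

#' Simulate clinical metadata with group-dependent exponential survival
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum of matching log-hazard effects)`; censoring
#' is independent exponential; observed time is the minimum of the two,
#' with the event flag set accordingly.
#'
#' @param config a [clinical_sim_config()].
#' @param expression_groups named character vector mapping sample id to an
#'   expression-group label (e.g. "high"/"low"); if given, its samples
#'   define the cohort (`n_patients` is ignored) and every label must be
#'   known, i.e. appear in `log_hazard_effects` or be one of the standard
#'   "high"/"low" labels (labels without a configured effect are the
#'   reference, log hazard ratio 0).
#' @return data.frame of class `clinical_table`: `sample_id`, `time`
#'   (months), `event` (0/1), `arm`, `coo`, `expr_group`.
#' @export
generate_clinical <- function(config, expression_groups = NULL) {
  if (!inherits(config, "clinical_sim_config")) config <- do.call(clinical_sim_config, config)
  eff <- config$log_hazard_effects
  if (!is.null(expression_groups)) {
    if (is.null(names(expression_groups))) {
      stop("expression_groups must be a named sample -> label vector", call. = FALSE)
    }
    unknown <- setdiff(unique(expression_groups), c(names(eff), "high", "low"))
    if (length(unknown)) {
      stop("unknown expression group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    ids <- names(expression_groups)
    grp <- unname(expression_groups)
  } else {
    ids <- sprintf("P%04d", seq_len(config$n_patients))
    grp <- rep(NA_character_, length(ids))
  }
  with_rng(config$rng_seed, {
    n <- length(ids)
    coo <- sample(names(config$coo_probs), n, replace = TRUE, prob = config$coo_probs)
    arm <- sample(names(config$arm_probs), n, replace = TRUE, prob = config$arm_probs)
    lp <- numeric(n)
    for (lab in names(eff)) {
      lp <- lp + eff[[lab]] * ((!is.na(grp) & grp == lab) | coo == lab | arm == lab)
    }
    hazard <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    t_cens <- rexp(n, rate = config$censoring_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    out <- data.frame(sample_id = ids, time = time, event = event,
                      arm = arm, coo = coo, expr_group = grp,
                      stringsAsFactors = FALSE)
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}

#' Write a complete, round-trippable fixture bundle to disk
#'
#' Materializes a synthetic compendium and its companion tables in the
#' pipeline's on-disk formats: one GCT 1.2 and one TSV matrix per batch, a
#' probe map TSV, a GMT with the nine pathway-annotation categories plus a
#' "BCR signaling" exclusion set and a "DLBCL trials" exclusion set, a
#' drug-gene interaction TSV over the planted module, a clinical TSV tied
#' to the first batch's samples, and a ground-truth JSON.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @param clinical_config a [clinical_sim_config()]; its
#'   `log_hazard_effects` should reference the "high" expression label.
#' @return Invisibly, a named list of written paths.
#' @export
write_fixture_bundle <- function(outdir, config = sim_config(),
                                 clinical_config = clinical_sim_config()) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  sim <- generate_compendium(config)
  paths <- list()
  for (b in sim$batches) {
    gct <- file.path(outdir, paste0("expr_", b$batch_id, ".gct"))
    tsv <- file.path(outdir, paste0("expr_", b$batch_id, ".tsv"))
    write_gct(b$expr, gct)
    write_matrix_tsv(b$expr, tsv)
    paths[[paste0("gct_", b$batch_id)]] <- gct
    paths[[paste0("tsv_", b$batch_id)]] <- tsv
  }
  paths$batches_tsv <- file.path(outdir, "batches.tsv")
  write.table(data.frame(sample_id = names(sim$truth$batch_assignments),
                         batch = unname(sim$truth$batch_assignments)),
              paths$batches_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$probe_map <- file.path(outdir, "probe_map.tsv")
  write.table(sim$probe_map, paths$probe_map, sep = "\t", quote = FALSE,
              row.names = FALSE)

  categories <- c("BCR signaling", "cytoskeleton regulation",
                  "DNA repair and cell cycle", "histone modification",
                  "immune regulation", "metabolism", "protein processing",
                  "RNA processing", "signaling protein")
  module_genes <- sim$truth$associated_genes$gene_symbol
  sets <- list()
  if (length(module_genes) >= length(categories)) {
    cut <- split(module_genes, rep_len(seq_along(categories), length(module_genes)))
    names(cut) <- categories
    sets <- cut
  } else {
    sets <- stats::setNames(as.list(module_genes),
                            categories[seq_along(module_genes)])
  }
  sets[["BCR signaling"]] <- unique(c(config$seed_gene, sets[["BCR signaling"]]))
  sets[["DLBCL trials"]] <- utils::head(module_genes, 3)
  paths$gmt <- file.path(outdir, "gene_sets.gmt")
  write_gmt(sets, paths$gmt)

  drugged <- utils::head(module_genes, min(20L, length(module_genes)))
  inter <- data.frame(gene = drugged,
                      drug = sprintf("drug_%02d", seq_along(drugged)),
                      source = "synthetic", stringsAsFactors = FALSE)
  paths$interactions <- file.path(outdir, "interactions.tsv")
  write.table(inter, paths$interactions, sep = "\t", quote = FALSE, row.names = FALSE)

  b1 <- sim$batches[[1]]
  seed_expr <- collapse_probes(b1$expr, sim$probe_map, config$seed_gene)[1, ]
  groups <- dichotomize_expression(seed_expr)
  clin <- generate_clinical(clinical_config, stats::setNames(groups, colnames(b1$expr)))
  paths$clinical <- file.path(outdir, "clinical.tsv")
  write.table(clin, paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
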