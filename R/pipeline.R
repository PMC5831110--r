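#' Pipeline configuration
#'
#' @param expression_files character vector of batch expression files
#'   (GCT or TSV), or NULL when running on an in-memory compendium.
#' @param probe_map_file probe-to-gene map TSV.
#' @param gene_sets_file optional GMT for enrichment.
#' @param interactions_file optional drug-gene interaction TSV.
#' @param clinical_file optional clinical TSV.
#' @param exclusion_sets names of gene sets used as prioritization
#'   exclusion filters (must exist in the GMT).
#' @param seed_gene seed gene symbol (default "MS4A1").
#' @param qc_threshold PCqc removal cutoff (default 0.8).
#' @param top_k size of the top-ranked slice (default 500).
#' @param perms number of permutations (default 1000).
#' @param fdr target false discovery rate (default 0.01).
#' @param confidence confidence level of the FDP bound (default 0.99).
#' @param rng_seed integer seed.
#' @param outdir output directory for stage TSVs and the manifest.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_files = NULL, probe_map_file = NULL,
                            gene_sets_file = NULL, interactions_file = NULL,
                            clinical_file = NULL,
                            exclusion_sets = c("BCR signaling", "DLBCL trials"),
                            seed_gene = "MS4A1", qc_threshold = 0.8,
                            top_k = 500, perms = 1000, fdr = 0.01,
                            confidence = 0.99, rng_seed = 1L,
                            outdir = tempfile("seedgba_run")) {
  if (qc_threshold < -1 || qc_threshold > 1) stop_field("qc_threshold", "must be in [-1, 1]")
  if (top_k < 1) stop_field("top_k", "must be >= 1")
  if (perms < 1) stop_field("perms", "must be >= 1")
  if (fdr <= 0 || fdr >= 1) stop_field("fdr", "must be in (0, 1)")
  if (confidence <= 0 || confidence >= 1) stop_field("confidence", "must be in (0, 1)")
  for (f in c(expression_files, probe_map_file, gene_sets_file,
              interactions_file, clinical_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input path does not exist: ", f, call. = FALSE)
  }
  structure(list(expression_files = expression_files,
                 probe_map_file = probe_map_file,
                 gene_sets_file = gene_sets_file,
                 interactions_file = interactions_file,
                 clinical_file = clinical_file,
                 exclusion_sets = exclusion_sets,
                 seed_gene = seed_gene, qc_threshold = qc_threshold,
                 top_k = as.integer(top_k), perms = as.integer(perms),
                 fdr = fdr, confidence = confidence,
                 rng_seed = as.integer(rng_seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full guilt-by-association pipeline
#'
#' Executes deduplication, PCqc sample QC, seed-probe collapsing,
#' per-batch association with fixed-effect meta-analysis, permutation FDR
#' selection, then (when the corresponding inputs are configured) gene-set
#' enrichment, drug-target prioritization and expression-stratified
#' survival comparison. Every stage writes its TSV under
#' `config$outdir`, and a machine-readable `manifest.json` records
#' parameters, the RNG seed and per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param compendium optional in-memory result of [generate_compendium()];
#'   when supplied, `expression_files`/`probe_map_file` are not read.
#' @return Invisibly, a list with the per-stage results (`qc`,
#'   `association`, `ranked`, `selection`, `enrichment`, `targets`,
#'   `survival`, `manifest`).
#' @export
run_pipeline <- function(config, compendium = NULL) {
  stage <- "setup"
  result <- try({
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(compendium)) {
      stage <- "read"
      batches <- lapply(config$expression_files, read_expression)
      probe_map <- read_probe_map(config$probe_map_file)
    } else {
      batches <- compendium$batches
      probe_map <- compendium$probe_map
    }
    n_in <- vapply(batches, function(b) ncol(b$expr), integer(1))

    stage <- "deduplicate"
    dd <- deduplicate(batches)
    batches <- dd$batches

    stage <- "qc"
    qc <- lapply(batches, qc_batch, threshold = config$qc_threshold)
    batches <- lapply(qc, `[[`, "batch")
    qc_report <- do.call(rbind, lapply(qc, `[[`, "report"))
    qc_report$digest <- dd$report$digest[match(qc_report$sample_id, dd$report$sample_id)]
    utils::write.table(qc_report, file.path(config$outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "association"
    assoc <- meta_associate(batches, probe_map, config$seed_gene)
    utils::write.table(assoc, file.path(config$outdir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ranked <- rank_genes(assoc, k = min(config$top_k, sum(!assoc$is_seed)))
    utils::write.table(ranked$top, file.path(config$outdir, "top_ranked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "permutation_fdr"
    null <- permute_null(batches, probe_map, config$seed_gene,
                         B = config$perms, rng_seed = config$rng_seed)
    obs <- stats::setNames(assoc$statistic, assoc$probe_id)
    sel <- select_significant(obs, null, gamma = config$fdr,
                              confidence = config$confidence)
    sel_tab <- sel$table
    sel_tab$gene_symbol <- assoc$gene_symbol[match(sel_tab$id, assoc$probe_id)]
    sel_tab$threshold <- sel$threshold
    sel_tab$gamma <- sel$gamma
    sel_tab$confidence <- sel$confidence
    sel_tab$B <- sel$B
    sel_tab$rng_seed <- config$rng_seed
    utils::write.table(sel_tab, file.path(config$outdir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    enr <- NULL
    targets <- NULL
    surv <- NULL
    collection <- NULL
    selected_genes <- unique(sel_tab$gene_symbol[sel_tab$selected &
                                                   sel_tab$gene_symbol != config$seed_gene])
    if (!is.null(config$gene_sets_file)) {
      stage <- "enrichment"
      collection <- read_gmt(config$gene_sets_file)
      universe <- unique(assoc$gene_symbol)
      top_genes <- unique(ranked$top$gene_symbol)
      enr <- hypergeom_enrich(top_genes, collection, universe)
      utils::write.table(enr, file.path(config$outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(config$interactions_file)) {
      stage <- "prioritization"
      inter <- read_interactions(config$interactions_file)
      excl <- if (!is.null(collection)) {
        collection[intersect(config$exclusion_sets, names(collection))]
      } else list()
      ranked_sel <- ranked$top$gene_symbol[ranked$top$gene_symbol %in% selected_genes]
      targets <- prioritize_targets(unique(ranked_sel), inter, excl)
      utils::write.table(targets$table, file.path(config$outdir, "targets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(config$clinical_file)) {
      stage <- "survival"
      clin <- read_clinical(config$clinical_file)
      strata <- intersect(c("coo", "expr_group"), colnames(clin))
      surv <- compare_survival(clin, "arm", strata)
      utils::write.table(surv, file.path(config$outdir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summarize_cohort(clin),
                         file.path(config$outdir, "cohort_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("seedgba")),
      parameters = config[setdiff(names(config), "outdir")],
      rng_seed = config$rng_seed,
      stages = list(
        input = list(batches = length(batches), samples = sum(n_in)),
        deduplicate = list(samples_in = sum(n_in),
                           samples_out = sum(dd$report$kept),
                           duplicates_removed = sum(!dd$report$kept)),
        qc = list(samples_in = sum(dd$report$kept),
                  samples_out = sum(qc_report$kept),
                  outliers_removed = sum(!qc_report$kept),
                  pc1_variance_fraction = vapply(qc, `[[`, numeric(1),
                                                 "pc1_variance_fraction")),
        association = list(probes = nrow(assoc),
                           unique_genes = length(unique(assoc$gene_symbol)),
                           top_k = nrow(ranked$top),
                           top_k_unique_genes = ranked$n_unique_genes),
        permutation_fdr = list(B = config$perms, threshold = sel$threshold,
                               selected_probes = sum(sel_tab$selected),
                               selected_genes = length(selected_genes)),
        enrichment = if (is.null(enr)) NULL else list(sets = nrow(enr)),
        prioritization = if (is.null(targets)) NULL else
          list(with_interaction = nrow(targets$table),
               excluded = sum(targets$table$excluded),
               retained = sum(!targets$table$excluded)),
        survival = if (is.null(surv)) NULL else list(comparisons = nrow(surv))
      ))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    list(qc = qc_report, association = assoc, ranked = ranked,
         selection = sel, enrichment = enr, targets = targets,
         survival = surv, manifest = manifest)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(result, "condition")$message), call. = FALSE)
  }
  invisible(result)
}
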