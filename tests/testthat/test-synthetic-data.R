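test_that("sim_config validates its fields and names the offender", {
  expect_error(sim_config(module_size = 10, n_genes = 10), "module_size")
  expect_error(sim_config(module_correlations = c(0.5, 1)), "module_correlations")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_outliers = -1), "n_outliers")
  expect_error(sim_config(common_factor_sd = -2), "common_factor_sd")
})

test_that("identical rng_seed reproduces the compendium exactly", {
  cfg <- sim_config(n_batches = 2, samples_per_batch = 30, n_genes = 50,
                    module_size = 5, rng_seed = 9)
  a <- generate_compendium(cfg)
  b <- generate_compendium(cfg)
  expect_identical(a$batches[[1]]$expr, b$batches[[1]]$expr)
  expect_identical(a$batches[[2]]$expr, b$batches[[2]]$expr)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x <- rnorm(3)
  set.seed(1); invisible(generate_compendium(cfg)); y <- rnorm(3)
  expect_identical(x, y)
})

test_that("a null configuration yields no gene-seed association", {
  sim <- generate_compendium(sim_config(
    n_batches = 1, samples_per_batch = 500, n_genes = 300,
    probes_per_gene = 1, module_size = 0, module_correlations = numeric(0),
    common_factor_sd = 0, batch_shift_sd = 0, n_outliers = 0, rng_seed = 11))
  X <- sim$batches[[1]]$expr
  seedv <- X[paste0(sim$truth$seed_gene, "_at1"), ]
  r <- cor(t(X[rownames(X) != paste0(sim$truth$seed_gene, "_at1"), ]), seedv)
  # sampling bound: sd(r) ~ 1/sqrt(n); 5/sqrt(500) = 0.22 is a generous cap
  expect_lt(max(abs(r)), 5 / sqrt(500))
  expect_equal(nrow(sim$truth$associated_genes), 0)
})

test_that("planted correlations are recovered within the Fisher-z sampling bound", {
  sim <- generate_compendium(sim_config(
    n_batches = 3, samples_per_batch = 500, n_genes = 100,
    probes_per_gene = 1, module_size = 1, module_correlations = 0.9,
    n_outliers = 0, rng_seed = 12))
  g <- sim$truth$associated_genes$gene_symbol
  for (b in sim$batches) {
    seedv <- b$expr[paste0(sim$truth$seed_gene, "_at1"), ]
    r <- cor(b$expr[paste0(g, "_at1"), ], seedv)
    expect_true(abs(r - 0.9) < 0.05)
  }
})

test_that("negative planted correlations flip the loading sign", {
  sim <- generate_compendium(sim_config(
    n_batches = 1, samples_per_batch = 500, n_genes = 50, probes_per_gene = 1,
    module_size = 1, module_correlations = -0.7, n_outliers = 0, rng_seed = 13))
  b <- sim$batches[[1]]
  seedv <- b$expr[paste0(sim$truth$seed_gene, "_at1"), ]
  g <- sim$truth$associated_genes$gene_symbol
  expect_lt(abs(cor(b$expr[paste0(g, "_at1"), ], seedv) + 0.7), 0.06)
})

test_that("mean planted correlation over replicates is unbiased at n = 500", {
  rs <- vapply(1:30, function(i) {
    sim <- generate_compendium(sim_config(
      n_batches = 1, samples_per_batch = 500, n_genes = 20, probes_per_gene = 1,
      module_size = 1, module_correlations = 0.6, n_outliers = 0, rng_seed = 1000 + i))
    b <- sim$batches[[1]]
    cor(b$expr[paste0(sim$truth$associated_genes$gene_symbol, "_at1"), ],
        b$expr[paste0(sim$truth$seed_gene, "_at1"), ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.02)
})

test_that("clinical simulation: null effect, known hazard ratio, censoring limit", {
  # null: both expression groups share the survival distribution
  grp <- setNames(rep(c("high", "low"), each = 1000), sprintf("S%04d", 1:2000))
  clin0 <- generate_clinical(clinical_sim_config(
    log_hazard_effects = c(high = 0), censoring_rate = 1e-6, rng_seed = 21), grp)
  cmp0 <- logrank_hr(clin0$time, clin0$event, clin0$expr_group)
  expect_lt(abs(cmp0$hr - 1), 0.2)

  # log HR of ln(2), effectively no censoring: estimated HR near 2
  clin2 <- generate_clinical(clinical_sim_config(
    log_hazard_effects = c(high = log(2)), censoring_rate = 1e-9, rng_seed = 22), grp)
  cmp2 <- logrank_hr(clin2$time, clin2$event, factor(clin2$expr_group, c("high", "low")))
  expect_gt(cmp2$hr, 1.8)
  expect_lt(cmp2$hr, 2.2)
  expect_true(all(clin2$event == 1))

  # censoring rate far above the hazard: nearly everything censored
  clinc <- generate_clinical(clinical_sim_config(
    baseline_hazard = 0.001, censoring_rate = 5, rng_seed = 23), grp)
  expect_lt(mean(clinc$event), 0.01)
})

test_that("clinical simulation rejects unknown group labels", {
  grp <- c(S1 = "mystery")
  expect_error(generate_clinical(clinical_sim_config(), grp), "mystery")
  expect_error(clinical_sim_config(coo_probs = c(0.5, 0.4)), "coo_probs")
})

test_that("fixture bundle round-trips through the io layer", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(n_batches = 2, samples_per_batch = 40, n_genes = 60,
                    probes_per_gene = 2, module_size = 10, n_outliers = 0,
                    rng_seed = 31)
  paths <- write_fixture_bundle(outdir, cfg, clinical_sim_config(rng_seed = 31))
  sim <- generate_compendium(cfg)

  b1_gct <- read_expression(paths$gct_batch01)
  b1_tsv <- read_expression(paths$tsv_batch01)
  expect_equal(b1_gct$expr, sim$batches[[1]]$expr, tolerance = 1e-4)
  expect_equal(b1_tsv$expr, sim$batches[[1]]$expr, tolerance = 1e-4)

  pm <- read_probe_map(paths$probe_map)
  expect_equal(pm, sim$probe_map)
  # probes_per_gene = 2 for all genes: exactly 2 probe rows per gene
  expect_true(all(table(pm$gene_symbol) == 2))

  sets <- read_gmt(paths$gmt)
  expect_true("BCR signaling" %in% names(sets))
  expect_true("DLBCL trials" %in% names(sets))
  clin <- read_clinical(paths$clinical)
  expect_setequal(clin$sample_id, colnames(sim$batches[[1]]$expr))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$associated_genes$gene_symbol,
                  sim$truth$associated_genes$gene_symbol)
})

test_that("a one-batch bundle emits a single GCT with a constant batch column", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(n_batches = 1, samples_per_batch = 30, n_genes = 40,
                    module_size = 5, n_outliers = 0, rng_seed = 32)
  paths <- write_fixture_bundle(outdir, cfg, clinical_sim_config(rng_seed = 32))
  expect_length(grep("^gct_", names(paths)), 1)
  batches <- read.delim(paths$batches_tsv)
  expect_equal(length(unique(batches$batch)), 1)
})
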