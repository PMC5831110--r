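test_that("probe collapsing takes the per-sample arithmetic mean", {
  mat <- matrix(c(2, 4, 1, 2, 6, 10), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1_a", "g1_b", "g2_a"), c("s1", "s2")))
  pm <- data.frame(probe_id = c("g1_a", "g1_b", "g2_a"),
                   gene_symbol = c("G1", "G1", "G2"))
  out <- collapse_probes(mat, pm)
  expect_equal(out["G1", "s1"], mean(c(2, 1)))
  expect_equal(out["G1", "s2"], mean(c(4, 2)))
  # single-probe gene passes through unchanged
  expect_equal(out["G2", ], mat["g2_a", ])

  three <- matrix(c(1, 2, 6), 3, 1, dimnames = list(c("x_a", "x_b", "x_c"), "s1"))
  pm3 <- data.frame(probe_id = rownames(three), gene_symbol = "X")
  expect_equal(unname(collapse_probes(three, pm3)["X", 1]), mean(c(1, 2, 6)))

  expect_error(collapse_probes(mat, pm, c("G1", "G9")), "G9")
})

test_that("per-batch correlation matches the brute-force covariance oracle", {
  seed <- c(1, 2, 3, 4, 5)
  gene <- c(2, 1, 4, 3, 6)
  mat <- rbind(gene = gene, self = seed, anti = -seed)
  colnames(mat) <- paste0("s", 1:5)
  ba <- batch_correlations(mat, seed)
  expect_equal(ba$r[ba$probe_id == "gene"], pearson_oracle(seed, gene),
               tolerance = 1e-12)
  expect_equal(ba$r[ba$probe_id == "self"], 1)
  expect_equal(ba$r[ba$probe_id == "anti"], -1)
  expect_true(all(ba$n == 5))
  expect_true(all(is.finite(ba$z)))  # |r| = 1 clipped before atanh

  matz <- rbind(mat, flat = rep(7, 5))
  baz <- batch_correlations(matz, seed)
  expect_true(is.na(baz$r[baz$probe_id == "flat"]))
  expect_error(batch_correlations(mat[, 1:3], seed[1:3]), "4 samples")
})

test_that("fisher_z matches its closed forms and clips degenerate input", {
  expect_equal(fisher_z(0, 10)$z, 0)
  expect_equal(fisher_z(0.3, 7)$se, 0.5)  # 1/sqrt(4)
  expect_equal(fisher_z(0.5, 10)$z, atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 10)$z, 0.549306, tolerance = 1e-6)
  expect_true(is.finite(fisher_z(1, 10)$z))
  expect_error(fisher_z(0.5, 3), "n >= 4")
})

test_that("fixed-effect pooling: identity, doubling, and oracle equivalence", {
  one <- meta_fixed_effect(z = 0.4, se = 0.1)
  expect_equal(one$statistic, 0.4 / 0.1)
  expect_equal(one$zbar, 0.4)

  two <- meta_fixed_effect(z = c(0.4, 0.4), se = c(0.1, 0.1))
  expect_equal(two$zbar, 0.4)
  expect_equal(two$statistic, sqrt(2) * one$statistic, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    z <- rnorm(k); se <- runif(k, 0.05, 0.5)
    got <- meta_fixed_effect(z, se)
    want <- meta_oracle(z, se)
    expect_equal(got$zbar, want$zbar, tolerance = 1e-12)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  }
  expect_error(meta_fixed_effect(numeric(0), numeric(0)), "no batch")
})

test_that("meta statistic is invariant to batch order and exact for one batch", {
  sim <- small_sim()
  batches <- lapply(sim$batches, function(b) qc_batch(b)$batch)
  tab <- meta_associate(batches, sim$probe_map, sim$truth$seed_gene)
  tab_rev <- meta_associate(rev(batches), sim$probe_map, sim$truth$seed_gene)
  m <- match(tab$probe_id, tab_rev$probe_id)
  expect_equal(tab$statistic, tab_rev$statistic[m], tolerance = 1e-12)
  expect_true(all(abs(tab$r_pooled) < 1))

  # one-batch compendium: pooled result equals the single-batch z/se exactly
  one <- meta_associate(batches[1], sim$probe_map, sim$truth$seed_gene)
  seedv <- seed_profile(batches[[1]], sim$probe_map, sim$truth$seed_gene)
  ba <- batch_correlations(batches[[1]]$expr, seedv)
  m2 <- match(one$probe_id, ba$probe_id)
  expect_equal(one$zbar, ba$z[m2], tolerance = 1e-12)
  expect_equal(one$statistic, ba$z[m2] / ba$se[m2], tolerance = 1e-12)
})

test_that("probes missing from a batch are pooled complete-case", {
  sim <- small_sim()
  batches <- lapply(sim$batches, function(b) qc_batch(b)$batch)
  drop_probe <- setdiff(rownames(batches[[1]]$expr),
                        sim$probe_map$probe_id[sim$probe_map$gene_symbol ==
                                                 sim$truth$seed_gene])[1]
  batches2 <- batches
  batches2[[2]]$expr <- batches2[[2]]$expr[rownames(batches2[[2]]$expr) != drop_probe, ]
  tab <- meta_associate(batches2, sim$probe_map, sim$truth$seed_gene)
  row <- tab[tab$probe_id == drop_probe, ]
  expect_true(is.na(row[[paste0("r.", batches[[2]]$batch_id)]]))
  # pooled value equals pooling over the two batches that carry the probe
  z1 <- fisher_z(row[[paste0("r.", batches[[1]]$batch_id)]],
                 row[[paste0("n.", batches[[1]]$batch_id)]])
  z3 <- fisher_z(row[[paste0("r.", batches[[3]]$batch_id)]],
                 row[[paste0("n.", batches[[3]]$batch_id)]])
  want <- meta_oracle(c(z1$z, z3$z), c(z1$se, z3$se))
  expect_equal(row$statistic, want$statistic, tolerance = 1e-10)
})

test_that("ranking is deterministic, excludes the seed, and recovers the module", {
  # one probe per gene so the top-k probe slice maps 1:1 onto genes
  sim <- generate_compendium(sim_config(probes_per_gene = 1, rng_seed = 301))
  batches <- lapply(sim$batches, function(b) qc_batch(b)$batch)
  tab <- meta_associate(batches, sim$probe_map, sim$truth$seed_gene)

  # the seed gene's own probes attain r = 1 per batch and the top statistic
  seed_rows <- tab[tab$is_seed, ]
  expect_true(all(abs(seed_rows[[paste0("r.", batches[[1]]$batch_id)]] - 1) < 1e-9))
  expect_equal(tab$gene_symbol[which.max(tab$statistic)], sim$truth$seed_gene)

  expect_setequal(tab$rank, seq_len(nrow(tab)))
  ranked <- rank_genes(tab, k = 50)
  expect_false(any(ranked$top$is_seed))
  planted <- sim$truth$associated_genes$gene_symbol
  expect_gte(sum(unique(ranked$top$gene_symbol) %in% planted), 48)
  expect_equal(ranked$n_unique_genes, length(unique(ranked$top$gene_symbol)))

  whole <- rank_genes(tab, k = sum(!tab$is_seed))
  expect_equal(nrow(whole$top), sum(!tab$is_seed))
  expect_error(rank_genes(tab, k = nrow(tab) + 1), "k exceeds")
})

test_that("pooled correlation is a consistent estimate of the planted value", {
  # mean tanh(zbar) across replicates within +/-0.02 of the generating r
  est <- vapply(1:25, function(i) {
    sim <- generate_compendium(sim_config(
      n_batches = 3, samples_per_batch = 350, n_genes = 30, probes_per_gene = 1,
      module_size = 1, module_correlations = 0.6, n_outliers = 0,
      rng_seed = 400 + i))
    tab <- meta_associate(sim$batches, sim$probe_map, sim$truth$seed_gene)
    tab$r_pooled[tab$gene_symbol == sim$truth$associated_genes$gene_symbol]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.02)
})
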