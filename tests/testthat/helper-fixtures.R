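# Shared fixtures for the test suite. Everything is generated in code;
# small configurations keep individual tests fast while the acceptance
# tests use the full default study conditions.

# a small compendium with a planted module, cached per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_compendium(sim_config(
        n_batches = 3, samples_per_batch = 120, n_genes = 400,
        probes_per_gene = 1:2, module_size = 20,
        module_correlations = seq(0.5, 0.9, length.out = 20),
        n_outliers = 3, rng_seed = 101))
    }
    cache
  }
})

# a global-null compendium: no module, independent genes
null_sim <- function(n_genes = 400, samples = 60, rng_seed = 202,
                     common_factor_sd = 0) {
  generate_compendium(sim_config(
    n_batches = 3, samples_per_batch = samples, n_genes = n_genes,
    probes_per_gene = 1, module_size = 0, module_correlations = numeric(0),
    common_factor_sd = common_factor_sd, batch_shift_sd = 0,
    n_outliers = 0, rng_seed = rng_seed))
}

# brute-force two-pass Pearson correlation, the oracle for cor-based code
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force inverse-variance fixed-effect pooling oracle
meta_oracle <- function(z, se) {
  w <- 1 / se^2
  zbar <- sum(w * z) / sum(w)
  sep <- sqrt(1 / sum(w))
  list(zbar = zbar, se = sep, statistic = zbar / sep)
}

# exhaustive hypergeometric upper tail by enumeration over combn draws
hyper_tail_oracle <- function(k, K, N, n) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(hits >= k)
}

# per-event-time 2x2 log-rank O/E construction (risk-set oracle)
logrank_oracle <- function(times, events, group) {
  g1 <- levels(factor(group))[1]
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V)
}

# clinical table reconstructed from published-style cohort counts:
# total patients, named vector of classified counts, remainder missing
cohort_from_counts <- function(total, counts, field = "coo") {
  lab <- c(rep(names(counts), counts), rep(NA_character_, total - sum(counts)))
  df <- data.frame(sample_id = sprintf("P%04d", seq_len(total)),
                   stringsAsFactors = FALSE)
  df[[field]] <- lab
  class(df) <- c("clinical_table", "data.frame")
  df
}
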