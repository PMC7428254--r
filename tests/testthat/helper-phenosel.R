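# shared fixtures for the suite -------------------------------------------

# pure birth-death network: stationary law Poisson(b/d)
bd_network <- function(b = 0.1, d = 0.01) {
  custom_network("X", list(
    list(stoich = 1L, kind = 0L, rate = b),
    list(stoich = -1L, kind = 1L, rate = d, dep1 = 1)
  ))
}

# stationary samples from n independent long birth-death runs
bd_sample <- function(n, b = 0.1, d = 0.01, window = 500,
                      method = "ssa", n_sub = 1L) {
  net <- bd_network(b, d)
  cfg <- engine_config(method, n_sub = n_sub)
  x0 <- round(b / d)
  vapply(seq_len(n), function(i) {
    advance_reactions(c(X = x0), net, window, cfg)$state[["X"]]
  }, numeric(1))
}

# block standard error of a statistic over a sample (for 3-SE checks)
block_se <- function(x, stat, n_blocks = 20) {
  blocks <- split(x, rep(seq_len(n_blocks), length.out = length(x)))
  stats::sd(vapply(blocks, stat, numeric(1))) / sqrt(n_blocks)
}

# small general-model parameter set for fast population tests
params_small <- function(...) params_general(K = 200L, ...)

# replicate means of a wide assay table (test-side oracle helper)
viability_means_for_test <- function(tbl) {
  reps <- grep("^rep", names(tbl), value = TRUE)
  out <- tbl[, c("dose_uM", "time_h")]
  out$mean_pct <- rowMeans(tbl[reps])
  out
}

# one-row cell for division tests
one_cell <- function(volume = 30, mgmt = 100, ref = 80,
                     mrna_mgmt = 3, mrna_ref = 2) {
  tibble::tibble(volume = volume, vf_target = volume,
                 mrna_mgmt = mrna_mgmt, mgmt = mgmt,
                 mrna_ref = mrna_ref, ref = ref, alive = TRUE)
}
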