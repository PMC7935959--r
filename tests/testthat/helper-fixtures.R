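# Small programmatic fixtures shared across test files.

# A named gene x sample matrix with iid normal entries.
random_expression <- function(n_genes, n_samples, seed, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# A structure-free Gaussian mixing matrix wrapped for scoring.
random_mixing <- function(n_genes, k, seed) {
  set.seed(seed)
  mixing_matrix(matrix(rnorm(n_genes * k), n_genes, k,
                       dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                       paste0("TC", seq_len(k)))))
}

# Write a GMT file from a named list of member vectors; returns the path.
write_gmt_lines <- function(sets, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1)), path)
  path
}

# Shared planted-structure fixture at the default study scale, computed once
# per test session (used by several decomposition/prediction tests).
planted_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_expression(n_genes = 300, n_samples = 600, k = 6,
                                 noise_sd = 0.1, set_size = 20, seed = 42)
      basis <- whiten(sim$X)
      cres <- run_consensus_ica(basis, n_runs = 25, seed = 42)
      MM <- recompute_mixing(sim$X, cres)
      cache <<- list(sim = sim, basis = basis, cres = cres, MM = MM)
    }
    cache
  }
})
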