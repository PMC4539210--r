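# shared fixtures and independent oracles, all generated in code

small_cohort <- function(m = 400, n = 40, mu = 2, mu0 = 3,
                         frac = 0.95, seed = 1) {
  simulate_latent_cohort(m = m, n = n, frac_ms_genes = frac, mu = mu,
                         mu0 = mu0, seed = seed)
}

# brute-force standard FDR: explicit min-scan over ranks i >= k
bf_fdr_standard <- function(p, pi0) {
  m <- length(p)
  o <- order(p)
  raw <- m * pi0 * p[o] / seq_len(m)
  out <- numeric(m)
  for (k in seq_len(m)) out[o[k]] <- min(1, min(raw[k:m]))
  out
}

# independent pooled-variance t oracle via stats::t.test
oracle_t <- function(x, y) {
  unname(stats::t.test(x, y, var.equal = TRUE)$statistic)
}

# a matrix with two planted patient blocks separated on all genes
planted_patient_blocks <- function(m = 60, n1 = 15, n2 = 15, shift = 6,
                                   seed = 5) {
  withr::with_seed(seed, {
    X <- cbind(matrix(rnorm(m * n1), m, n1),
               matrix(rnorm(m * n2, mean = shift), m, n2))
    dimnames(X) <- list(sprintf("g%03d", 1:m), sprintf("p%03d", 1:(n1 + n2)))
    X
  })
}
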