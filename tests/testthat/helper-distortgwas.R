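# Shared generators for property-style tests.

# random valid two-locus LD draws: frequencies away from the boundary,
# r uniform within its feasible range
rand_ld <- function(n, f_range = c(0.05, 0.95)) {
  f_A <- runif(n, f_range[1], f_range[2])
  f_B <- runif(n, f_range[1], f_range[2])
  lapply(seq_len(n), function(i) {
    b <- r_bounds(f_A[i], f_B[i])
    two_locus_ld(f_A[i], f_B[i], runif(1, b[1], b[2]))
  })
}

# random valid single-SNP models with moderate effects
rand_model <- function(n, beta_max = log(2)) {
  lapply(seq_len(n), function(i)
    general_model(beta = runif(1, -beta_max, beta_max),
                  gamma = runif(1, -beta_max, beta_max),
                  mu = log(0.01)))
}

# genotype count table drawn from the theoretical case/control genotype
# frequencies of a model
simulate_counts <- function(model, f, n_case, n_ctrl, phi = 0.5) {
  fr <- cc_genotype_freqs(model, f, phi)
  genotype_counts(as.vector(rmultinom(1, n_case, fr$case)),
                  as.vector(rmultinom(1, n_ctrl, fr$control)))
}

# two-SNP table under independent null SNPs
simulate_null_counts_2snp <- function(f1, f2, n_case, n_ctrl) {
  p <- as.vector(outer(dbinom(0:2, 2, f1), dbinom(0:2, 2, f2)))
  genotype_counts(matrix(rmultinom(1, n_case, p), 3, 3),
                  matrix(rmultinom(1, n_ctrl, p), 3, 3))
}
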