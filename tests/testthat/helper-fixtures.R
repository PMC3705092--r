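# small data builders shared across test files

# tie-free survival fixture with a 0/1/2 dosage and optional age/sex
make_surv_fixture <- function(n, seed, covars = TRUE) {
  set.seed(seed)
  repeat {
    time <- round(runif(n, 1, 20), 3)
    event <- rbinom(n, 1, 0.7)
    dosage <- sample(0:2, n, replace = TRUE)
    if (sum(event) >= 2 && length(unique(dosage)) > 1 &&
        !any(duplicated(time))) break
  }
  out <- list(time = time, event = event, dosage = dosage)
  if (covars) {
    out$age <- round(rnorm(n, 70, 6), 1)
    out$sex <- rbinom(n, 1, 0.5)
  }
  out
}

# one simulated cohort: genotypes + phenotypes, defaults to a modest ROI
make_sim_cohort <- function(n = 500, n_snps = 5, maf = 0.3, adj_r2 = 0,
                            beta_g = 0, causal = 1, seed = 1,
                            event_frac = 0.5, imp_r2 = NULL) {
  blk <- ld_block_spec(n_snps, maf, adj_r2 = adj_r2)
  eff <- effect_spec(causal_snp_index = if (beta_g != 0) causal else NULL,
                     beta_g = beta_g)
  censor <- 15
  co <- cohort_spec(
    "sim", n,
    weibull_scale = weibull_scale_for_event_fraction(event_frac, censor),
    admin_censor_time = censor, seed = child_seed(seed, 1, 3)
  )
  h <- simulate_haplotypes(blk, 2 * n, seed = child_seed(seed, 1, 1))
  g <- genotypes_from_haplotypes(h, child_seed(seed, 1, 2), snp_table(blk))
  if (!is.null(imp_r2)) {
    g <- add_imputation_noise(g, imp_r2, child_seed(seed, 1, 4))
  }
  list(g = g, phen = simulate_survival(g, co, eff), block = blk)
}
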