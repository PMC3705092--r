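# Independent oracles the implementation is checked against. These are
# deliberately naive: direct evaluation of definitions, no shared code with
# the package internals.

# Cox partial log-likelihood for tie-free data (Breslow = Efron when no ties)
pl_loglik <- function(beta, time, event, X) {
  lp <- as.vector(X %*% beta)
  total <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    total <- total + lp[i] - log(sum(exp(lp[at_risk])))
  }
  total
}

# brute-force maximization of the partial likelihood over all coefficients
oracle_cox_beta <- function(time, event, X) {
  fit <- optim(rep(0, ncol(X)), function(b) -pl_loglik(b, time, event, X),
               method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  fit$par
}

# 200-point grid maximization for a single-covariate model, refined by
# optimize() within the bracketing grid cells
oracle_cox_beta_grid <- function(time, event, x, lo = -3, hi = 3) {
  grid <- seq(lo, hi, length.out = 200)
  ll <- vapply(grid, function(b) pl_loglik(b, time, event, cbind(x)),
               double(1))
  k <- which.max(ll)
  optimize(function(b) pl_loglik(b, time, event, cbind(x)),
           interval = c(grid[max(1, k - 1)], grid[min(200, k + 1)]),
           maximum = TRUE, tol = 1e-9)$maximum
}

# exact Hardy-Weinberg test: full enumeration of heterozygote counts
# conditional on the allele counts, summing probabilities <= the observed
hwe_exact_p <- function(n_ref, n_het, n_alt) {
  n <- n_ref + n_het + n_alt
  n_a <- 2 * n_alt + n_het
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lfactorial(n) - lfactorial(hom_major) - lfactorial(h) -
      lfactorial(hom_minor) + h * log(2) +
      lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n)
  }, double(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_het, hets)] + 1e-12])
}
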