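#' Specify an LD block of SNPs
#'
#' Describes the linkage-disequilibrium structure the haplotype simulator
#' targets: a set of SNPs with given minor-allele frequencies and a common
#' squared correlation between adjacent SNPs. A first-order Markov chain over
#' adjacent pairs is enough to give the max-T permutation something real to
#' correct for; no demographic realism is attempted.
#'
#' @param n_snps Number of SNPs in the block.
#' @param maf Vector of coded-allele frequencies in (0, 0.5], length `n_snps`
#'   (recycled if length 1).
#' @param adj_r2 Target squared correlation between adjacent SNP alleles on a
#'   haplotype, in \[0, 1).
#' @param positions Strictly increasing 1-based base-pair positions
#'   (default: 5 kb spacing starting at 1e6).
#' @param chrom Chromosome label.
#' @param gene_label Gene label attached to every SNP in the block.
#' @return An object of class `ld_block_spec`.
#' @export
#' @examples
#' ld_block_spec(10, maf = 0.3, adj_r2 = 0.8)
ld_block_spec <- function(n_snps, maf, adj_r2 = 0,
                          positions = NULL, chrom = "6",
                          gene_label = "GENE1") {
  stopifnot(is_count(n_snps), n_snps >= 1)
  if (length(maf) == 1) maf <- rep(maf, n_snps)
  if (length(maf) != n_snps) {
    stop("`maf` must have length 1 or `n_snps` (", n_snps, ")")
  }
  stopifnot(all(maf > 0), all(maf <= 0.5))
  stopifnot(length(adj_r2) == 1, adj_r2 >= 0, adj_r2 < 1)
  if (is.null(positions)) positions <- 1e6 + 5000 * (seq_len(n_snps) - 1)
  stopifnot(length(positions) == n_snps)
  if (n_snps > 1 && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), maf = as.numeric(maf),
      adj_r2 = adj_r2, positions = as.integer(positions),
      chrom = as.character(chrom), gene_label = gene_label
    ),
    class = "ld_block_spec"
  )
}

#' Specify additive genetic and covariate effects on the log-hazard scale
#'
#' @param causal_snp_index Index of the causal SNP within the block, or `NULL`
#'   for a global null.
#' @param beta_g Log hazard ratio per additional coded allele of the causal
#'   SNP. `exp(beta_g)` is the per-allele HR.
#' @param beta_age Log hazard ratio per year of age above the cohort mean.
#' @param beta_sex Log hazard ratio for female (sex = 1) versus male.
#' @return An object of class `effect_spec`.
#' @export
#' @examples
#' effect_spec(causal_snp_index = 1, beta_g = log(0.8))
effect_spec <- function(causal_snp_index = NULL, beta_g = 0,
                        beta_age = 0.09, beta_sex = -0.4) {
  if (!is.null(causal_snp_index)) {
    stopifnot(is_count(causal_snp_index), causal_snp_index >= 1)
    causal_snp_index <- as.integer(causal_snp_index)
  }
  stopifnot(is.numeric(beta_g), is.numeric(beta_age), is.numeric(beta_sex))
  structure(
    list(
      causal_snp_index = causal_snp_index, beta_g = beta_g,
      beta_age = beta_age, beta_sex = beta_sex
    ),
    class = "effect_spec"
  )
}

#' Specify a cohort for the survival simulator
#'
#' Baseline age is Normal(`age_mean`, `age_sd`) truncated below at 55 years
#' (the analysis eligibility age). Event times follow a Weibull
#' proportional-hazards model with baseline cumulative hazard
#' `(t / weibull_scale)^weibull_shape`, on the time-on-study scale;
#' everyone still alive at `admin_censor_time` years is administratively
#' censored there.
#'
#' @param name Cohort name (must be unique within a multi-cohort design).
#' @param n Number of individuals.
#' @param age_mean,age_sd Baseline age distribution in years.
#' @param frac_female Proportion of females.
#' @param weibull_shape Weibull shape rho > 0 (rho > 1 means hazard rising
#'   with time on study, as for mortality in older cohorts).
#' @param weibull_scale Weibull scale lambda > 0 in years. See
#'   [weibull_scale_for_event_fraction()] to calibrate it to a target
#'   fraction of deaths.
#' @param admin_censor_time Administrative censoring time in years.
#' @param seed Integer seed for this cohort's draws.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("discovery", n = 500, age_mean = 69, age_sd = 9,
#'             frac_female = 0.59, weibull_scale = 15,
#'             admin_censor_time = 16, seed = 1)
cohort_spec <- function(name, n, age_mean = 70, age_sd = 8,
                        frac_female = 0.55, weibull_shape = 1.3,
                        weibull_scale = 20, admin_censor_time = 15,
                        seed = 1L) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(is_count(n), n > 0)
  stopifnot(frac_female >= 0, frac_female <= 1)
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stop("Weibull shape and scale must be positive")
  }
  stopifnot(admin_censor_time > 0)
  if (age_mean < 55) {
    warning("cohort '", name, "': age_mean ", age_mean,
            " is below the 55-year eligibility age; most simulated ",
            "individuals will sit at the truncation boundary")
  }
  structure(
    list(
      name = name, n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
      frac_female = frac_female, weibull_shape = weibull_shape,
      weibull_scale = weibull_scale, admin_censor_time = admin_censor_time,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Weibull scale giving a target event fraction at the censoring time
#'
#' Under the baseline hazard (linear predictor 0) the probability of death
#' before time `censor_time` is `1 - exp(-(censor_time / lambda)^shape)`.
#' Inverting for lambda calibrates a cohort to a target fraction deceased.
#'
#' @param event_fraction Target fraction of deaths in (0, 1).
#' @param censor_time Administrative censoring time in years.
#' @param shape Weibull shape rho.
#' @return The scale lambda in years.
#' @export
#' @examples
#' weibull_scale_for_event_fraction(0.53, censor_time = 16)
weibull_scale_for_event_fraction <- function(event_fraction, censor_time,
                                             shape = 1.3) {
  stopifnot(event_fraction > 0, event_fraction < 1,
            censor_time > 0, shape > 0)
  censor_time / (-log(1 - event_fraction))^(1 / shape)
}

#' Nine-cohort design emulating a large aging consortium
#'
#' A ready-made list of [cohort_spec()]s: one large discovery cohort followed
#' by eight replication cohorts of heterogeneous size, baseline age and
#' follow-up, with Weibull scales calibrated so the expected fraction
#' deceased spans roughly 0.17-0.53 — the range typical of population-based
#' aging cohorts with 5-16 years of follow-up. Per-cohort seeds are derived
#' from `master_seed` with [child_seed()].
#'
#' @param master_seed Integer master seed.
#' @return A named list of nine `cohort_spec` objects.
#' @export
#' @examples
#' specs <- example_cohort_specs(1)
#' sapply(specs, `[[`, "n")
example_cohort_specs <- function(master_seed = 1L) {
  pars <- tibble::tribble(
    ~name,        ~n,   ~age_mean, ~age_sd, ~frac_female, ~event_frac, ~fu,
    "discovery",  5974, 69.4,      9.1,     0.59,         0.53,        12.5,
    "rep1",       3267, 72.3,      5.4,     0.61,         0.53,        12.3,
    "rep2",       3136, 70.0,      10.2,    0.56,         0.21,        6.0,
    "rep3",       4511, 59.4,      2.9,     0.50,         0.25,        15.7,
    "rep4",       3219, 76.4,      5.5,     0.58,         0.17,        5.2,
    "rep5",       1661, 73.8,      2.8,     0.47,         0.28,        8.2,
    "rep6",       620,  62.0,      8.8,     0.41,         0.30,        15.7,
    "rep7",       902,  72.5,      7.7,     0.56,         0.20,        5.9,
    "rep8",       1717, 66.4,      7.2,     0.47,         0.24,        9.2
  )
  specs <- vector("list", nrow(pars))
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    censor <- p$fu * 1.25
    cohort <- cohort_spec(
      name = p$name, n = p$n, age_mean = p$age_mean, age_sd = p$age_sd,
      frac_female = p$frac_female, weibull_shape = 1.3,
      weibull_scale = weibull_scale_for_event_fraction(p$event_frac, censor),
      admin_censor_time = censor,
      seed = child_seed(master_seed, i)
    )
    specs[[i]] <- cohort
  }
  names(specs) <- pars$name
  specs
}
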