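NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))

#' Configuration for the summary-statistics generator
#'
#' Defaults reproduce the study conditions of the two-sample analysis this
#' package reimplements: exposure GWAS of 44,147 individuals (the
#' homocysteine meta-analysis), outcome GWAS of 567,460 (the European eGFR
#' meta-analysis), instrument strengths drawn from the packaged homocysteine
#' betas, and a causal effect of -0.0095 log-eGFR per SD exposure (about a
#' -0.95% eGFR change, the scale of the headline estimate), with no
#' pleiotropy unless requested.
#'
#' @param m_snps number of instruments.
#' @param theta true causal effect, log-outcome per SD exposure.
#' @param gamma_source `"table1"` (resample the packaged per-SD betas of
#'   `exposure`) or `"random"` (half-normal with SD `gamma_sd`).
#' @param exposure which packaged instrument supplies `table1` strengths.
#' @param gamma_sd scale of random instrument strengths.
#' @param n_exp,n_out GWAS sample sizes.
#' @param outcome_sd phenotypic SD of the outcome trait. The exposure is
#'   instrumented per SD (unit variance by construction) but the outcome is
#'   on natural-log eGFR units, whose population SD is about 0.2; per-allele
#'   SEs scale with it, `se^2 = sd^2 / (2 eaf (1 - eaf) n)`.
#' @param pleiotropy_mean,pleiotropy_sd direct-effect distribution of invalid
#'   instruments. Directionality is defined on the exposure-increasing allele
#'   (the convention under which MR-Egger's intercept captures it): a
#'   variant whose tabulated effect allele lowers the exposure carries the
#'   sign-reflected direct effect on that coding.
#' @param inside_violation correlation between pleiotropic effects and
#'   instrument strength (0 = InSIDE holds).
#' @param prop_invalid fraction of instruments given a direct effect.
#' @param eaf_range effect-allele frequency range (uniform).
#' @param allele_scramble randomly re-express outcome records on the opposite
#'   allele, to exercise harmonization.
#' @param seed mandatory integer seed.
#' @return validated config list of class `summary_sim_config`.
#' @export
summary_sim_config <- function(m_snps = 16L, theta = -0.0095,
                               gamma_source = c("table1", "random"),
                               exposure = "homocysteine", gamma_sd = 0.08,
                               n_exp = 44147L, n_out = 567460L,
                               outcome_sd = 0.2,
                               pleiotropy_mean = 0, pleiotropy_sd = 0,
                               inside_violation = 0, prop_invalid = 0,
                               eaf_range = c(0.05, 0.95),
                               allele_scramble = FALSE, seed) {
  if (missing(seed)) stop_mrkit("seed is mandatory", "mrkit_config_error")
  gamma_source <- match.arg(gamma_source)
  cfg <- list(m_snps = as.integer(m_snps), theta = theta,
              gamma_source = gamma_source, exposure = exposure,
              gamma_sd = gamma_sd, n_exp = n_exp, n_out = n_out,
              outcome_sd = outcome_sd, pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              inside_violation = inside_violation, prop_invalid = prop_invalid,
              eaf_range = eaf_range, allele_scramble = isTRUE(allele_scramble),
              seed = as.integer(seed))
  with(cfg, {
    if (m_snps < 1L || n_exp < 10 || n_out < 10 || outcome_sd <= 0 ||
        prop_invalid < 0 || prop_invalid > 1 ||
        abs(inside_violation) > 1 ||
        eaf_range[1] <= 0 || eaf_range[2] >= 1 || eaf_range[1] > eaf_range[2])
      stop_mrkit("invalid summary simulation config", "mrkit_config_error")
  })
  structure(cfg, class = c("summary_sim_config", "list"))
}

#' Simulate two-sample GWAS summary statistics under a linear causal model
#'
#' Per variant j: `eaf_j ~ Uniform(eaf_range)`; true strength `gamma_j` from
#' the packaged betas or a half-normal; direct (pleiotropic) effect
#' `alpha_j = 0` for valid variants, otherwise normal with the configured
#' mean/SD and correlation `inside_violation` with `|gamma_j|`. Observed
#' effects are `beta_exp = gamma + e_x` and
#' `beta_out = theta gamma + sign(gamma) alpha + e_y` (alpha is the direct
#' effect on the exposure-increasing allele),
#' with per-allele SEs from the standard variance approximation
#' `se^2 = sd^2 / (2 eaf (1 - eaf) n)` (`sd = 1` for the per-SD exposure,
#' `outcome_sd` for the outcome), and p-values from the normal z (floored at
#' the smallest positive double). Alleles are
#' drawn from non-palindromic pairs; with `allele_scramble` a random subset
#' of outcome records is re-expressed on the opposite allele (beta negated,
#' frequency reflected, alleles swapped), which harmonization must undo.
#'
#' @param config a [summary_sim_config()].
#' @return list: `instrument` (an [instrument_set()]), `outcome` (canonical
#'   variant data frame) and `truth` (theta, per-SNP strengths, direct
#'   effects, validity flags, scramble flags, seed).
#' @export
simulate_summary <- function(config) {
  stopifnot(inherits(config, "summary_sim_config"))
  set.seed(derive_seed(config$seed, "simulate_summary"))
  m <- config$m_snps
  eaf <- stats::runif(m, config$eaf_range[1], config$eaf_range[2])
  gamma <- if (config$gamma_source == "table1") {
    betas <- mr_instruments(config$exposure)$beta
    sample(betas, m, replace = m > length(betas))
  } else {
    abs(stats::rnorm(m, 0, config$gamma_sd))
  }
  n_invalid <- round(config$prop_invalid * m)
  valid <- rep(TRUE, m)
  if (n_invalid > 0L) valid[sample.int(m, n_invalid)] <- FALSE
  alpha <- rep(0, m)
  if (n_invalid > 0L) {
    rho <- config$inside_violation
    g <- abs(gamma[!valid])
    gz <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, length(g))
    z <- stats::rnorm(length(g))
    alpha[!valid] <- config$pleiotropy_mean +
      config$pleiotropy_sd * (rho * gz + sqrt(1 - rho^2) * z)
  }
  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exp)
  se_out <- config$outcome_sd / sqrt(2 * eaf * (1 - eaf) * config$n_out)
  beta_exp <- gamma + stats::rnorm(m, 0, se_exp)
  # alpha lives on the exposure-increasing allele; re-express it on the
  # tabulated effect allele
  beta_out <- config$theta * gamma + sign(gamma) * alpha +
    stats::rnorm(m, 0, se_out)

  pair <- NONPALINDROMIC_PAIRS[sample.int(4L, m, replace = TRUE)]
  swap <- stats::runif(m) < 0.5
  ea <- vapply(seq_len(m), function(i) pair[[i]][1 + swap[i]], character(1))
  oa <- vapply(seq_len(m), function(i) pair[[i]][2 - swap[i]], character(1))
  rsid <- sprintf("rs%07d", sample.int(9999999L, m))

  instrument <- instrument_set(
    data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta_exp, se = se_exp,
               pval = pval_from_beta_se(beta_exp, se_exp), n = config$n_exp,
               stringsAsFactors = FALSE),
    exposure_name = paste0("simulated_", config$exposure))

  outcome <- data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                        eaf = eaf, beta = beta_out, se = se_out,
                        pval = pval_from_beta_se(beta_out, se_out),
                        n = config$n_out, stringsAsFactors = FALSE)
  scrambled <- rep(FALSE, m)
  if (config$allele_scramble) {
    scrambled <- stats::runif(m) < 0.5
    outcome$effect_allele[scrambled] <- oa[scrambled]
    outcome$other_allele[scrambled] <- ea[scrambled]
    outcome$eaf[scrambled] <- 1 - outcome$eaf[scrambled]
    outcome$beta[scrambled] <- -outcome$beta[scrambled]
  }
  list(instrument = instrument, outcome = outcome,
       truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                    valid = valid, scrambled = scrambled, eaf = eaf,
                    seed = config$seed))
}

#' Configuration for the cohort generator
#'
#' Defaults emulate the replication cohort of the source analysis: ages
#' 40-69, 46% male, median eGFR near 92.5 mL/min/1.73 m^2 (log-normal
#' phenotype), 10 genetic principal components, genotyping batches, the
#' comorbidity flags used by the clinical sensitivity model, and the
#' missingness rates implied by that cohort's reported analysis-set sizes
#' (about 4.7% of individuals without creatinine-based eGFR and 1.2% without
#' complete comorbidity information).
#'
#' @param n_individuals cohort size.
#' @param instrument an [instrument_set()] supplying rsids, effect alleles,
#'   frequencies and per-SD weights (default: packaged homocysteine set).
#' @param theta causal effect of the exposure on log eGFR per SD exposure.
#' @param confounder_effect_exposure,confounder_effect_outcome loadings of a
#'   shared standard-normal confounder; nonzero values make the naive
#'   exposure-outcome regression biased while the genetic analysis stays
#'   consistent.
#' @param egfr_log_mean,egfr_log_sd location/scale of log eGFR.
#' @param age_range,male_fraction,n_batches,n_pcs covariate model.
#' @param comorbidity_prev named prevalences for hypertension, diabetes,
#'   obesity.
#' @param missing_egfr,missing_clinical missingness rates.
#' @param seed mandatory integer seed.
#' @return validated config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_individuals = 20000L,
                              instrument = mr_instruments("homocysteine"),
                              theta = -0.0095,
                              confounder_effect_exposure = 0.3,
                              confounder_effect_outcome = 0.05,
                              egfr_log_mean = log(92.5), egfr_log_sd = 0.16,
                              age_range = c(40L, 69L), male_fraction = 0.46,
                              n_batches = 8L, n_pcs = 10L,
                              comorbidity_prev = c(hypertension = 0.27,
                                                   diabetes = 0.05,
                                                   obesity = 0.24),
                              missing_egfr = 0.047,
                              missing_clinical = 0.012, seed) {
  if (missing(seed)) stop_mrkit("seed is mandatory", "mrkit_config_error")
  cfg <- list(n_individuals = as.integer(n_individuals),
              instrument = instrument, theta = theta,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_outcome = confounder_effect_outcome,
              egfr_log_mean = egfr_log_mean, egfr_log_sd = egfr_log_sd,
              age_range = age_range, male_fraction = male_fraction,
              n_batches = as.integer(n_batches), n_pcs = as.integer(n_pcs),
              comorbidity_prev = comorbidity_prev,
              missing_egfr = missing_egfr, missing_clinical = missing_clinical,
              seed = as.integer(seed))
  probs <- c(cfg$male_fraction, cfg$comorbidity_prev, cfg$missing_egfr,
             cfg$missing_clinical)
  if (cfg$n_individuals < 10L || any(probs < 0 | probs > 1) ||
      cfg$egfr_log_sd <= 0)
    stop_mrkit("invalid cohort simulation config", "mrkit_config_error")
  genet_var <- sum(cfg$instrument$beta^2)
  if (genet_var + cfg$confounder_effect_exposure^2 >= 1)
    stop_mrkit("genetic plus confounder variance of the exposure exceeds 1",
               "mrkit_config_error")
  structure(cfg, class = c("cohort_sim_config", "list"))
}

#' Simulate an individual-level cohort with genotypes, eGFR and covariates
#'
#' Genotypes `G_ij ~ Binomial(2, eaf_j)` counting the instrument's effect
#' allele. The latent exposure (SD units) is the standardized-genotype sum
#' `sum_j gamma_j (G_ij - 2 eaf_j) / sqrt(2 eaf_j (1 - eaf_j))` plus a shared
#' confounder and residual noise scaled to unit total variance; log eGFR is
#' `egfr_log_mean + theta * exposure + confounder load + noise`. Serum
#' creatinine is back-derived with [creatinine_from_egfr()], so recomputing
#' eGFR from creatinine, age and sex reproduces the phenotype exactly.
#' Missingness is applied to creatinine/eGFR and (jointly) to the three
#' comorbidity flags.
#'
#' @param config a [cohort_sim_config()].
#' @return list: `cohort` (a [cohort_data()]) and `truth` (theta, latent
#'   exposure, confounder, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(derive_seed(config$seed, "simulate_cohort"))
  n <- config$n_individuals
  ins <- config$instrument
  m <- nrow(ins)
  G <- matrix(stats::rbinom(n * m, 2L, rep(ins$eaf, each = n)), nrow = n)
  Gs <- sweep(G, 2, 2 * ins$eaf)
  Gs <- sweep(Gs, 2, sqrt(2 * ins$eaf * (1 - ins$eaf)), "/")
  U <- stats::rnorm(n)
  genet <- as.vector(Gs %*% ins$beta)
  resid_sd <- sqrt(1 - sum(ins$beta^2) - config$confounder_effect_exposure^2)
  exposure <- genet + config$confounder_effect_exposure * U +
    stats::rnorm(n, 0, resid_sd)
  log_egfr <- config$egfr_log_mean + config$theta * exposure +
    config$confounder_effect_outcome * U +
    stats::rnorm(n, 0, config$egfr_log_sd)
  egfr <- exp(log_egfr)

  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  sex <- stats::rbinom(n, 1L, config$male_fraction)
  batch <- sample.int(config$n_batches, n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), nrow = n,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))
  com <- vapply(config$comorbidity_prev,
                function(p) stats::rbinom(n, 1L, p), integer(n))
  creat <- creatinine_from_egfr(egfr, age, sex)

  miss_e <- stats::runif(n) < config$missing_egfr
  egfr[miss_e] <- NA_real_
  creat[miss_e] <- NA_real_
  miss_c <- stats::runif(n) < config$missing_clinical
  com[miss_c, ] <- NA_integer_

  cohort <- cohort_data(
    dosages = G,
    snp_meta = data.frame(rsid = ins$rsid, effect_allele = ins$effect_allele,
                          eaf = ins$eaf, stringsAsFactors = FALSE),
    phenotype = data.frame(sample_id = sprintf("id%06d", seq_len(n)),
                           creatinine = creat, egfr = egfr,
                           stringsAsFactors = FALSE),
    covariates = cbind(data.frame(age = age, sex = sex, batch = batch),
                       as.data.frame(pcs), as.data.frame(com)))
  list(cohort = cohort,
       truth = list(theta = config$theta, exposure = exposure, confounder = U,
                    seed = config$seed))
}

#' Simulate an outcome-GWAS table covering given instruments
#'
#' Convenience generator for pipeline runs: produces one outcome record per
#' instrument variant (across one or several instrument sets) under
#' per-exposure causal effects, with SEs from the outcome sample size and
#' optional withholding of rsids to emulate non-overlap between GWAS panels.
#'
#' @param instruments named list of [instrument_set()]s (names are exposure
#'   labels) or a single set.
#' @param theta named vector of causal effects per exposure (log-outcome per
#'   SD), recycled if length 1.
#' @param n_out outcome GWAS sample size.
#' @param outcome_sd phenotypic SD of the outcome trait (log-eGFR scale,
#'   default 0.2); see [summary_sim_config()].
#' @param withhold rsids to leave out of the outcome table.
#' @param seed integer seed.
#' @return canonical variant-association data frame for the outcome trait.
#' @export
simulate_outcome <- function(instruments, theta, n_out = 567460L,
                             outcome_sd = 0.2, withhold = character(0),
                             seed) {
  if (missing(seed)) stop_mrkit("seed is mandatory", "mrkit_config_error")
  if (inherits(instruments, "instrument_set"))
    instruments <- stats::setNames(list(instruments),
                                   attr(instruments, "exposure_name"))
  if (length(theta) == 1L && is.null(names(theta)))
    theta <- stats::setNames(rep(theta, length(instruments)), names(instruments))
  set.seed(derive_seed(seed, "simulate_outcome"))
  # a variant shared by two instruments can be tabulated on opposite effect
  # alleles (e.g. the MTHFR variant: homocysteine-raising allele = folate-
  # lowering allele); record both so the outcome's allele pair lets every
  # exposure harmonize, by flip where needed
  all_ins <- do.call(rbind, lapply(instruments, function(x)
    as.data.frame(x)[, c("rsid", "effect_allele", "other_allele")]))
  second_allele <- function(rsid, ea, oa) {
    if (!is.na(oa)) return(oa)
    others <- setdiff(all_ins$effect_allele[all_ins$rsid == rsid], ea)
    if (length(others) > 0L) return(others[1])
    # avoid creating a palindromic pair
    setdiff(c("A", "C", "G", "T"), c(ea, chartr("ACGT", "TGCA", ea)))[1]
  }
  rows <- list()
  for (nm in names(instruments)) {
    ins <- instruments[[nm]]
    new <- !ins$rsid %in% unlist(lapply(rows, `[[`, "rsid"))
    ins <- ins[new, , drop = FALSE]
    if (nrow(ins) == 0L) next
    se_out <- outcome_sd / sqrt(2 * ins$eaf * (1 - ins$eaf) * n_out)
    beta_out <- theta[[nm]] * ins$beta + stats::rnorm(nrow(ins), 0, se_out)
    oa <- vapply(seq_len(nrow(ins)), function(i)
      second_allele(ins$rsid[i], ins$effect_allele[i], ins$other_allele[i]),
      character(1))
    rows[[nm]] <- data.frame(rsid = ins$rsid,
                             effect_allele = ins$effect_allele,
                             other_allele = oa, eaf = ins$eaf,
                             beta = beta_out, se = se_out,
                             pval = pval_from_beta_se(beta_out, se_out),
                             n = n_out, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!out$rsid %in% withhold, , drop = FALSE]
}
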