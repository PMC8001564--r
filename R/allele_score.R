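#' Construct an individual-level cohort object
#'
#' @param dosages numeric matrix, individuals by variants, values in
#'   \[0, 2\]; columns named by rsid.
#' @param snp_meta data frame with `rsid`, `effect_allele` (the allele the
#'   dosage counts) and `eaf`, one row per dosage column.
#' @param phenotype data frame with `sample_id` and any of `egfr`
#'   (mL/min/1.73 m^2) and `creatinine` (mg/dL); missing values are `NA`,
#'   never sentinel numbers.
#' @param covariates data frame with `age` (years), `sex` (1 = male,
#'   0 = female), `batch` (categorical), `pc1`..`pc10`, and the binary
#'   comorbidity flags `hypertension`, `diabetes`, `obesity`.
#' @return object of class `cohort_data`.
#' @export
cohort_data <- function(dosages, snp_meta, phenotype, covariates) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(snp_meta) == ncol(dosages),
            nrow(phenotype) == nrow(dosages),
            nrow(covariates) == nrow(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_mrkit("dosage values must lie in [0, 2]", "mrkit_data_error")
  colnames(dosages) <- snp_meta$rsid
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 phenotype = phenotype, covariates = covariates),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals x %d variants; eGFR available for %d\n",
              nrow(x$dosages), ncol(x$dosages), sum(!is.na(x$phenotype$egfr))))
  invisible(x)
}

#' Weighted allele score from a dosage matrix
#'
#' Per-individual weighted sum of effect-allele dosages, weights being the
#' instrument's per-SD exposure effects: `score_i = sum_j dosage_ij beta_j`.
#' A cohort column whose counted allele differs from the instrument's effect
#' allele is flip-corrected (`2 - dosage`). With `standardize` the score is
#' centered and scaled to unit SD, the convention under which downstream
#' regression coefficients read "per 1 SD of allele score" — and under which
#' rescaling all instrument betas by a positive constant leaves results
#' unchanged.
#'
#' @param cohort a [cohort_data()] object.
#' @param instrument an [instrument_set()].
#' @param standardize center/scale the score (default `TRUE`).
#' @param missing_snp `"error"` (default) or `"drop"` instrument variants
#'   absent from the cohort (dropped variants are recorded in the
#'   `"dropped"` attribute).
#' @return numeric score vector, one value per individual.
#' @export
allele_score <- function(cohort, instrument, standardize = TRUE,
                         missing_snp = c("error", "drop")) {
  missing_snp <- match.arg(missing_snp)
  stopifnot(inherits(cohort, "cohort_data"))
  idx <- match(instrument$rsid, cohort$snp_meta$rsid)
  absent <- instrument$rsid[is.na(idx)]
  if (length(absent) > 0L) {
    if (missing_snp == "error")
      stop_mrkit(paste0("instrument variant(s) absent from cohort: ",
                        paste(absent, collapse = ", ")), "mrkit_config_error")
    instrument <- instrument[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  d <- cohort$dosages[, idx, drop = FALSE]
  flip <- cohort$snp_meta$effect_allele[idx] != instrument$effect_allele
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  score <- as.vector(d %*% instrument$beta)
  if (standardize) {
    s <- stats::sd(score, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_mrkit("allele score has zero variance; cannot standardize",
                 "mrkit_domain_error")
    score <- (score - mean(score, na.rm = TRUE)) / s
  }
  attr(score, "dropped") <- absent
  score
}

#' CKD-EPI 2009 creatinine equation for estimated GFR
#'
#' `eGFR = 141 min(Scr/k, 1)^a max(Scr/k, 1)^-1.209 0.993^age (1.018 if
#' female)`, with `k = 0.7` (female) / `0.9` (male) and `a = -0.329` /
#' `-0.411`. The race coefficient is omitted by default (current reporting
#' convention); `race_coefficient = TRUE` multiplies by the original 1.159
#' term for strict replication of historical analyses.
#'
#' @param creatinine serum creatinine, mg/dL (> 0).
#' @param age years (> 0).
#' @param sex 1/`"male"` or 0/`"female"`.
#' @param race_coefficient apply the 2009 race term (default `FALSE`).
#' @return eGFR in mL/min/1.73 m^2. Vectorized; `NA`s propagate.
#' @export
egfr_ckd_epi <- function(creatinine, age, sex, race_coefficient = FALSE) {
  female <- !as_male(sex)
  ok <- is.na(creatinine) | creatinine > 0
  if (!all(ok, is.na(age) | age > 0))
    stop_mrkit("creatinine and age must be positive", "mrkit_domain_error")
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  scr_k <- creatinine / kappa
  egfr <- 141 * pmin(scr_k, 1)^alpha * pmax(scr_k, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
  if (race_coefficient) egfr <- egfr * 1.159
  egfr
}

#' Invert the CKD-EPI equation for serum creatinine
#'
#' Solves [egfr_ckd_epi()] for creatinine given eGFR, age and sex — used by
#' the cohort simulator so that recomputing eGFR from simulated creatinine
#' reproduces the simulated phenotype exactly. The equation is strictly
#' decreasing in creatinine, so the inverse is unique.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (> 0).
#' @param age,sex as in [egfr_ckd_epi()].
#' @return creatinine, mg/dL.
#' @export
creatinine_from_egfr <- function(egfr, age, sex) {
  female <- !as_male(sex)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  g <- egfr / (141 * 0.993^age * ifelse(female, 1.018, 1))
  # g > 1: below the knot (Scr < kappa), governed by the alpha branch
  ifelse(g > 1, kappa * g^(1 / alpha), kappa * g^(-1 / 1.209))
}

as_male <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    tolower(as.character(sex)) %in% c("male", "m", "1")
  } else {
    as.numeric(sex) == 1
  }
}

#' Ordinary least squares with stable orthogonal decomposition
#'
#' Complete-case OLS via Householder QR, with SEs from the unbiased residual
#' variance estimator and two-sided t p-values on `n - k` degrees of freedom.
#' Rank deficiency is an error naming the offending columns rather than a
#' silent coefficient drop.
#'
#' @param response numeric response vector.
#' @param design numeric design matrix including the intercept column;
#'   columns should be named.
#' @return data frame `term`, `estimate`, `se`, `statistic`, `pval`, with
#'   attributes `n_used`, `sigma`, `df`.
#' @export
fit_linear <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  keep <- !is.na(response) & stats::complete.cases(design)
  y <- response[keep]
  X <- design[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X))
    stop_mrkit("fewer complete rows than design columns", "mrkit_data_error")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_mrkit(paste0("design is rank deficient; collinear column(s): ",
                      paste(drop_cols, collapse = ", ")),
               "mrkit_collinearity_error")
  }
  cf <- qr.coef(qx, y)
  res <- y - as.vector(X %*% cf)
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  R <- qr.R(qx)
  V <- chol2inv(R)
  piv <- qx$pivot
  V[piv, piv] <- V
  se <- sqrt(diag(V) * s2)
  tt <- cf / se
  out <- data.frame(term = colnames(X), estimate = unname(cf), se = se,
                    statistic = unname(tt),
                    pval = 2 * stats::pt(-abs(unname(tt)), df),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_used") <- length(y)
  attr(out, "sigma") <- sqrt(s2)
  attr(out, "df") <- df
  out
}

#' Allele-score Mendelian randomization on individual-level data
#'
#' Regresses eGFR on the standardized allele score plus covariates over
#' complete cases. The main model adjusts for age, sex, genotyping batch and
#' the first 10 genetic principal components; the clinical sensitivity model
#' additionally adjusts for hypertension, diabetes and obesity status. The
#' reported coefficient is the eGFR change (mL/min/1.73 m^2) per 1 SD
#' increase of the allele score.
#'
#' @param cohort a [cohort_data()]; if `egfr` is missing but creatinine is
#'   present, eGFR is computed with [egfr_ckd_epi()].
#' @param instrument an [instrument_set()].
#' @param model `"main"` or `"clinical_adjusted"`.
#' @param missing_snp passed to [allele_score()].
#' @return a `score_result` list: `exposure_name`, `model`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `n_used`, plus the full coefficient table
#'   as `fit`.
#' @export
score_mr <- function(cohort, instrument,
                     model = c("main", "clinical_adjusted"),
                     missing_snp = "error") {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "cohort_data"))
  egfr <- cohort$phenotype$egfr
  if (all(is.na(egfr))) {
    if (!is.null(cohort$phenotype$creatinine) &&
        any(!is.na(cohort$phenotype$creatinine))) {
      egfr <- egfr_ckd_epi(cohort$phenotype$creatinine,
                           cohort$covariates$age, cohort$covariates$sex)
    } else {
      stop_mrkit("no eGFR or creatinine available", "mrkit_empty_error")
    }
  }
  score <- allele_score(cohort, instrument, standardize = TRUE,
                        missing_snp = missing_snp)
  cv <- cohort$covariates
  pc_cols <- grep("^pc[0-9]+$", names(cv), value = TRUE)
  vars <- c("age", "sex", pc_cols)
  if (model == "clinical_adjusted") {
    clin <- c("hypertension", "diabetes", "obesity")
    miss <- setdiff(clin, names(cv))
    if (length(miss) > 0L)
      stop_mrkit(paste0("clinical_adjusted model needs columns: ",
                        paste(miss, collapse = ", ")), "mrkit_config_error")
    vars <- c(vars, clin)
  }
  miss <- setdiff(c("age", "sex", "batch"), names(cv))
  if (length(miss) > 0L)
    stop_mrkit(paste0("missing covariate column(s): ",
                      paste(miss, collapse = ", ")), "mrkit_config_error")
  dat <- cbind(data.frame(allele_score = score), cv[, vars, drop = FALSE],
               batch = factor(cv$batch))
  # keep NA rows here; fit_linear performs the complete-case restriction and
  # reports n_used
  mf <- stats::model.frame(~ ., data = dat, na.action = stats::na.pass)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_linear(egfr, X)
  b <- fit[fit$term == "allele_score", ]
  tq <- stats::qt(0.975, attr(fit, "df"))
  structure(list(exposure_name = attr(instrument, "exposure_name") %||% "custom",
                 model = model, beta = b$estimate, se = b$se,
                 ci_low = b$estimate - tq * b$se,
                 ci_high = b$estimate + tq * b$se,
                 pval = b$pval, n_used = attr(fit, "n_used"), fit = fit),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "Allele-score MR (%s, %s model): beta = %.4f eGFR per SD score, 95%% CI [%.4f, %.4f], p = %.3g, n = %d\n",
    x$exposure_name, x$model, x$beta, x$ci_low, x$ci_high, x$pval, x$n_used))
  invisible(x)
}

#' Write / read a cohort as plain text
#'
#' Dosages as a TSV matrix (individuals x variants, rsid header), SNP
#' metadata, phenotype and covariates as sidecar TSVs in `dir`.
#'
#' @param cohort a [cohort_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write_cohort`); a `cohort_data`
#'   (`read_cohort`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$dosages, file.path(dir, "dosages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (part in c("snp_meta", "phenotype", "covariates"))
    utils::write.table(cohort[[part]], file.path(dir, paste0(part, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE,
                                      check.names = FALSE)
  cohort_data(as.matrix(rd("dosages.tsv")), rd("snp_meta.tsv"),
              rd("phenotype.tsv"), rd("covariates.tsv"))
}
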