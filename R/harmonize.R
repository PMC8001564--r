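HARMONIZE_ACTIONS <- c("kept_as_is", "flipped", "dropped_palindromic",
                       "dropped_nonoverlap", "dropped_steiger")

is_palindromic_pair <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  !is.na(a1) & !is.na(a2) & (p == "A T" | p == "C G")
}

#' Align exposure and outcome summary statistics to a shared effect allele
#'
#' For each instrument variant, locates the outcome record with the same rsid
#' and re-expresses the outcome association on the exposure's effect allele:
#' matching effect alleles are kept as-is; when the outcome's effect allele is
#' the exposure's other allele the outcome beta is sign-flipped and its
#' frequency reflected (`1 - eaf`). Variants absent from the outcome (or with
#' irreconcilable alleles) are dropped as non-overlapping. Palindromic
#' variants (A/T or C/G), whose strand cannot be resolved from allele letters,
#' are handled per `palindromic_policy`: dropped, or oriented by comparing
#' allele frequencies — flipped when the two frequencies straddle 0.5, dropped
#' when either is within `eaf_tolerance` of 0.5 (frequency too uninformative).
#'
#' When the exposure records carry no other allele (effect-allele-only
#' instrument tables), matching is done against the outcome's two alleles
#' alone; a variant whose exposure effect allele matches neither outcome
#' allele cannot be disambiguated and is dropped as non-overlapping.
#'
#' @param exposure an [instrument_set()] (or canonical variant data frame).
#' @param outcome canonical variant-association data frame for the outcome
#'   trait, keyed by rsid; duplicate rsids among the instrument's variants
#'   are an error (multi-allelic meta-analysis dumps must be resolved
#'   upstream).
#' @param palindromic_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_tolerance half-width of the frequency band around 0.5 inside
#'   which a palindromic variant is considered unresolvable (default 0.08,
#'   i.e. drop when either frequency lies in \[0.42, 0.58\]).
#' @param outcome_name label for reporting.
#' @return a `harmonized_set`: list with `exposure_name`, `outcome_name`,
#'   `variants` (one row per instrument variant: exposure and outcome effects
#'   aligned to the exposure effect allele, plus an `action` column and a
#'   `keep` flag) and `audit` (per-SNP action log).
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("infer_by_eaf", "drop"),
                      eaf_tolerance = 0.08, outcome_name = "outcome") {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(eaf_tolerance >= 0, eaf_tolerance < 0.5)
  exposure_name <- attr(exposure, "exposure_name") %||% "exposure"
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)

  dup <- out_df$rsid[duplicated(out_df$rsid)]
  dup <- intersect(dup, exp_df$rsid)
  if (length(dup) > 0L)
    stop_mrkit(paste0("duplicate outcome records for rsid(s): ",
                      paste(unique(dup), collapse = ", ")),
               "mrkit_ambiguity_error")

  n <- nrow(exp_df)
  res <- data.frame(rsid = exp_df$rsid,
                    effect_allele = exp_df$effect_allele,
                    other_allele = exp_df$other_allele,
                    beta_exp = exp_df$beta, se_exp = exp_df$se,
                    eaf_exp = exp_df$eaf,
                    pval_exp = exp_df$pval, n_exp = exp_df$n,
                    beta_out = NA_real_, se_out = NA_real_,
                    eaf_out = NA_real_, pval_out = NA_real_, n_out = NA_real_,
                    action = NA_character_, note = "",
                    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    j <- match(res$rsid[i], out_df$rsid)
    if (is.na(j)) {
      res$action[i] <- "dropped_nonoverlap"
      res$note[i] <- "rsid absent from outcome"
      next
    }
    ea_x <- res$effect_allele[i]
    oa_x <- res$other_allele[i]
    ea_y <- out_df$effect_allele[j]
    oa_y <- out_df$other_allele[j]

    flip <- NA
    if (!is.na(ea_y) && ea_x == ea_y) {
      flip <- FALSE
      if (!is.na(oa_x) && !is.na(oa_y) && oa_x != oa_y) flip <- NA
    } else if (!is.na(oa_y) && ea_x == oa_y) {
      flip <- TRUE
      if (!is.na(oa_x) && !is.na(ea_y) && oa_x != ea_y) flip <- NA
    }
    if (is.na(flip)) {
      res$action[i] <- "dropped_nonoverlap"
      res$note[i] <- sprintf("alleles irreconcilable (exposure %s/%s vs outcome %s/%s)",
                             ea_x, oa_x %||% NA, ea_y, oa_y %||% NA)
      next
    }

    beta_out <- if (flip) -out_df$beta[j] else out_df$beta[j]
    eaf_out <- if (flip) 1 - out_df$eaf[j] else out_df$eaf[j]
    action <- if (flip) "flipped" else "kept_as_is"

    # palindromic pair: letters cannot resolve strand; use frequencies
    pal <- if (!is.na(oa_x)) is_palindromic_pair(ea_x, oa_x)
           else is_palindromic_pair(ea_y, oa_y)
    if (isTRUE(pal)) {
      if (palindromic_policy == "drop") {
        res$action[i] <- "dropped_palindromic"
        res$note[i] <- "palindromic variant (policy: drop)"
        next
      }
      near_half <- abs(res$eaf_exp[i] - 0.5) < eaf_tolerance ||
        abs(eaf_out - 0.5) < eaf_tolerance
      if (is.na(near_half) || near_half) {
        res$action[i] <- "dropped_palindromic"
        res$note[i] <- "palindromic variant with frequency near 0.5"
        next
      }
      if ((res$eaf_exp[i] - 0.5) * (eaf_out - 0.5) < 0) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
        action <- "flipped"
        res$note[i] <- "palindromic variant oriented by allele frequency"
      }
    }

    res$beta_out[i] <- beta_out
    res$se_out[i] <- out_df$se[j]
    res$eaf_out[i] <- eaf_out
    res$pval_out[i] <- out_df$pval[j]
    res$n_out[i] <- out_df$n[j]
    res$action[i] <- action
  }

  res$keep <- res$action %in% c("kept_as_is", "flipped")
  if (!any(res$keep))
    stop_mrkit("no overlapping variants between exposure and outcome",
               "mrkit_empty_error")
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 variants = res,
                 audit = res[, c("rsid", "action", "note")]),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s vs %s\n", x$exposure_name, x$outcome_name))
  print(table(x$variants$action))
  invisible(x)
}

#' Kept (analysis-ready) variants of a harmonized set
#'
#' @param hset a `harmonized_set`.
#' @return data frame of variants with `keep == TRUE`.
#' @export
kept_variants <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  hset$variants[hset$variants$keep, , drop = FALSE]
}

#' Trait variance explained by one variant
#'
#' Two interchangeable approximations used by Steiger directionality
#' filtering: `"t_statistic"` recovers the association z from the p-value
#' (log-space, underflow-safe) and computes `r2 = z^2 / (z^2 + n - 2)`;
#' `"af_beta"` uses the per-SD closed form `r2 = 2 eaf (1 - eaf) beta^2`,
#' which needs no sample size but assumes a standardized trait.
#'
#' @param pval,n association p-value and sample size (`t_statistic`).
#' @param eaf,beta effect-allele frequency and per-SD beta (`af_beta`).
#' @param method `"t_statistic"` or `"af_beta"`.
#' @return r-squared fraction in \[0, 1). Vectorized.
#' @export
variance_explained <- function(method = c("t_statistic", "af_beta"),
                               pval = NULL, n = NULL, eaf = NULL, beta = NULL) {
  method <- match.arg(method)
  if (method == "t_statistic") {
    if (is.null(pval) || is.null(n))
      stop_mrkit("t_statistic method needs pval and n", "mrkit_domain_error")
    if (any(!is.finite(n) | n <= 2))
      stop_mrkit("sample size must exceed 2", "mrkit_domain_error")
    t2 <- stats::qchisq(log(pval), df = 1, lower.tail = FALSE, log.p = TRUE)
    t2 / (t2 + n - 2)
  } else {
    if (is.null(eaf) || is.null(beta))
      stop_mrkit("af_beta method needs eaf and beta", "mrkit_domain_error")
    pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12)
  }
}

#' Steiger directionality filter
#'
#' Guards against reverse causation: a variant explaining more variance in
#' the outcome than in the exposure is more plausibly an outcome variant, and
#' is dropped (`action = "dropped_steiger"`). Ties are kept. The per-variant
#' r-squared values of both traits are recorded in the audit log. The result
#' does not depend on input order.
#'
#' @param hset a `harmonized_set`.
#' @param method r-squared method, see [variance_explained()].
#' @return the filtered `harmonized_set`, audit updated with `r2_exp`,
#'   `r2_out`.
#' @export
steiger_filter <- function(hset, method = c("t_statistic", "af_beta")) {
  method <- match.arg(method)
  stopifnot(inherits(hset, "harmonized_set"))
  v <- hset$variants
  r2_exp <- rep(NA_real_, nrow(v))
  r2_out <- rep(NA_real_, nrow(v))
  k <- which(v$keep)
  if (length(k) > 0L) {
    if (method == "t_statistic") {
      p_out <- ifelse(is.na(v$pval_out[k]),
                      pval_from_beta_se(v$beta_out[k], v$se_out[k]),
                      v$pval_out[k])
      r2_exp[k] <- variance_explained("t_statistic", pval = v$pval_exp[k], n = v$n_exp[k])
      r2_out[k] <- variance_explained("t_statistic", pval = p_out, n = v$n_out[k])
    } else {
      r2_exp[k] <- variance_explained("af_beta", eaf = v$eaf_exp[k], beta = v$beta_exp[k])
      r2_out[k] <- variance_explained("af_beta", eaf = v$eaf_out[k], beta = v$beta_out[k])
    }
    drop <- k[r2_out[k] > r2_exp[k]]
    if (length(drop) > 0L) {
      v$action[drop] <- "dropped_steiger"
      v$note[drop] <- "outcome r2 exceeds exposure r2"
      v$keep[drop] <- FALSE
    }
  }
  hset$variants <- v
  hset$audit <- cbind(v[, c("rsid", "action", "note")],
                      r2_exp = r2_exp, r2_out = r2_out)
  hset
}

#' Write the per-SNP harmonization audit log
#'
#' @param hset a `harmonized_set` (after [harmonize()] and optionally
#'   [steiger_filter()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(hset, path) {
  utils::write.table(hset$audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
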