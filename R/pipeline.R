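#' Run configuration for the two analysis arms
#'
#' @param exposures character vector of packaged exposure names, or a named
#'   list of [instrument_set()]s.
#' @param outcome outcome GWAS: a canonical variant data frame, a file path
#'   (read with [read_summary_stats()]), or `NULL` when only the cohort arm
#'   runs.
#' @param outcome_dialect dialect for file outcomes.
#' @param cohort a [cohort_data()] or a [cohort_sim_config()] (simulated at
#'   run time), or `NULL` when only the summary arm runs.
#' @param palindromic_policy,eaf_tolerance harmonization block, see
#'   [harmonize()].
#' @param steiger apply Steiger directionality filtering (default `TRUE`).
#' @param estimators an [mr_config()] block.
#' @param single_snp rsid reported additionally as a single-variant Wald
#'   ratio where present (default the MTHFR variant rs1801133, the
#'   biologically anchored instrument of the source analysis); `NULL`
#'   disables.
#' @param out_dir directory for report files, or `NULL` to skip writing.
#' @param seed root seed for every stochastic component.
#' @return `run_config` list.
#' @export
run_config <- function(exposures = c("homocysteine", "folate", "cobalamin"),
                       outcome = NULL, outcome_dialect = NULL, cohort = NULL,
                       palindromic_policy = "infer_by_eaf",
                       eaf_tolerance = 0.08, steiger = TRUE,
                       estimators = mr_config(seed = seed),
                       single_snp = "rs1801133", out_dir = NULL, seed = 1L) {
  structure(list(exposures = exposures, outcome = outcome,
                 outcome_dialect = outcome_dialect, cohort = cohort,
                 palindromic_policy = palindromic_policy,
                 eaf_tolerance = eaf_tolerance, steiger = steiger,
                 estimators = estimators, single_snp = single_snp,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = c("run_config", "list"))
}

resolve_instruments <- function(exposures) {
  if (is.list(exposures) && !is.data.frame(exposures)) return(exposures)
  stats::setNames(lapply(exposures, mr_instruments), exposures)
}

provenance <- function(config) {
  list(config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("mrkit")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Summary-level analysis arm
#'
#' For each exposure: load the instrument, harmonize against the outcome
#' GWAS, apply Steiger filtering, run the estimator suite
#' ([run_all_methods()]), percent-transform, and (optionally) the
#' single-variant Wald ratio. Per-exposure SNP attrition
#' (loaded / overlapping / post-Steiger) is recorded. An error in one
#' exposure is captured as a structured diagnostic and the remaining
#' exposures continue.
#'
#' @param config a [run_config()] with a resolvable `outcome`.
#' @return a `report_bundle`: `estimates` (table-shaped data frame across
#'   exposures and methods), `single_snp` (Wald-ratio rows), `attrition`,
#'   `audit`, `scatter` (per-SNP effects and fitted lines for plotting),
#'   `errors`, `provenance`.
#' @export
run_summary_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outcome <- config$outcome
  if (is.character(outcome))
    outcome <- read_summary_stats(outcome, dialect = config$outcome_dialect)
  if (is.null(outcome))
    stop_mrkit("summary arm needs an outcome source", "mrkit_config_error")
  instruments <- resolve_instruments(config$exposures)

  estimates <- list()
  singles <- list()
  attrition <- list()
  audit <- list()
  scatter <- list()
  errors <- list()
  for (nm in names(instruments)) {
    res <- tryCatch({
      ins <- instruments[[nm]]
      hset <- harmonize(ins, outcome,
                        palindromic_policy = config$palindromic_policy,
                        eaf_tolerance = config$eaf_tolerance,
                        outcome_name = "outcome")
      n_overlap <- sum(hset$variants$keep)
      if (config$steiger) hset <- steiger_filter(hset)
      n_post <- sum(hset$variants$keep)
      ests <- run_all_methods(hset, config$estimators)
      tab <- mr_table(ests, exposure = nm)
      att <- data.frame(exposure = nm, loaded = nrow(ins),
                        overlapping = n_overlap, post_steiger = n_post,
                        stringsAsFactors = FALSE)
      sct <- make_scatter(hset, ests, nm)
      sngl <- NULL
      if (!is.null(config$single_snp)) {
        kv <- kept_variants(hset)
        if (config$single_snp %in% kv$rsid) {
          wr <- transform_pct(wald_ratio(kv[kv$rsid == config$single_snp, ]))
          sngl <- cbind(rsid = config$single_snp,
                        mr_table(list(wr), exposure = nm))
        }
      }
      list(tab = tab, att = att, audit = cbind(exposure = nm, hset$audit),
           sct = sct, sngl = sngl)
    }, mrkit_error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- data.frame(exposure = nm,
                                 error = conditionMessage(res),
                                 class = class(res)[1],
                                 stringsAsFactors = FALSE)
      next
    }
    estimates[[nm]] <- res$tab
    attrition[[nm]] <- res$att
    audit[[nm]] <- res$audit
    scatter[[nm]] <- res$sct
    if (!is.null(res$sngl)) singles[[nm]] <- res$sngl
  }
  bundle <- structure(list(
    estimates = rbind_all(estimates), single_snp = rbind_all(singles),
    attrition = rbind_all(attrition), audit = rbind_all(audit),
    scatter = rbind_all(scatter), errors = rbind_all(errors),
    provenance = provenance(config)), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir, "summary")
  bundle
}

rbind_all <- function(x) {
  if (length(x) == 0L) return(NULL)
  out <- do.call(rbind, unname(x))
  rownames(out) <- NULL
  out
}

# per-SNP scatter export: exposure/outcome effects with SE bars and the
# fitted line of each estimator (slope through origin except Egger)
make_scatter <- function(hset, ests, exposure) {
  kv <- kept_variants(hset)
  pts <- data.frame(exposure = exposure, rsid = kv$rsid,
                    beta_exp = kv$beta_exp, se_exp = kv$se_exp,
                    beta_out = kv$beta_out, se_out = kv$se_out,
                    stringsAsFactors = FALSE)
  for (e in ests) {
    pts[[paste0("fit_", e$method)]] <-
      (e$intercept %||% 0) * sign(pts$beta_exp) + e$beta * pts$beta_exp
  }
  pts
}

#' Individual-level (allele-score) analysis arm
#'
#' For each exposure: build the standardized allele score and fit both the
#' main and the clinically adjusted linear models for eGFR ([score_mr()]).
#'
#' @param config a [run_config()] with a `cohort` (data or simulation
#'   config).
#' @return a `report_bundle` with `score_results` (one row per exposure and
#'   model), `errors` and `provenance`.
#' @export
run_cohort_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_sim_config")) cohort <- simulate_cohort(cohort)$cohort
  if (!inherits(cohort, "cohort_data"))
    stop_mrkit("cohort arm needs cohort data or a simulation config",
               "mrkit_config_error")
  instruments <- resolve_instruments(config$exposures)
  rows <- list()
  errors <- list()
  for (nm in names(instruments)) {
    for (model in c("main", "clinical_adjusted")) {
      res <- tryCatch(
        score_mr(cohort, instruments[[nm]], model = model,
                 missing_snp = "drop"),
        mrkit_error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(nm, model)]] <- data.frame(
          exposure = nm, model = model, error = conditionMessage(res),
          class = class(res)[1], stringsAsFactors = FALSE)
      } else {
        rows[[paste(nm, model)]] <- data.frame(
          exposure = nm, model = model, beta = res$beta, se = res$se,
          ci_low = res$ci_low, ci_high = res$ci_high, pval = res$pval,
          n_used = res$n_used, stringsAsFactors = FALSE)
      }
    }
  }
  bundle <- structure(list(score_results = rbind_all(rows),
                           errors = rbind_all(errors),
                           provenance = provenance(config)),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir, "cohort")
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("MR report bundle (config", x$provenance$config_hash,
      "seed", x$provenance$seed, ")\n")
  for (part in c("estimates", "single_snp", "score_results", "attrition")) {
    if (!is.null(x[[part]])) {
      cat("\n--", part, "--\n")
      print(x[[part]], digits = 4)
    }
  }
  if (!is.null(x$errors)) {
    cat("\n-- errors --\n")
    print(x$errors)
  }
  invisible(x)
}

#' Write a report bundle as TSV + JSON
#'
#' Every table is written as `<prefix>_<name>.tsv` and the whole bundle —
#' provenance (config hash, seed, package version) included — as
#' `<prefix>_report.json`.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, prefix = "mr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- Filter(is.data.frame, unclass(bundle))
  for (nm in names(tables)) {
    tab <- cbind(tables[[nm]], config_hash = bundle$provenance$config_hash,
                 seed = bundle$provenance$seed)
    utils::write.table(tab, file.path(dir, paste0(prefix, "_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(bundle),
                       file.path(dir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
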