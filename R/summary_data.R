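#' Canonical summary-statistics columns
#'
#' A variant association is one SNP's summary statistics for one trait:
#' `rsid`, `effect_allele`, `other_allele` (may be `NA`: some published
#' instrument tables print only the effect allele), `eaf` (effect-allele
#' frequency), `beta` (additive per-allele effect, in phenotype SD units for
#' SD-scaled instruments), `se`, `pval`, `n`.
#'
#' @format character vector of the canonical column names.
#' @export
SUMMARY_COLS <- c("rsid", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

# GWAS sample sizes of the source meta-analyses for each exposure.
EXPOSURE_N <- c(homocysteine = 44147L, folate = 37465L, cobalamin = 45576L)

#' Build a canonical variant-association table
#'
#' Coerces a data frame to the canonical column set, upper-cases alleles and
#' validates the per-row invariants (`eaf` in \[0,1\], `se > 0` when present,
#' `pval` in (0,1\], non-empty rsid).
#'
#' @param df data frame holding at least `rsid`, `effect_allele`, `eaf`,
#'   `beta`; remaining canonical columns are filled with `NA` when absent.
#' @param strict if `TRUE` (default) any invalid row is an error naming the
#'   offending rows; if `FALSE` invalid rows are dropped with a warning and
#'   recorded in the `"problems"` attribute.
#' @return data frame with columns [SUMMARY_COLS].
#' @export
as_variant_assoc <- function(df, strict = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("rsid", "effect_allele", "eaf", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_mrkit(paste0("missing mandatory column(s): ",
                      paste(miss, collapse = ", ")), "mrkit_config_error")
  }
  out <- data.frame(rsid = as.character(df$rsid),
                    effect_allele = toupper(as.character(df$effect_allele)),
                    other_allele = if ("other_allele" %in% names(df))
                      toupper(as.character(df$other_allele)) else NA_character_,
                    eaf = as.numeric(df$eaf),
                    beta = as.numeric(df$beta),
                    se = if ("se" %in% names(df)) as.numeric(df$se) else NA_real_,
                    pval = if ("pval" %in% names(df)) as.numeric(df$pval) else NA_real_,
                    n = if ("n" %in% names(df)) as.numeric(df$n) else NA_real_,
                    stringsAsFactors = FALSE)
  bad <- validate_variant_rows(out)
  if (length(bad) > 0L) {
    msg <- paste0("invalid summary-statistics row(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop_mrkit(msg, "mrkit_data_error")
    warning(msg, call. = FALSE)
    problems <- out[as.integer(sub(" .*$", "", bad)), , drop = FALSE]
    out <- out[-as.integer(sub(" .*$", "", bad)), , drop = FALSE]
    attr(out, "problems") <- problems
  }
  rownames(out) <- NULL
  out
}

# returns "row (reason)" strings, one per offending row
validate_variant_rows <- function(df) {
  reasons <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    why <- c(
      if (is.na(r$rsid) || !nzchar(r$rsid)) "empty rsid",
      if (!is.na(r$eaf) && (r$eaf < 0 || r$eaf > 1)) "eaf outside [0,1]",
      if (is.na(r$beta)) "beta not numeric",
      if (!is.na(r$se) && r$se <= 0) "se <= 0",
      if (!is.na(r$pval) && (r$pval <= 0 || r$pval > 1)) "pval outside (0,1]"
    )
    if (length(why) > 0L)
      reasons <- c(reasons, paste0(i, " (", paste(why, collapse = "; "), ")"))
  }
  reasons
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads tab- or comma-separated summary statistics (gzip-transparent) and
#' maps source column names to the canonical fields through a dialect.
#' Consortium dumps disagree on headers (e.g. CKDGen uses
#' `RSID/Allele1/Allele2/Freq1/Effect/StdErr/P-value/n`), so the dialect is a
#' named vector `c(canonical = "source_name", ...)`; canonical fields absent
#' from the dialect but present verbatim in the header are picked up as-is.
#'
#' @param path delimited text file with a header (may be `.gz`).
#' @param dialect named character vector mapping canonical names (see
#'   [SUMMARY_COLS]) to source column names, or a path to a YAML/JSON file
#'   holding such a map (see [read_dialect()]). `NULL` for canonical headers.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @param strict passed to [as_variant_assoc()]: fail on any malformed row.
#' @return canonical variant-association data frame.
#' @export
read_summary_stats <- function(path, dialect = NULL, sep = NULL, strict = TRUE) {
  if (!file.exists(path))
    stop_mrkit(paste0("no such file: ", path), "mrkit_config_error")
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
    dialect <- read_dialect(dialect)
  if (is.null(sep)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    header <- readLines(con, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    miss <- setdiff(dialect, names(raw))
    if (length(miss) > 0L)
      stop_mrkit(paste0("dialect names absent from header: ",
                        paste(miss, collapse = ", ")), "mrkit_config_error")
    for (canon in names(dialect)) names(raw)[names(raw) == dialect[[canon]]] <- canon
  }
  as_variant_assoc(raw, strict = strict)
}

#' Read a column-dialect map from YAML or JSON
#'
#' @param path `.yaml`/`.yml` (needs the yaml package) or `.json` file whose
#'   top level maps canonical field names to source column names.
#' @return named character vector.
#' @export
read_dialect <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_mrkit("yaml package required for YAML dialect files", "mrkit_config_error")
    unlist(yaml::read_yaml(path))
  } else {
    unlist(jsonlite::fromJSON(path))
  }
}

#' Write summary statistics in the canonical on-disk format
#'
#' Tab-separated with the canonical header; `.gz` paths are compressed.
#' `read_summary_stats(write_summary_stats(x))` is the identity on canonical
#' records.
#'
#' @param df canonical variant-association data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(df, path) {
  df <- df[, intersect(SUMMARY_COLS, names(df)), drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconstruct a standard error from an effect size and p-value
#'
#' Instrument tables often print the per-SD beta and p-value but no SE. Under
#' the normal approximation `se = |beta| / z`, with `z` the two-sided normal
#' quantile of the p-value. The quantile is computed through the chi-square
#' survival inverse on the log-probability scale, so p-values down to 1e-300
#' are handled without underflow. Reconstructed SEs inherit the rounding of
#' the printed betas and p-values.
#'
#' @param beta nonzero effect size.
#' @param pval p-value in (0,1).
#' @param two_sided is `pval` two-sided (default) or one-tailed?
#' @return standard error, same units as `beta`. Vectorized.
#' @export
se_from_beta_pval <- function(beta, pval, two_sided = TRUE) {
  if (any(!is.finite(pval) | pval <= 0 | pval >= 1))
    stop_mrkit("pval must lie strictly in (0, 1)", "mrkit_domain_error")
  if (any(!is.finite(beta) | beta == 0))
    stop_mrkit("beta must be nonzero (z has undefined scale)", "mrkit_domain_error")
  lp <- if (two_sided) log(pval) else pmin(log(2) + log(pval), log1p(-1e-16))
  z <- sqrt(stats::qchisq(lp, df = 1, lower.tail = FALSE, log.p = TRUE))
  abs(beta) / z
}

#' Two-sided p-value from beta and SE, underflow-safe
#'
#' Companion of [se_from_beta_pval()]; `log10` mode returns log10(p) computed
#' fully in log space for round-trip checks at extreme significance.
#'
#' @param beta,se effect and standard error.
#' @param log10 return log10 of the p-value instead of the p-value.
#' @return p-value (floored at the smallest positive double) or log10(p).
#' @export
pval_from_beta_se <- function(beta, se, log10 = FALSE) {
  lz <- stats::pnorm(abs(beta) / se, lower.tail = FALSE, log.p = TRUE) + log(2)
  if (log10) return(lz / log(10))
  pmax(exp(lz), .Machine$double.xmin)
}

#' Keep genome-wide significant variants
#'
#' @param variants canonical variant-association data frame.
#' @param threshold p-value threshold, default the conventional genome-wide
#'   `5e-8`.
#' @return subset with `pval < threshold`, input order preserved.
#' @export
filter_genome_wide <- function(variants, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  variants[!is.na(variants$pval) & variants$pval < threshold, , drop = FALSE]
}

#' Load a packaged genetic-instrument set
#'
#' Returns the packaged instrument table for one exposure: 18 SNPs for blood
#' total homocysteine, 3 for folate, 14 for cobalamin, each row holding the
#' published rsid, effect allele, effect-allele frequency, per-SD beta and
#' p-value. The source table prints no SEs and no other allele: SEs are
#' reconstructed with [se_from_beta_pval()] and `other_allele` is `NA`
#' (harmonization supports this effect-allele-only mode). The GWAS sample
#' size of the source meta-analysis is attached as `n`.
#'
#' @param exposure one of `"homocysteine"`, `"folate"`, `"cobalamin"`.
#' @return an `instrument_set`: a canonical variant data frame with
#'   attributes `exposure_name` and `sd_scaled = TRUE`.
#' @export
mr_instruments <- function(exposure) {
  if (!is.character(exposure) || length(exposure) != 1L ||
      !exposure %in% names(EXPOSURE_N))
    stop_mrkit(paste0("unknown exposure '", paste(exposure, collapse = ","),
                      "'; expected one of: ",
                      paste(names(EXPOSURE_N), collapse = ", ")),
               "mrkit_lookup_error")
  path <- system.file("extdata", "instruments.tsv", package = "mrkit",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(eaf = "character", beta = "character",
                                          pval = "character"))
  tab <- tab[tab$exposure == exposure, , drop = FALSE]
  df <- data.frame(rsid = tab$rsid,
                   effect_allele = tab$effect_allele,
                   other_allele = NA_character_,
                   eaf = as.numeric(tab$eaf),
                   beta = as.numeric(tab$beta),
                   se = NA_real_,
                   pval = as.numeric(tab$pval),
                   n = as.numeric(EXPOSURE_N[[exposure]]),
                   stringsAsFactors = FALSE)
  df$se <- se_from_beta_pval(df$beta, df$pval)
  instrument_set(df, exposure_name = exposure, sd_scaled = TRUE)
}

#' Construct an instrument set
#'
#' @param variants canonical variant-association data frame; rsids must be
#'   unique.
#' @param exposure_name label for the exposure trait.
#' @param sd_scaled are betas per SD of the exposure?
#' @param check_threshold if non-`NULL`, require every variant to pass this
#'   significance threshold.
#' @return `instrument_set` object (a data frame subclass).
#' @export
instrument_set <- function(variants, exposure_name = "custom",
                           sd_scaled = TRUE, check_threshold = NULL) {
  variants <- as_variant_assoc(variants)
  if (anyDuplicated(variants$rsid))
    stop_mrkit("duplicate rsids within an instrument set", "mrkit_data_error")
  if (!is.null(check_threshold) &&
      any(is.na(variants$pval) | variants$pval >= check_threshold))
    stop_mrkit("instrument contains sub-threshold variants", "mrkit_data_error")
  structure(variants, exposure_name = exposure_name, sd_scaled = sd_scaled,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Genetic instrument for %s: %d variant(s)%s\n",
              attr(x, "exposure_name"), nrow(x),
              if (isTRUE(attr(x, "sd_scaled"))) " (betas per SD of exposure)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Shared rsids between two instrument sets
#'
#' Instruments for biomarkers on one metabolic pathway can share variants
#' (e.g. the MTHFR variant rs1801133 instruments both homocysteine and
#' folate).
#'
#' @param a,b instrument sets or canonical variant data frames.
#' @return lexicographically sorted character vector of shared rsids.
#' @export
instrument_overlap <- function(a, b) {
  sort(intersect(as.character(a$rsid), as.character(b$rsid)))
}
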