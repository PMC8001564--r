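#' Construct an MR causal-effect estimate
#'
#' Container for one method's result: point estimate on the log-outcome scale
#' per SD of exposure, SE, 95% CI, p-value, and method-specific diagnostics
#' (Egger intercept; contamination-mixture confidence segments).
#'
#' @param method method label.
#' @param beta,se estimate and standard error (se may be `NA` for the
#'   contamination mixture, whose uncertainty is the likelihood-based
#'   confidence set).
#' @param pval two-sided p-value.
#' @param n_snps number of variants used.
#' @param ci_low,ci_high 95% confidence limits.
#' @param intercept,intercept_se,intercept_pval Egger intercept diagnostics.
#' @param ci_segments list of `c(low, high)` intervals (contamination mixture
#'   can return a non-contiguous confidence set).
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, pval, n_snps,
                        ci_low = beta - stats::qnorm(0.975) * se,
                        ci_high = beta + stats::qnorm(0.975) * se,
                        intercept = NULL, intercept_se = NULL,
                        intercept_pval = NULL, ci_segments = NULL) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snps = n_snps, intercept = intercept,
                 intercept_se = intercept_se, intercept_pval = intercept_pval,
                 ci_segments = ci_segments %||% list(c(ci_low, ci_high)),
                 pct_beta = NULL, pct_ci = NULL, pct_segments = NULL),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.*g, 95%% CI [%.*g, %.*g], p = %.3g\n",
              x$method, x$n_snps, digits, x$beta, digits, x$ci_low,
              digits, x$ci_high, x$pval))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.*g (SE %.*g), p = %.3g\n", digits,
                x$intercept, digits, x$intercept_se, x$intercept_pval))
  if (!is.null(x$pct_beta))
    cat(sprintf("  eGFR change: %.2f%% [%.2f%%, %.2f%%]\n",
                x$pct_beta, x$pct_ci[1], x$pct_ci[2]))
  invisible(x)
}

# per-variant ratio ingredients from the kept rows of a harmonized set
ratio_components <- function(hset) {
  hv <- if (inherits(hset, "harmonized_set")) kept_variants(hset) else hset
  if (nrow(hv) == 0L)
    stop_mrkit("no variants retained for estimation", "mrkit_empty_error")
  if (any(hv$beta_exp == 0))
    stop_mrkit("degenerate instrument: zero exposure effect", "mrkit_domain_error")
  hv
}

#' Single-variant Wald ratio
#'
#' Ratio of the variant's outcome effect to its exposure effect, the causal
#' estimate from a single instrument. First-order delta-method SE
#' `se_out / |beta_exp|` (uncertainty of the exposure effect is ignored,
#' appropriate for strong instruments); a second-order SE incorporating
#' `se_exp` is available behind `second_order`.
#'
#' @param hv one harmonized variant (single row), or a `harmonized_set` with
#'   exactly one kept variant.
#' @param second_order add the second-order delta term
#'   `theta^2 se_exp^2 / beta_exp^2` to the variance.
#' @return an `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(hv, second_order = FALSE) {
  hv <- ratio_components(hv)
  if (nrow(hv) != 1L)
    stop_mrkit("wald_ratio expects exactly one variant", "mrkit_domain_error")
  theta <- hv$beta_out / hv$beta_exp
  se <- hv$se_out / abs(hv$beta_exp)
  if (second_order)
    se <- sqrt(se^2 + theta^2 * hv$se_exp^2 / hv$beta_exp^2)
  est <- mr_estimate("wald_ratio", theta, se,
                     pval = 2 * stats::pnorm(-abs(theta / se)), n_snps = 1L)
  est$rsid <- hv$rsid
  est
}

#' Per-variant Wald ratios with inverse-variance weights
#'
#' @param hset harmonized set or kept-variant data frame.
#' @return data frame `rsid`, `theta`, `se_theta`, `weight`
#'   (`weight = se_theta^-2`).
#' @export
ratio_table <- function(hset) {
  hv <- ratio_components(hset)
  se_theta <- hv$se_out / abs(hv$beta_exp)
  data.frame(rsid = hv$rsid, theta = hv$beta_out / hv$beta_exp,
             se_theta = se_theta, weight = se_theta^-2,
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance weighted estimator
#'
#' The conventional main MR estimator: equivalent to zero-intercept weighted
#' least squares of the outcome effects on the exposure effects with weights
#' `se_out^-2`, i.e. the precision-weighted mean of the per-variant Wald
#' ratios. Assumes all instruments are valid and share one causal effect.
#'
#' @param hset harmonized (and typically Steiger-filtered) set.
#' @return an `mr_estimate` with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(hset) {
  hv <- ratio_components(hset)
  w <- hv$se_out^-2
  denom <- sum(hv$beta_exp^2 * w)
  beta <- sum(hv$beta_exp * hv$beta_out * w) / denom
  se <- denom^-0.5
  mr_estimate("ivw_fixed", beta, se,
              pval = 2 * stats::pnorm(-abs(beta / se)), n_snps = nrow(hv))
}

# weighted least squares of y on x with intercept; closed form
wls_fit <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

# parametric bootstrap draws: m x n_boot matrices resampling each effect from
# Normal(estimate, se)
boot_draws <- function(hv, n_boot, seed) {
  set.seed(seed)
  m <- nrow(hv)
  list(bx = matrix(stats::rnorm(m * n_boot, hv$beta_exp, hv$se_exp), m),
       by = matrix(stats::rnorm(m * n_boot, hv$beta_out, hv$se_out), m))
}

#' MR-Egger regression with bootstrapped standard errors
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `se_out^-2`). The slope is a pleiotropy-robust causal
#' estimate under the InSIDE assumption; a nonzero intercept is the formal
#' test for directional pleiotropy. Egger regression is not invariant to
#' allele coding, so each variant is first re-expressed to a positive
#' exposure effect. Standard errors come from a parametric bootstrap: each
#' replicate redraws every `beta_exp` and `beta_out` from
#' `Normal(estimate, se)`, re-orients, and refits; the SE is the standard
#' deviation of the replicate estimates and p-values are two-sided normal.
#'
#' @param hset harmonized set with at least 3 kept variants.
#' @param n_boot bootstrap replicates (default 1000; fewer than 100 triggers
#'   a warning).
#' @param seed integer seed for the bootstrap (mandatory for reproducibility).
#' @return an `mr_estimate` with method `"egger"` and intercept diagnostics.
#' @export
egger <- function(hset, n_boot = 1000L, seed = 1L) {
  hv <- ratio_components(hset)
  if (nrow(hv) < 3L)
    stop_mrkit("MR-Egger needs at least 3 variants", "mrkit_insufficient_error")
  if (n_boot < 100L) warning("n_boot < 100: bootstrap SEs will be noisy")
  s <- sign(hv$beta_exp)
  x <- hv$beta_exp * s
  y <- hv$beta_out * s
  w <- hv$se_out^-2
  pt <- wls_fit(x, y, w)

  d <- boot_draws(hv, n_boot, seed)
  sb <- sign(d$bx)
  sb[sb == 0] <- 1
  bx <- d$bx * sb
  by <- d$by * sb
  sw <- sum(w)
  mx <- colSums(w * bx) / sw
  my <- colSums(w * by) / sw
  cx <- sweep(bx, 2, mx)
  cy <- sweep(by, 2, my)
  slope_b <- colSums(w * cx * cy) / colSums(w * cx^2)
  int_b <- my - slope_b * mx
  se_slope <- stats::sd(slope_b)
  se_int <- stats::sd(int_b)

  mr_estimate("egger", pt[["slope"]], se_slope,
              pval = 2 * stats::pnorm(-abs(pt[["slope"]] / se_slope)),
              n_snps = nrow(hv),
              intercept = pt[["intercept"]], intercept_se = se_int,
              intercept_pval = 2 * stats::pnorm(-abs(pt[["intercept"]] / se_int)))
}

# weighted median of theta via cumulative-weight interpolation
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

# heterogeneity penalization of ratio weights against a reference estimate
penalize_weights <- function(theta, w, ref, penalty_k) {
  q <- stats::pchisq(w * (theta - ref)^2, df = 1, lower.tail = FALSE)
  w * pmin(1, penalty_k * q)
}

#' (Penalized) weighted median estimator
#'
#' Robust estimator valid when up to half the instrument weight is invalid:
#' the weighted median of the per-variant Wald ratios, weights
#' `se_theta^-2`, located by cumulative-weight interpolation (sort the
#' ratios, take cumulative weight minus half the variant's own weight,
#' normalized, and interpolate the ratio at 0.5). Penalization downweights
#' heterogeneity outliers: each variant's contribution `Q_j = w_j (theta_j -
#' theta_WM)^2` against the unpenalized estimate is converted to an
#' upper-tail chi-square(1) probability `q_j` and the weight is replaced by
#' `w_j min(1, penalty_k q_j)` before re-taking the median. The SE is from
#' the same parametric bootstrap draws as [egger()], following the reference
#' convention for this estimator: each replicate redraws the per-variant
#' ratios and re-takes the median at the observed (penalized) weights.
#'
#' @param hset harmonized set with at least 3 kept variants.
#' @param penalized apply outlier penalization (default `TRUE`).
#' @param penalty_k penalty multiplier (default 20, the originating method's
#'   convention).
#' @param n_boot,seed bootstrap control as in [egger()].
#' @return an `mr_estimate` with method `"penalized_weighted_median"` or
#'   `"weighted_median"`.
#' @export
weighted_median <- function(hset, penalized = TRUE, penalty_k = 20,
                            n_boot = 1000L, seed = 1L) {
  hv <- ratio_components(hset)
  if (nrow(hv) < 3L)
    stop_mrkit("weighted median needs at least 3 variants",
               "mrkit_insufficient_error")
  if (n_boot < 100L) warning("n_boot < 100: bootstrap SEs will be noisy")

  rt <- ratio_table(hv)
  w <- rt$weight
  if (penalized) {
    ref <- weighted_median_point(rt$theta, w)
    w <- penalize_weights(rt$theta, w, ref, penalty_k)
  }
  beta <- weighted_median_point(rt$theta, w)

  d <- boot_draws(hv, n_boot, seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    weighted_median_point(d$by[, b] / d$bx[, b], w)
  }, numeric(1))
  se <- stats::sd(reps)
  mr_estimate(if (penalized) "penalized_weighted_median" else "weighted_median",
              beta, se, pval = 2 * stats::pnorm(-abs(beta / se)),
              n_snps = nrow(hv))
}

# profile log-likelihood of the contamination mixture on a grid of theta
conmix_profile <- function(theta_grid, theta_j, se_j, psi) {
  # grid x variant matrix of valid-model contributions
  dev <- outer(theta_grid, theta_j, "-")
  valid <- sweep(-dev^2 / (2 * rep(se_j^2, each = length(theta_grid))),
                 2, log(se_j), "-")
  inval <- matrix(-theta_j^2 / (2 * (se_j^2 + psi^2)) -
                    0.5 * log(se_j^2 + psi^2),
                  nrow = length(theta_grid), ncol = length(theta_j),
                  byrow = TRUE)
  rowSums(pmax(valid, inval))
}

#' Contamination mixture estimator
#'
#' Profile-likelihood estimator robust to invalid instruments: each variant's
#' ratio is modelled as either valid — normal around the causal effect with
#' its own SE — or invalid — normal around zero with extra dispersion `psi`.
#' For each candidate effect on a grid, every variant contributes the larger
#' of the two log-likelihoods; the estimate is the grid argmax and the
#' confidence set is the likelihood-ratio region `2(llmax - ll) <=
#' qchisq(1 - alpha, 1)`, reported as (possibly non-contiguous) segments.
#'
#' @param hset harmonized set with at least 2 kept variants.
#' @param psi dispersion of invalid-variant effects; `NULL` (default) uses
#'   the reference convention `1.5 * sd(ratio estimates)`.
#' @param grid_points grid resolution (default 5001) over
#'   `[min theta_j - 2 max se_theta, max theta_j + 2 max se_theta]`; if the
#'   argmax lands on a grid edge the range is widened and the search retried.
#' @param alpha confidence level complement (default 0.05).
#' @return an `mr_estimate` with method `"contamination_mixture"`;
#'   `ci_low`/`ci_high` are the envelope of the confidence set and
#'   `ci_segments` its maximal runs. The p-value is the likelihood-ratio test
#'   of `theta = 0`.
#' @export
contamination_mixture <- function(hset, psi = NULL, grid_points = 5001L,
                                  alpha = 0.05) {
  hv <- ratio_components(hset)
  if (nrow(hv) < 2L)
    stop_mrkit("contamination mixture needs at least 2 variants",
               "mrkit_insufficient_error")
  rt <- ratio_table(hv)
  if (is.null(psi)) {
    psi <- 1.5 * stats::sd(rt$theta)
    if (!is.finite(psi) || psi == 0) psi <- max(rt$se_theta)
  }
  if (psi <= 0) stop_mrkit("psi must be positive", "mrkit_domain_error")

  pad <- 2 * max(rt$se_theta)
  lo <- min(rt$theta) - pad
  hi <- max(rt$theta) + pad
  for (attempt in 1:5) {
    grid <- seq(lo, hi, length.out = grid_points)
    ll <- conmix_profile(grid, rt$theta, rt$se_theta, psi)
    imax <- which.max(ll)
    if (imax > 1L && imax < length(grid)) break
    span <- hi - lo
    lo <- lo - span
    hi <- hi + span
    if (attempt == 5L)
      stop_mrkit("contamination-mixture grid failed to bracket the maximum",
                 "mrkit_domain_error")
  }
  beta <- grid[imax]
  llmax <- ll[imax]
  inside <- 2 * (llmax - ll) <= stats::qchisq(1 - alpha, df = 1)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_idx <- which(r$values)
  segments <- lapply(seg_idx, function(k) c(grid[starts[k]], grid[ends[k]]))
  ll0 <- conmix_profile(0, rt$theta, rt$se_theta, psi)
  pval <- stats::pchisq(2 * (llmax - ll0), df = 1, lower.tail = FALSE)

  est <- mr_estimate("contamination_mixture", beta, NA_real_, pval,
                     n_snps = nrow(hv),
                     ci_low = min(vapply(segments, `[`, numeric(1), 1L)),
                     ci_high = max(vapply(segments, `[`, numeric(1), 2L)),
                     ci_segments = segments)
  est$psi <- psi
  est$grid_step <- grid[2] - grid[1]
  # variants better explained by the valid model at the estimate
  dev <- (rt$theta - beta)^2 / (2 * rt$se_theta^2) + log(rt$se_theta)
  inv <- rt$theta^2 / (2 * (rt$se_theta^2 + psi^2)) +
    0.5 * log(rt$se_theta^2 + psi^2)
  est$valid_variants <- rt$rsid[dev <= inv]
  est
}

#' Transform a log-scale estimate to percent change in the outcome
#'
#' Estimates are on the natural-log outcome scale per SD of exposure; for
#' reporting they are re-expressed as a percent change,
#' `100 (exp(beta) - 1)`, the exact transformation rather than the
#' small-effect `100 beta` approximation. The monotone map is applied to CI
#' endpoints (and each confidence segment), preserving coverage.
#'
#' @param est an `mr_estimate`.
#' @return the estimate with `pct_beta`, `pct_ci` and `pct_segments` filled.
#' @export
transform_pct <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  to_pct <- function(x) 100 * (exp(x) - 1)
  est$pct_beta <- to_pct(est$beta)
  est$pct_ci <- c(to_pct(est$ci_low), to_pct(est$ci_high))
  est$pct_segments <- lapply(est$ci_segments, to_pct)
  est
}

#' Estimator configuration block
#'
#' @param n_boot bootstrap replicates for Egger and weighted median.
#' @param seed root seed; per-estimator streams are derived with
#'   [derive_seed()].
#' @param penalty_k weighted-median penalty multiplier.
#' @param psi contamination-mixture dispersion (`NULL` = auto).
#' @param grid_points contamination-mixture grid resolution.
#' @param alpha confidence level complement.
#' @param fallback_wald with fewer than 3 variants, report the single-variant
#'   Wald ratio (or IVW) instead of erroring.
#' @return list of settings for [run_all_methods()].
#' @export
mr_config <- function(n_boot = 1000L, seed = 1L, penalty_k = 20, psi = NULL,
                      grid_points = 5001L, alpha = 0.05,
                      fallback_wald = FALSE) {
  list(n_boot = as.integer(n_boot), seed = as.integer(seed),
       penalty_k = penalty_k, psi = psi,
       grid_points = as.integer(grid_points), alpha = alpha,
       fallback_wald = isTRUE(fallback_wald))
}

#' Run the full summary-level estimator suite
#'
#' Applies, in reporting order, the fixed-effects IVW, MR-Egger (with
#' intercept test), penalized weighted median and contamination mixture to a
#' harmonized (and typically Steiger-filtered) set, and percent-transforms
#' every estimate. Deterministic given `config$seed`.
#'
#' @param hset harmonized set.
#' @param config an [mr_config()] list.
#' @return named list of `mr_estimate` objects
#'   (`ivw_fixed`, `egger`, `penalized_weighted_median`,
#'   `contamination_mixture`), or a single-element list `wald_ratio` when
#'   fewer than 3 variants remain and `fallback_wald` is set.
#' @export
run_all_methods <- function(hset, config = mr_config()) {
  hv <- kept_variants(hset)
  if (nrow(hv) < 3L) {
    if (!config$fallback_wald)
      stop_mrkit(sprintf("only %d variant(s) remain; Egger and median need 3",
                         nrow(hv)), "mrkit_insufficient_error")
    est <- if (nrow(hv) == 1L) wald_ratio(hset) else ivw_fixed(hset)
    return(stats::setNames(list(transform_pct(est)), est$method))
  }
  ests <- list(
    ivw_fixed = ivw_fixed(hset),
    egger = egger(hset, n_boot = config$n_boot,
                  seed = derive_seed(config$seed, "egger")),
    penalized_weighted_median = weighted_median(
      hset, penalized = TRUE, penalty_k = config$penalty_k,
      n_boot = config$n_boot, seed = derive_seed(config$seed, "wmedian")),
    contamination_mixture = contamination_mixture(
      hset, psi = config$psi, grid_points = config$grid_points,
      alpha = config$alpha)
  )
  lapply(ests, transform_pct)
}

#' Flatten a list of MR estimates to a reporting table
#'
#' @param ests named list of `mr_estimate` objects (e.g. from
#'   [run_all_methods()]).
#' @param exposure optional exposure label column.
#' @return data frame, one row per method, with log-scale and %-scale
#'   estimates, CIs, p-values and the Egger intercept p.
#' @export
mr_table <- function(ests, exposure = NA_character_) {
  rows <- lapply(ests, function(e) {
    data.frame(exposure = exposure, method = e$method, n_snps = e$n_snps,
               beta = e$beta, se = e$se %||% NA_real_,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               intercept_pval = e$intercept_pval %||% NA_real_,
               pct_beta = e$pct_beta %||% NA_real_,
               pct_low = if (is.null(e$pct_ci)) NA_real_ else e$pct_ci[1],
               pct_high = if (is.null(e$pct_ci)) NA_real_ else e$pct_ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
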