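# Build a harmonized_set directly from effect vectors, bypassing harmonize(),
# so estimator tests can inject exact inputs.
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      rsid = sprintf("rs%03d", seq_along(beta_exp)),
                      eaf_exp = rep(0.3, length(beta_exp)),
                      pval_exp = NA_real_, n_exp = NA_real_,
                      pval_out = NA_real_, n_out = NA_real_) {
  m <- length(beta_exp)
  v <- data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
                  beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf_exp,
                  pval_exp = rep_len(pval_exp, m), n_exp = rep_len(n_exp, m),
                  beta_out = beta_out, se_out = se_out,
                  eaf_out = eaf_exp, pval_out = rep_len(pval_out, m),
                  n_out = rep_len(n_out, m),
                  action = "kept_as_is", note = "", keep = TRUE,
                  stringsAsFactors = FALSE)
  structure(list(exposure_name = "test", outcome_name = "test",
                 variants = v, audit = v[, c("rsid", "action", "note")]),
            class = "harmonized_set")
}

# Random instrument/outcome effect sets for oracle-equivalence checks.
rand_hset <- function(m = 16, theta = -0.0095, seed = 1) {
  set.seed(seed)
  bx <- runif(m, 0.04, 0.16) * sample(c(-1, 1), m, replace = TRUE)
  sx <- runif(m, 0.004, 0.01)
  sy <- runif(m, 5e-4, 3e-3)
  by <- theta * bx + rnorm(m, 0, sy)
  make_hset(bx + rnorm(m, 0, sx), sx, by, sy)
}

# Independent weighted-median oracle: plain loop + manual interpolation,
# written without reference to the package implementation.
oracle_weighted_median <- function(theta, w) {
  idx <- sort.list(theta)
  th <- theta[idx]
  ww <- w[idx] / sum(w)
  cum <- 0
  pos <- numeric(length(th))
  for (i in seq_along(th)) {
    pos[i] <- cum + ww[i] / 2
    cum <- cum + ww[i]
  }
  if (0.5 <= pos[1]) return(th[1])
  if (0.5 >= pos[length(th)]) return(th[length(th)])
  i <- max(which(pos <= 0.5))
  th[i] + (th[i + 1] - th[i]) * (0.5 - pos[i]) / (pos[i + 1] - pos[i])
}
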