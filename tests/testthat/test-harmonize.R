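out_row <- function(rsid = "rsA", ea = "T", oa = "C", beta = 0.1, eaf = 0.3,
                    se = 0.01, pval = 0.001, n = 1e5) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

exp_row <- function(rsid = "rsA", ea = "T", oa = NA_character_, beta = 0.05,
                    eaf = 0.3, se = 0.005, pval = 1e-10, n = 44147) {
  instrument_set(out_row(rsid, ea, oa, beta, eaf, se, pval, n))
}

test_that("matching and flipped alleles are aligned correctly", {
  h <- harmonize(exp_row(ea = "T"), out_row(ea = "T", beta = 0.1))
  expect_equal(h$variants$action, "kept_as_is")
  expect_equal(h$variants$beta_out, 0.1)

  h <- harmonize(exp_row(ea = "T", oa = "C"),
                 out_row(ea = "C", oa = "T", beta = 0.1, eaf = 0.3))
  expect_equal(h$variants$action, "flipped")
  expect_equal(h$variants$beta_out, -0.1)
  expect_equal(h$variants$eaf_out, 0.7)

  # effect-allele-only instrument: flip resolved via the outcome's pair
  h <- harmonize(exp_row(ea = "T", oa = NA),
                 out_row(ea = "C", oa = "T", beta = 0.1, eaf = 0.3))
  expect_equal(h$variants$action, "flipped")
  expect_equal(h$variants$beta_out, -0.1)
})

test_that("nonoverlapping and allele-irreconcilable variants are dropped", {
  hcy <- mr_instruments("homocysteine")
  outcome <- simulate_outcome(hcy, theta = -0.0095, seed = 11,
                              withhold = c("rs12921383", "rs2851391"))
  h <- harmonize(hcy, outcome)
  expect_equal(sum(h$variants$keep), 16L)
  expect_equal(sum(h$variants$action == "dropped_nonoverlap"), 2L)
  expect_setequal(h$variants$rsid[!h$variants$keep],
                  c("rs12921383", "rs2851391"))
  # exposure effect allele matching neither outcome allele
  h <- harmonize(rbind(exp_row("rs1", "A"), exp_row("rs2", "A")),
                 rbind(out_row("rs1", "T", "C"), out_row("rs2", "A", "G")))
  expect_equal(h$variants$action,
               c("dropped_nonoverlap", "kept_as_is"))
})

test_that("ambiguous or empty overlaps are structured errors", {
  expect_error(harmonize(exp_row("rs1", "T"),
                         rbind(out_row("rs1"), out_row("rs1"))),
               class = "mrkit_ambiguity_error")
  expect_error(harmonize(exp_row("rs1", "T"), out_row("rs9", "T")),
               class = "mrkit_empty_error")
})

test_that("palindromic variants follow the configured policy", {
  pal_exp <- exp_row("rs1", "A", "T", eaf = 0.2)
  # frequencies concordant away from 0.5: kept on letter alignment
  h <- harmonize(pal_exp, out_row("rs1", "A", "T", eaf = 0.21, beta = 0.1))
  expect_equal(h$variants$action, "kept_as_is")
  expect_equal(h$variants$beta_out, 0.1)
  # frequencies straddle 0.5: orientation inferred, effect flipped
  h <- harmonize(pal_exp, out_row("rs1", "A", "T", eaf = 0.8, beta = 0.1))
  expect_equal(h$variants$action, "flipped")
  expect_equal(h$variants$beta_out, -0.1)
  expect_equal(h$variants$eaf_out, 0.2)
  # frequency near 0.5 is uninformative: dropped (needs a second variant to
  # avoid the empty-set error)
  two <- rbind(as.data.frame(pal_exp), as.data.frame(exp_row("rs2", "A", "G")))
  h <- harmonize(instrument_set(two),
                 rbind(out_row("rs1", "A", "T", eaf = 0.55),
                       out_row("rs2", "A", "G")))
  expect_equal(h$variants$action, c("dropped_palindromic", "kept_as_is"))
  # policy drop removes palindromic variants outright
  h <- harmonize(instrument_set(two),
                 rbind(out_row("rs1", "A", "T", eaf = 0.2),
                       out_row("rs2", "A", "G")),
                 palindromic_policy = "drop")
  expect_equal(h$variants$action[1], "dropped_palindromic")
})

test_that("flipping is an involution and preserves the effect product", {
  out <- out_row("rs1", "C", "T", beta = 0.1, eaf = 0.3)
  flip_rec <- function(r) {
    tmp <- r$effect_allele; r$effect_allele <- r$other_allele
    r$other_allele <- tmp; r$beta <- -r$beta; r$eaf <- 1 - r$eaf
    r
  }
  expect_equal(flip_rec(flip_rec(out)), out)
  expo <- exp_row("rs1", "T", "C", beta = 0.05)
  h1 <- harmonize(expo, out)
  h2 <- harmonize(expo, flip_rec(out))
  expect_equal(h1$variants$beta_out, h2$variants$beta_out)
  expect_equal(h1$variants$beta_exp * h1$variants$beta_out,
               h2$variants$beta_exp * h2$variants$beta_out)
})

test_that("harmonization restores scrambled non-palindromic effects exactly", {
  for (seed in 1:5) {
    cfg_s <- summary_sim_config(m_snps = 20, allele_scramble = TRUE,
                                seed = seed)
    sim <- simulate_summary(cfg_s)
    h <- harmonize(sim$instrument, sim$outcome)
    expect_true(all(h$variants$keep))
    # unscrambled truth: theta * gamma + alpha + noise as generated
    unscrambled <- sim$outcome
    sc <- sim$truth$scrambled
    unscrambled$beta[sc] <- -unscrambled$beta[sc]
    expect_equal(h$variants$beta_out, unscrambled$beta)
    expect_equal(h$variants$action, ifelse(sc, "flipped", "kept_as_is"))
  }
})

test_that("variance explained matches its closed forms", {
  expect_equal(variance_explained("af_beta", eaf = 0.5, beta = 0.1), 0.005)
  expect_equal(variance_explained("af_beta", eaf = 0.5, beta = 0), 0)
  z <- qnorm(0.025, lower.tail = FALSE)
  expect_equal(variance_explained("t_statistic", pval = 0.05, n = 1000),
               z^2 / (z^2 + 998), tolerance = 1e-10)
  expect_error(variance_explained("t_statistic", pval = 0.05, n = 2),
               class = "mrkit_domain_error")
  expect_error(variance_explained("t_statistic", pval = 0.05),
               class = "mrkit_domain_error")
})

test_that("Steiger filtering drops reverse-direction variants only", {
  fwd <- exp_row("rs1", "T", beta = 0.1583, pval = 1e-104, n = 44147)
  out_weak <- out_row("rs1", "T", beta = 0.001, pval = 0.2, n = 567460)
  h <- steiger_filter(harmonize(fwd, out_weak))
  expect_equal(h$variants$action, "kept_as_is")
  # swap the two traits' association strengths: same SNP now looks reverse
  rev <- exp_row("rs1", "T", beta = 0.001, pval = 0.2, n = 567460)
  out_strong <- out_row("rs1", "T", beta = 0.1583, pval = 1e-104, n = 44147)
  h <- steiger_filter(harmonize(rev, out_strong))
  expect_equal(h$variants$action, "dropped_steiger")
  expect_false(any(h$variants$keep))
  expect_true(h$audit$r2_out[1] > h$audit$r2_exp[1])
})

test_that("Steiger filtering is order-independent and no-drop sets pass through", {
  hcy <- mr_instruments("homocysteine")
  outcome <- simulate_outcome(hcy, theta = -0.0095, seed = 3)
  h <- harmonize(hcy, outcome)
  f1 <- steiger_filter(h)
  expect_equal(f1$variants[, c("rsid", "action", "keep")],
               h$variants[, c("rsid", "action", "keep")]) # nothing dropped
  perm <- sample(nrow(outcome))
  h2 <- steiger_filter(harmonize(hcy, outcome[perm, ]))
  expect_equal(f1$variants$action, h2$variants$action)
})
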