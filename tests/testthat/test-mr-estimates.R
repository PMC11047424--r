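test_that("harmonization keeps, flips and drops as the allele rules dictate", {
  ex <- make_records(c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.2, 0.3, 0.4, 0.5), se = 0.05,
                     effect_allele = c("A", "A", "A", "A"),
                     other_allele = c("G", "G", "T", "G"),
                     eaf = c(0.3, 0.3, 0.50, 0.3))
  oy <- make_records(c("rs1", "rs2", "rs3", "rs5"),
                     beta = c(0.10, 0.10, 0.10, 0.10), se = 0.02,
                     effect_allele = c("A", "G", "A", "A"),
                     other_allele = c("G", "A", "T", "G"),
                     eaf = c(0.3, 0.7, 0.50, 0.3))
  h <- harmonize(ex, oy)
  expect_identical(h$action[h$snp_id == "rs1"], "kept")
  expect_equal(h$beta_y[h$snp_id == "rs1"], 0.10)
  expect_identical(h$action[h$snp_id == "rs2"], "flipped")
  expect_equal(h$beta_y[h$snp_id == "rs2"], -0.10)
  expect_false("rs3" %in% h$snp_id)      # palindromic, eaf = 0.50
  log <- attr(h, "log")
  expect_identical(log$action[log$snp_id == "rs3"], "dropped_palindromic")
  expect_identical(log$action[log$snp_id == "rs4"], "dropped_unmatched")

  # palindromic with missing eaf also dropped; with extreme eaf kept
  ex2 <- make_records(c("rs6", "rs7"), beta = c(0.2, 0.2), se = 0.05,
                      effect_allele = "C", other_allele = "G",
                      eaf = c(NA, 0.10))
  oy2 <- make_records(c("rs6", "rs7"), beta = c(0.1, 0.1), se = 0.02,
                      effect_allele = "C", other_allele = "G",
                      eaf = c(0.2, 0.10))
  h2 <- harmonize(ex2, oy2)
  expect_identical(h2$snp_id, "rs7")

  # incompatible allele sets warn and drop
  ex3 <- make_records("rs8", beta = 0.2, se = 0.05,
                      effect_allele = "A", other_allele = "G")
  oy3 <- make_records("rs8", beta = 0.1, se = 0.02,
                      effect_allele = "A", other_allele = "C")
  expect_warning(h3 <- harmonize(ex3, oy3), "mismatch")
  expect_identical(nrow(h3), 0L)
})

test_that("harmonization is idempotent and orientation-invariant", {
  set.seed(31)
  b <- simulate_mr_study(m = 20, theta = 0.2, seed = 31)
  ex <- b$exposure_panel$records
  oy <- b$outcome_panel$records
  h1 <- harmonize(ex, oy)
  # re-harmonize the already-aligned pairs expressed as records
  ex2 <- ex[match(h1$snp_id, ex$snp_id), ]
  oy2 <- ex2
  oy2$beta <- h1$beta_y; oy2$se <- h1$se_y
  h2 <- harmonize(ex2, oy2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_true(all(h2$action == "kept"))

  # flip outcome orientation everywhere: estimates unchanged
  oy_flip <- oy
  oy_flip$effect_allele <- oy$other_allele
  oy_flip$other_allele <- oy$effect_allele
  oy_flip$beta <- -oy$beta
  oy_flip$eaf <- 1 - oy$eaf
  f1 <- mr_fit(harmonize(ex, oy))
  f2 <- mr_fit(harmonize(ex, oy_flip))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$se, f1$se, tolerance = 1e-12)
})

test_that("Wald ratio follows the delta-method formulas", {
  pair <- data.frame(snp_id = "rs1", beta_x = 0.5, se_x = 0.05,
                     beta_y = 0.1, se_y = 0.02)
  est <- wald_ratio(pair)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  expect_identical(est$method, "wald")

  null <- wald_ratio(data.frame(snp_id = "rs1", beta_x = 0.5, se_x = 0.05,
                                beta_y = 0, se_y = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(data.frame(snp_id = "rs1", beta_x = 0, se_x = 0.05,
                                     beta_y = 0.1, se_y = 0.02)), "beta_x")
})

test_that("first-order Wald SE matches Monte Carlo at high instrument strength", {
  # strong instrument: F = (0.5/0.02)^2 = 625
  set.seed(77)
  bx <- 0.5; sx <- 0.02; by <- 0.15; sy <- 0.03
  draws <- rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)
  est <- wald_ratio(data.frame(snp_id = "r", beta_x = bx, se_x = sx,
                               beta_y = by, se_y = sy))
  mc_sd <- sd(draws)
  # first-order se_y/|bx| understates slightly (ignores se_x); 5% agreement
  expect_equal(est$se, mc_sd, tolerance = 0.05)
})

test_that("IVW reduces to known closed forms", {
  # equal weights: arithmetic mean of the ratios
  p <- data.frame(snp_id = c("a", "b"), beta_x = c(0.5, 0.25),
                  se_x = 0.05, beta_y = c(0.10, 0.06),
                  se_y = c(0.02, 0.01))
  est <- ivw(p)
  ratios <- p$beta_y / p$beta_x
  expect_equal(est$beta, mean(ratios))   # se_j = 0.04 for both pairs
  expect_equal(est$se, sqrt(1 / (2 / 0.04^2)))

  # single valid pair after beta_x = 0 exclusion equals the Wald ratio
  p2 <- rbind(p[1, ], data.frame(snp_id = "c", beta_x = 0, se_x = 0.05,
                                 beta_y = 0.1, se_y = 0.02))
  expect_warning(est2 <- ivw(p2), "beta_x = 0")
  expect_equal(est2$beta, wald_ratio(p[1, ])$beta)
  expect_identical(est2$method, "wald")
  expect_error(suppressWarnings(ivw(p2[2, ])), "no usable")

  # n identical pairs: same point estimate, se shrinks by sqrt(n)
  one <- wald_ratio(p[1, ])
  for (n in c(2, 5, 9)) {
    many <- p[rep(1, n), ]
    many$snp_id <- sprintf("s%d", seq_len(n))
    est_n <- ivw(many)
    expect_equal(est_n$beta, one$beta)
    expect_equal(est_n$se, one$se / sqrt(n))
  }
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(12)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    p <- data.frame(snp_id = sprintf("s%d", 1:k),
                    beta_x = runif(k, 0.1, 0.6), se_x = 0.05,
                    beta_y = rnorm(k, 0.05, 0.03),
                    se_y = runif(k, 0.01, 0.05))
    est <- ivw(p)
    # independent oracle: WLS of beta_y on beta_x, no intercept, w = 1/se_y^2
    fit <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
    # fixed-effect IVW se equals the WLS se with dispersion forced to 1
    se_wls <- sqrt(1 / sum(p$beta_x^2 / p$se_y^2))
    expect_equal(est$se, se_wls, tolerance = 1e-12)
  }
})

test_that("OR/CI reporting matches the log-scale convention", {
  ci <- or_ci(0, 0.1)
  expect_equal(unname(ci["or"]), 1)
  expect_equal(ci[["ci_low"]] * ci[["ci_high"]], 1, tolerance = 1e-12)
  expect_equal(unname(or_ci(0.5, 0)), rep(exp(0.5), 3))
  # OR is the geometric mean of the bounds
  ci2 <- or_ci(-0.2433, 0.0468)
  expect_equal(sqrt(ci2[["ci_low"]] * ci2[["ci_high"]]), ci2[["or"]],
               tolerance = 1e-12)
  expect_equal(unname(round(ci2, 3)), c(0.784, 0.715, 0.859))
  # quantile constant used at 95%
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
})

test_that("Bonferroni thresholds reproduce the factorial corrections", {
  expect_equal(bonferroni_threshold(0.05, c(95, 13, 7)), 5.78e-6,
               tolerance = 5e-4)
  expect_equal(bonferroni_threshold(0.05, c(48, 7)), 1.49e-4,
               tolerance = 5e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, c(3, 0)), "positive")
  expect_error(bonferroni_threshold(0.05, integer(0)), "non-empty")
})

test_that("mr_fit recovers a known causal effect with a strong instrument", {
  hits <- 0
  for (k in 1:20) {
    b <- simulate_mr_study(theta = 0.3, seed = 400 + k)
    inst <- select_top_instrument(b$exposure_panel)
    inst <- filter_weak_instruments(inst)
    fit <- mr_fit(exposure = b$exposure_panel, outcome = b$outcome_panel,
                  instruments = inst)
    if (abs(fit$beta - 0.3) <= 3 * fit$se) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("mr_estimate methods expose the fit consistently", {
  b <- simulate_mr_study(theta = 0.3, seed = 7)
  fit <- mr_fit(exposure = b$exposure_panel, outcome = b$outcome_panel,
                instruments = select_top_instrument(b$exposure_panel))
  expect_s3_class(fit, "mr_estimate")
  expect_equal(unname(coef(fit)), fit$beta)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), log(c(fit$ci_low, fit$ci_high)),
               tolerance = 1e-10)
  expect_equal(unname(vcov(fit)[1, 1]), fit$se^2)
  s <- summary(fit)
  expect_equal(s$or, fit$or_value)
  expect_output(print(fit), "OR")
})
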