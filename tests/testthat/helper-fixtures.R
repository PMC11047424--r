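# Shared fixture builders: tiny panels, random LD matrices and independent
# oracles used across the suite.

make_records <- function(snp_id, beta, se, pval = NULL, pos = NULL,
                         eaf = 0.3, effect_allele = "A", other_allele = "G",
                         n = 1e4, trait_type = "quantitative",
                         chrom = "1", case_fraction = NA_real_) {
  m <- length(snp_id)
  if (is.null(pos)) pos <- seq(1e6, by = 1000, length.out = m)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = rep_len(effect_allele, m),
             other_allele = rep_len(other_allele, m),
             eaf = rep_len(eaf, m), beta = beta, se = rep_len(se, m),
             pval = pval, n = rep_len(n, m),
             trait_type = rep_len(trait_type, m),
             case_fraction = rep_len(case_fraction, m),
             stringsAsFactors = FALSE)
}

make_panel <- function(..., trait_name = "gene1", tissue = "NA",
                       panel_kind = "eqtl", validate = TRUE) {
  summary_panel(make_records(...), trait_name = trait_name, tissue = tissue,
                panel_kind = panel_kind, validate = validate)
}

# Random valid correlation matrix of dimension m (positive definite, unit
# diagonal) built from random loadings; positions on a 1 kb grid.
random_ld <- function(m, snp_ids = sprintf("s%02d", seq_len(m))) {
  a <- matrix(rnorm(m * (m + 2L)), m, m + 2L)
  s <- tcrossprod(a)
  d <- 1 / sqrt(diag(s))
  r <- s * outer(d, d)
  ld_matrix(r, snp_ids = snp_ids, pos = seq(1e6, by = 1000, length.out = m),
            sym_tol = 1e-6)
}

# Independent brute-force clumping oracle: straight transcription of the
# greedy rule using repeated scans over a data.frame, no shared code with
# ld_clump().
clump_oracle <- function(rec, r, p_threshold, r2_cutoff, window_kb) {
  rownames(r) <- colnames(r) <- rec$snp_id
  pool <- rec[rec$pval < p_threshold, , drop = FALSE]
  kept <- character(0)
  while (nrow(pool) > 0L) {
    o <- order(pool$pval, pool$pos, pool$snp_id)
    idx <- pool[o[1L], ]
    kept <- c(kept, idx$snp_id)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      near <- abs(pool$pos[i] - idx$pos) <= window_kb * 1000
      near && r[idx$snp_id, pool$snp_id[i]]^2 > r2_cutoff
    }, logical(1L))
    drop[o[1L]] <- TRUE
    pool <- pool[!drop, , drop = FALSE]
  }
  kept
}

# Numerical-quadrature oracle for the log approximate Bayes factor: log of
# the ratio of N(beta; mu, se^2) integrated over mu ~ N(0, W) to the
# point-null likelihood N(beta; 0, se^2).
labf_quadrature <- function(beta, se, prior_sd) {
  log_integrand <- function(mu) {
    dnorm(beta, mean = mu, sd = se, log = TRUE) +
      dnorm(mu, mean = 0, sd = prior_sd, log = TRUE)
  }
  # the integrand is a (scaled) Gaussian in mu; integrate around its peak on
  # a relative scale so extreme z-scores neither underflow nor get missed
  shrink <- prior_sd^2 / (prior_sd^2 + se^2)
  mu0 <- shrink * beta
  width <- sqrt(se^2 * prior_sd^2 / (se^2 + prior_sd^2))
  peak <- log_integrand(mu0)
  rel <- function(mu) exp(log_integrand(mu) - peak)
  I <- integrate(rel, lower = mu0 - 15 * width, upper = mu0 + 15 * width,
                 rel.tol = 1e-10, subdivisions = 500L)$value
  peak + log(I) - dnorm(beta, mean = 0, sd = se, log = TRUE)
}
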