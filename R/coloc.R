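# Bayesian colocalization of two summary-statistic panels under the
# single-causal-variant assumption: per-SNP approximate Bayes factors from a
# Gaussian prior on the true effect, five-hypothesis posterior masses
# assembled entirely in log space, and a p12 prior-sensitivity scan.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 (`p1`), trait 2
#' (`p2`) or both (`p12`), plus the prior standard deviation of true effects
#' used in the approximate Bayes factor: 0.15 (SD units) for quantitative
#' traits, 0.2 (log-OR) for case-control traits.
#'
#' @param p1,p2 per-SNP association priors (defaults `1e-4`).
#' @param p12 shared-causal-variant prior (default `1e-5`); must not exceed
#'   `min(p1, p2)`.
#' @param sd_quant,sd_cc prior effect SDs by trait type.
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd_quant = 0.15, sd_cc = 0.2) {
  if (p12 <= 0 || p12 > min(p1, p2)) {
    stop("require 0 < p12 <= min(p1, p2)", call. = FALSE)
  }
  if (sd_quant <= 0 || sd_cc <= 0) stop("prior SDs must be > 0",
                                        call. = FALSE)
  structure(list(p1 = p1, p2 = p2, p12 = p12, sd_quant = sd_quant,
                 sd_cc = sd_cc), class = "coloc_priors")
}

prior_sd_for <- function(panel, priors) {
  tt <- unique(panel$records$trait_type)
  if (identical(tt, "case_control")) priors$sd_cc else priors$sd_quant
}

#' Restrict two panels to a window around the trait-1 top SNP
#'
#' Intersects the panels on shared SNP ids and keeps variants within
#' `window_kb` kilobases (inclusive on both ends) of the SNP with the
#' smallest trait-1 p-value. Trait 1 is by convention the disease GWAS, so
#' the window is anchored at its association peak.
#'
#' @param panel1,panel2 [summary_panel()]s sharing at least one SNP id.
#' @param window_kb half-window in kb (default 100).
#' @return list of the two windowed panels, aligned to identical SNP order.
#' @export
coloc_window <- function(panel1, panel2, window_kb = 100) {
  stopifnot(inherits(panel1, "summary_panel"),
            inherits(panel2, "summary_panel"))
  shared <- intersect(panel1$records$snp_id, panel2$records$snp_id)
  if (length(shared) == 0L) stop("panels share no SNPs", call. = FALSE)
  r1 <- panel1$records[match(shared, panel1$records$snp_id), , drop = FALSE]
  r2 <- panel2$records[match(shared, panel2$records$snp_id), , drop = FALSE]
  top_pos <- r1$pos[which.min(r1$pval)]
  keep <- abs(r1$pos - top_pos) <= window_kb * 1000
  p1 <- panel1; p1$records <- r1[keep, , drop = FALSE]
  p2 <- panel2; p2$records <- r2[keep, , drop = FALSE]
  rownames(p1$records) <- rownames(p2$records) <- NULL
  list(panel1 = p1, panel2 = p2)
}

#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximation: with `z = beta/se`, sampling variance
#' `V = se^2` and prior effect variance `W = prior_sd^2`, the shrinkage
#' factor is `r = W/(W+V)` and `lABF = (log(1 - r) + r z^2) / 2`. This is the
#' log ratio of the marginal likelihood of the data under a N(0, W) effect
#' prior to that under the point-null.
#'
#' @param beta,se association estimate and standard error (vectorized).
#' @param prior_sd prior SD of the true effect.
#' @return numeric log-ABF value(s).
#' @export
labf <- function(beta, se, prior_sd) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (prior_sd <= 0) stop("prior_sd must be > 0", call. = FALSE)
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z2)
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference is non-positive
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Five-hypothesis colocalization posteriors
#'
#' Under the one-causal-variant-per-trait assumption the five hypotheses
#' are: H0 no association with either trait; H1/H2 association with trait
#' 1/2 only; H3 both traits, distinct causal variants; H4 both traits, one
#' shared causal variant. With per-SNP log-ABFs and
#' `L1 = logSum(lABF1)`, `L2 = logSum(lABF2)`,
#' `L12 = logSum(lABF1 + lABF2)`, the unnormalized log masses are `H0 = 0`,
#' `H1 = log(p1) + L1`, `H2 = log(p2) + L2`,
#' `H3 = log(p1) + log(p2) + log(exp(L1 + L2) - exp(L12))` (zero mass when
#' the difference is numerically non-positive, as for a single shared SNP)
#' and `H4 = log(p12) + L12`; posteriors follow by normalized
#' exponentiation. All arithmetic is in log space.
#'
#' @param panel1,panel2 [summary_panel()]s already windowed and intersected
#'   to identical SNP order (see [coloc_window()]); `run_coloc()` does both
#'   steps.
#' @param priors a [coloc_priors()].
#' @return object of class `coloc_result`: posterior vector `pp`
#'   (`PP.H0` ... `PP.H4`), `n_snps`, `top_snp`, `priors`, `labf1`, `labf2`.
#' @export
coloc_posteriors <- function(panel1, panel2, priors = coloc_priors()) {
  stopifnot(inherits(panel1, "summary_panel"),
            inherits(panel2, "summary_panel"))
  r1 <- panel1$records
  r2 <- panel2$records
  if (nrow(r1) < 1L) stop("no shared SNPs to colocalize", call. = FALSE)
  if (!identical(r1$snp_id, r2$snp_id)) {
    stop("panels must be intersected to identical SNP order; see coloc_window()",
         call. = FALSE)
  }
  l1 <- labf(r1$beta, r1$se, prior_sd_for(panel1, priors))
  l2 <- labf(r2$beta, r2$se, prior_sd_for(panel2, priors))
  res <- posteriors_from_labf(l1, l2, priors)
  structure(list(pp = res, n_snps = nrow(r1),
                 top_snp = r1$snp_id[which.min(r1$pval)],
                 window_kb = attr(panel1, "window_kb") %||% NA_real_,
                 priors = priors, labf1 = l1, labf2 = l2,
                 snp_ids = r1$snp_id),
            class = "coloc_result")
}

posteriors_from_labf <- function(l1, l2, priors) {
  L1 <- log_sum_exp(l1)
  L2 <- log_sum_exp(l2)
  L12 <- log_sum_exp(l1 + l2)
  h <- c(H0 = 0,
         H1 = log(priors$p1) + L1,
         H2 = log(priors$p2) + L2,
         H3 = log(priors$p1) + log(priors$p2) + log_diff_exp(L1 + L2, L12),
         H4 = log(priors$p12) + L12)
  denom <- log_sum_exp(h)
  pp <- exp(h - denom)
  names(pp) <- paste0("PP.", names(h))
  pp
}

#' Run colocalization on two raw panels
#'
#' Convenience wrapper: window around the trait-1 top SNP, intersect, and
#' compute posteriors.
#'
#' @inheritParams coloc_posteriors
#' @param window_kb half-window in kb (default 100).
#' @return a `coloc_result`.
#' @export
run_coloc <- function(panel1, panel2, priors = coloc_priors(),
                      window_kb = 100) {
  w <- coloc_window(panel1, panel2, window_kb = window_kb)
  attr(w$panel1, "window_kb") <- window_kb
  coloc_posteriors(w$panel1, w$panel2, priors = priors)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNPs (top SNP %s)\n", x$n_snps,
              x$top_snp))
  print(round(x$pp, 4))
  cat(sprintf("  PP.H4 > 0.5 rule: %s\n",
              if (x$pp[["PP.H4"]] > 0.5) "colocalized" else "not colocalized"))
  invisible(x)
}

#' Sensitivity of the colocalization call to the p12 prior
#'
#' Recomputes the posteriors over a grid of p12 values, reusing the cached
#' per-SNP log-ABFs (the likelihood does not change, only the prior mass on
#' H4), and marks where the decision rule `PP.H4 > rule_threshold` holds.
#'
#' @param result a `coloc_result` from [coloc_posteriors()] / [run_coloc()].
#' @param p12_grid p12 values, each in `(0, min(p1, p2)]`; default 40
#'   log-spaced points from 1e-8 to `min(p1, p2)`.
#' @param rule_threshold decision threshold on PP.H4 (default 0.5).
#' @return data.frame: `p12`, `PP.H0` ... `PP.H4`, `rule_pass`.
#' @export
p12_sensitivity <- function(result, p12_grid = NULL, rule_threshold = 0.5) {
  stopifnot(inherits(result, "coloc_result"))
  pr <- result$priors
  pmax12 <- min(pr$p1, pr$p2)
  if (is.null(p12_grid)) {
    p12_grid <- exp(seq(log(1e-8), log(pmax12), length.out = 40L))
    p12_grid <- pmin(p12_grid, pmax12)   # guard rounding at the upper end
  }
  if (any(p12_grid <= 0 | p12_grid > pmax12)) {
    stop("p12 grid values must lie in (0, min(p1, p2)]", call. = FALSE)
  }
  rows <- lapply(p12_grid, function(p12) {
    pr2 <- pr; pr2$p12 <- p12
    pp <- posteriors_from_labf(result$labf1, result$labf2, pr2)
    data.frame(p12 = p12, t(pp), rule_pass = pp[["PP.H4"]] > rule_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
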