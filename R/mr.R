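# Two-sample MR core: allele harmonization of exposure and outcome records,
# the Wald ratio for single instruments, fixed-effect IVW for several, and
# OR/CI/multiplicity reporting conventions.

PALINDROMIC <- c("A_T", "T_A", "C_G", "G_C")

as_records <- function(x) {
  if (inherits(x, "summary_panel")) return(x$records)
  as.data.frame(x)
}

#' Harmonize exposure and outcome summary records
#'
#' Aligns the two studies to a common effect allele per SNP. Records are
#' matched on `snp_id`; when the outcome's effect/other alleles are swapped
#' relative to the exposure, the outcome beta is negated and its allele
#' frequency reflected (`eaf <- 1 - eaf`). Palindromic SNPs (A/T or C/G) are
#' dropped when either study's allele frequency is missing or falls in the
#' ambiguity window (default `[0.42, 0.58]`), since strand cannot be
#' resolved. Pairs with incompatible allele sets are dropped with a warning.
#'
#' @param exposure,outcome [summary_panel()]s (or their `records`
#'   data.frames); exposure is typically restricted to selected instruments
#'   first.
#' @param ambiguous_eaf two-element numeric, the inclusive allele-frequency
#'   window in which palindromic SNPs are deemed unresolvable.
#' @return data.frame of class `harmonized_pairs` with columns `snp_id`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `action`; only rows with action
#'   `kept` or `flipped` carry estimates. The full per-SNP disposition
#'   (including drops) is in `attr(, "log")`.
#' @export
harmonize <- function(exposure, outcome, ambiguous_eaf = c(0.42, 0.58)) {
  ex <- as_records(exposure)
  oy <- as_records(outcome)
  common <- intersect(ex$snp_id, oy$snp_id)
  log <- data.frame(snp_id = ex$snp_id, action = "dropped_unmatched",
                    stringsAsFactors = FALSE)
  rows <- list()
  for (id in common) {
    e <- ex[ex$snp_id == id, , drop = FALSE][1L, ]
    o <- oy[oy$snp_id == id, , drop = FALSE][1L, ]
    pal <- paste(e$effect_allele, e$other_allele, sep = "_") %in% PALINDROMIC
    same <- o$effect_allele == e$effect_allele &&
      o$other_allele == e$other_allele
    swapped <- o$effect_allele == e$other_allele &&
      o$other_allele == e$effect_allele
    if (!same && !swapped) {
      warning(sprintf("allele mismatch at %s (%s/%s vs %s/%s); pair dropped",
                      id, e$effect_allele, e$other_allele, o$effect_allele,
                      o$other_allele), call. = FALSE)
      log$action[log$snp_id == id] <- "dropped_unmatched"
      next
    }
    if (pal) {
      eafs <- c(e$eaf, o$eaf)
      ambiguous <- any(is.na(eafs)) ||
        any(eafs >= ambiguous_eaf[1L] & eafs <= ambiguous_eaf[2L])
      if (ambiguous) {
        log$action[log$snp_id == id] <- "dropped_palindromic"
        next
      }
    }
    beta_y <- if (swapped) -o$beta else o$beta
    action <- if (swapped) "flipped" else "kept"
    log$action[log$snp_id == id] <- action
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = id, beta_x = e$beta, se_x = e$se, beta_y = beta_y,
      se_y = o$se, action = action, stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(snp_id = character(), beta_x = numeric(), se_x = numeric(),
               beta_y = numeric(), se_y = numeric(), action = character(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "log") <- log
  class(pairs) <- c("harmonized_pairs", "data.frame")
  pairs
}

new_mr_estimate <- function(beta, se, method, n_snps, snps, level = 0.95) {
  pval <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else
    as.numeric(beta == 0)
  ci <- or_ci(beta, se, level = level)
  structure(list(beta = beta, se = se, pval = pval,
                 or_value = ci[["or"]], ci_low = ci[["ci_low"]],
                 ci_high = ci[["ci_high"]], method = method,
                 n_snps = n_snps, snps = snps, level = level),
            class = "mr_estimate")
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta = beta_y / beta_x`, with first-order delta-method standard error
#' `se = se_y / |beta_x|` (uncertainty in the exposure association is
#' neglected; anti-conservative for weak instruments, which the F >= 10
#' gate excludes upstream). P-values are two-sided normal.
#'
#' @param pairs a one-row `harmonized_pairs` (or data.frame with `beta_x`,
#'   `se_x`, `beta_y`, `se_y`).
#' @return an object of class `mr_estimate`.
#' @export
wald_ratio <- function(pairs) {
  p <- as.data.frame(pairs)
  if (nrow(p) != 1L) stop("wald_ratio expects exactly one pair", call. = FALSE)
  if (p$beta_x == 0) stop("beta_x = 0: Wald ratio undefined", call. = FALSE)
  new_mr_estimate(beta = p$beta_y / p$beta_x, se = p$se_y / abs(p$beta_x),
                  method = "wald", n_snps = 1L, snps = p$snp_id)
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' Per-SNP Wald ratios `b_j = beta_yj / beta_xj` with delta-method standard
#' errors `s_j = se_yj / |beta_xj|` are combined with weights `w_j = 1/s_j^2`:
#' `beta = sum(w b) / sum(w)` and `se = 1/sqrt(sum(w))` (fixed-effect).
#' Algebraically this equals weighted least squares of `beta_y` on `beta_x`
#' through the origin with weights `1/se_y^2`. Pairs with `beta_x = 0` are
#' excluded with a warning.
#'
#' @param pairs a `harmonized_pairs` with at least two usable rows (a single
#'   usable row degenerates to [wald_ratio()]).
#' @param random_effects if `TRUE`, inflate the fixed-effect SE by the
#'   multiplicative residual dispersion when it exceeds 1 (off by default).
#' @return an object of class `mr_estimate` (`method = "ivw"`, or `"wald"`
#'   for the degenerate single-pair case).
#' @export
ivw <- function(pairs, random_effects = FALSE) {
  p <- as.data.frame(pairs)
  zero <- p$beta_x == 0
  if (any(zero)) {
    warning(sprintf("%d pair(s) with beta_x = 0 excluded from IVW",
                    sum(zero)), call. = FALSE)
    p <- p[!zero, , drop = FALSE]
  }
  if (nrow(p) == 0L) stop("no usable pairs for IVW", call. = FALSE)
  if (nrow(p) == 1L) return(wald_ratio(p))
  b <- p$beta_y / p$beta_x
  s <- p$se_y / abs(p$beta_x)
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  if (random_effects) {
    phi <- sum(w * (b - beta)^2) / (nrow(p) - 1L)
    se <- se * sqrt(max(1, phi))
  }
  new_mr_estimate(beta = beta, se = se, method = "ivw", n_snps = nrow(p),
                  snps = p$snp_id)
}

#' Fit a two-sample MR causal-effect model
#'
#' The front-end estimator: takes harmonized exposure/outcome pairs (or an
#' exposure and outcome panel plus an instrument set, which it harmonizes
#' first), applies the Wald ratio when a single instrument survives and
#' fixed-effect IVW otherwise, and returns a classed estimate with
#' odds-ratio and confidence-interval reporting.
#'
#' @param pairs a `harmonized_pairs`; alternatively supply `exposure`,
#'   `outcome` and optionally `instruments` and the pairs are built here.
#' @param exposure,outcome [summary_panel()]s (used when `pairs` is missing).
#' @param instruments an `instrument_set` restricting the exposure panel.
#' @param random_effects passed to [ivw()].
#' @return an object of class `mr_estimate` with components `beta`, `se`,
#'   `pval`, `or_value`, `ci_low`, `ci_high`, `method`, `n_snps`, `snps`.
#' @examples
#' bundle <- simulate_mr_study(theta = 0.3, seed = 7)
#' inst <- select_top_instrument(bundle$exposure_panel)
#' fit <- mr_fit(exposure = bundle$exposure_panel,
#'               outcome = bundle$outcome_panel, instruments = inst)
#' print(fit)
#' coef(fit)
#' confint(fit)
#' @export
mr_fit <- function(pairs = NULL, exposure = NULL, outcome = NULL,
                   instruments = NULL, random_effects = FALSE) {
  if (is.null(pairs)) {
    if (is.null(exposure) || is.null(outcome)) {
      stop("supply either harmonized pairs or exposure+outcome panels",
           call. = FALSE)
    }
    ex <- as_records(exposure)
    if (!is.null(instruments)) {
      ex <- ex[ex$snp_id %in% instruments$snp_id, , drop = FALSE]
    }
    pairs <- harmonize(ex, outcome)
  }
  p <- as.data.frame(pairs)
  p <- p[p$action %in% c("kept", "flipped") | !("action" %in% names(p)), ,
         drop = FALSE]
  if (nrow(p) == 0L) stop("no harmonized pairs to estimate from",
                          call. = FALSE)
  if (nrow(p) == 1L) wald_ratio(p) else ivw(p, random_effects = random_effects)
}

#' Odds ratio and confidence interval from a log-scale estimate
#'
#' `OR = exp(beta)` with bounds `exp(beta -/+ z * se)`, `z` the two-sided
#' normal quantile for `level` (1.959964 at 0.95). The OR is the geometric
#' mean of the bounds by construction.
#'
#' @param beta log-scale effect (or an `mr_estimate`).
#' @param se standard error (ignored when `beta` is an `mr_estimate`).
#' @param level confidence level (default 0.95).
#' @return named numeric: `or`, `ci_low`, `ci_high`.
#' @export
or_ci <- function(beta, se, level = 0.95) {
  if (inherits(beta, "mr_estimate")) {
    se <- beta$se
    beta <- beta$beta
  }
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Bonferroni multiplicity threshold over a factorial test family
#'
#' Divides `alpha` by the product of panel counts, e.g. targets x tissues x
#' outcomes.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param counts positive integer counts of each multiplicity dimension.
#' @return the per-test significance threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, counts) {
  if (length(counts) == 0L) stop("counts must be non-empty", call. = FALSE)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  alpha / prod(counts)
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR estimate (%s, %d SNP%s)\n", toupper(x$method),
              x$n_snps, if (x$n_snps == 1L) "" else "s"))
  cat(sprintf("  beta = %.*g (se %.*g), p = %.3g\n", digits, x$beta, digits,
              x$se, x$pval))
  cat(sprintf("  OR = %.3f, %d%% CI = %.3f-%.3f\n", x$or_value,
              round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  c(beta = object$beta)
}

#' @export
vcov.mr_estimate <- function(object, ...) {
  matrix(object$se^2, 1L, 1L, dimnames = list("beta", "beta"))
}

#' @export
confint.mr_estimate <- function(object, parm = "beta", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              1L, 2L,
              dimnames = list("beta", sprintf("%.1f %%",
                                              100 * c((1 - level) / 2,
                                                      1 - (1 - level) / 2))))
  m
}

#' @export
summary.mr_estimate <- function(object, ...) {
  out <- data.frame(method = object$method, n_snps = object$n_snps,
                    beta = object$beta, se = object$se, pval = object$pval,
                    or = object$or_value, ci_low = object$ci_low,
                    ci_high = object$ci_high, stringsAsFactors = FALSE)
  class(out) <- c("summary.mr_estimate", "data.frame")
  out
}

#' @export
print.summary.mr_estimate <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
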