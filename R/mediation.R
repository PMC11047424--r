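# Two-step MR mediation: step 1 estimates the exposure -> mediator effect
# with the exposure's own instruments; step 2 estimates the mediator ->
# outcome effect with the mediator's genome-wide-significant clumped
# instruments; the indirect effect is the product of the two, and the
# proportion mediated is indirect / total.

#' Step 1: causal effect of the exposure on a mediator
#'
#' Uses the exposure's selected genetic instruments against the mediator
#' panel: Wald ratio for a single instrument, IVW otherwise.
#'
#' @param instruments an `instrument_set` of exposure instruments.
#' @param exposure_panel the exposure [summary_panel()] (provides the
#'   SNP-exposure associations; instruments carry them too, so this may be
#'   omitted).
#' @param mediator_panel the mediator [summary_panel()].
#' @return an `mr_estimate`.
#' @export
step1_effect <- function(instruments, mediator_panel, exposure_panel = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  ex <- if (!is.null(exposure_panel)) {
    r <- as_records(exposure_panel)
    r[r$snp_id %in% instruments$snp_id, , drop = FALSE]
  } else {
    df <- as.data.frame(instruments)
    df$trait_type <- "quantitative"
    df$case_fraction <- NA_real_
    df
  }
  if (!any(ex$snp_id %in% mediator_panel$records$snp_id)) {
    stop("no instrument overlaps the mediator panel", call. = FALSE)
  }
  mr_fit(harmonize(ex, mediator_panel))
}

#' Step 2: causal effect of a mediator on the outcome
#'
#' Selects the mediator's own instruments at genome-wide significance
#' (default p < 5e-8) with LD clumping and the F >= 10 gate, harmonizes them
#' against the outcome panel, and estimates by Wald ratio or IVW.
#'
#' When `exposure_panel` is supplied, candidate mediator instruments that
#' are themselves genome-wide associated with the exposure are excluded.
#' This enforces the step-2 exclusion restriction: a SNP that instruments
#' the exposure reaches the outcome through the direct exposure path as
#' well, so its mediator Wald ratio estimates `b + direct/a` rather than
#' the mediator effect `b`.
#'
#' @param mediator_panel the mediator [summary_panel()].
#' @param outcome_panel the outcome [summary_panel()].
#' @param ld an [ld_matrix()] covering the mediator SNPs.
#' @param gw_threshold instrument p-value threshold (default `5e-8`).
#' @param r2_cutoff clumping r^2 cutoff (default 0.001).
#' @param f_min minimum instrument F statistic (default 10).
#' @param exposure_panel optional exposure [summary_panel()] used to screen
#'   out exposure-associated candidates.
#' @param exposure_p exclusion threshold on the exposure association
#'   (default `5e-8`, strict `<`).
#' @return an `mr_estimate`.
#' @export
step2_effect <- function(mediator_panel, outcome_panel, ld,
                         gw_threshold = 5e-8, r2_cutoff = 0.001,
                         f_min = 10, exposure_panel = NULL,
                         exposure_p = 5e-8) {
  inst <- ld_clump(mediator_panel, ld, p_threshold = gw_threshold,
                   r2_cutoff = r2_cutoff)
  inst <- filter_weak_instruments(inst, f_min = f_min)
  if (!is.null(exposure_panel) && nrow(inst) > 0L) {
    ex <- as_records(exposure_panel)
    shared <- ex$snp_id[!is.na(ex$pval) & ex$pval < exposure_p]
    drop <- inst$snp_id %in% shared
    if (any(drop)) {
      message(sprintf(
        "step 2: excluded %d exposure-associated mediator instrument(s): %s",
        sum(drop), paste(inst$snp_id[drop], collapse = ", ")))
      inst <- inst[!drop, , drop = FALSE]
      class(inst) <- c("instrument_set", "data.frame")
    }
  }
  if (nrow(inst) == 0L) {
    near <- sum(mediator_panel$records$pval < gw_threshold * 100)
    stop(sprintf(paste0("no mediator instrument at p < %.3g after clumping ",
                        "and F filter (%d SNP(s) within two orders of ",
                        "magnitude)"), gw_threshold, near), call. = FALSE)
  }
  mr_fit(exposure = mediator_panel, outcome = outcome_panel,
         instruments = inst)
}

#' Combine the two steps into a mediation decomposition
#'
#' Product-of-coefficients decomposition: `indirect = a * b` with delta-
#' method standard error `sqrt(a^2 se_b^2 + b^2 se_a^2)`; the proportion
#' mediated is `indirect / total` (reported as a percentage, unclamped). The
#' path is labelled `mediating` when the indirect and total effects share a
#' sign, `suppressing` when they oppose, and `not_significant` unless both
#' step p-values are below `alpha`.
#'
#' @param a step-1 `mr_estimate` (exposure -> mediator).
#' @param b step-2 `mr_estimate` (mediator -> outcome).
#' @param total the total-effect `mr_estimate` (exposure -> outcome, from
#'   [mr_fit()]); its beta must be nonzero.
#' @param alpha per-step significance gate (default 0.05).
#' @return object of class `mediation_result`.
#' @export
mediation_summary <- function(a, b, total, alpha = 0.05) {
  stopifnot(inherits(a, "mr_estimate"), inherits(b, "mr_estimate"),
            inherits(total, "mr_estimate"))
  if (total$beta == 0) {
    stop("total effect is zero: proportion mediated undefined", call. = FALSE)
  }
  indirect <- a$beta * b$beta
  se_ind <- sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2)
  proportion <- indirect / total$beta
  significant <- a$pval < alpha && b$pval < alpha
  label <- if (!significant) "not_significant" else if
    (sign(indirect) == sign(total$beta)) "mediating" else "suppressing"
  structure(list(a = a$beta, se_a = a$se, p_a = a$pval,
                 b = b$beta, se_b = b$se, p_b = b$pval,
                 total = total$beta, se_total = total$se,
                 indirect = indirect, se_indirect = se_ind,
                 proportion = proportion,
                 proportion_pct = 100 * proportion,
                 label = label, alpha = alpha),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  step 1 (exposure -> mediator): a = %.4g (se %.3g, p %.3g)\n",
              x$a, x$se_a, x$p_a))
  cat(sprintf("  step 2 (mediator -> outcome):  b = %.4g (se %.3g, p %.3g)\n",
              x$b, x$se_b, x$p_b))
  cat(sprintf("  indirect a*b = %.4g (se %.3g); total = %.4g\n",
              x$indirect, x$se_indirect, x$total))
  cat(sprintf("  proportion mediated = %.2f%% [%s]\n",
              abs(x$proportion_pct), x$label))
  invisible(x)
}
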