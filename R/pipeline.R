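# Pipeline orchestration over configured target x tissue x outcome
# combinations: instrument selection -> MR -> (for Bonferroni-significant
# hits) colocalization and two-step mediation, with per-stage counts logged
# and deterministic seeding throughout.

#' Build a pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' Defaults follow the drug-target MR design: eQTL inclusion at p < 1e-4
#' (one top SNP per gene), pQTL inclusion at p < 0.05 with LD clumping at
#' r^2 = 0.001, weak instruments removed at F < 10, confounder exclusion at
#' p < 5e-8, colocalization over a +/-100 kb window with the PP.H4 > 0.5
#' rule, and a Bonferroni threshold of `alpha / prod(counts)`.
#'
#' @param combinations list of combination descriptions; each element is a list
#'   with `target`, `tissue`, `outcome`, optional `role` and `kind`
#'   (`"eqtl"` or `"pqtl"`), plus either file paths (`exposure`, `outcome_path`,
#'   `mediator`, `ld`) or a `simulate` sub-list of [simulate_mr_study()]
#'   arguments.
#' @param eqtl_p,pqtl_p,clump_r2,clump_window_kb,f_min,confounder_p
#'   instrument-selection thresholds.
#' @param coloc_window_kb,rule_h4 colocalization window and decision rule.
#' @param alpha family-wise error rate before multiplicity correction.
#' @param counts integer vector of multiplicity dimensions
#'   (targets, tissues, outcomes).
#' @param priors a [coloc_priors()].
#' @param mediator_gw_p mediator instrument threshold for step-2 MR.
#' @param confounder_lookup path to a confounder lookup TSV, or `NULL`.
#' @param force_all run coloc/mediation for every combination, not only
#'   Bonferroni-significant ones.
#' @param seed master seed for all simulated combinations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(combinations, eqtl_p = 1e-4, pqtl_p = 5e-2,
                            clump_r2 = 1e-3, clump_window_kb = 10000,
                            f_min = 10, confounder_p = 5e-8,
                            coloc_window_kb = 100, rule_h4 = 0.5,
                            alpha = 0.05, counts = c(1L, 1L, 1L),
                            priors = coloc_priors(), mediator_gw_p = 5e-8,
                            confounder_lookup = NULL, force_all = FALSE,
                            seed = 1L) {
  stopifnot(length(combinations) >= 1L)
  for (p in list(eqtl_p, pqtl_p, clump_r2, confounder_p, alpha, rule_h4,
                 mediator_gw_p)) {
    if (!is.numeric(p) || p <= 0 || p > 1) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  if (f_min < 0 || coloc_window_kb <= 0 || any(counts < 1)) {
    stop("invalid f_min, window or counts", call. = FALSE)
  }
  structure(list(combinations = combinations, eqtl_p = eqtl_p,
                 pqtl_p = pqtl_p, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 confounder_p = confounder_p,
                 coloc_window_kb = coloc_window_kb, rule_h4 = rule_h4,
                 alpha = alpha, counts = as.integer(counts),
                 priors = priors, mediator_gw_p = mediator_gw_p,
                 confounder_lookup = confounder_lookup,
                 force_all = isTRUE(force_all), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [pipeline_config()], with `priors` given as a mapping.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$combinations)) stop("config lacks 'combinations'",
                                    call. = FALSE)
  pr <- if (is.null(y$priors)) coloc_priors() else
    do.call(coloc_priors, y$priors)
  args <- y[setdiff(names(y), "priors")]
  args$priors <- pr
  do.call(pipeline_config, args)
}

load_combination <- function(cmb, seed) {
  if (!is.null(cmb$simulate)) {
    args <- cmb$simulate
    args$seed <- args$seed %||% seed
    return(do.call(simulate_mr_study, args))
  }
  for (f in c("exposure", "outcome_path", "ld")) {
    if (is.null(cmb[[f]])) stop("combination lacks '", f, "'", call. = FALSE)
    if (!file.exists(cmb[[f]])) {
      stop("input file not found: ", cmb[[f]], call. = FALSE)
    }
  }
  if (!is.null(cmb$mediator) && !file.exists(cmb$mediator)) {
    stop("input file not found: ", cmb$mediator, call. = FALSE)
  }
  structure(list(
    exposure_panel = read_sumstats(cmb$exposure),
    outcome_panel = read_sumstats(cmb$outcome_path),
    mediator_panel = if (!is.null(cmb$mediator))
      read_sumstats(cmb$mediator) else NULL,
    ld = read_ld_matrix(cmb$ld), truth = NULL), class = "study_bundle")
}

#' Run the full drug-target MR pipeline
#'
#' For each configured target x tissue x outcome combination: select and QC
#' instruments (eQTL top-SNP rule or pQTL clumping, F filter, confounder
#' screen), estimate the causal effect (Wald/IVW), flag Bonferroni
#' significance at `alpha / prod(counts)`, and for significant hits run
#' colocalization (trait 1 = outcome GWAS, trait 2 = QTL) and, when a
#' mediator panel is present, two-step MR mediation. Estimation failures in
#' one combination are logged and skipped, never fatal; unreadable inputs
#' abort before any computation.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory; receives `mr_results.tsv`,
#'   `coloc_results.tsv`, `mediation_results.tsv` and `run_log.txt`.
#' @return invisibly, a list with the three result data.frames and the log
#'   lines.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail fast on unreadable inputs before any estimation
  for (cmb in config$combinations) {
    if (is.null(cmb$simulate)) {
      for (f in c(cmb$exposure, cmb$outcome_path, cmb$mediator, cmb$ld)) {
        if (!is.null(f) && !file.exists(f)) {
          stop("input file not found: ", f, call. = FALSE)
        }
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lookup <- if (!is.null(config$confounder_lookup))
    read_confounder_lookup(config$confounder_lookup) else NULL
  threshold <- bonferroni_threshold(config$alpha, config$counts)
  seeds <- split_seed(config$seed, length(config$combinations))
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("bonferroni threshold: %.6g = %.3g / (%s)", threshold,
                   config$alpha, paste(config$counts, collapse = " x ")),
           sprintf("thresholds: eqtl_p=%.3g pqtl_p=%.3g clump_r2=%.3g f_min=%.3g confounder_p=%.3g",
                   config$eqtl_p, config$pqtl_p, config$clump_r2,
                   config$f_min, config$confounder_p))
  mr_rows <- list(); coloc_rows <- list(); med_rows <- list()
  for (k in seq_along(config$combinations)) {
    cmb <- config$combinations[[k]]
    tag <- sprintf("%s/%s/%s", cmb$target %||% "target",
                   cmb$tissue %||% "NA", cmb$outcome %||% "outcome")
    res <- tryCatch({
      bundle <- load_combination(cmb, seeds[k])
      kind <- cmb$kind %||% bundle$exposure_panel$panel_kind
      n0 <- nrow(bundle$exposure_panel$records)
      inst <- if (identical(kind, "pqtl")) {
        ld_clump(bundle$exposure_panel, bundle$ld,
                 p_threshold = config$pqtl_p, r2_cutoff = config$clump_r2,
                 window_kb = config$clump_window_kb)
      } else {
        select_top_instrument(bundle$exposure_panel,
                              p_threshold = config$eqtl_p)
      }
      n1 <- nrow(inst)
      inst <- filter_weak_instruments(inst, f_min = config$f_min)
      n2 <- nrow(inst)
      inst <- exclude_confounded(inst, lookup,
                                 p_threshold = config$confounder_p)
      n3 <- nrow(inst)
      log <- c(log, sprintf(
        "[%s] SNPs %d -> p-filter %d -> F-filter %d -> confounder %d",
        tag, n0, n1, n2, n3))
      if (n3 == 0L) stop("no instruments survive QC", call. = FALSE)
      fit <- mr_fit(exposure = bundle$exposure_panel,
                    outcome = bundle$outcome_panel, instruments = inst)
      pass <- fit$pval < threshold
      mr_rows[[length(mr_rows) + 1L]] <- data.frame(
        target = cmb$target %||% "target", tissue = cmb$tissue %||% "NA",
        outcome = cmb$outcome %||% "outcome", role = cmb$role %||% "NA",
        method = fit$method, n_snps = fit$n_snps, beta = fit$beta,
        se = fit$se, or = fit$or_value, ci_low = fit$ci_low,
        ci_high = fit$ci_high, pval = fit$pval,
        pass_bonferroni = pass, nominal = fit$pval < config$alpha,
        stringsAsFactors = FALSE)
      if (pass || config$force_all) {
        cl <- run_coloc(bundle$outcome_panel, bundle$exposure_panel,
                        priors = config$priors,
                        window_kb = config$coloc_window_kb)
        coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
          target = cmb$target %||% "target", tissue = cmb$tissue %||% "NA",
          outcome = cmb$outcome %||% "outcome", n_snps = cl$n_snps,
          top_snp = cl$top_snp, t(cl$pp),
          coloc_pass = cl$pp[["PP.H4"]] > config$rule_h4,
          stringsAsFactors = FALSE)
        if (!is.null(bundle$mediator_panel)) {
          med <- tryCatch({
            a <- step1_effect(inst, bundle$mediator_panel)
            b <- step2_effect(bundle$mediator_panel, bundle$outcome_panel,
                              bundle$ld, gw_threshold = config$mediator_gw_p,
                              r2_cutoff = config$clump_r2,
                              f_min = config$f_min,
                              exposure_panel = bundle$exposure_panel)
            mediation_summary(a, b, fit, alpha = config$alpha)
          }, error = function(e) {
            log <<- c(log, sprintf("[%s] mediation skipped: %s", tag,
                                   conditionMessage(e)))
            NULL
          })
          if (!is.null(med)) {
            med_rows[[length(med_rows) + 1L]] <- data.frame(
              target = cmb$target %||% "target",
              tissue = cmb$tissue %||% "NA",
              outcome = cmb$outcome %||% "outcome",
              mediator = bundle$mediator_panel$trait_name,
              a = med$a, se_a = med$se_a, p_a = med$p_a,
              b = med$b, se_b = med$se_b, p_b = med$p_b,
              total = med$total, indirect = med$indirect,
              proportion_pct = med$proportion_pct, label = med$label,
              stringsAsFactors = FALSE)
          }
        }
      }
      TRUE
    }, error = function(e) {
      log <<- c(log, sprintf("[%s] skipped: %s", tag, conditionMessage(e)))
      FALSE
    })
  }
  bind_or_empty <- function(rows, proto) {
    if (length(rows) > 0L) do.call(rbind, rows) else proto
  }
  mr_df <- bind_or_empty(mr_rows, data.frame(
    target = character(), tissue = character(), outcome = character(),
    role = character(), method = character(), n_snps = integer(),
    beta = numeric(), se = numeric(), or = numeric(), ci_low = numeric(),
    ci_high = numeric(), pval = numeric(), pass_bonferroni = logical(),
    nominal = logical(), stringsAsFactors = FALSE))
  coloc_df <- bind_or_empty(coloc_rows, data.frame(
    target = character(), tissue = character(), outcome = character(),
    n_snps = integer(), top_snp = character(), PP.H0 = numeric(),
    PP.H1 = numeric(), PP.H2 = numeric(), PP.H3 = numeric(),
    PP.H4 = numeric(), coloc_pass = logical(), stringsAsFactors = FALSE))
  med_df <- bind_or_empty(med_rows, data.frame(
    target = character(), tissue = character(), outcome = character(),
    mediator = character(), a = numeric(), se_a = numeric(), p_a = numeric(),
    b = numeric(), se_b = numeric(), p_b = numeric(), total = numeric(),
    indirect = numeric(), proportion_pct = numeric(), label = character(),
    stringsAsFactors = FALSE))
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(mr_df, "mr_results.tsv")
  write_tsv(coloc_df, "coloc_results.tsv")
  write_tsv(med_df, "mediation_results.tsv")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(mr = mr_df, coloc = coloc_df, mediation = med_df,
                 log = log, threshold = threshold))
}

#' Forest-plot table of MR results
#'
#' Tabular companion to a forest plot: rows sorted by outcome then p-value
#' (stable for ties), with the odds ratio and confidence interval formatted
#' to 3 decimal places as `"OR (low-high)"`.
#'
#' @param rows data.frame as produced in `mr_results.tsv` by
#'   [run_pipeline()] (needs `outcome`, `pval`, `beta`, `se` or
#'   `or`/`ci_low`/`ci_high`).
#' @param path optional output TSV path.
#' @return the formatted data.frame (invisibly when `path` is given).
#' @export
forest_table <- function(rows, path = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) > 0L) {
    if (!all(c("or", "ci_low", "ci_high") %in% names(rows))) {
      ci <- t(vapply(seq_len(nrow(rows)),
                     function(i) or_ci(rows$beta[i], rows$se[i]),
                     numeric(3L)))
      rows$or <- ci[, 1L]; rows$ci_low <- ci[, 2L]; rows$ci_high <- ci[, 3L]
    }
    ord <- order(rows$outcome, rows$pval)   # order() is a stable sort
    rows <- rows[ord, , drop = FALSE]
    rows$or_ci <- sprintf("%.3f (%.3f–%.3f)", rows$or, rows$ci_low,
                          rows$ci_high)
    rownames(rows) <- NULL
  } else {
    rows$or_ci <- character(0)
  }
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(rows))
  }
  rows
}
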