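# LD-aware simulator of QTL/GWAS/mediator summary statistics with known
# causal structure. Genotypes are standardized, so marginal effects are
# beta_marg = R %*% b and each marginal SE is 1/sqrt(n); observed betas are a
# single MVN draw with covariance R/n per (independent) cohort.

#' AR(1) linkage-disequilibrium matrix
#'
#' Builds the stationary first-order autoregressive correlation structure
#' `r[i, j] = rho^|i - j|`, a standard stand-in for the decay of LD with
#' distance along a chromosome. SNP positions are assigned on a uniform grid
#' spanning `region_kb` kilobases starting at `start_pos`.
#'
#' @param m number of SNPs (>= 1).
#' @param rho adjacent-SNP correlation in `[0, 1)`.
#' @param region_kb region length in kb over which SNPs are placed
#'   (default 200).
#' @param start_pos position of the first SNP (1-based; default 1e6).
#' @param snp_prefix prefix for generated SNP ids.
#' @return an [ld_matrix()] with a `pos` attribute.
#' @export
make_ld_ar1 <- function(m, rho, region_kb = 200, start_pos = 1e6,
                        snp_prefix = "rs") {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  idx <- seq_len(m)
  r <- rho^abs(outer(idx, idx, "-"))
  pos <- if (m == 1L) start_pos else
    round(seq(start_pos, start_pos + region_kb * 1000, length.out = m))
  ld_matrix(r, snp_ids = sprintf("%s%04d", snp_prefix, idx), pos = pos)
}

# Deterministic per-panel sub-seeds from one master seed.
split_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, k)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Shared per-SNP metadata (alleles, eaf) for a study so that all panels of a
# bundle agree in orientation. Non-palindromic allele pairs only; eaf from
# U(0.05, 0.95). Used for harmonization plumbing, not for the likelihood.
snp_metadata <- function(ld, seed) {
  m <- nrow(ld)
  set.seed(seed)
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- sample.int(4L, m, replace = TRUE)
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ea <- oa <- character(m)
  for (i in seq_len(m)) {
    p <- pairs[[pick[i]]]
    if (flip[i]) p <- rev(p)
    ea[i] <- p[1L]; oa[i] <- p[2L]
  }
  pos <- attr(ld, "pos") %||% seq_len(m)
  data.frame(snp_id = rownames(ld), chrom = "1", pos = pos,
             effect_allele = ea, other_allele = oa,
             eaf = stats::runif(m, 0.05, 0.95), stringsAsFactors = FALSE)
}

#' Simulate marginal summary statistics for one trait
#'
#' Draws one cohort's observed marginal effects from
#' `MVN(R %*% b, R / n)` on the standardized-genotype scale, so every SE is
#' `1/sqrt(n)` and the z-score of a lone causal SNP is `b * sqrt(n)` in
#' expectation. P-values are two-sided normal. Case-control traits are
#' simulated on the same linear scale (betas read as log-OR); the label only
#' drives downstream prior choices.
#'
#' @param ld an [ld_matrix()] (R).
#' @param causal_betas numeric vector of true per-SNP causal effects, length
#'   `nrow(ld)` (sparse: mostly zeros).
#' @param n cohort sample size (>= 10; the sampling model is asymptotic).
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param seed integer seed; identical seeds give identical panels.
#' @param trait_name,tissue,panel_kind panel metadata.
#' @param snp_meta optional pre-built SNP metadata (internal; lets all panels
#'   of a study share alleles and frequencies).
#' @return a [summary_panel()].
#' @export
simulate_trait_sumstats <- function(ld, causal_betas, n,
                                    trait_type = c("quantitative",
                                                   "case_control"),
                                    seed = 1L, trait_name = "trait",
                                    tissue = "NA", panel_kind = "gwas",
                                    snp_meta = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(ld, "ld_matrix"))
  m <- nrow(ld)
  if (length(causal_betas) != m) {
    stop("causal_betas length must equal LD dimension", call. = FALSE)
  }
  if (n < 10) stop("n must be >= 10 (asymptotic sampling model)",
                   call. = FALSE)
  R <- unclass(ld); attr(R, "pos") <- NULL
  beta_marg <- drop(R %*% causal_betas)
  se <- rep(1 / sqrt(n), m)
  # MVN draw via the (pivoted, PSD-safe) Cholesky factor of R.
  ch <- suppressWarnings(chol(R, pivot = TRUE))
  piv <- attr(ch, "pivot")
  rank <- attr(ch, "rank")
  set.seed(seed)
  z <- stats::rnorm(m)
  z[seq_len(m) > rank] <- 0
  eps <- numeric(m)
  eps[piv] <- drop(crossprod(ch, z))
  beta_obs <- beta_marg + eps / sqrt(n)
  # two-sided normal p, floored so extreme z-scores cannot underflow to 0
  pval <- pmax(2 * stats::pnorm(-abs(beta_obs / se)), 1e-300)
  if (is.null(snp_meta)) snp_meta <- snp_metadata(ld, seed)
  rec <- data.frame(
    snp_meta[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf")],
    beta = beta_obs, se = se, pval = pval, n = n, trait_type = trait_type,
    case_fraction = if (trait_type == "case_control") 0.5 else NA_real_,
    stringsAsFactors = FALSE)
  summary_panel(rec, trait_name = trait_name, tissue = tissue,
                panel_kind = panel_kind)
}

#' Simulate a full two-sample MR study with a mediation chain
#'
#' Generates exposure, outcome and mediator summary panels over one LD region
#' from three independent cohorts (the two-sample design), with the causal
#' chain exposure -> mediator -> outcome plus a direct exposure -> outcome
#' path. The total exposure effect on the outcome is
#' `theta = direct_effect + a_effect * b_effect` by construction. Mediator-
#' specific causal SNPs (independent of the exposure's, in low LD with them)
#' give the mediator its own genome-wide-significant instruments and feed the
#' outcome through `b_effect`, so step-2 mediator MR is identified.
#'
#' @param m SNP count (default 50).
#' @param rho AR(1) LD parameter (default 0.5).
#' @param causal_betas either a full length-`m` vector or a sparse description
#'   via `causal_idx`/`causal_b`; default one causal SNP of effect 0.3 at the
#'   region centre (F about `n * 0.09` at the causal SNP).
#' @param causal_idx,causal_b indices and effects of exposure causal SNPs.
#' @param theta total causal effect of exposure on outcome; when the
#'   mediation chain is given, `theta` is derived as
#'   `direct_effect + a_effect * b_effect` and this argument must be `NULL`.
#' @param a_effect exposure -> mediator effect (default 0).
#' @param b_effect mediator -> outcome effect (default 0).
#' @param direct_effect exposure -> outcome effect not via the mediator.
#' @param mediator_idx,mediator_b mediator-specific causal SNPs; default one
#'   SNP of effect 0.1 at the far end of the region when the chain is active.
#' @param n_exposure,n_outcome,n_mediator cohort sizes (default 1e4).
#' @param trait_type_outcome `"case_control"` (default) or `"quantitative"`.
#' @param region_kb region length in kb (default 200).
#' @param seed master seed; per-panel seeds are split from it.
#' @return object of class `study_bundle`: list with `exposure_panel`,
#'   `outcome_panel`, `mediator_panel`, `ld`, `truth`.
#' @export
simulate_mr_study <- function(m = 50L, rho = 0.5, causal_betas = NULL,
                              causal_idx = NULL, causal_b = 0.3,
                              theta = NULL, a_effect = 0, b_effect = 0,
                              direct_effect = NULL,
                              mediator_idx = NULL, mediator_b = 0.1,
                              n_exposure = 1e4, n_outcome = 1e4,
                              n_mediator = 1e4,
                              trait_type_outcome = "case_control",
                              region_kb = 200, seed = 1L) {
  ld <- make_ld_ar1(m, rho, region_kb = region_kb)
  b_x <- numeric(m)
  if (!is.null(causal_betas)) {
    stopifnot(length(causal_betas) == m)
    b_x <- causal_betas
  } else {
    if (is.null(causal_idx)) causal_idx <- as.integer(ceiling(m / 2))
    b_x[causal_idx] <- causal_b
  }
  if (all(b_x == 0)) stop("at least one nonzero exposure causal beta required",
                          call. = FALSE)
  chain <- a_effect != 0 || b_effect != 0 || !is.null(direct_effect)
  if (chain) {
    if (!is.null(theta)) {
      stop("theta is derived from the mediation chain; do not supply both",
           call. = FALSE)
    }
    if (is.null(direct_effect)) direct_effect <- 0
    theta <- direct_effect + a_effect * b_effect
  } else {
    if (is.null(theta)) theta <- 0
    direct_effect <- theta
  }
  b_m <- numeric(m)   # mediator-specific causal SNPs
  if (chain) {
    if (is.null(mediator_idx)) mediator_idx <- m
    b_m[mediator_idx] <- mediator_b
  }
  # Causal effect vectors implied by the chain:
  #   mediator genotype effects: a * b_x + b_m
  #   outcome genotype effects:  direct * b_x + b * (a * b_x + b_m)
  b_med <- a_effect * b_x + b_m
  b_out <- theta * b_x + b_effect * b_m
  seeds <- split_seed(seed, 4L)
  meta <- snp_metadata(ld, seeds[4L])
  exposure <- simulate_trait_sumstats(
    ld, b_x, n_exposure, trait_type = "quantitative", seed = seeds[1L],
    trait_name = "exposure", tissue = "synthetic_tissue",
    panel_kind = "eqtl", snp_meta = meta)
  outcome <- simulate_trait_sumstats(
    ld, b_out, n_outcome, trait_type = trait_type_outcome, seed = seeds[2L],
    trait_name = "outcome", panel_kind = "gwas", snp_meta = meta)
  mediator <- simulate_trait_sumstats(
    ld, b_med, n_mediator, trait_type = "quantitative", seed = seeds[3L],
    trait_name = "mediator", panel_kind = "mediator", snp_meta = meta)
  truth <- structure(list(
    theta = theta, a_effect = a_effect, b_effect = b_effect,
    direct_effect = direct_effect,
    causal_idx_exposure = which(b_x != 0),
    causal_idx_outcome = which(b_out != 0),
    causal_betas = b_x[b_x != 0],
    mediator_idx = which(b_m != 0), mediator_betas = b_m[b_m != 0],
    n_exposure = n_exposure, n_outcome = n_outcome, n_mediator = n_mediator,
    rho = rho, seed = seed), class = "mr_truth")
  structure(list(exposure_panel = exposure, outcome_panel = outcome,
                 mediator_panel = mediator, ld = ld, truth = truth),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle> m=%d SNPs, rho=%.2f, theta=%.3f (direct %.3f + a*b %.3f)\n",
    nrow(x$ld), x$truth$rho, x$truth$theta, x$truth$direct_effect,
    x$truth$a_effect * x$truth$b_effect))
  cat(sprintf("  exposure causal SNPs: %s\n",
              paste(x$truth$causal_idx_exposure, collapse = ", ")))
  invisible(x)
}

#' Simulate a colocalization scenario
#'
#' Generates two summary panels over one LD region under a named causal
#' configuration, sized so the causal SNP reaches an expected z-score of
#' `z_target`: `shared` puts one causal SNP in both traits; `distinct` uses
#' two causal SNPs in negligible LD (pairwise r^2 < 0.01); `trait1_only` /
#' `trait2_only` leave the other trait null; `null` leaves both null.
#'
#' @param scenario one of `"shared"`, `"distinct"`, `"trait1_only"`,
#'   `"trait2_only"`, `"null"`.
#' @param m SNP count (default 100).
#' @param rho AR(1) LD parameter (default 0.2).
#' @param z_target expected z at the causal SNP (> 0 unless `null`).
#' @param n per-cohort sample size (default 1e4).
#' @param region_kb region length in kb (default 200; keeps the region inside
#'   the 100 kb coloc window of the top SNP).
#' @param seed master seed.
#' @return list with `panel1`, `panel2` ([summary_panel()]s) and `truth`.
#' @export
simulate_coloc_scenario <- function(scenario = c("shared", "distinct",
                                                 "trait1_only", "trait2_only",
                                                 "null"),
                                    m = 100L, rho = 0.2, z_target = 8,
                                    n = 1e4, region_kb = 200, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario != "null" && z_target <= 0) {
    stop("z_target must be > 0 for non-null scenarios", call. = FALSE)
  }
  ld <- make_ld_ar1(m, rho, region_kb = region_kb)
  b <- z_target / sqrt(n)           # expected z at the causal SNP = b*sqrt(n)
  b1 <- b2 <- numeric(m)
  i1 <- as.integer(ceiling(m / 2))
  # second causal SNP far enough that r^2 = rho^(2*dist) < 0.01
  dist <- if (rho > 0) max(2L, ceiling(log(0.1) / log(rho)) + 1L) else 2L
  i2 <- min(m, i1 + dist)
  if (scenario == "shared") { b1[i1] <- b; b2[i1] <- b }
  if (scenario == "distinct") { b1[i1] <- b; b2[i2] <- b }
  if (scenario == "trait1_only") b1[i1] <- b
  if (scenario == "trait2_only") b2[i1] <- b
  seeds <- split_seed(seed, 3L)
  meta <- snp_metadata(ld, seeds[3L])
  p1 <- simulate_trait_sumstats(ld, b1, n, trait_type = "case_control",
                                seed = seeds[1L], trait_name = "trait1",
                                panel_kind = "gwas", snp_meta = meta)
  p2 <- simulate_trait_sumstats(ld, b2, n, trait_type = "quantitative",
                                seed = seeds[2L], trait_name = "trait2",
                                panel_kind = "eqtl", snp_meta = meta)
  truth <- structure(list(
    theta = NA_real_, a_effect = 0, b_effect = 0, direct_effect = 0,
    causal_idx_exposure = which(b2 != 0), causal_idx_outcome = which(b1 != 0),
    causal_betas = b, n_exposure = n, n_outcome = n, n_mediator = NA_real_,
    rho = rho, seed = seed, scenario = scenario), class = "mr_truth")
  list(panel1 = p1, panel2 = p2, truth = truth)
}

#' Write a simulated study to an output directory
#'
#' Emits the three panel TSVs, the LD matrix TSV and a plain-text truth file
#' (key: value) into `dir`.
#'
#' @param bundle a `study_bundle` from [simulate_mr_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(bundle$exposure_panel, file.path(dir, "exposure.tsv"))
  write_sumstats(bundle$outcome_panel, file.path(dir, "outcome.tsv"))
  write_sumstats(bundle$mediator_panel, file.path(dir, "mediator.tsv"))
  write_ld_matrix(bundle$ld, file.path(dir, "ld.tsv"))
  tr <- bundle$truth
  lines <- vapply(names(tr), function(k) {
    paste0(k, ": ", paste(format(tr[[k]], digits = 17), collapse = ","))
  }, character(1L))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
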