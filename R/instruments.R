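# Instrument selection and QC: p-value gates, top-SNP rule for eQTL panels,
# greedy LD clumping for pQTL panels, the F >= 10 weak-instrument filter and
# the confounder-association exclusion screen.

#' Instrument-strength F statistic
#'
#' For a single-SNP instrument the approximate F statistic is the squared
#' z-score of the SNP-exposure association, `(beta/se)^2`. Instruments with
#' F below 10 are conventionally treated as weak and excluded before
#' estimation.
#'
#' @param beta SNP-exposure effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return numeric F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) {
    stop("se must be > 0 for the F statistic", call. = FALSE)
  }
  (beta / se)^2
}

instrument_set <- function(rec, flags) {
  df <- data.frame(
    rec[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")],
    f_stat = f_statistic(rec$beta, rec$se),
    stringsAsFactors = FALSE)
  df <- cbind(df, flags)
  rownames(df) <- NULL
  class(df) <- c("instrument_set", "data.frame")
  df
}

empty_instrument_set <- function() {
  df <- data.frame(snp_id = character(), chrom = character(), pos = numeric(),
                   effect_allele = character(), other_allele = character(),
                   eaf = numeric(), beta = numeric(), se = numeric(),
                   pval = numeric(), n = numeric(), f_stat = numeric(),
                   top_snp = logical(), clump_index = integer(),
                   f_pass = logical(), confounder_excluded = logical(),
                   excluded_phenotype = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("instrument_set", "data.frame")
  df
}

#' Select the single top instrument from an eQTL panel
#'
#' The one-gene-one-instrument rule: keep the SNP with the most significant
#' exposure association, provided its p-value clears the eQTL inclusion
#' threshold (default p < 1e-4, strict). Ties on p are broken by smaller
#' position, then lexicographic SNP id.
#'
#' @param panel a [summary_panel()] of SNP-exposure associations.
#' @param p_threshold inclusion threshold (default `1e-4`, strict `<`).
#' @return an `instrument_set` with one row, or zero rows when no SNP
#'   qualifies.
#' @export
select_top_instrument <- function(panel, p_threshold = 1e-4) {
  stopifnot(inherits(panel, "summary_panel"))
  rec <- panel$records
  if (nrow(rec) == 0L) return(empty_instrument_set())
  ord <- order(rec$pval, rec$pos, rec$snp_id)
  top <- rec[ord[1L], , drop = FALSE]
  if (!(top$pval < p_threshold)) return(empty_instrument_set())
  inst <- instrument_set(top, data.frame(
    top_snp = TRUE, clump_index = NA_integer_,
    f_pass = f_statistic(top$beta, top$se) >= 10,
    confounder_excluded = FALSE, excluded_phenotype = NA_character_,
    stringsAsFactors = FALSE))
  inst
}

#' Greedy LD clumping of a summary panel
#'
#' Standard clumping semantics: restrict to SNPs with p below the inclusion
#' threshold, then repeatedly promote the remaining SNP with the smallest
#' p-value to index SNP and discard every remaining SNP within `window_kb`
#' of it whose squared correlation with it exceeds `r2_cutoff`. Index SNPs
#' are returned in selection order; the retained set is pairwise
#' `r^2 <= r2_cutoff` within the window by construction.
#'
#' @param panel a [summary_panel()] (typically pQTL, threshold p < 0.05).
#' @param ld an [ld_matrix()] covering every panel SNP.
#' @param p_threshold inclusion threshold (default 0.05, strict `<`).
#' @param r2_cutoff squared-correlation cutoff (default 0.001).
#' @param window_kb clumping window in kb around each index SNP
#'   (default 10000).
#' @return an `instrument_set`, one row per index SNP, `clump_index` giving
#'   selection order.
#' @export
ld_clump <- function(panel, ld, p_threshold = 0.05, r2_cutoff = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(panel, "summary_panel"), inherits(ld, "ld_matrix"))
  rec <- panel$records
  missing <- setdiff(rec$snp_id, rownames(ld))
  if (length(missing) > 0L) {
    stop("SNP(s) absent from the LD matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  rec <- rec[rec$pval < p_threshold, , drop = FALSE]
  if (nrow(rec) == 0L) return(empty_instrument_set())
  # deterministic processing order: ascending p, then pos, then id
  rec <- rec[order(rec$pval, rec$pos, rec$snp_id), , drop = FALSE]
  r2 <- unclass(ld)[rec$snp_id, rec$snp_id, drop = FALSE]^2
  alive <- rep(TRUE, nrow(rec))
  keep <- integer(0)
  while (any(alive)) {
    i <- which(alive)[1L]          # smallest remaining p
    keep <- c(keep, i)
    in_window <- abs(rec$pos - rec$pos[i]) <= window_kb * 1000
    alive <- alive & !(in_window & r2[i, ] > r2_cutoff)
    alive[i] <- FALSE
  }
  out <- rec[keep, , drop = FALSE]
  instrument_set(out, data.frame(
    top_snp = FALSE, clump_index = seq_along(keep),
    f_pass = f_statistic(out$beta, out$se) >= 10,
    confounder_excluded = FALSE,
    excluded_phenotype = NA_character_, stringsAsFactors = FALSE))
}

#' Read a confounder-association lookup table
#'
#' A local stand-in for GWAS-catalog queries (e.g. PhenoScanner): a TSV with
#' columns `snp_id`, `phenotype`, `pval` listing previously reported
#' SNP-phenotype associations.
#'
#' @param path file path.
#' @return data.frame of class `confounder_lookup`.
#' @export
read_confounder_lookup <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("snp_id", "phenotype", "pval")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("confounder lookup lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$pval <- as.numeric(df$pval)
  if (any(is.na(df$pval) | df$pval <= 0 | df$pval > 1)) {
    stop("confounder lookup p-values must lie in (0, 1]", call. = FALSE)
  }
  class(df) <- c("confounder_lookup", "data.frame")
  df
}

#' Exclude instruments with known confounder associations
#'
#' Drops any instrument whose SNP has a reported association with a screened
#' phenotype at p below the genome-wide threshold (default 5e-8, strict).
#' Removed instruments are kept in the returned object's
#' `"excluded"` attribute with the offending phenotype, and reported via
#' `message()`.
#'
#' @param instruments an `instrument_set`.
#' @param lookup a `confounder_lookup` (or data.frame with `snp_id`,
#'   `phenotype`, `pval`).
#' @param p_threshold exclusion threshold (default `5e-8`, strict `<`).
#' @return the filtered `instrument_set`; excluded rows (flagged, with
#'   `excluded_phenotype` filled) in `attr(, "excluded")`.
#' @export
exclude_confounded <- function(instruments, lookup, p_threshold = 5e-8) {
  stopifnot(inherits(instruments, "instrument_set"))
  if (nrow(instruments) == 0L || is.null(lookup) || nrow(lookup) == 0L) {
    attr(instruments, "excluded") <- empty_instrument_set()
    return(instruments)
  }
  hits <- lookup[lookup$pval < p_threshold, , drop = FALSE]
  bad <- instruments$snp_id %in% hits$snp_id
  excl <- instruments[bad, , drop = FALSE]
  if (nrow(excl) > 0L) {
    excl$confounder_excluded <- TRUE
    excl$excluded_phenotype <- vapply(excl$snp_id, function(id) {
      h <- hits[hits$snp_id == id, , drop = FALSE]
      h$phenotype[which.min(h$pval)]
    }, character(1L))
    message(sprintf("excluded instrument %s (association with %s, p=%.3g)",
                    excl$snp_id, excl$excluded_phenotype,
                    vapply(excl$snp_id, function(id) {
                      h <- hits[hits$snp_id == id, , drop = FALSE]
                      min(h$pval)
                    }, numeric(1L))))
  }
  out <- instruments[!bad, , drop = FALSE]
  class(out) <- c("instrument_set", "data.frame")
  class(excl) <- c("instrument_set", "data.frame")
  attr(out, "excluded") <- excl
  out
}

#' Drop weak instruments by the F >= 10 rule
#'
#' @param instruments an `instrument_set`.
#' @param f_min minimum F statistic (default 10; `F = f_min` passes).
#' @return the filtered `instrument_set`.
#' @export
filter_weak_instruments <- function(instruments, f_min = 10) {
  stopifnot(inherits(instruments, "instrument_set"))
  out <- instruments[instruments$f_stat >= f_min, , drop = FALSE]
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instrument(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    print.data.frame(x[, c("snp_id", "pos", "beta", "se", "pval", "f_stat",
                           "f_pass")], digits = 4)
  }
  invisible(x)
}
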