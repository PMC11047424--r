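SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n", "trait_type",
                  "case_fraction")
NUMERIC_COLS <- c("pos", "eaf", "beta", "se", "pval", "n", "case_fraction")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics panel
#'
#' A panel bundles one trait's per-SNP marginal association statistics for a
#' genomic region: effect sizes (log-OR for case-control traits, SD units for
#' quantitative traits), standard errors, two-sided p-values and per-SNP
#' sample sizes, keyed by SNP id and 1-based position.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `trait_type`, `case_fraction`. `eaf` and `case_fraction` may be `NA`.
#' @param trait_name name of the trait (gene, protein, disorder, ...).
#' @param tissue tissue label, or `"NA"` when not applicable.
#' @param panel_kind one of `"eqtl"`, `"pqtl"`, `"gwas"`, `"mediator"`.
#' @param validate if `TRUE` (default), reject panels with duplicate SNP ids,
#'   non-positive standard errors or mixed trait types.
#' @return object of class `summary_panel`.
#' @seealso [read_sumstats()], [validate_panel()]
#' @export
summary_panel <- function(records, trait_name, tissue = "NA",
                          panel_kind = c("eqtl", "pqtl", "gwas", "mediator"),
                          validate = TRUE) {
  panel_kind <- match.arg(panel_kind)
  missing_cols <- setdiff(SUMSTAT_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[, SUMSTAT_COLS]
  for (col in NUMERIC_COLS) records[[col]] <- as.numeric(records[[col]])
  for (col in c("snp_id", "chrom", "effect_allele", "other_allele",
                "trait_type")) {
    records[[col]] <- as.character(records[[col]])
  }
  rownames(records) <- NULL
  panel <- structure(
    list(trait_name = as.character(trait_name), tissue = as.character(tissue),
         panel_kind = panel_kind, records = records),
    class = "summary_panel")
  if (validate) {
    report <- validate_panel(panel)
    hard <- report[report$check %in% c("duplicate_id", "se_nonpositive",
                                       "allele", "pval_range"), , drop = FALSE]
    if (nrow(hard) > 0L) {
      stop("invalid summary panel: ", hard$message[1L], call. = FALSE)
    }
  }
  panel
}

#' @export
print.summary_panel <- function(x, ...) {
  cat(sprintf("<summary_panel> %s [%s] tissue=%s: %d SNPs\n",
              x$trait_name, x$panel_kind, x$tissue, nrow(x$records)))
  if (nrow(x$records) > 0L) {
    cat(sprintf("  min p = %.3g at %s\n", min(x$records$pval),
                x$records$snp_id[which.min(x$records$pval)]))
  }
  invisible(x)
}

#' @export
`[.summary_panel` <- function(x, i, ...) {
  x$records <- x$records[i, , drop = FALSE]
  rownames(x$records) <- NULL
  x
}

#' Validate a summary panel
#'
#' Reports (never raises) quality violations: duplicate SNP ids, non-positive
#' standard errors, invalid alleles, p-values outside (0, 1], and p-values
#' inconsistent with the two-sided normal tail of `|beta/se|` by more than 10%
#' relative error (only checked when p is large enough for the comparison to
#' be numerically meaningful).
#'
#' @param panel a [summary_panel()].
#' @param z_rel_tol relative tolerance for the p vs. beta/se consistency
#'   check (default 0.10).
#' @return data.frame with columns `snp_id`, `check`, `message`; zero rows for
#'   a clean panel.
#' @export
validate_panel <- function(panel, z_rel_tol = 0.10) {
  stopifnot(inherits(panel, "summary_panel"))
  rec <- panel$records
  out <- list()
  flag <- function(ids, check, msg) {
    out[[length(out) + 1L]] <<- data.frame(
      snp_id = ids, check = check, message = msg, stringsAsFactors = FALSE)
  }
  dup <- unique(rec$snp_id[duplicated(rec$snp_id)])
  if (length(dup) > 0L) {
    flag(dup, "duplicate_id", paste0("duplicate snp_id: ", dup))
  }
  bad_se <- !is.na(rec$se) & rec$se <= 0
  if (any(bad_se)) {
    flag(rec$snp_id[bad_se], "se_nonpositive", "se must be > 0")
  }
  bad_al <- !(rec$effect_allele %in% VALID_ALLELES) |
    !(rec$other_allele %in% VALID_ALLELES) |
    rec$effect_allele == rec$other_allele
  if (any(bad_al)) {
    flag(rec$snp_id[bad_al], "allele",
         "alleles must be distinct single bases in {A,C,G,T}")
  }
  bad_p <- !is.na(rec$pval) & (rec$pval <= 0 | rec$pval > 1)
  if (any(bad_p)) {
    flag(rec$snp_id[bad_p], "pval_range", "pval must be in (0, 1]")
  }
  # p/z consistency: two-sided normal reference; skip where se invalid or the
  # implied p underflows the comparison (|z| > 30).
  ok <- !is.na(rec$beta) & !is.na(rec$se) & rec$se > 0 & !is.na(rec$pval) &
    rec$pval > 0 & rec$pval <= 1
  z <- abs(rec$beta / rec$se)
  check <- ok & z < 30
  p_ref <- 2 * stats::pnorm(-z)
  incons <- check & abs(rec$pval - p_ref) > z_rel_tol * pmax(p_ref, 1e-300)
  if (any(incons)) {
    flag(rec$snp_id[incons], "pz_inconsistent",
         sprintf("pval %.3g inconsistent with |beta/se|=%.3f (expect %.3g)",
                 rec$pval[incons], z[incons], p_ref[incons]))
  }
  if (length(out) == 0L) {
    return(data.frame(snp_id = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a summary-statistics panel from TSV
#'
#' The dialect is UTF-8, tab-separated, header row naming all required
#' columns, `"."` (or empty) for missing values; scientific notation is
#' accepted everywhere. Panel metadata may be carried in `#key: value`
#' comment lines before the header.
#'
#' @param path file path.
#' @param trait_name,tissue,panel_kind metadata overrides; when `NULL`, taken
#'   from `#trait_name:` / `#tissue:` / `#panel_kind:` header comments, with
#'   fallbacks to the file name and `"gwas"`.
#' @return a [summary_panel()].
#' @export
read_sumstats <- function(path, trait_name = NULL, tissue = NULL,
                          panel_kind = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L) stop("empty summary-statistics file: ", path,
                              call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(SUMSTAT_COLS, header)
  if (length(missing_cols) > 0L) {
    stop("summary-statistics file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          header = TRUE, sep = "\t", na.strings = c(".", ""),
                          colClasses = "character", check.names = FALSE)
  for (col in NUMERIC_COLS) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   raw[bad[1L]], col, bad[1L] + 1L + length(meta_lines), path),
           call. = FALSE)
    }
    df[[col]] <- val
  }
  summary_panel(
    df,
    trait_name = trait_name %||% meta$trait_name %||%
      sub("\\.[^.]*$", "", basename(path)),
    tissue = tissue %||% meta$tissue %||% "NA",
    panel_kind = panel_kind %||% meta$panel_kind %||% "gwas")
}

#' Write a summary-statistics panel to TSV
#'
#' Inverse of [read_sumstats()]: metadata as `#key: value` comments, missing
#' values as `"."`, numbers at full precision so read-write roundtrips are
#' lossless.
#'
#' @param panel a [summary_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(panel, path) {
  stopifnot(inherits(panel, "summary_panel"))
  rec <- panel$records
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "." else format(v, digits = 17, scientific = NA)
      }, character(1L))
    } else {
      out <- ifelse(is.na(x), ".", as.character(x))
    }
    out
  }
  body <- do.call(cbind, lapply(rec, fmt))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#trait_name: ", panel$trait_name),
               paste0("#tissue: ", panel$tissue),
               paste0("#panel_kind: ", panel$panel_kind),
               paste(SUMSTAT_COLS, collapse = "\t")), con)
  if (nrow(rec) > 0L) {
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Construct an LD correlation matrix
#'
#' Square symmetric matrix of pairwise genotype correlations (r, not r^2)
#' with unit diagonal, keyed by SNP id. Optional per-SNP base-pair positions
#' ride along as an attribute for window-aware operations.
#'
#' @param r numeric square matrix of correlations in `[-1, 1]`.
#' @param snp_ids character vector, one id per row/column.
#' @param pos optional integer positions (1-based) aligned with `snp_ids`.
#' @param sym_tol maximum tolerated asymmetry `max|r - t(r)|`; asymmetry
#'   below `sym_tol` is symmetrized by averaging, above it is an error.
#' @return matrix of class `ld_matrix` with `snp_ids` as dimnames.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r), pos = NULL, sym_tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(snp_ids) || length(snp_ids) != nrow(r)) {
    stop("snp_ids must match LD matrix dimension", call. = FALSE)
  }
  asym <- max(abs(r - t(r)))
  if (asym > sym_tol) {
    stop(sprintf("LD matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, sym_tol), call. = FALSE)
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-6) {
    stop("LD matrix diagonal must be 1 (max deviation ",
         format(max(abs(diag(r) - 1)), digits = 3), ")", call. = FALSE)
  }
  diag(r) <- 1
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(as.character(snp_ids), as.character(snp_ids))
  if (!is.null(pos)) {
    if (length(pos) != nrow(r)) stop("pos length must match dimension",
                                     call. = FALSE)
    attr(r, "pos") <- as.numeric(pos)
  }
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs (%s ... %s)\n", nrow(x),
              rownames(x)[1L], rownames(x)[nrow(x)]))
  invisible(x)
}

#' Read an LD matrix from TSV
#'
#' Expects a header row of SNP ids and one labeled row per SNP. Asymmetry up
#' to 1e-8 is symmetrized by averaging; larger asymmetry, a non-unit
#' diagonal (beyond 1e-6), or a non-square body is an error.
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("LD matrix file is not square: ", nrow(m), " rows x ", ncol(m),
         " columns", call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column SNP ids disagree", call. = FALSE)
  }
  storage.mode(m) <- "double"
  ld_matrix(m, rownames(m))
}

#' Write an LD matrix to TSV
#'
#' @param ld an [ld_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- unclass(ld)
  attr(m, "pos") <- NULL
  df <- as.data.frame(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
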