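test_that("F statistic follows (beta/se)^2 and is monotone", {
  expect_equal(f_statistic(0.2, 0.05), 16)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_error(f_statistic(0.1, 0), "se")
  expect_error(f_statistic(0.1, -1), "se")
  # monotone increasing in |beta| at fixed se, decreasing in se at fixed beta
  betas <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(betas, 0.05)) > 0))
  ses <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(0.2, ses)) < 0))
})

test_that("weak instruments (F < 10) are excluded, F = 10 passes", {
  # F = 9.99 (just under the gate) and F = 10 exactly
  se <- 0.1
  weak <- make_panel("rs1", beta = sqrt(9.99) * se, se = se)
  inst <- select_top_instrument(weak, p_threshold = 1)
  expect_false(inst$f_pass)
  expect_identical(nrow(filter_weak_instruments(inst)), 0L)
  boundary <- make_panel("rs2", beta = sqrt(10) * se, se = se)
  inst2 <- select_top_instrument(boundary, p_threshold = 1)
  expect_true(inst2$f_pass)
  expect_identical(nrow(filter_weak_instruments(inst2)), 1L)
})

test_that("top-instrument rule takes the argmin p under a strict threshold", {
  p <- make_panel(c("rs1", "rs2", "rs3"), beta = c(0.5, 0.3, 0.4),
                  se = 0.1, pval = c(1e-6, 1e-3, 5e-5))
  top <- select_top_instrument(p)
  expect_identical(top$snp_id, "rs1")
  expect_true(top$top_snp)

  none <- make_panel(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.1,
                     pval = c(1e-4, 2e-4))     # 1e-4 is NOT < 1e-4
  expect_identical(nrow(select_top_instrument(none)), 0L)

  # exact p tie: lower position wins, then lexicographic id
  tie <- make_panel(c("rsB", "rsA"), beta = c(0.5, 0.5), se = 0.1,
                    pval = c(1e-6, 1e-6), pos = c(2e6, 1e6))
  expect_identical(select_top_instrument(tie)$snp_id, "rsA")
  tie2 <- make_panel(c("rsB", "rsA"), beta = c(0.5, 0.5), se = 0.1,
                     pval = c(1e-6, 1e-6), pos = c(1e6, 1e6))
  expect_identical(select_top_instrument(tie2)$snp_id, "rsA")
})

test_that("greedy clumping keeps the most significant SNP per LD block", {
  # two SNPs in strong LD: only the smaller-p one survives
  ld <- make_ld_ar1(2, 0.9)       # r^2 = 0.81
  p <- make_panel(rownames(ld), beta = c(0.6, 0.4), se = 0.1,
                  pval = c(1e-8, 1e-4),
                  pos = attr(ld, "pos"), panel_kind = "pqtl")
  got <- ld_clump(p, ld)
  expect_identical(got$snp_id, rownames(ld)[1])
  expect_identical(got$clump_index, 1L)

  # single qualifying SNP is retained
  single <- make_panel("s01", beta = 0.4, se = 0.1, pval = 1e-3,
                       panel_kind = "pqtl")
  ld1 <- ld_matrix(matrix(1), "s01", pos = 1e6)
  expect_identical(nrow(ld_clump(single, ld1)), 1L)

  # SNP missing from the LD matrix is a lookup error naming it
  p2 <- make_panel(c("s01", "zz9"), beta = c(0.4, 0.4), se = 0.1,
                   pval = c(1e-3, 1e-3), panel_kind = "pqtl")
  expect_error(ld_clump(p2, make_ld_ar1(2, 0, snp_prefix = "s")), "zz9")
})

test_that("clumping matches a brute-force oracle on random panels", {
  set.seed(2024)
  for (case in 1:300) {
    m <- sample(2:8, 1)
    ld <- random_ld(m)
    rec <- make_records(rownames(ld), beta = rnorm(m, sd = 0.3),
                        se = runif(m, 0.02, 0.2),
                        pos = attr(ld, "pos"))
    panel <- summary_panel(rec, "prot", panel_kind = "pqtl")
    cutoff <- sample(c(0.001, 0.1, 0.5), 1)
    window <- sample(c(2, 10000), 1)
    got <- ld_clump(panel, ld, p_threshold = 0.5, r2_cutoff = cutoff,
                    window_kb = window)
    want <- clump_oracle(rec, unclass(ld)[,], 0.5, cutoff, window)
    expect_identical(got$snp_id, want)
    # retained set is pairwise r^2 <= cutoff within the window
    if (nrow(got) > 1L) {
      r2 <- unclass(ld)[got$snp_id, got$snp_id]^2
      near <- abs(outer(got$pos, got$pos, "-")) <= window * 1000
      diag(near) <- FALSE
      expect_true(all(r2[near] <= cutoff))
    }
  }
})

test_that("clump output is invariant to input row order", {
  set.seed(7)
  m <- 8
  ld <- random_ld(m)
  rec <- make_records(rownames(ld), beta = rnorm(m, sd = 0.3), se = 0.05,
                      pos = attr(ld, "pos"))
  base <- ld_clump(summary_panel(rec, "p", panel_kind = "pqtl"), ld,
                   r2_cutoff = 0.1, p_threshold = 0.9)
  for (k in 1:10) {
    perm <- rec[sample(m), , drop = FALSE]
    got <- ld_clump(summary_panel(perm, "p", panel_kind = "pqtl"), ld,
                    r2_cutoff = 0.1, p_threshold = 0.9)
    expect_identical(got$snp_id, base$snp_id)
  }
})

test_that("confounder screen removes only sub-threshold associations", {
  p <- make_panel(c("rs1", "rs2", "rs3"), beta = c(0.5, 0.5, 0.5), se = 0.1,
                  pval = c(1e-6, 1e-7, 1e-8), panel_kind = "pqtl")
  ld <- ld_matrix(diag(3), c("rs1", "rs2", "rs3"),
                  pos = p$records$pos)
  inst <- ld_clump(p, ld)
  lookup <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    phenotype = c("disorderA", "disorderB", "disorderC"),
    pval = c(1e-9, 1e-7, 0.5))           # strict: 1e-7 is retained at 5e-8
  expect_message(kept <- exclude_confounded(inst, lookup), "disorderA")
  expect_setequal(kept$snp_id, c("rs2", "rs3"))
  excl <- attr(kept, "excluded")
  expect_identical(excl$snp_id, "rs1")
  expect_identical(excl$excluded_phenotype, "disorderA")
  expect_true(excl$confounder_excluded)

  # empty lookup leaves the set unchanged
  same <- exclude_confounded(inst, NULL)
  expect_identical(same$snp_id, inst$snp_id)
})

test_that("confounder lookup reader validates its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tphenotype\tpval", "rs1\tdisorderA\t1e-9"), path)
  lk <- read_confounder_lookup(path)
  expect_identical(lk$pval, 1e-9)
  writeLines(c("snp_id\tpval", "rs1\t1e-9"), path)
  expect_error(read_confounder_lookup(path), "phenotype")
})
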