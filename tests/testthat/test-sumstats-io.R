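write_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("summary statistics round-trip field-exactly and honour column maps", {
  f <- write_fixture(c(
    "snp_id\teffect_allele\tother_allele\tbeta\tse\tpval\teaf\tn",
    "rs1\ta\tg\t0.1\t0.02\t1e-9\t0.3\t30000",
    "rs2\tC\tT\t-0.05\t0.01\t0.5\t0.6\t30000"))
  rec <- read_sumstats(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$effect_allele, c("A", "C"))  # uppercased
  out <- tempfile(fileext = ".tsv")
  write_sumstats(rec, out)
  rec2 <- read_sumstats(out)
  expect_equal(rec2, rec, ignore_attr = TRUE)

  # same content with renamed columns and comma delimiter parses identically
  g <- write_fixture(c("rsid,ea,oa,b,stderr,p,eaf,n",
                       "rs1,a,g,0.1,0.02,1e-9,0.3,30000",
                       "rs2,C,T,-0.05,0.01,0.5,0.6,30000"), ".csv")
  rec3 <- read_sumstats(g, column_map = c(snp_id = "rsid",
                                          effect_allele = "ea",
                                          other_allele = "oa", beta = "b",
                                          se = "stderr", pval = "p"))
  expect_equal(rec3, rec, ignore_attr = TRUE)
})

test_that("malformed rows are rejected by row number; duplicates and missing columns error", {
  f <- write_fixture(c(
    "snp_id\teffect_allele\tother_allele\tbeta\tse\tpval",
    "rs1\tA\tG\t0.1\t0.02\t1e-9",
    "rs2\tA\tG\t0.1\tNA\t0.5",
    "rs3\tA\tA\t0.1\t0.02\t0.5"))
  expect_warning(rec <- read_sumstats(f), "rows: 2, 3")
  expect_equal(rec$snp_id, "rs1")
  expect_equal(attr(rec, "rejected_rows"), c(2L, 3L))

  dup <- write_fixture(c("snp_id\teffect_allele\tother_allele\tbeta\tse\tpval",
                         "rs1\tA\tG\t0.1\t0.02\t1e-9",
                         "rs1\tA\tG\t0.2\t0.02\t1e-9"))
  expect_error(read_sumstats(dup), "duplicate snp_id.*rs1")
  nobeta <- write_fixture(c("snp_id\teffect_allele\tother_allele\tse\tpval",
                            "rs1\tA\tG\t0.02\t1e-9"))
  expect_error(read_sumstats(nobeta), "missing required column")
})

test_that("instrument selection applies both significance gates", {
  exposure <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                         pval = c(1e-9, 1e-6, 1e-9, 1e-9))
  outcome <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                        pval = c(0.2, 0.3, 1e-9))
  expect_equal(select_instruments(exposure, outcome), "rs1")
  # rs2 fails the exposure gate, rs3 the outcome gate, rs4 is absent
  expect_warning(
    ids <- select_instruments(exposure, outcome, p_exp_max = 1e-12),
    "no SNPs")
  expect_length(ids, 0)
})

test_that("palindromic allele pairs are flagged ambiguous", {
  expect_true(flag_ambiguous("A", "T"))
  expect_true(flag_ambiguous("C", "G"))
  expect_false(flag_ambiguous("A", "G"))
  expect_equal(flag_ambiguous(c("T", "G", "c"), c("A", "C", "g")),
               c(TRUE, TRUE, TRUE))
})

test_that("harmonization keeps aligned pairs, sign-flips swapped pairs, errors on mismatch", {
  exposure <- data.frame(snp_id = c("rs1", "rs2"),
                         effect_allele = c("A", "A"),
                         other_allele = c("G", "G"),
                         beta = c(0.10, 0.10), se = 0.02, pval = 1e-9,
                         eaf = 0.3, n = 1000)
  same <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                     beta = 0.05, se = 0.01, pval = 0.2, eaf = 0.3, n = 2000)
  swapped <- data.frame(snp_id = "rs2", effect_allele = "G",
                        other_allele = "A", beta = 0.05, se = 0.01,
                        pval = 0.2, eaf = 0.3, n = 2000)
  h <- harmonize(exposure, rbind(same, swapped))
  expect_equal(h$beta_out, c(0.05, -0.05))
  expect_equal(h$eaf_out, c(0.3, 0.7))
  expect_equal(h$flipped, c(FALSE, TRUE))

  mismatch <- data.frame(snp_id = "rs1", effect_allele = "A",
                         other_allele = "C", beta = 0.05, se = 0.01,
                         pval = 0.2, eaf = 0.3, n = 2000)
  expect_error(harmonize(exposure[1, ], mismatch), "allele mismatch.*rs1")
})

test_that("harmonization is involutive: re-aligning an aligned pair is the identity", {
  sim <- simulate_sumstats(sumstats_scenario(J = 12, swap_fraction = 0.5),
                           seed = 7)
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome table already on the exposure orientation
  aligned <- data.frame(snp_id = h1$snp_id, effect_allele = h1$effect_allele,
                        other_allele = h1$other_allele, beta = h1$beta_out,
                        se = h1$se_out, pval = h1$pval_out, eaf = h1$eaf_out,
                        n = h1$n_out)
  h2 <- harmonize(sim$exposure, aligned)
  expect_equal(h2$beta_out, h1$beta_out, tolerance = 1e-12)
  # double swap restores the original sign
  reswapped <- transform(aligned, effect_allele = other_allele,
                         other_allele = effect_allele, beta = -beta,
                         eaf = 1 - eaf)
  h3 <- harmonize(sim$exposure, reswapped)
  expect_equal(h3$beta_out, h1$beta_out, tolerance = 1e-12)
})

test_that("Steiger filter keeps direction-consistent instruments and is scale invariant", {
  iv <- data.frame(snp_id = c("fwd", "tie", "rev"),
                   beta_exp = c(10 * 0.01, 0.05, 3 * 0.01),
                   se_exp = 0.01,
                   beta_out = c(2 * 0.01, 0.05, 15 * 0.01),
                   se_out = 0.01,
                   n_exp = 30000, n_out = 30000,
                   ambiguous = FALSE, steiger_fail = FALSE,
                   confounder_associated = FALSE, steiger_p = NA_real_)
  out <- steiger_filter(iv)
  # t-based r2: forward 10 vs 2, tie exactly equal, reverse 3 vs 15
  expect_equal(out$steiger_fail, c(FALSE, TRUE, TRUE))
  # r2 computed independently confirms the forward ordering
  r2 <- function(b, se, n) (b / se)^2 / ((b / se)^2 + n - 2)
  expect_gt(r2(0.1, 0.01, 30000), r2(0.02, 0.01, 30000))

  # jointly rescaling one trait's beta and SE leaves decisions unchanged
  scaled <- iv
  scaled$beta_exp <- iv$beta_exp * 7.3
  scaled$se_exp <- iv$se_exp * 7.3
  expect_equal(steiger_filter(scaled)$steiger_fail, out$steiger_fail)

  no_n <- iv; no_n$n_out <- NA
  expect_warning(res <- steiger_filter(no_n), "missing sample size")
  expect_false(any(res$steiger_fail))
})

test_that("confounder exclusion list splits full and conservative sets", {
  sim <- simulate_sumstats(sumstats_scenario(J = 18, swap_fraction = 0),
                           seed = 3)
  ivs <- steiger_filter(harmonize(sim$exposure, sim$outcome))
  listed <- ivs$snp_id[1:7]
  f <- tempfile()
  writeLines(c("# annotation lines are ignored",
               paste(listed, "some_trait")), f)
  res <- apply_exclusion_list(ivs, f)
  expect_equal(nrow(res$full), 18L)
  expect_equal(nrow(res$conservative), 11L)
  expect_setequal(res$excluded, listed)

  # empty list: conservative equals full
  res0 <- apply_exclusion_list(ivs, character(0))
  expect_equal(res0$conservative, res0$full)
  # unknown SNP: informational only, no change
  expect_message(res1 <- apply_exclusion_list(ivs, "rs_not_here"),
                 "not among instruments")
  expect_equal(nrow(res1$conservative), 18L)
})

test_that("validity filters commute: flags are independent of application order", {
  sim <- simulate_sumstats(sumstats_scenario(J = 15, swap_fraction = 0.3),
                           seed = 11)
  listed <- sim$exposure$snp_id[c(2, 5, 9)]
  a <- apply_exclusion_list(steiger_filter(
    harmonize(sim$exposure, sim$outcome)), listed)$ivs
  b <- steiger_filter(apply_exclusion_list(
    harmonize(sim$exposure, sim$outcome), listed)$ivs)
  cols <- c("snp_id", "ambiguous", "steiger_fail", "confounder_associated")
  expect_equal(a[cols], b[cols])
  expect_equal(iv_analysis_set(a, "conservative"),
               iv_analysis_set(b, "conservative"))
})

test_that("harmonized instrument tables round-trip through TSV", {
  sim <- simulate_sumstats(sumstats_scenario(J = 6, n_invalid = 2), seed = 2)
  ivs <- steiger_filter(harmonize(sim$exposure, sim$outcome))
  f <- tempfile(fileext = ".tsv")
  write_harmonized_ivs(ivs, f)
  back <- read_harmonized_ivs(f)
  expect_equal(back$beta_out, ivs$beta_out, tolerance = 1e-12)
  expect_equal(back$steiger_fail, ivs$steiger_fail)
})
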