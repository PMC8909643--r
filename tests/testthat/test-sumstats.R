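test_that("reading a TSV yields one record per valid row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\tA\tG\t0.2\t0.10\t0.02\t1e-9\t50000",
               "rs2\tC\tT\t0.6\t-0.05\t0.01\t2e-8\t50000"), path)
  tab <- read_sumstats(path, "t2dm", "binary")
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$beta, c(0.10, -0.05))
  expect_identical(attr(tab, "trait_type"), "binary")
})

test_that("invalid rows are rejected with a reason and valid rows survive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\tA\tG\t0.2\t0.10\t-0.1\t1e-9\t50000",
               "rs2\tC\tT\t0.6\t-0.05\t0.01\t2e-8\t50000",
               "rs3\tA\tA\t0.5\t0.02\t0.01\t0.5\t50000"), path)
  tab <- read_sumstats(path, "t2dm", "binary")
  expect_equal(tab$snp, "rs2")
  rej <- attr(tab, "rejected")
  expect_setequal(rej$snp, c("rs1", "rs3"))
  expect_identical(rej$reason[rej$snp == "rs1"], "nonpositive se")
  expect_identical(rej$reason[rej$snp == "rs3"], "identical alleles")
})

test_that("a file missing a required column raises a format error naming it", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tse\tpval\tn",
               "rs1\tA\tG\t0.2\t0.02\t1e-9\t50000"), path)
  expect_error(read_sumstats(path, "x", "binary"), "beta")
})

test_that("duplicate snp ids keep the smallest-p row", {
  tab <- make_table(c("rs1", "rs1", "rs2"), beta = c(0.1, 0.2, 0.3),
                    se = c(0.01, 0.01, 0.01), pval = c(1e-4, 1e-8, 1e-6))
  expect_equal(tab$snp, c("rs1", "rs2"))
  expect_equal(tab$beta[tab$snp == "rs1"], 0.2)
  expect_true("duplicate snp id (larger p-value)" %in%
                attr(tab, "rejected")$reason)
})

test_that("write/read round trip is lossless including missing fields", {
  tab <- make_table(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                    se = c(0.01, 0.02, 0.03), pval = c(1e-10, 1e-5, 0.2),
                    trait_name = "sbp")
  tab$eaf[2] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, "sbp", "continuous")
  for (col in c("snp", "effect_allele", "other_allele", "eaf", "beta",
                "se", "pval", "n"))
    expect_equal(back[[col]], tab[[col]], info = col)
  expect_true(is.na(back$eaf[2]))
  expect_error(write_sumstats(tab[0, ], path))
})

test_that("harmonization aligns swapped and strand-complement alleles", {
  exp <- make_table("rs1", beta = 0.10, se = 0.01, ea = "A", oa = "G",
                    eaf = 0.2, trait_name = "x")
  # swapped alleles: sign flip, frequency reflected
  out_swap <- make_table("rs1", beta = 0.05, se = 0.01, ea = "G", oa = "A",
                         eaf = 0.8, trait_name = "y")
  h <- harmonize(exp, out_swap)
  expect_equal(h$by, -0.05)
  expect_equal(h$eafy, 0.2)
  # strand complement T/C of A/G: aligned without sign flip
  out_comp <- make_table("rs1", beta = 0.05, se = 0.01, ea = "T", oa = "C",
                         eaf = 0.2, trait_name = "y")
  h2 <- harmonize(exp, out_comp)
  expect_equal(h2$by, 0.05)
  # complement-swapped C/T: sign flip
  out_cs <- make_table("rs1", beta = 0.05, se = 0.01, ea = "C", oa = "T",
                       eaf = 0.8, trait_name = "y")
  h3 <- harmonize(exp, out_cs)
  expect_equal(h3$by, -0.05)
})

test_that("ambiguous palindromic SNPs are dropped with a reason", {
  exp <- make_table(c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.01, 0.01),
                    ea = c("A", "A"), oa = c("T", "G"), eaf = c(0.50, 0.2),
                    trait_name = "x")
  out <- make_table(c("rs1", "rs2"), beta = c(0.05, 0.07),
                    se = c(0.01, 0.01), ea = c("A", "A"), oa = c("T", "G"),
                    eaf = c(0.50, 0.2), trait_name = "y")
  h <- harmonize(exp, out)
  expect_equal(h$snp_ids, "rs2")
  expect_match(h$dropped$reason[h$dropped$snp == "rs1"],
               "palindromic, ambiguous frequency")
  h_drop <- harmonize(exp, out, palindrome_policy = "drop")
  expect_equal(h_drop$snp_ids, "rs2")
})

test_that("unambiguous palindromic SNPs align by frequency", {
  exp <- make_table("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                    eaf = 0.15, trait_name = "x")
  # same strand, frequency agrees: no flip
  out_same <- make_table("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T",
                         eaf = 0.18, trait_name = "y")
  expect_equal(harmonize(exp, out_same)$by, 0.05)
  # effect allele reported on the other side: frequency disagrees -> flip
  out_flip <- make_table("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T",
                         eaf = 0.85, trait_name = "y")
  expect_equal(harmonize(exp, out_flip)$by, -0.05)
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(42)
  J <- 20
  snp <- sprintf("rs%03d", 1:J)
  exp <- make_table(snp, beta = rnorm(J, 0, 0.05), se = rep(0.01, J),
                    eaf = runif(J, 0.1, 0.4), trait_name = "x")
  out <- make_table(snp, beta = rnorm(J, 0, 0.02), se = rep(0.01, J),
                    eaf = runif(J, 0.1, 0.4), trait_name = "y")
  h1 <- harmonize(exp, out)
  # already-aligned inputs pass through unchanged
  expect_equal(h1$bx[, 1], exp$beta)
  expect_equal(h1$by, out$beta)
  # negating exposure betas and swapping its allele labels leaves the
  # products bx * by invariant
  exp_flip <- make_table(snp, beta = -exp$beta, se = exp$se, ea = "G",
                         oa = "A", eaf = 1 - exp$eaf, trait_name = "x")
  h2 <- harmonize(exp_flip, out)
  expect_equal(h2$bx[, 1] * h2$by, h1$bx[, 1] * h1$by)
})

test_that("empty overlap is an error", {
  exp <- make_table("rs1", beta = 0.1, se = 0.01, trait_name = "x")
  out <- make_table("rs9", beta = 0.1, se = 0.01, trait_name = "y")
  expect_error(harmonize(exp, out), "shared")
})
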