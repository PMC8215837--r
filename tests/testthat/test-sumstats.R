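test_that("reading a well-formed table ingests all rows and normalizes alleles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tEAF\tBETA\tSE\tP\tN",
               "rs1\t1\t100\ta\tg\t0.2\t0.10\t0.02\t5e-7\t10000",
               "rs2\t1\t200\tC\tT\t0.4\t-0.05\t0.01\t6e-7\t10000",
               "rs3\t2\t300\tG\tA\t0.3\t0.02\t0.02\t0.3\t10000"),
             path)
  tab <- read_sumstats(path, trait_name = "bmi")
  expect_s3_class(tab, "sumstat_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_dropped"), 0L)
  expect_equal(tab$effect_allele[1], "A")
  expect_equal(tab$other_allele[1], "G")
  expect_equal(attr(tab, "trait_name"), "bmi")
})

test_that("rows with non-positive SE or unparsable beta are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,CHR,BP,A1,A2,EAF,BETA,SE,P,N",
               "rs1,1,100,A,G,0.2,0.10,0.02,5e-7,10000",
               "rs2,1,200,C,T,0.4,-0.05,0,6e-7,10000",
               "rs3,2,300,G,A,0.3,xyz,0.02,0.3,10000"),
             path)
  tab <- read_sumstats(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_dropped"), 2L)
})

test_that("missing mandatory columns and empty files are clear errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tBETA\tSE", "rs1\tA\t0.1\t0.02"), path)
  expect_error(read_sumstats(path), "other_allele")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_sumstats(empty), "input error")
})

test_that("palindromic detection follows the strand-ambiguity definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "input error")
})

test_that("harmonize flips the outcome sign on swapped alleles", {
  exp_tab <- make_table("rs1", 0.10, 0.02, ea = "A", oa = "G", name = "X")
  out_tab <- make_table("rs1", -0.05, 0.03, ea = "G", oa = "A", name = "Y")
  h <- harmonize(exp_tab, out_tab, "rs1")
  expect_equal(h$beta_out, 0.05)
  expect_equal(unname(h$beta_exp[1, 1]), 0.10)
  expect_equal(nrow(h$dropped), 0L)
})

test_that("strand-complement alleles are reconciled, with sign flip when swapped", {
  exp_tab <- make_table("rs1", 0.10, 0.02, ea = "A", oa = "G", name = "X")
  # same variant reported on the opposite strand: T/C == A/G
  out_same <- make_table("rs1", 0.07, 0.03, ea = "T", oa = "C", name = "Y")
  h1 <- harmonize(exp_tab, out_same, "rs1")
  expect_equal(h1$beta_out, 0.07)
  # opposite strand and swapped: C/T -> flip
  out_flip <- make_table("rs1", 0.07, 0.03, ea = "C", oa = "T", name = "Y")
  h2 <- harmonize(exp_tab, out_flip, "rs1")
  expect_equal(h2$beta_out, -0.07)
})

test_that("palindromic, direct-effect, missing and mismatched variants drop with reasons", {
  exp_tab <- make_table(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                        beta = rep(0.1, 5), se = rep(0.02, 5),
                        ea = c("A", "A", "A", "A", "A"),
                        oa = c("G", "T", "G", "G", "G"), name = "X")
  out_tab <- make_table(c("rs1", "rs2", "rs3", "rs5"),
                        beta = c(0.05, 0.05, 0.30, 0.05),
                        se = c(0.03, 0.03, 0.03, 0.03),
                        ea = c("A", "A", "A", "A"),
                        oa = c("G", "T", "G", "C"),
                        pvalue = c(0.1, 0.1, 1e-9, 0.1), name = "Y")
  h <- harmonize(exp_tab, out_tab, c("rs1", "rs2", "rs3", "rs4", "rs5"))
  expect_equal(h$variant_ids, "rs1")
  reasons <- setNames(h$dropped$reason, h$dropped$variant_id)
  expect_equal(reasons[["rs2"]], "palindromic")
  expect_equal(reasons[["rs3"]], "direct_effect")
  expect_equal(reasons[["rs4"]], "missing_in_outcome")
  expect_equal(reasons[["rs5"]], "allele_mismatch")
  # drop accounting: retained + dropped = requested
  expect_equal(length(h$variant_ids) + nrow(h$dropped), 5L)
})

test_that("all variants dropped is an analysis error listing reasons", {
  exp_tab <- make_table("rs1", 0.1, 0.02, ea = "A", oa = "T", name = "X")
  out_tab <- make_table("rs1", 0.05, 0.03, ea = "A", oa = "T", name = "Y")
  expect_error(harmonize(exp_tab, out_tab, "rs1"), "palindromic")
})

test_that("harmonization is idempotent and sign-symmetric", {
  set.seed(31)
  J <- 20
  ids <- sprintf("rs%02d", 1:J)
  ea <- sample(c("A", "C"), J, TRUE)
  oa <- ifelse(ea == "A", "G", "T")
  bx <- rnorm(J, 0, 0.1); by <- rnorm(J, 0, 0.05)
  exp_tab <- make_table(ids, bx, 0.02, ea = ea, oa = oa, name = "X")
  out_tab <- make_table(ids, by, 0.03, ea = ea, oa = oa, name = "Y")
  h1 <- harmonize(exp_tab, out_tab, ids, direct_effect_p = 0)
  # already aligned: nothing changes
  expect_equal(h1$beta_out, by[match(h1$variant_ids, ids)])
  # flip alleles and beta of some outcome records: identical harmonized set
  flip <- seq(1, J, by = 3)
  out_df <- as.data.frame(out_tab)
  out_df[flip, c("effect_allele", "other_allele")] <-
    out_df[flip, c("other_allele", "effect_allele")]
  out_df$beta[flip] <- -out_df$beta[flip]
  out_flipped <- as_sumstat_table(out_df, trait_name = "Y")
  h2 <- harmonize(exp_tab, out_flipped, ids, direct_effect_p = 0)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$variant_ids, h1$variant_ids)
})

test_that("missing outcome p-values are recomputed for the direct-effect filter", {
  exp_tab <- make_table(c("rs1", "rs2"), c(0.1, 0.1), c(0.02, 0.02), name = "X")
  out_df <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
                       pos = c(100L, 200L), effect_allele = "A",
                       other_allele = "G", eaf = 0.3,
                       beta = c(0.30, 0.01), se = c(0.03, 0.03),
                       pvalue = NA, n = 1e5)
  out_tab <- as_sumstat_table(out_df, trait_name = "Y")
  h <- harmonize(exp_tab, out_tab, c("rs1", "rs2"))
  expect_equal(h$variant_ids, "rs2")  # rs1: |z|=10 -> p < 5e-8
  expect_equal(h$dropped$reason, "direct_effect")
})

test_that("round trip through write_sumstats/read_sumstats preserves records", {
  tab <- make_table(c("rs1", "rs2"), c(0.1, -0.2), c(0.02, 0.03), name = "X")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_name = "X")
  expect_equal(back$beta, tab$beta)
  expect_equal(back$variant_id, tab$variant_id)
})

test_that("write_harmonized emits the aligned table and a drop log", {
  exp_tab <- make_table(c("rs1", "rs2"), c(0.1, 0.1), c(0.02, 0.02),
                        ea = c("A", "A"), oa = c("G", "T"), name = "X")
  out_tab <- make_table(c("rs1", "rs2"), c(0.05, 0.05), c(0.03, 0.03),
                        ea = c("A", "A"), oa = c("G", "T"), name = "Y")
  h <- harmonize(exp_tab, out_tab, c("rs1", "rs2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  main <- read.delim(path)
  drops <- read.delim(paste0(path, ".drops.tsv"))
  expect_equal(main$variant_id, "rs1")
  expect_equal(drops$reason, "palindromic")
})
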