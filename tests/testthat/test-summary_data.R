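test_that("read_gwas_table parses well-formed rows and normalizes alleles", {
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("a", "C", "g"),
                   other_allele = c("g", "T", "a"),
                   eaf = c(0.2, 0.4, 0.5),
                   beta = c(0.1, -0.05, 0.02),
                   se = c(0.01, 0.02, 0.01),
                   pvalue = c(1e-10, 1e-2, 5e-2),
                   n = 1000, chrom = "1", pos = c(100, 200, 300))
  path <- write_tsv_fixture(df, tempfile(fileext = ".tsv"))
  tab <- read_gwas_table(path)
  expect_s3_class(tab, "gwas_assoc")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$effect_allele, c("A", "C", "G"))
  expect_equal(tab$other_allele, c("G", "T", "A"))
  expect_equal(tab$beta, df$beta)
  expect_equal(nrow(attr(tab, "rejected")), 0)
})

test_that("read_gwas_table rejects invariant-violating rows with diagnostics", {
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "A", "G"),
                   eaf = c(0.2, 0.3, 0.3, 1.2),
                   beta = c(0.1, 0.1, 0.1, 0.1),
                   se = c(0.01, 0, 0.01, 0.01),
                   pvalue = c(1e-5, 1e-5, 1e-5, 1e-5))
  path <- write_tsv_fixture(df, tempfile(fileext = ".tsv"))
  expect_warning(tab <- read_gwas_table(path), "rs2.*se not strictly positive")
  rej <- attr(tab, "rejected")
  expect_equal(rej$variant_id, c("rs2", "rs3", "rs4"))
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_match(rej$reason[2], "effect_allele equals other_allele")
  expect_match(rej$reason[3], "eaf")
  expect_equal(tab$variant_id, "rs1")
})

test_that("read_gwas_table errors on missing columns and empty files", {
  df <- data.frame(variant_id = "rs1", effect_allele = "A",
                   other_allele = "G", beta = 0.1, se = 0.01)
  path <- write_tsv_fixture(df, tempfile(fileext = ".tsv"))
  expect_error(read_gwas_table(path), "missing mandatory column.*pvalue")
  empty <- tempfile(fileext = ".tsv")
  writeLines("variant_id\teffect_allele\tother_allele\tbeta\tse\tpvalue", empty)
  expect_error(read_gwas_table(empty), "empty")
  expect_error(read_gwas_table(tempfile()), "not found")
})

test_that("custom dialects map columns and unknown fields fail", {
  df <- data.frame(SNP = "rs1", A1 = "a", A2 = "g", b = 0.1,
                   std_err = 0.01, p = 0.001)
  path <- write_tsv_fixture(df, tempfile(fileext = ".tsv"))
  d <- gwas_dialect(variant_id = "SNP", effect_allele = "A1",
                    other_allele = "A2", beta = "b", se = "std_err",
                    pvalue = "p")
  tab <- read_gwas_table(path, d)
  expect_equal(tab$effect_allele, "A")
  expect_equal(tab$se, 0.01)
  expect_error(gwas_dialect(nonsense = "x"), "unknown dialect field")
})

test_that("harmonize aligns matching, swapped and strand-flipped alleles", {
  ex <- make_assoc(c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele  = c("G", "G", "G", "G"),
                   beta = 0.1, eaf = 0.3)
  ou <- make_assoc(c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "G", "T", "A"),
                   other_allele  = c("G", "A", "C", "C"),
                   beta = 0.05, eaf = c(0.3, 0.7, 0.3, 0.3))
  set <- harmonize(ex, ou)
  inst <- set$instruments
  # v1 unchanged
  expect_equal(inst$action[inst$variant_id == "v1"], "unchanged")
  expect_equal(inst$wald_ratio[inst$variant_id == "v1"], 0.5)
  # v2 swapped: beta negated
  expect_equal(inst$wald_ratio[inst$variant_id == "v2"], -0.5)
  expect_equal(inst$eaf_outcome[inst$variant_id == "v2"], 0.3)
  # v3 on the complementary strand (T/C -> A/G): kept with original sign
  expect_equal(inst$action[inst$variant_id == "v3"], "allele_flipped")
  expect_equal(inst$wald_ratio[inst$variant_id == "v3"], 0.5)
  # v4 irreconcilable (A/C vs A/G): dropped
  expect_false("v4" %in% inst$variant_id)
  expect_match(set$dropped$reason[set$dropped$variant_id == "v4"],
               "irreconcilable")
  expect_equal(nrow(inst) + nrow(set$dropped), 4)
})

test_that("palindromic variants are kept only with concordant informative eafs", {
  ex <- make_assoc(c("p1", "p2", "p3", "p4"),
                   effect_allele = "A", other_allele = "T",
                   beta = 0.1, eaf = c(0.50, 0.30, 0.30, 0.30))
  ou <- make_assoc(c("p1", "p2", "p3", "p4"),
                   effect_allele = "A", other_allele = "T",
                   beta = 0.05, eaf = c(0.30, 0.30, 0.70, NA))
  set <- harmonize(ex, ou)
  inst <- set$instruments
  # p1: exposure eaf exactly 0.5 -> strand indeterminate -> dropped
  expect_false("p1" %in% inst$variant_id)
  # p2: both 0.30, same side, informative -> aligned
  expect_equal(inst$action[inst$variant_id == "p2"], "palindromic_aligned")
  expect_equal(inst$wald_ratio[inst$variant_id == "p2"], 0.5)
  # p3: opposite sides of 0.5 -> dropped
  expect_false("p3" %in% inst$variant_id)
  # p4: missing outcome eaf -> dropped
  expect_false("p4" %in% inst$variant_id)
  expect_equal(nrow(inst) + nrow(set$dropped), 4)
})

test_that("zero exposure beta drops the variant with a diagnostic", {
  ex <- make_assoc(c("v1", "v2"), beta = c(0, 0.1))
  ou <- make_assoc(c("v1", "v2"), beta = 0.05)
  set <- harmonize(ex, ou)
  expect_equal(set$instruments$variant_id, "v2")
  expect_match(set$dropped$reason, "zero exposure beta")
})

test_that("harmonization is idempotent on generated data", {
  sim <- generate_two_sample(mr_truth(theta = 0.3, n_snps = 40,
                                      palindromic_fraction = 0.3, seed = 11))
  set1 <- harmonize(sim$exposure, sim$outcome)
  inst <- set1$instruments
  # rebuild already-aligned exposure/outcome tables and harmonize again
  rebuild <- function(beta, se, eaf) {
    make_assoc(inst$variant_id, effect_allele = inst$effect_allele,
               other_allele = inst$other_allele, beta = beta, se = se,
               eaf = eaf)
  }
  set2 <- harmonize(rebuild(inst$beta_exposure, inst$se_exposure,
                            inst$eaf_exposure),
                    rebuild(inst$beta_outcome, inst$se_outcome,
                            inst$eaf_outcome))
  expect_equal(set2$instruments$variant_id, inst$variant_id)
  expect_equal(set2$instruments$wald_ratio, inst$wald_ratio)
  expect_equal(set2$instruments$wald_se, inst$wald_se)
  expect_equal(nrow(set2$dropped), 0)
})

test_that("flipping every outcome record's alleles and beta sign preserves Wald ratios", {
  sim <- generate_two_sample(mr_truth(theta = 0.3, n_snps = 40,
                                      palindromic_fraction = 0.3, seed = 12))
  ou2 <- sim$outcome
  tmp <- ou2$effect_allele
  ou2$effect_allele <- ou2$other_allele
  ou2$other_allele <- tmp
  ou2$beta <- -ou2$beta
  ou2$eaf <- 1 - ou2$eaf
  set1 <- harmonize(sim$exposure, sim$outcome)
  set2 <- harmonize(sim$exposure, ou2)
  expect_equal(set1$instruments$variant_id, set2$instruments$variant_id)
  expect_equal(set1$instruments$wald_ratio, set2$instruments$wald_ratio)
})

test_that("instrument sets round-trip through TSV + JSON sidecar", {
  sim <- generate_two_sample(mr_truth(theta = 0.2, n_snps = 12, seed = 3))
  set <- harmonize(sim$exposure, sim$outcome,
                   exposure_name = "X", outcome_name = "Y")
  path <- tempfile(fileext = ".tsv")
  write_instrument_set(set, path)
  back <- read_instrument_set(path)
  expect_equal(back$exposure_name, "X")
  expect_equal(back$instruments$wald_ratio, set$instruments$wald_ratio)
  expect_equal(back$instruments$beta_exposure, set$instruments$beta_exposure)
  expect_equal(back$selection_record$n_retained,
               set$selection_record$n_retained)
})
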