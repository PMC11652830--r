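test_that("read_sumstats parses, drops unparseable rows, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "variant_id\tchrom\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\t1\t1000\tA\tG\t0.30\t0.10\t0.01\t1e-10\t1000",
    "rs2\t2\t2000\tC\tT\t0.20\t0.05\t0.02\t1e-05\t1000",
    "rs3\t3\t3000\tG\tA\t0.40\t-0.07\t0.01\t1e-08\t1000"), path)
  ds <- read_sumstats(path, trait_label = "toy")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$beta, c(0.10, 0.05, -0.07))
  expect_equal(attr(ds, "n_dropped"), 0L)

  # NA se on line 2 -> dropped and counted
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "variant_id\teffect_allele\tother_allele\tbeta\tse\tpval",
    "rs1\tA\tG\t0.10\t0.01\t1e-10",
    "rs2\tC\tT\t0.05\tNA\t1e-05",
    "rs3\tG\tA\t-0.07\t0.01\t1e-08"), bad)
  expect_message(ds2 <- read_sumstats(bad), "1 record\\(s\\) dropped")
  expect_equal(nrow(ds2), 2L)
  expect_equal(attr(ds2, "n_dropped"), 1L)

  # round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ds, out)
  ds3 <- read_sumstats(out, trait_label = "toy")
  expect_equal(as.data.frame(ds3), as.data.frame(ds))

  # column_map and missing-column error
  cm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,EA,OA,BETA,SE,P",
               "rs1,A,G,0.1,0.01,1e-10"), cm)
  ds4 <- read_sumstats(cm, column_map = c(variant_id = "SNP",
                                          effect_allele = "EA",
                                          other_allele = "OA",
                                          beta = "BETA", se = "SE",
                                          pval = "P"))
  expect_equal(ds4$beta, 0.1)
  expect_error(read_sumstats(cm), "missing mandatory column")
})

test_that("summary_dataset enforces its invariants", {
  df <- data.frame(variant_id = "rs1", effect_allele = "A",
                   other_allele = "G", beta = 0.1, se = 0.01, pval = 1e-9)
  expect_s3_class(summary_dataset(df), "summary_dataset")
  expect_error(summary_dataset(transform(df, se = -1)), "se")
  expect_error(summary_dataset(transform(df, other_allele = "A")),
               "effect_allele equals other_allele")
  expect_error(summary_dataset(rbind(df, df)), "duplicate variant_id")
  expect_error(summary_dataset(transform(df, pval = 0)), "pval")
})

test_that("harmonise aligns swapped, strand-flipped and palindromic variants", {
  ids <- c("rs1", "rs2", "rs3", "rs4", "rs5")
  exp_ds <- make_ds(ids,
                    ea = c("A", "A", "A", "A", "A"),
                    oa = c("G", "G", "T", "G", "G"),
                    beta = c(0.10, 0.12, 0.08, 0.09, 0.11),
                    eaf = c(0.30, 0.30, 0.50, 0.30, 0.30),
                    label = "exp")
  out_ds <- make_ds(c("rs1", "rs2", "rs3", "rs4"),
                    ea = c("G", "T", "A", "A"),
                    oa = c("A", "C", "T", "C"),
                    beta = c(-0.05, 0.07, 0.02, 0.04),
                    eaf = c(0.70, 0.30, 0.50, 0.30),
                    label = "out")
  h <- harmonise(exp_ds, out_ds, ids, palindromic_eaf_window = 0.08)
  # rs1: alleles swapped -> sign flip
  expect_equal(h$by[h$rows$variant_id == "rs1"], 0.05)
  # rs2: complementary strand (T/C vs A/G) -> kept as-is
  expect_equal(h$by[h$rows$variant_id == "rs2"], 0.07)
  # rs3: palindromic with eaf = 0.5 -> dropped
  expect_equal(h$dropped$reason[h$dropped$variant_id == "rs3"],
               "palindromic_ambiguous")
  # rs4: A/C vs A/G irreconcilable -> allele_mismatch
  expect_equal(h$dropped$reason[h$dropped$variant_id == "rs4"],
               "allele_mismatch")
  # rs5: absent from outcome -> missing
  expect_equal(h$dropped$reason[h$dropped$variant_id == "rs5"], "missing")
  # conservation: rows + dropped = instruments
  expect_equal(nrow(h$rows) + nrow(h$dropped), length(ids))
})

test_that("harmonise is idempotent and sign round-trips on allele swap", {
  ids <- c("rs1", "rs2", "rs3")
  exp_ds <- make_ds(ids, ea = "A", oa = "G", beta = c(0.1, -0.2, 0.15),
                    label = "exp")
  out_ds <- make_ds(ids, ea = "A", oa = "G", beta = c(0.05, 0.07, -0.01),
                    label = "out")
  h1 <- harmonise(exp_ds, out_ds, ids)
  # rebuild datasets from the harmonised rows and harmonise again
  out2 <- make_ds(h1$rows$variant_id, ea = h1$rows$effect_allele,
                  oa = h1$rows$other_allele, beta = h1$by,
                  se = h1$sy, eaf = h1$rows$eaf, label = "out")
  h2 <- harmonise(exp_ds, out2, h1$rows$variant_id)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$bx, h1$bx)
  expect_equal(nrow(h2$dropped), 0L)

  # swapping outcome alleles (and negating beta) recovers the same by
  swapped <- make_ds(ids, ea = "G", oa = "A", beta = -c(0.05, 0.07, -0.01),
                     eaf = 0.7, label = "out")
  h3 <- harmonise(exp_ds, swapped, ids)
  expect_equal(h3$by, h1$by)
})

test_that("palindromic variants with missing eaf are dropped", {
  exp_ds <- make_ds("rs1", ea = "A", oa = "T", beta = 0.1, eaf = NA,
                    label = "exp")
  out_ds <- make_ds("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.2,
                    label = "out")
  h <- harmonise(exp_ds, out_ds, "rs1")
  expect_equal(h$dropped$reason, "palindromic_ambiguous")
})

test_that("unambiguous palindromic variants are oriented by eaf concordance", {
  # exposure eaf 0.2, outcome eaf 0.8: the outcome record is on the other
  # strand (its effect allele is really the complement) -> beta negated
  exp_ds <- make_ds("rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.2,
                    label = "exp")
  out_ds <- make_ds("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.8,
                    label = "out")
  h <- harmonise(exp_ds, out_ds, "rs1")
  expect_equal(h$by, -0.05)
  # concordant frequencies: kept as-is
  out2 <- make_ds("rs1", ea = "A", oa = "T", beta = 0.05, eaf = 0.25,
                  label = "out")
  expect_equal(harmonise(exp_ds, out2, "rs1")$by, 0.05)
})

test_that("beta_to_or matches the closed form and inverts", {
  r <- beta_to_or(0, 0.1)
  expect_equal(r$or, 1)
  expect_equal(r$ci_low, exp(-1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(r$ci_high, exp(1.959964 * 0.1), tolerance = 1e-6)
  # se -> 0 collapses the CI
  r2 <- beta_to_or(log(2), 0)
  expect_equal(c(r2$or, r2$ci_low, r2$ci_high), rep(2, 3))
  # inverse identity
  for (b in c(-1, 0, 1)) expect_equal(log(beta_to_or(b, 0.1)$or), b)
})
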