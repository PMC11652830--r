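test_that("simulation_config validates its inputs", {
  expect_error(simulation_config(seed = 1, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulation_config(seed = 1, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(simulation_config(a = 0.4), "seed")
  expect_s3_class(simulation_config(seed = 1), "simulation_config")
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- simulation_config(seed = 77)
  s1 <- simulate_mediation_gwas(cfg)
  s2 <- simulate_mediation_gwas(cfg)
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
  expect_identical(s1$truth$true_beta_y, s2$truth$true_beta_y)
  s3 <- simulate_mediation_gwas(simulation_config(seed = 78))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("IVW recovers the total effect in the noiseless limit", {
  # n -> infinity: observed betas converge to the structural truths
  cfg <- simulation_config(a = 0.4, b = 0.5, c_prime = 0.1,
                           n_x = 1e12, n_m = 1e12, n_y = 1e12, seed = 4)
  sim <- simulate_mediation_gwas(cfg)
  h <- hset_from_sim(sim$exposure, sim$outcome, sim$truth$x_instruments)
  expect_lt(abs(ivw(h)$beta - 0.3), 1e-3)
})

test_that("estimator error shrinks as sample sizes grow", {
  # mean absolute error over 8 seeds at each sample size
  errs <- vapply(c(1e4, 1e5, 1e6), function(n) {
    mean(vapply(1:8, function(s) {
      cfg <- simulation_config(n_x = n, n_m = n, n_y = n, seed = 100 + s)
      sim <- simulate_mediation_gwas(cfg)
      h <- hset_from_sim(sim$exposure, sim$outcome, sim$truth$x_instruments)
      abs(ivw(h)$beta - sim$truth$total)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("pleiotropy modes shift the Egger intercept as designed", {
  # directional pleiotropy with positive mean: intercept positive in >= 90%
  # (reduced to 40 reps for runtime; the mean is well above its se)
  pos <- vapply(1:40, function(i) {
    cfg <- simulation_config(n_instruments_x = 50, n_instruments_m = 0,
                             pleiotropy_mode = "directional",
                             pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                             seed = 1000 + i)
    sim <- simulate_mediation_gwas(cfg)
    h <- hset_from_sim(sim$exposure, sim$outcome, sim$truth$x_instruments)
    mr_egger(h)$intercept > 0
  }, logical(1))
  expect_gte(mean(pos), 0.9)
  # balanced pleiotropy: intercept consistent with zero
  cfg <- simulation_config(n_instruments_x = 100, n_instruments_m = 0,
                           pleiotropy_mode = "balanced",
                           pleiotropy_sd = 0.01, seed = 6)
  sim <- simulate_mediation_gwas(cfg)
  h <- hset_from_sim(sim$exposure, sim$outcome, sim$truth$x_instruments)
  e <- mr_egger(h)
  expect_lt(abs(e$intercept), 3 * e$intercept_se)
})

test_that("planted outliers distort the outcome effect as configured", {
  cfg <- simulation_config(n_instruments_x = 30, n_instruments_m = 0,
                           n_outliers = 2, outlier_multiplier = 10,
                           seed = 19)
  sim <- simulate_mediation_gwas(cfg)
  expect_length(sim$truth$outlier_ids, 2L)
  oi <- match(sim$truth$outlier_ids, sim$truth$variant_id)
  ratio <- sim$truth$true_beta_y[oi] / sim$truth$true_beta_x[oi]
  expect_equal(ratio, rep(10 * sim$truth$total, 2), tolerance = 1e-12)
})

test_that("write_fixture_suite emits parseable named fixtures with truth", {
  dir <- withr::local_tempdir()
  manifest <- write_fixture_suite(dir)
  names <- manifest$file
  for (fx in c("consensus", "egger_line", "outlier", "mediation")) {
    expect_true(any(grepl(fx, names)), info = fx)
  }
  # every summary-statistic fixture parses losslessly
  for (f in grep("\\.tsv$", names, value = TRUE)) {
    if (f == "MANIFEST.tsv") next
    ds <- read_sumstats(file.path(dir, f))
    expect_s3_class(ds, "summary_dataset")
    expect_equal(attr(ds, "n_dropped"), 0L)
  }
  # the egger_line fixture reproduces its sidecar truth exactly
  exp_ds <- read_sumstats(file.path(dir, "egger_line_exposure.tsv"),
                          trait_label = "x")
  out_ds <- read_sumstats(file.path(dir, "egger_line_outcome.tsv"),
                          trait_label = "y")
  h <- harmonise(exp_ds, out_ds, exp_ds$variant_id)
  r <- mr_egger(h)
  truth <- jsonlite::read_json(file.path(dir, "egger_line_truth.json"))
  expect_equal(r$intercept, truth$intercept, tolerance = 1e-10)
  expect_equal(r$beta, truth$slope, tolerance = 1e-10)
  # the planted-outlier fixture is flagged by MR-PRESSO
  ho <- harmonise(read_sumstats(file.path(dir, "outlier_exposure.tsv"),
                                trait_label = "x"),
                  read_sumstats(file.path(dir, "outlier_outcome.tsv"),
                                trait_label = "y"),
                  sprintf("out%02d", 1:31))
  pr <- mr_presso(ho, n_sim = 1000, seed = 2)
  expect_equal(pr$outlier_ids, "out16")
})
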