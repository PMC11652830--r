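test_that("wald_ratio matches the closed form and flags null instruments", {
  r <- wald_ratio(0.1, 0.005, 0.05, 0.01)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  r0 <- wald_ratio(0.1, 0.005, 0, 0.01)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pval, 1)
  expect_error(wald_ratio(0, 0.005, 0.05, 0.01), "null instrument")
})

test_that("first- and second-order Wald se agree for strong instruments", {
  # sx/|bx| = 0.04 < 0.05 -> within 1%
  bx <- 0.25; sx <- 0.01; by <- 0.05; sy <- 0.02
  se1 <- wald_ratio(bx, sx, by, sy)$se
  se2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)$se
  expect_lt(abs(se2 - se1) / se2, 0.01)
  # and the second-order form is always the larger
  expect_gt(se2, se1)
})

test_that("IVW: consensus, frozen oracle values, and single-SNP reduction", {
  # exact consensus: all ratios 0.5 -> beta = 0.5, Q = 0, fixed == random
  h <- make_hset(c(0.1, 0.2), c(0.005, 0.005), c(0.05, 0.10),
                 c(0.01, 0.02))
  expect_equal(ivw(h, "fixed")$beta, 0.5)
  expect_equal(ivw(h, "random")$se, ivw(h, "fixed")$se)

  # 3-instrument set: weighted least squares through the origin
  h3 <- make_hset(c(0.1, 0.2, 0.15), rep(0.005, 3),
                  c(0.03, 0.05, 0.04), rep(0.01, 3))
  r <- ivw(h3, "fixed")
  expect_equal(r$beta, 0.262069, tolerance = 1e-6)
  expect_equal(r$se, 0.03713907, tolerance = 1e-6)
  o <- oracle_wls(h3$bx, h3$by, h3$sy)
  expect_equal(r$beta, o$coefs[1], tolerance = 1e-12)

  # single instrument reduces to the Wald ratio
  h1 <- make_hset(0.1, 0.005, 0.05, 0.01)
  w <- wald_ratio(0.1, 0.005, 0.05, 0.01)
  expect_equal(ivw(h1, "fixed")$beta, w$beta)
  expect_equal(ivw(h1, "fixed")$se, w$se)
})

test_that("IVW equals the WLS oracle on random sets (n <= 10)", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(3:10, 1)
    h <- make_hset(rnorm(n, 0.1, 0.05), runif(n, 0.003, 0.01),
                   rnorm(n, 0.03, 0.02), runif(n, 0.005, 0.02))
    o <- oracle_wls(h$bx, h$by, h$sy)
    expect_equal(ivw(h, "fixed")$beta, o$coefs[1], tolerance = 1e-10)
    expect_equal(ivw(h, "fixed")$se, sqrt(o$vcov_unscaled[1, 1]),
                 tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the se exactly by sqrt(Q/(n-1))", {
  set.seed(21)
  n <- 8
  h <- make_hset(runif(n, 0.05, 0.2), rep(0.005, n),
                 rnorm(n, 0.05, 0.03), rep(0.01, n))
  fixed <- ivw(h, "fixed")
  q <- cochran_q(h)$q
  expect_equal(ivw(h, "random")$se,
               fixed$se * sqrt(max(1, q / (n - 1))))
})

test_that("MR-Egger recovers an exact affine relationship", {
  h <- make_hset(c(0.1, 0.2, 0.3), rep(0.005, 3),
                 0.02 + 0.3 * c(0.1, 0.2, 0.3), c(0.01, 0.02, 0.015))
  r <- mr_egger(h)
  expect_equal(r$intercept, 0.02, tolerance = 1e-12)
  expect_equal(r$beta, 0.30, tolerance = 1e-12)
  # exact fit: residual Q = 0, inflation clipped at 1
  o <- oracle_wls(h$bx, h$by, h$sy, intercept = TRUE)
  expect_equal(o$q, 0, tolerance = 1e-20)
  expect_equal(r$se, sqrt(o$vcov_unscaled[2, 2]), tolerance = 1e-10)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), rep(0.005, 2),
                                  c(0.03, 0.06), rep(0.01, 2))),
               "insufficient instruments")
})

test_that("Egger slope equals IVW when residuals are weight-orthogonal", {
  # by = 0.3*bx + e with sum(e) = 0 and sum(bx*e) = 0 under equal weights
  bx <- c(1, 2, 3) / 10
  e <- c(1, -2, 1) * 0.001
  h <- make_hset(bx, rep(0.005, 3), 0.3 * bx + e, rep(0.01, 3))
  expect_equal(mr_egger(h)$beta, ivw(h, "fixed")$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h)$intercept, 0, tolerance = 1e-12)
})

test_that("weighted median interpolates the ratio distribution at 0.5", {
  # equal weights: bx = 1, sy = 1 -> w_i identical; p_i = {1/6, 1/2, 5/6}
  h <- make_hset(rep(1, 3), rep(0.001, 3), c(0.1, 0.2, 0.9), rep(1, 3))
  r <- weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(r$beta, 0.2)
  # all ratios equal -> estimate exact, bootstrap se small
  hc <- make_hset(rep(0.1, 4), rep(1e-4, 4), rep(0.05, 4), rep(1e-4, 4))
  rc <- weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(rc$beta, 0.5, tolerance = 1e-3)
  expect_lt(rc$se, 0.01)
  expect_error(weighted_median(h, n_boot = 10),
               "explicit seed")
})

test_that("weighted median resists up to 50% invalid weight", {
  # 10 valid instruments (ratio 0.3), 4 invalid (ratio 1.5), equal strength:
  # valid weight 10/14 > 50%
  set.seed(31)
  n <- 14
  bx_true <- rep(0.15, n)
  ratio <- c(rep(0.3, 10), rep(1.5, 4))
  sx <- rep(0.004, n); sy <- rep(0.004, n)
  h <- make_hset(rnorm(n, bx_true, sx), sx,
                 rnorm(n, ratio * bx_true, sy), sy)
  r <- weighted_median(h, n_boot = 500, seed = 31)
  expect_lt(abs(r$beta - 0.3), 0.05)
  # the estimate always lies within the ratio range
  ratios <- h$by / h$bx[, 1]
  expect_gte(r$beta, min(ratios))
  expect_lte(r$beta, max(ratios))
})

test_that("estimators are order-invariant and sign-equivariant", {
  set.seed(41)
  n <- 9
  h <- make_hset(runif(n, 0.05, 0.25), rep(0.005, n),
                 rnorm(n, 0.04, 0.02), runif(n, 0.008, 0.02))
  perm <- sample(n)
  hp <- subset_harmonised(h, perm)
  expect_equal(ivw(hp)$beta, ivw(h)$beta)
  expect_equal(mr_egger(hp)$beta, mr_egger(h)$beta)
  expect_equal(weighted_median(hp, 200, seed = 5)$beta,
               weighted_median(h, 200, seed = 5)$beta)
  hn <- h; hn$by <- -h$by
  expect_equal(ivw(hn)$beta, -ivw(h)$beta)
  expect_equal(mr_egger(hn)$beta, -mr_egger(h)$beta)
  expect_equal(weighted_median(hn, 200, seed = 5)$beta,
               -weighted_median(h, 200, seed = 5)$beta)
})

test_that("results_table has the standard layout", {
  h <- make_hset(c(0.1, 0.2, 0.3), rep(0.005, 3),
                 c(0.03, 0.07, 0.10), rep(0.01, 3))
  tab <- results_table(list(ivw(h), mr_egger(h),
                            weighted_median(h, 100, seed = 1)),
                       outcome = "y")
  expect_equal(names(tab),
               c("method", "exposure", "outcome", "n_snp", "beta", "se",
                 "or", "ci_low", "ci_high", "pval", "egger_intercept",
                 "egger_intercept_pval"))
  expect_equal(tab$method, c("ivw_random", "mr_egger", "weighted_median"))
  expect_true(is.na(tab$egger_intercept[1]))
  expect_false(is.na(tab$egger_intercept[2]))
  expect_equal(tab$or, exp(tab$beta))
})
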