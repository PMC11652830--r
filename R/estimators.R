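# Univariable two-sample MR estimators.
#
# All estimators consume a harmonised_set with a single exposure (column 1
# of bx/sx) and return an mr_result.  Weights throughout are 1/sy^2, the
# standard second-order-ignored inverse-variance weights.

.z95 <- 1.959964

mr_result <- function(method, beta, se, n_snp, pval = NULL, df = NULL,
                      intercept = NULL, intercept_se = NULL,
                      intercept_pval = NULL, exposure = NA_character_) {
  crit <- if (is.null(df)) .z95 else stats::qt(0.975, df)
  if (is.null(pval)) {
    z <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
            else 2 * stats::pt(-abs(z), df)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, n_snp = n_snp,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = intercept_pval,
                 exposure = exposure),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  or <- beta_to_or(x$beta, x$se)
  cat(sprintf("%s (n_snp = %d): beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", or$or, or$ci_low, or$ci_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

.check_single_exposure <- function(h) {
  if (ncol(h$bx) != 1L) {
    stop("estimator requires a single-exposure harmonised set; use mvmr_ivw")
  }
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = by / bx`.  The default standard error is the first-order delta
#' approximation `|sy / bx|` (ignores the exposure uncertainty); set
#' `second_order = TRUE` for
#' `sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)`.
#'
#' @param bx,sx Exposure beta and standard error.
#' @param by,sy Outcome beta and standard error.
#' @param second_order Use the second-order delta standard error.
#' @return An `mr_result` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) stop("null instrument: exposure beta is zero")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    abs(sy / bx)
  }
  mr_result("wald_ratio", beta, se, n_snp = 1L)
}

# Internal IVW core shared by the estimator and leave-one-out / PRESSO.
.ivw_core <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  list(beta = beta, se_fixed = 1 / sqrt(sxx),
       q = sum(w * (by - beta * bx)^2))
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/sy^2`.  `mode = "fixed"` uses the plain standard
#' error `1/sqrt(sum(bx^2/sy^2))`; `mode = "random"` (default) multiplies it
#' by `sqrt(max(1, Q/(n-1)))` (multiplicative random effects), where Q is
#' Cochran's Q at the fixed-effect estimate.
#'
#' @param h A single-exposure `harmonised_set` with >= 1 instrument.
#' @param mode `"random"` (default) or `"fixed"`.
#' @return An `mr_result` with method `"ivw_random"` or `"ivw_fixed"`.
#' @export
ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  .check_single_exposure(h)
  n <- n_instruments(h)
  if (n < 1L) stop("no instruments")
  core <- .ivw_core(h$bx[, 1L], h$by, h$sy)
  se <- core$se_fixed
  if (mode == "random" && n >= 2L) {
    se <- se * sqrt(max(1, core$q / (n - 1)))
  }
  mr_result(paste0("ivw_", mode), core$beta, se, n_snp = n,
            exposure = h$exposure_labels[1L])
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept, weights `1/sy^2`, after orienting every row so the exposure
#' beta is non-negative.  The slope is the causal estimate; the intercept,
#' its standard error and p-value form the directional-pleiotropy test.
#' Coefficient covariance is the unscaled WLS covariance inflated by
#' `max(1, Q/(n-2))` where Q is the weighted residual sum of squares;
#' p-values and CIs use the t distribution with n-2 df.
#'
#' @param h A single-exposure `harmonised_set` with >= 3 instruments.
#' @return An `mr_result` with method `"mr_egger"` and intercept fields.
#' @export
mr_egger <- function(h) {
  .check_single_exposure(h)
  n <- n_instruments(h)
  if (n < 3L) stop("insufficient instruments for Egger (need >= 3)")
  h <- orient_positive(h)
  bx <- h$bx[, 1L]; by <- h$by; w <- 1 / h$sy^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coefs <- unname(drop(solve(xtwx, crossprod(X, w * by))))
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  infl <- max(1, q / (n - 2))
  vc <- solve(xtwx) * infl
  ses <- unname(sqrt(diag(vc)))
  df <- n - 2L
  int_p <- 2 * stats::pt(-abs(coefs[1L] / ses[1L]), df)
  mr_result("mr_egger", coefs[2L], ses[2L], n_snp = n, df = df,
            intercept = coefs[1L], intercept_se = ses[1L],
            intercept_pval = int_p, exposure = h$exposure_labels[1L])
}

# Weighted-median point estimate from ratios and weights.
.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Per-instrument Wald ratios `by/bx` with inverse-variance weights
#' `bx^2/sy^2`; the estimate is the weighted median (linear interpolation of
#' the sorted ratios at cumulative standardized weight 0.5).  The standard
#' error comes from a parametric bootstrap: `by` and `bx` are resampled from
#' normal distributions centred on their estimates, and the weighted median
#' recomputed.  Consistent when valid instruments carry more than half the
#' weight.
#'
#' @param h A single-exposure `harmonised_set` with >= 3 instruments.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed for the bootstrap (mandatory, for
#'   reproducibility).
#' @return An `mr_result` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 5000, seed) {
  .check_single_exposure(h)
  if (missing(seed)) stop("weighted_median requires an explicit seed")
  n <- n_instruments(h)
  if (n < 3L) stop("insufficient instruments for weighted median (need >= 3)")
  bx <- h$bx[, 1L]; sx <- h$sx[, 1L]; by <- h$by; sy <- h$sy
  est <- .weighted_median_point(by / bx, bx^2 / sy^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(n, bx, sx)
      bys <- stats::rnorm(n, by, sy)
      .weighted_median_point(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
  })
  mr_result("weighted_median", est, stats::sd(boots), n_snp = n,
            exposure = h$exposure_labels[1L])
}

#' Format a list of MR results as the standard results table
#'
#' One row per result with columns `method`, `exposure`, `outcome`, `n_snp`,
#' `beta`, `se`, `or`, `ci_low`, `ci_high` (OR scale), `pval`,
#' `egger_intercept`, `egger_intercept_pval` (NA where inapplicable).
#'
#' @param results A list of `mr_result` objects.
#' @param outcome Outcome label recorded in each row.
#' @return A data frame.
#' @export
results_table <- function(results, outcome = NA_character_) {
  do.call(rbind, lapply(results, function(r) {
    or <- beta_to_or(r$beta, r$se)
    data.frame(method = r$method,
               exposure = r$exposure,
               outcome = outcome,
               n_snp = r$n_snp,
               beta = r$beta, se = r$se,
               or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               pval = r$pval,
               egger_intercept = if (is.null(r$intercept)) NA_real_
                                 else r$intercept,
               egger_intercept_pval = if (is.null(r$intercept_pval)) NA_real_
                                      else r$intercept_pval,
               stringsAsFactors = FALSE)
  }))
}
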