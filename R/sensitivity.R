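# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum((by - beta_hat * bx)^2 / sy^2)` with df = n - 1 for a
#' through-the-origin (IVW) estimate or n - 2 for the Egger residual Q; the
#' p-value is the chi-square upper tail.
#'
#' @param h A single-exposure `harmonised_set` with >= 2 instruments.
#' @param beta_hat Causal estimate at which residuals are evaluated
#'   (default: the fixed-effect IVW estimate).
#' @param df Residual degrees of freedom; default `n - 1`.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, beta_hat = NULL,
                      df = n_instruments(h) - 1L) {
  .check_single_exposure(h)
  n <- n_instruments(h)
  if (n < 2L) stop("Cochran's Q needs >= 2 instruments")
  if (is.null(beta_hat)) beta_hat <- .ivw_core(h$bx[, 1L], h$by, h$sy)$beta
  q <- sum((h$by - beta_hat * h$bx[, 1L])^2 / h$sy^2)
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect with each instrument omitted in turn.  A
#' row is flagged when omitting that instrument flips the estimate's sign or
#' moves it outside the full-set 95% CI.
#'
#' @param h A single-exposure `harmonised_set` with >= 2 instruments.
#' @param method `"ivw"` (default; random-effects), `"ivw_fixed"`, or
#'   `"egger"`.
#' @return Data frame with one row per omitted instrument:
#'   `left_out`, `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   `flagged`.
#' @export
leave_one_out <- function(h, method = c("ivw", "ivw_fixed", "egger")) {
  method <- match.arg(method)
  .check_single_exposure(h)
  n <- n_instruments(h)
  if (n < 2L) stop("leave-one-out needs >= 2 instruments")
  fit <- function(hh) {
    switch(method,
           ivw = ivw(hh, "random"),
           ivw_fixed = ivw(hh, "fixed"),
           egger = mr_egger(hh))
  }
  full <- fit(h)
  rows <- lapply(seq_len(n), function(i) {
    r <- fit(subset_harmonised(h, -i))
    data.frame(left_out = h$rows$variant_id[i],
               n_snp = r$n_snp, beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               flagged = (sign(r$beta) != sign(full$beta) && full$beta != 0) ||
                 r$beta < full$ci_low || r$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

# Leave-one-out IVW betas for all i at once, via totals.
.loo_ivw_betas <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares
#' `RSS = sum((by_i - beta_loo_i * bx_i)^2 / sy_i^2)`, where `beta_loo_i` is
#' the IVW estimate with instrument i left out, is compared with its
#' parametric null distribution obtained by simulating
#' `by_i ~ N(beta_loo_i * bx_i, sy_i)` and recomputing the statistic
#' (leave-one-out estimates re-fit on each simulated dataset).  The global
#' p-value uses the add-one Monte-Carlo estimator
#' `(1 + #sim >= obs) / (1 + n_sim)`.  Per-instrument outlier test: each
#' observed weighted squared residual is compared with its own simulated
#' distribution; instruments with Bonferroni-corrected p below
#' `outlier_alpha` are flagged.  The corrected estimate is random-effects
#' IVW on the non-flagged instruments (outliers are removed once, without
#' iteration).  The distortion test compares the corrected estimate with
#' estimates from removing equally many instruments at random.
#'
#' @param h A single-exposure `harmonised_set` with >= 4 instruments.
#' @param n_sim Number of parametric simulations (>= 100; default 1000).
#' @param seed Integer seed (mandatory).
#' @param outlier_alpha Familywise significance level for the outlier test
#'   (default 0.05; per-instrument threshold is `outlier_alpha / n`).
#' @return A `presso_result`: list with `global_rss`, `global_pval`,
#'   `outlier_ids`, `per_snp_pvals`, `corrected` (an `mr_result`), and
#'   `distortion_pval` (NA when no outliers).
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05) {
  .check_single_exposure(h)
  if (missing(seed)) stop("mr_presso requires an explicit seed")
  n <- n_instruments(h)
  if (n < 4L) stop("MR-PRESSO needs >= 4 instruments")
  if (n_sim < 100L) stop("n_sim must be >= 100")
  bx <- h$bx[, 1L]; by <- h$by; sy <- h$sy
  w <- 1 / sy^2

  loo <- .loo_ivw_betas(bx, by, sy)
  obs_res2 <- w * (by - loo * bx)^2
  obs_rss <- sum(obs_res2)

  sim <- with_seed(seed, {
    mu <- loo * bx
    # n_sim x n matrix of simulated outcome betas under the null
    bys <- matrix(stats::rnorm(n_sim * n, rep(mu, each = n_sim),
                               rep(sy, each = n_sim)), n_sim, n)
    sxy <- bys %*% (w * bx)                    # per-sim totals
    sxx <- sum(w * bx^2)
    loo_b <- (matrix(sxy, n_sim, n) - sweep(bys, 2L, w * bx, `*`)) /
      matrix(sxx - w * bx^2, n_sim, n, byrow = TRUE)
    res2 <- sweep((bys - sweep(loo_b, 2L, bx, `*`))^2, 2L, w, `*`)
    list(rss = rowSums(res2), res2 = res2)
  })

  global_pval <- (1 + sum(sim$rss >= obs_rss)) / (1 + n_sim)
  per_snp <- (1 + colSums(sim$res2 >= rep(obs_res2, each = n_sim))) /
    (1 + n_sim)
  names(per_snp) <- h$rows$variant_id
  outliers <- h$rows$variant_id[per_snp < outlier_alpha / n]
  keep <- !(h$rows$variant_id %in% outliers)
  if (!any(keep)) stop("no instruments survive PRESSO")
  corrected <- ivw(subset_harmonised(h, keep), "random")

  distortion_pval <- NA_real_
  if (length(outliers) > 0L && sum(keep) >= 2L) {
    n_out <- length(outliers)
    dist_seed <- derive_seed(seed, "presso_distortion")
    null_betas <- with_seed(dist_seed, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(n, n_out)
        .ivw_core(bx[-drop_idx], by[-drop_idx], sy[-drop_idx])$beta
      }, numeric(1))
    })
    full_beta <- .ivw_core(bx, by, sy)$beta
    obs_shift <- abs(corrected$beta - full_beta)
    distortion_pval <- (1 + sum(abs(null_betas - full_beta) >= obs_shift)) /
      (1 + n_sim)
  }

  structure(list(global_rss = obs_rss, global_pval = global_pval,
                 outlier_ids = outliers, per_snp_pvals = per_snp,
                 corrected = corrected, distortion_pval = distortion_pval),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %.4g\n",
              x$global_rss, x$global_pval))
  if (length(x$outlier_ids) > 0L) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers detected\n")
  }
  cat("  corrected "); print(x$corrected)
  invisible(x)
}
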