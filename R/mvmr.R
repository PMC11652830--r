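# Multivariable MR: joint direct effects of several exposures.

# Weighted multiple regression of by on the exposure beta columns.
# intercept = TRUE adds a pleiotropy intercept (MVMR-Egger style test).
.mvmr_fit <- function(bx, by, sy, intercept = FALSE) {
  w <- 1 / sy^2
  X <- if (intercept) cbind(`(intercept)` = 1, bx) else bx
  if (kappa(sqrt(w) * X) > 1e8) stop("collinear exposures")
  xtwx <- crossprod(X, w * X)
  coefs <- unname(drop(solve(xtwx, crossprod(X, w * by))))
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  infl <- max(1, q / df)
  ses <- unname(sqrt(diag(solve(xtwx)) * infl))
  list(coefs = coefs, ses = ses, q = q, df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Multivariable IVW estimation
#'
#' Weighted multiple linear regression of the outcome betas on the k
#' exposure beta columns without intercept, weights `1/sy^2`.  Coefficient
#' j is exposure j's direct effect, conditional on the other exposures.
#' Standard errors use the unscaled WLS covariance inflated by
#' `max(1, Q/(n-k))`; p-values and CIs use the t distribution with n - k df.
#' With k = 1 this reduces to univariable IVW (with an n - 1 inflation
#' denominator difference only through the t vs normal reference).
#'
#' @param h A `harmonised_set` with k exposures and n > k instruments.
#' @return List of k `mr_result` objects (method `"mvmr_ivw"`), one per
#'   exposure, with attribute `"q"` holding the residual heterogeneity test.
#' @export
mvmr_ivw <- function(h) {
  k <- ncol(h$bx)
  n <- n_instruments(h)
  if (n <= k) stop("MVMR needs more instruments than exposures")
  fit <- .mvmr_fit(h$bx, h$by, h$sy, intercept = FALSE)
  df <- n - k
  res <- lapply(seq_len(k), function(j) {
    mr_result("mvmr_ivw", fit$coefs[j], fit$ses[j], n_snp = n, df = df,
              exposure = h$exposure_labels[j])
  })
  names(res) <- h$exposure_labels
  attr(res, "q") <- list(q = fit$q, df = df, pval = fit$q_pval)
  res
}

#' Multivariable MR diagnostics table
#'
#' Per-exposure heterogeneity and pleiotropy tests in the layout
#' (exposure x method x p-value): the `IVW` row is the residual Cochran's Q
#' p of the no-intercept fit; the `MR Egger` row is the residual Q p after
#' adding an intercept with rows oriented so that exposure's betas are
#' non-negative; the `Egger intercept` row is that intercept's p-value.
#'
#' @param h A `harmonised_set` with k >= 1 exposures.
#' @param results Output of [mvmr_ivw()] on `h`.
#' @return Data frame with columns `exposure`, `method`, `n_snp`, `p_value`.
#' @export
mvmr_diagnostics <- function(h, results) {
  k <- ncol(h$bx)
  n <- n_instruments(h)
  ivw_q <- attr(results, "q")
  rows <- lapply(seq_len(k), function(j) {
    hj <- orient_positive(h, exposure = j)
    ef <- .mvmr_fit(hj$bx, hj$by, hj$sy, intercept = TRUE)
    int_p <- 2 * stats::pt(-abs(ef$coefs[1L] / ef$ses[1L]), ef$df)
    data.frame(exposure = h$exposure_labels[j],
               method = c("MR Egger", "IVW", "Egger intercept"),
               n_snp = c(n, n, NA_integer_),
               p_value = c(ef$q_pval, ivw_q$pval, int_p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
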