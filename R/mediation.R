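# Two-step MR mediation: product of coefficients, delta-method intervals,
# signed proportion mediated.

#' Indirect (mediated) effect by the product of coefficients
#'
#' `indirect = a * b` with the first-order delta-method standard error
#' `sqrt(b^2 * se_a^2 + a^2 * se_b^2)` (zero covariance: the two estimates
#' come from non-overlapping two-sample fits) and a normal 95% CI.
#'
#' @param a Exposure -> mediator effect estimate.
#' @param se_a Its standard error, > 0.
#' @param b Mediator -> outcome effect adjusted for the exposure.
#' @param se_b Its standard error, > 0.
#' @param z Critical value (default 1.959964).
#' @return List with `indirect`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
indirect_effect <- function(a, se_a, b, se_b, z = 1.959964) {
  stopifnot(se_a > 0, se_b > 0)
  ind <- a * b
  se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  pval <- if (se > 0) 2 * stats::pnorm(-abs(ind / se)) else as.numeric(ind == 0)
  list(indirect = ind, se = se,
       ci_low = ind - z * se, ci_high = ind + z * se, pval = pval)
}

#' Signed proportion of the total effect that is mediated
#'
#' `indirect / total`, sign preserved: the proportion is negative when the
#' indirect and total effects oppose.  Returned as a fraction; multiply by
#' 100 for the percentage scale used in report tables.
#'
#' @param indirect Indirect effect estimate.
#' @param total Total effect estimate (nonzero).
#' @return Signed proportion (fraction).
#' @export
proportion_mediated <- function(indirect, total) {
  if (abs(total) < 1e-12) stop("undefined proportion: total effect is zero")
  indirect / total
}

#' Assemble a two-step MR mediation result
#'
#' Combines the univariable total effect (exposure -> outcome), the
#' univariable step-a effect (exposure -> mediator) and the mediator's MVMR
#' coefficient (mediator -> outcome conditional on the exposure) into a
#' mediation decomposition: `indirect = a * b`, delta-method SE/CI,
#' `direct = total - indirect`, and the signed proportion mediated.
#'
#' @param total `mr_result` for exposure -> outcome (univariable).
#' @param step_a `mr_result` for exposure -> mediator (univariable).
#' @param step_b_mvmr `mr_result`: the mediator's coefficient from MVMR of
#'   the outcome on (exposure, mediator).
#' @return A `mediation_result`: list with `total_effect`, `total_se`,
#'   `effect_a`, `effect_a_se`, `effect_b`, `effect_b_se`, `indirect`,
#'   `indirect_se`, `ci_low`, `ci_high`, `pval`, `direct`, `proportion`.
#' @export
two_step_mediation <- function(total, step_a, step_b_mvmr) {
  for (nm in c("total", "step_a", "step_b_mvmr")) {
    v <- get(nm)
    if (is.null(v) || !inherits(v, "mr_result")) {
      stop("missing or invalid mediation input: ", nm)
    }
  }
  ind <- indirect_effect(step_a$beta, step_a$se,
                         step_b_mvmr$beta, step_b_mvmr$se)
  structure(list(total_effect = total$beta, total_se = total$se,
                 effect_a = step_a$beta, effect_a_se = step_a$se,
                 effect_b = step_b_mvmr$beta, effect_b_se = step_b_mvmr$se,
                 indirect = ind$indirect, indirect_se = ind$se,
                 ci_low = ind$ci_low, ci_high = ind$ci_high,
                 pval = ind$pval,
                 direct = total$beta - ind$indirect,
                 proportion = proportion_mediated(ind$indirect, total$beta)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("total = %.4f, direct = %.4f, indirect = %.4f (se %.4f)\n",
              x$total_effect, x$direct, x$indirect, x$indirect_se))
  cat(sprintf("  95%% CI [%.4f, %.4f], p = %.3g, proportion mediated = %.2f%%\n",
              x$ci_low, x$ci_high, x$pval, 100 * x$proportion))
  invisible(x)
}

#' Format mediation results as the standard mediation table
#'
#' Columns: `outcome`, `exposure`, `mediator`, `total`, `direct1`
#' (exposure -> mediator), `direct2` (mediator -> outcome, MVMR-adjusted),
#' `indirect`, `indirect_se`, `ci_low`, `ci_high`, `proportion_pct`.
#'
#' @param med A `mediation_result` or list of them.
#' @param outcome,exposure,mediator Labels (vectorised over `med`).
#' @return A data frame.
#' @export
mediation_table <- function(med, outcome, exposure, mediator) {
  if (inherits(med, "mediation_result")) med <- list(med)
  if (length(med) == 0L) {
    return(data.frame(outcome = character(0), exposure = character(0),
                      mediator = character(0), total = numeric(0),
                      direct1 = numeric(0), direct2 = numeric(0),
                      indirect = numeric(0), indirect_se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      proportion_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, Map(function(m, o, e, md) {
    data.frame(outcome = o, exposure = e, mediator = md,
               total = m$total_effect,
               direct1 = m$effect_a, direct2 = m$effect_b,
               indirect = m$indirect, indirect_se = m$indirect_se,
               ci_low = m$ci_low, ci_high = m$ci_high,
               proportion_pct = 100 * m$proportion,
               stringsAsFactors = FALSE)
  }, med, outcome, exposure, mediator))
}
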