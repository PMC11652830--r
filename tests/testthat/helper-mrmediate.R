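# Shared fixtures and independent oracles for the test suite.

# Build a harmonised_set directly (single exposure unless bx is a matrix),
# bypassing harmonise(), so estimators can be fed exact numbers.
make_hset <- function(bx, sx, by, sy, ids = NULL,
                      exposure_labels = NULL, outcome_label = "y") {
  bx <- as.matrix(bx)
  sx <- as.matrix(sx)
  n <- nrow(bx)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(n))
  if (is.null(exposure_labels)) {
    exposure_labels <- paste0("x", seq_len(ncol(bx)))
  }
  structure(list(exposure_labels = exposure_labels,
                 outcome_label = outcome_label,
                 rows = data.frame(variant_id = ids, effect_allele = "A",
                                   other_allele = "G", eaf = 0.3,
                                   stringsAsFactors = FALSE),
                 bx = bx, sx = sx, by = by, sy = sy,
                 dropped = data.frame(variant_id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "harmonised_set")
}

# Harmonised set straight from simulated datasets (alleles already aligned,
# identity LD); used where selection/harmonisation is not under test.
hset_from_sim <- function(exp_ds, out_ds, ids, med_ds = NULL) {
  ix <- match(ids, exp_ds$variant_id)
  iy <- match(ids, out_ds$variant_id)
  if (is.null(med_ds)) {
    make_hset(exp_ds$beta[ix], exp_ds$se[ix], out_ds$beta[iy],
              out_ds$se[iy], ids = ids,
              exposure_labels = trait_label(exp_ds),
              outcome_label = trait_label(out_ds))
  } else {
    im <- match(ids, med_ds$variant_id)
    make_hset(cbind(exp_ds$beta[ix], med_ds$beta[im]),
              cbind(exp_ds$se[ix], med_ds$se[im]),
              out_ds$beta[iy], out_ds$se[iy], ids = ids,
              exposure_labels = c(trait_label(exp_ds),
                                  trait_label(med_ds)),
              outcome_label = trait_label(out_ds))
  }
}

# Independent weighted-least-squares oracle via lm().
oracle_wls <- function(bx, by, sy, intercept = FALSE) {
  w <- 1 / sy^2
  df <- as.data.frame(as.matrix(bx))
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$y <- by
  form <- stats::as.formula(paste("y ~", if (intercept) "" else "0 +",
                                  paste(setdiff(names(df), "y"),
                                        collapse = " + ")))
  fit <- stats::lm(form, data = df, weights = w)
  list(coefs = unname(stats::coef(fit)),
       # unscaled covariance: vcov(fit) has sigma^2 factor = Q/df
       vcov_unscaled = unname(stats::vcov(fit) / stats::sigma(fit)^2),
       q = sum(w * stats::residuals(fit)^2),
       df = stats::df.residual(fit))
}

# Minimal summary dataset for harmonisation tests.
make_ds <- function(ids, ea, oa, beta, se = 0.01, eaf = 0.3, pval = 1e-9,
                    label = "trait", chrom = "1",
                    pos = seq(1e6, by = 3e7, length.out = length(ids))) {
  summary_dataset(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                             effect_allele = ea, other_allele = oa,
                             eaf = eaf, beta = beta, se = se, pval = pval,
                             n = 1e5, stringsAsFactors = FALSE),
                  trait_label = label)
}
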