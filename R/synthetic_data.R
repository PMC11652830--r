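# Synthetic three-trait GWAS summary statistics under a linear structural
# mediation model X -> M -> Y with a direct path X -> Y.
#
# Summary statistics are generated directly (no individual-level genotypes):
# an instrument's true per-allele effect on its own trait is drawn from
# N(0, effect_scale^2) and propagates linearly through the structural
# coefficients; observed betas add normal noise with the standard
# per-allele-regression standard error 1/sqrt(2*maf*(1-maf)*n).

#' Simulation configuration for the mediation generator
#'
#' @param n_instruments_x,n_instruments_m Instrument counts for the exposure
#'   and the mediator (default 100 each; disjoint sets unless
#'   `overlap_fraction > 0`).
#' @param maf_range Minor-allele-frequency interval, a sub-interval of
#'   (0, 0.5\] (default c(0.05, 0.5)).
#' @param effect_scale SD of true per-allele instrument effects on their own
#'   trait (default 0.1, which with the default sample sizes yields strong
#'   instruments, F in the hundreds).
#' @param n_x,n_m,n_y GWAS sample sizes per trait (default 1e5 each).
#' @param a True exposure -> mediator effect (default 0.4).
#' @param b True mediator -> outcome effect (default 0.5).
#' @param c_prime True direct exposure -> outcome effect (default 0.1);
#'   the total effect is `c_prime + a * b`.
#' @param pleiotropy_mode `"none"` (default), `"balanced"` (mean-zero direct
#'   instrument -> outcome effects) or `"directional"` (nonzero mean).
#' @param pleiotropy_sd,pleiotropy_mean Distribution of the pleiotropic
#'   effects (defaults 0.01 and 0; the mean applies only to
#'   `"directional"`).
#' @param n_outliers Number of planted outlier instruments among the
#'   exposure's (default 0).
#' @param outlier_multiplier Factor applied to an outlier's true outcome
#'   effect (default 10).
#' @param overlap_fraction Fraction of mediator instruments that also carry
#'   an independent direct effect on the exposure (default 0).
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_instruments_x = 100, n_instruments_m = 100,
                              maf_range = c(0.05, 0.5),
                              effect_scale = 0.1,
                              n_x = 1e5, n_m = 1e5, n_y = 1e5,
                              a = 0.4, b = 0.5, c_prime = 0.1,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional"),
                              pleiotropy_sd = 0.01, pleiotropy_mean = 0,
                              n_outliers = 0, outlier_multiplier = 10,
                              overlap_fraction = 0, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("simulation_config requires an explicit seed")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be a sub-interval of (0, 0.5]")
  }
  stopifnot(n_x > 0, n_m > 0, n_y > 0,
            n_instruments_x >= 1, n_instruments_m >= 0,
            n_outliers <= n_instruments_x,
            overlap_fraction >= 0, overlap_fraction <= 1)
  structure(list(n_instruments_x = n_instruments_x,
                 n_instruments_m = n_instruments_m,
                 maf_range = maf_range, effect_scale = effect_scale,
                 n_x = n_x, n_m = n_m, n_y = n_y,
                 a = a, b = b, c_prime = c_prime,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 n_outliers = n_outliers,
                 outlier_multiplier = outlier_multiplier,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Positions spaced 20 Mb apart within chromosomes 1..22 so that identity-LD
# clumping with the default 10,000 kb window never removes anything.
.variant_map <- function(n) {
  chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
  pos <- 1e6 + 2e7 * ((seq_len(n) - 1L) %/% 22L)
  list(chrom = chrom, pos = pos)
}

#' Simulate three-trait GWAS summary statistics with known truth
#'
#' Generates exposure, mediator and outcome summary datasets under the
#' linear structural model `M = a X`, `Y = c_prime X + b M` at the level of
#' per-allele instrument effects, plus optional pleiotropy and planted
#' outliers.  Every dataset records all instruments (both sets), as a real
#' GWAS export would, so harmonisation, MVMR instrument-union logic and
#' reverse-direction analyses are all exercisable.
#'
#' @param config A [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` (each a
#'   [summary_dataset()]) and `truth` (a `simulation_truth`: per-instrument
#'   true effects, the scalar truths `a`, `b`, `c_prime`,
#'   `total = c_prime + a*b`, instrument id sets, and `outlier_ids`).
#' @export
simulate_mediation_gwas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  with_seed(cf$seed, {
    nx <- cf$n_instruments_x; nm <- cf$n_instruments_m
    n <- nx + nm
    ids <- sprintf("rs%05d", seq_len(n))
    x_ids <- ids[seq_len(nx)]
    m_ids <- if (nm > 0) ids[nx + seq_len(nm)] else character(0)
    map <- .variant_map(n)
    maf <- stats::runif(n, cf$maf_range[1], cf$maf_range[2])

    # true per-allele effects on own trait
    g_x <- stats::rnorm(nx, 0, cf$effect_scale)         # X instruments on X
    g_m <- stats::rnorm(nm, 0, cf$effect_scale)         # M instruments on M

    # optional overlap: some M instruments also hit X directly
    x_direct_of_m <- numeric(nm)
    if (cf$overlap_fraction > 0 && nm > 0) {
      n_ov <- round(cf$overlap_fraction * nm)
      if (n_ov > 0) {
        x_direct_of_m[seq_len(n_ov)] <- stats::rnorm(n_ov, 0, cf$effect_scale)
      }
    }

    # direct instrument -> outcome pleiotropy, defined on the allele that
    # increases the instrument's own trait (the orientation under which a
    # directional mean is visible to Egger's intercept)
    own_sign <- sign(c(g_x, g_m))
    own_sign[own_sign == 0] <- 1
    pleio <- switch(cf$pleiotropy_mode,
                    none = numeric(n),
                    balanced = stats::rnorm(n, 0, cf$pleiotropy_sd),
                    directional = stats::rnorm(n, cf$pleiotropy_mean,
                                               cf$pleiotropy_sd) * own_sign)

    total <- cf$c_prime + cf$a * cf$b
    # structural propagation of true effects to all three traits
    true_x <- c(g_x, x_direct_of_m)
    true_m <- c(cf$a * g_x, g_m + cf$a * x_direct_of_m)
    true_y <- c(total * g_x, cf$b * g_m + total * x_direct_of_m) + pleio

    outlier_ids <- character(0)
    if (cf$n_outliers > 0) {
      oi <- seq_len(cf$n_outliers)       # first X instruments, deterministic
      true_y[oi] <- true_y[oi] * cf$outlier_multiplier
      outlier_ids <- ids[oi]
    }

    make_ds <- function(true_beta, n_trait, label) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_trait)
      beta <- stats::rnorm(n, true_beta, se)
      p <- 2 * stats::pnorm(-abs(beta / se))
      p[p == 0] <- .Machine$double.xmin
      summary_dataset(data.frame(variant_id = ids,
                                 chrom = map$chrom, pos = map$pos,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = maf, beta = beta, se = se,
                                 pval = p, n = n_trait,
                                 stringsAsFactors = FALSE),
                      trait_label = label)
    }

    truth <- structure(list(variant_id = ids,
                            x_instruments = x_ids,
                            m_instruments = m_ids,
                            true_beta_x = true_x,
                            true_beta_m = true_m,
                            true_beta_y = true_y,
                            a = cf$a, b = cf$b, c_prime = cf$c_prime,
                            total = total,
                            outlier_ids = outlier_ids,
                            seed = cf$seed),
                       class = "simulation_truth")

    list(exposure = make_ds(true_x, cf$n_x, "exposure"),
         mediator = make_ds(true_m, cf$n_m, "mediator"),
         outcome = make_ds(true_y, cf$n_y, "outcome"),
         truth = truth)
  })
}

#' Write the canonical named fixture suite
#'
#' Emits the deterministic fixtures the test suite uses, each as
#' tab-delimited summary statistics plus a JSON truth sidecar:
#' \itemize{
#'   \item `consensus`: every instrument has exactly the same Wald ratio
#'     (0.3), so all estimators must agree and Q = 0;
#'   \item `egger_line`: points lying exactly on `by = 0.02 + 0.3 * bx`, the
#'     closed-form Egger fixture;
#'   \item `outlier`: 30 consensus-ratio instruments plus one planted
#'     10-fold outlier for MR-PRESSO;
#'   \item `mediation`: a full three-trait simulation with
#'     a = 0.4, b = 0.5, c' = 0.1 for parameter-recovery runs.
#' }
#'
#' @param dir Writable output directory (created if needed).
#' @return Data frame manifest (fixture, file), invisibly.
#' @export
write_fixture_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, df, label) {
    ds <- summary_dataset(df, trait_label = label)
    path <- file.path(dir, paste0(name, ".tsv"))
    write_sumstats(ds, path)
    files <<- c(files, path)
    ds
  }
  sidecar <- function(name, truth) {
    path <- file.path(dir, paste0(name, "_truth.json"))
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    files <<- c(files, path)
  }
  map <- .variant_map(40L)
  base <- function(n, beta, se, prefix) {
    data.frame(variant_id = sprintf("%s%02d", prefix, seq_len(n)),
               chrom = map$chrom[seq_len(n)], pos = map$pos[seq_len(n)],
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta = beta, se = se,
               pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                           .Machine$double.xmin),
               n = 1e5, stringsAsFactors = FALSE)
  }

  # consensus: ratios exactly 0.3 everywhere
  bx <- seq(0.08, 0.20, length.out = 10L)
  emit("consensus_exposure", base(10L, bx, 0.005, "cons"), "exposure")
  emit("consensus_outcome", base(10L, 0.3 * bx, 0.01, "cons"), "outcome")
  sidecar("consensus", list(ratio = 0.3))

  # egger_line: by = 0.02 + 0.3 * bx exactly
  bxe <- seq(0.10, 0.30, length.out = 8L)
  emit("egger_line_exposure", base(8L, bxe, 0.005, "egg"), "exposure")
  emit("egger_line_outcome", base(8L, 0.02 + 0.3 * bxe, 0.01, "egg"),
       "outcome")
  sidecar("egger_line", list(intercept = 0.02, slope = 0.3))

  # outlier: 30 consensus instruments + 1 with a 10x ratio at a
  # middle-leverage position (index 16)
  bxo <- seq(0.08, 0.22, length.out = 31L)
  byo <- 0.3 * bxo
  byo[16L] <- 3.0 * bxo[16L]
  emit("outlier_exposure", base(31L, bxo, 0.005, "out"), "exposure")
  emit("outlier_outcome", base(31L, byo, 0.01, "out"), "outcome")
  sidecar("outlier", list(ratio = 0.3, outlier_ids = "out16",
                          outlier_ratio = 3.0))

  # mediation: simulated three-trait set with known truth, seed 42
  cfg <- simulation_config(a = 0.4, b = 0.5, c_prime = 0.1, seed = 42)
  sim <- simulate_mediation_gwas(cfg)
  for (tr in c("exposure", "mediator", "outcome")) {
    path <- file.path(dir, paste0("mediation_", tr, ".tsv"))
    write_sumstats(sim[[tr]], path)
    files <- c(files, path)
  }
  sidecar("mediation", unclass(sim$truth))

  manifest <- data.frame(file = basename(files), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
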