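# Orchestration: bidirectional univariable MR, two-step mediation, CLI.

.default_config <- function() {
  list(datasets = list(),
       thresholds = list(p_threshold = 5e-8, r2_max = 0.001,
                         window_kb = 10000, f_min = 10,
                         palindromic_eaf_window = 0.08),
       estimators = list(ivw_mode = "random", n_boot = 5000),
       sensitivity = list(presso_n_sim = 1000, outlier_alpha = 0.05),
       mediation = list(alpha = 0.05),
       bidirectional = FALSE,
       seed = 1L)
}

# Merge user config over defaults (one level deep for the known blocks).
.resolve_config <- function(config) {
  base <- .default_config()
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base$seed <- as.integer(base$seed)
  base
}

.resolve_dataset <- function(x, label) {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_sumstats(x, trait_label = label))
  }
  stop("dataset '", label, "' must be a summary_dataset or a file path")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# One univariable direction: selection, harmonisation, estimation,
# diagnostics, PRESSO with outlier-corrected re-analysis.
.univariable_one <- function(exp_ds, out_ds, cfg, ld = NULL) {
  th <- cfg$thresholds
  direction <- paste0(trait_label(exp_ds), "->", trait_label(out_ds))
  inst <- .stage("select_instruments",
                 select_instruments(exp_ds, ld,
                                    p_threshold = th$p_threshold,
                                    r2_max = th$r2_max,
                                    window_kb = th$window_kb,
                                    f_min = th$f_min))
  h <- .stage("harmonise",
              harmonise(exp_ds, out_ds, inst$variant_ids,
                        palindromic_eaf_window = th$palindromic_eaf_window))
  wm_seed <- derive_seed(cfg$seed, paste0("wm:", direction))
  estimate_all <- function(hh) {
    list(ivw(hh, cfg$estimators$ivw_mode),
         mr_egger(hh),
         weighted_median(hh, n_boot = cfg$estimators$n_boot, seed = wm_seed))
  }
  ests <- .stage("estimators", estimate_all(h))
  q <- .stage("cochran_q", cochran_q(h))
  loo <- .stage("leave_one_out", leave_one_out(h))
  presso <- NULL
  if (n_instruments(h) >= 4L) {
    presso <- .stage("mr_presso",
                     mr_presso(h, n_sim = cfg$sensitivity$presso_n_sim,
                               seed = derive_seed(cfg$seed,
                                                  paste0("presso:", direction)),
                               outlier_alpha = cfg$sensitivity$outlier_alpha))
  }
  tab <- results_table(ests, outcome = trait_label(out_ds))
  tab$analysis <- "primary"
  if (!is.null(presso) && length(presso$outlier_ids) > 0L) {
    keep <- !(h$rows$variant_id %in% presso$outlier_ids)
    ests2 <- .stage("estimators_outlier_corrected",
                    estimate_all(subset_harmonised(h, keep)))
    tab2 <- results_table(ests2, outcome = trait_label(out_ds))
    tab2$analysis <- "outlier_corrected"
    tab <- rbind(tab, tab2)
  }
  list(direction = direction, instruments = inst, harmonised = h,
       results = tab, heterogeneity = q, leave_one_out = loo,
       presso = presso)
}

#' Run bidirectional univariable two-sample MR
#'
#' From a configuration naming exposure and outcome datasets (paths or
#' `summary_dataset` objects) and thresholds: selects instruments,
#' harmonises, runs IVW, MR-Egger and the weighted median, then Cochran's
#' Q, leave-one-out and MR-PRESSO; when PRESSO flags outliers the
#' estimators are re-run on the pruned set and both analyses are reported.
#' With `bidirectional = TRUE` the reverse direction is run as well.
#'
#' @param config List with blocks `datasets` (`exposure`, `outcome`,
#'   optionally `ld`), `thresholds`, `estimators`, `sensitivity`,
#'   `bidirectional`, `seed`.  Unspecified entries take the package
#'   defaults (p < 5e-8, r2 < 0.001, 10,000 kb, F > 10, random-effects IVW,
#'   5000 bootstrap draws, 1000 PRESSO simulations).
#' @return List with `results` (combined results table) and `directions`
#'   (per-direction detail: instruments, harmonised set, heterogeneity,
#'   leave-one-out, PRESSO).
#' @export
run_univariable <- function(config) {
  cfg <- .resolve_config(config)
  exp_ds <- .stage("read", .resolve_dataset(cfg$datasets$exposure, "exposure"))
  out_ds <- .stage("read", .resolve_dataset(cfg$datasets$outcome, "outcome"))
  ld <- if (!is.null(cfg$datasets$ld)) {
    .stage("read", read_ld_matrix(cfg$datasets$ld))
  } else NULL
  dirs <- list(.univariable_one(exp_ds, out_ds, cfg, ld))
  if (isTRUE(cfg$bidirectional)) {
    dirs <- c(dirs, list(.univariable_one(out_ds, exp_ds, cfg, ld)))
  }
  results <- do.call(rbind, lapply(dirs, `[[`, "results"))
  names(dirs) <- vapply(dirs, `[[`, character(1), "direction")
  list(results = results, directions = dirs, config = cfg)
}

#' Run two-step MR mediation
#'
#' Step 1: univariable MR for exposure -> mediator, mediator -> outcome and
#' exposure -> outcome (the total effect).  Step 2: multivariable MR of the
#' outcome on (exposure, mediator) over the union of both instrument sets.
#' The mediation decomposition (indirect effect, delta-method CI, signed
#' proportion mediated) is assembled only when the mediator's MVMR
#' coefficient is significant at `mediation$alpha` (default 0.05).
#'
#' @param config As [run_univariable()], with `datasets` naming `exposure`,
#'   `mediator` and `outcome`, and an optional `mediation$alpha`.
#' @return List with `mediation_table` (possibly zero rows when the
#'   significance gate suppresses the decomposition), `mediation`
#'   (`mediation_result` or NULL), `univariable` (the three step-1 result
#'   lists), `mvmr` (step-2 results and diagnostics), and `config`.
#' @export
run_two_step <- function(config) {
  cfg <- .resolve_config(config)
  th <- cfg$thresholds
  x <- .stage("read", .resolve_dataset(cfg$datasets$exposure, "exposure"))
  m <- .stage("read", .resolve_dataset(cfg$datasets$mediator, "mediator"))
  y <- .stage("read", .resolve_dataset(cfg$datasets$outcome, "outcome"))
  ld <- if (!is.null(cfg$datasets$ld)) {
    .stage("read", read_ld_matrix(cfg$datasets$ld))
  } else NULL

  step_xm <- .univariable_one(x, m, cfg, ld)   # a
  step_my <- .univariable_one(m, y, cfg, ld)   # univariable b (reported)
  step_xy <- .univariable_one(x, y, cfg, ld)   # total

  mv_ids <- union(step_xy$instruments$variant_ids,
                  step_my$instruments$variant_ids)
  h_mv <- .stage("harmonise",
                 harmonise(list(x, m), y, mv_ids,
                           palindromic_eaf_window = th$palindromic_eaf_window))
  mv <- .stage("mvmr", mvmr_ivw(h_mv))
  mv_diag <- .stage("mvmr", mvmr_diagnostics(h_mv, mv))

  pick <- function(res, method) {
    res[res$method == method & res$analysis == "primary", , drop = FALSE]
  }
  ivw_method <- paste0("ivw_", cfg$estimators$ivw_mode)
  as_result <- function(row) {
    mr_result(row$method, row$beta, row$se, n_snp = row$n_snp,
              pval = row$pval, exposure = row$exposure)
  }
  total <- as_result(pick(step_xy$results, ivw_method))
  step_a <- as_result(pick(step_xm$results, ivw_method))
  step_b <- mv[[trait_label(m)]]

  med <- NULL
  med_tab <- mediation_table(list(), character(0), character(0), character(0))
  if (step_b$pval < cfg$mediation$alpha) {
    med <- .stage("mediation", two_step_mediation(total, step_a, step_b))
    med_tab <- mediation_table(med, outcome = trait_label(y),
                               exposure = trait_label(x),
                               mediator = trait_label(m))
  }
  list(mediation_table = med_tab, mediation = med,
       univariable = list(exposure_mediator = step_xm,
                          mediator_outcome = step_my,
                          exposure_outcome = step_xy),
       mvmr = list(harmonised = h_mv, results = mv, diagnostics = mv_diag),
       config = cfg)
}

.write_manifest <- function(cfg, out_dir, extra = list()) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  cfg$datasets)
  hashes <- if (length(paths) > 0L) {
    as.list(tools::md5sum(unlist(paths)))
  } else list()
  manifest <- c(list(package = "mrmediate",
                     version = as.character(utils::packageVersion("mrmediate")),
                     seed = cfg$seed,
                     thresholds = cfg$thresholds,
                     estimators = cfg$estimators,
                     sensitivity = cfg$sensitivity,
                     mediation = cfg$mediation,
                     input_md5 = hashes),
                extra)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.cli_usage <- function() {
  paste(
    "usage: mrmediate <simulate|univariable|two-step|fixtures> [options]",
    "",
    "options:",
    "  --config PATH       JSON run configuration",
    "  --exposure PATH     exposure summary statistics (TSV)",
    "  --mediator PATH     mediator summary statistics (TSV)",
    "  --outcome PATH      outcome summary statistics (TSV)",
    "  --ld PATH           LD r2 matrix (TSV)",
    "  --p-threshold X     instrument p-value threshold (default 5e-8)",
    "  --clump-r2 X        clumping r2 exclusion threshold (default 0.001)",
    "  --clump-kb X        clumping window in kb (default 10000)",
    "  --f-min X           minimum instrument F (default 10)",
    "  --seed N            root seed (default 1)",
    "  --boot N            weighted-median bootstrap draws (default 5000)",
    "  --presso-sims N     MR-PRESSO simulations (default 1000)",
    "  --mediation-alpha X significance gate for mediation rows (default 0.05)",
    "  --bidirectional     run both directions (univariable)",
    "  --out DIR           output directory (default '.')",
    sep = "\n")
}

.cli_parse <- function(argv) {
  flags <- list(out = ".")
  known <- c("config", "exposure", "mediator", "outcome", "ld",
             "p-threshold", "clump-r2", "clump-kb", "f-min", "seed",
             "boot", "presso-sims", "mediation-alpha", "out")
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--bidirectional") {
      flags$bidirectional <- TRUE; i <- i + 1L; next
    }
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (!key %in% known) stop("unknown flag: ", a)
    if (i == length(argv)) stop("missing value for ", a)
    flags[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

.cli_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) {
    if (!file.exists(flags$config)) stop("config file not found: ",
                                         flags$config)
    jsonlite::read_json(flags$config, simplifyVector = TRUE)
  } else list()
  cfg <- .resolve_config(cfg)
  for (nm in c("exposure", "mediator", "outcome", "ld")) {
    if (!is.null(flags[[nm]])) cfg$datasets[[nm]] <- flags[[nm]]
  }
  num <- function(key, into, field) {
    if (!is.null(flags[[key]])) cfg[[into]][[field]] <<- as.numeric(flags[[key]])
  }
  num("p-threshold", "thresholds", "p_threshold")
  num("clump-r2", "thresholds", "r2_max")
  num("clump-kb", "thresholds", "window_kb")
  num("f-min", "thresholds", "f_min")
  num("boot", "estimators", "n_boot")
  num("presso-sims", "sensitivity", "presso_n_sim")
  num("mediation-alpha", "mediation", "alpha")
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  if (isTRUE(flags$bidirectional)) cfg$bidirectional <- TRUE
  cfg
}

.write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic three-trait dataset),
#' `univariable` (bidirectional univariable MR), `two-step` (two-step MR
#' mediation), `fixtures` (write the canonical fixture suite).  Writes
#' tab-delimited result tables, a plain-text run log and a JSON run
#' manifest recording all resolved thresholds, seeds and input hashes to
#' `--out`.  Intended to be called from a wrapper script as
#' `Rscript -e 'quit(status = mrmediate::cli_entry())'`.
#'
#' @param argv Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 1 on usage or
#'   runtime error.
#' @export
cli_entry <- function(argv = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg) {
    message("error: ", msg)
    message(.cli_usage())
    invisible(1L)
  }
  if (length(argv) == 0L) return(fail("no subcommand given"))
  sub <- argv[1L]
  if (!sub %in% c("simulate", "univariable", "two-step", "fixtures")) {
    return(fail(paste0("unknown subcommand '", sub, "'")))
  }
  flags <- tryCatch(.cli_parse(argv[-1L]), error = function(e) e)
  if (inherits(flags, "error")) return(fail(conditionMessage(flags)))
  status <- tryCatch({
    dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
    log_lines <- c(paste("mrmediate", sub),
                   paste("out:", flags$out))
    if (sub == "fixtures") {
      write_fixture_suite(flags$out)
      log_lines <- c(log_lines, "fixture suite written")
    } else if (sub == "simulate") {
      cfg <- .cli_config(flags)
      sim <- simulate_mediation_gwas(simulation_config(seed = cfg$seed))
      for (tr in c("exposure", "mediator", "outcome")) {
        write_sumstats(sim[[tr]], file.path(flags$out, paste0(tr, ".tsv")))
      }
      jsonlite::write_json(unclass(sim$truth),
                           file.path(flags$out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_manifest(cfg, flags$out)
      log_lines <- c(log_lines, paste("seed:", cfg$seed))
    } else if (sub == "univariable") {
      cfg <- .cli_config(flags)
      if (is.null(cfg$datasets$exposure) || is.null(cfg$datasets$outcome)) {
        stop("univariable needs --exposure and --outcome (or a config)")
      }
      run <- run_univariable(cfg)
      .write_table(run$results, file.path(flags$out, "mr_results.tsv"))
      for (d in run$directions) {
        safe <- gsub("[^A-Za-z0-9_.-]", "_", d$direction)
        .write_table(d$leave_one_out,
                     file.path(flags$out, paste0("loo_", safe, ".tsv")))
        write_dropped_report(d$harmonised,
                             file.path(flags$out,
                                       paste0("dropped_", safe, ".tsv")))
      }
      .write_manifest(run$config, flags$out)
      log_lines <- c(log_lines, paste("directions:",
                                      length(run$directions)),
                     paste("seed:", run$config$seed))
    } else {             # two-step
      cfg <- .cli_config(flags)
      needed <- c("exposure", "mediator", "outcome")
      miss <- needed[vapply(needed,
                            function(nm) is.null(cfg$datasets[[nm]]),
                            logical(1))]
      if (length(miss) > 0L) {
        stop("two-step needs --", paste(miss, collapse = ", --"),
             " (or a config)")
      }
      run <- run_two_step(cfg)
      .write_table(run$mediation_table,
                   file.path(flags$out, "mediation_table.tsv"))
      uni <- do.call(rbind, lapply(run$univariable, `[[`, "results"))
      .write_table(uni, file.path(flags$out, "univariable_results.tsv"))
      .write_table(results_table(run$mvmr$results,
                                 outcome = run$mvmr$harmonised$outcome_label),
                   file.path(flags$out, "mvmr_results.tsv"))
      .write_table(run$mvmr$diagnostics,
                   file.path(flags$out, "mvmr_diagnostics.tsv"))
      .write_manifest(run$config, flags$out)
      log_lines <- c(log_lines, paste("seed:", run$config$seed),
                     paste("mediation rows:", nrow(run$mediation_table)))
    }
    writeLines(log_lines, file.path(flags$out, "run_log.txt"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
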