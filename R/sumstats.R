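# I/O and harmonisation of GWAS summary statistics.

#' Canonical summary-statistic column names
#'
#' The column layout used throughout the package: one row per variant with
#' `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`.  This is the layout of OpenGWAS / GWAS-SSF
#' style tab-delimited exports after renaming.
#'
#' @return Character vector of canonical field names.
#' @export
sumstats_fields <- function() {
  c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

.mandatory_fields <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pval")

#' Construct a summary dataset
#'
#' Validates and wraps a data frame of per-variant association records for a
#' single trait.  Invariants enforced: unique `variant_id`, `se > 0`,
#' `pval` in (0, 1], `effect_allele != other_allele`, `eaf` (when present)
#' in \[0, 1\].
#'
#' @param records Data frame with at least the mandatory columns
#'   (`variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`).
#' @param trait_label Character label for the trait.
#' @return An object of class `summary_dataset` (a data frame with a
#'   `trait_label` attribute).
#' @export
summary_dataset <- function(records, trait_label = "trait") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.mandatory_fields, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$variant_id <- as.character(records$variant_id)
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in dataset")
  }
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele  <- toupper(as.character(records$other_allele))
  if (any(records$effect_allele == records$other_allele)) {
    stop("effect_allele equals other_allele for some variant")
  }
  if (!all(records$effect_allele %in% c("A", "C", "G", "T")) ||
      !all(records$other_allele %in% c("A", "C", "G", "T"))) {
    stop("alleles must be one of A, C, G, T")
  }
  if (any(!is.finite(records$se)) || any(records$se <= 0)) {
    stop("se must be finite and > 0")
  }
  if (any(records$pval <= 0 | records$pval > 1, na.rm = TRUE)) {
    stop("pval must lie in (0, 1]")
  }
  if ("eaf" %in% names(records) &&
      any(records$eaf < 0 | records$eaf > 1, na.rm = TRUE)) {
    stop("eaf must lie in [0, 1]")
  }
  for (f in setdiff(sumstats_fields(), names(records))) records[[f]] <- NA
  records <- records[, sumstats_fields()]
  rownames(records) <- NULL
  structure(records,
            trait_label = trait_label,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("summary_dataset:", attr(x, "trait_label"),
      "-", nrow(x), "variants\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Trait label of a summary dataset
#' @param x A `summary_dataset`.
#' @return Character label.
#' @export
trait_label <- function(x) attr(x, "trait_label")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header.  Lines whose `beta`
#' or `se` do not parse as numbers are dropped; the drop count is reported
#' with a message and attached as attribute `n_dropped`.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names
#'   (see [sumstats_fields()]) to the source column names, e.g.
#'   `c(variant_id = "SNP", beta = "BETA")`.  Unmapped fields are looked up
#'   under their canonical names.
#' @param trait_label Trait label; defaults to the file name.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [summary_dataset()].
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL,
                          delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  src <- stats::setNames(sumstats_fields(), sumstats_fields())
  if (!is.null(column_map)) src[names(column_map)] <- column_map
  missing_cols <- .mandatory_fields[!src[.mandatory_fields] %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(src[missing_cols], collapse = ", "))
  }
  out <- data.frame(variant_id = raw[[src["variant_id"]]],
                    stringsAsFactors = FALSE)
  for (f in setdiff(sumstats_fields(), "variant_id")) {
    out[[f]] <- if (src[f] %in% names(raw)) raw[[src[f]]] else NA_character_
  }
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  bad <- !is.finite(out$beta) | !is.finite(out$se)
  if (any(bad)) {
    message(sum(bad), " record(s) dropped: unparseable beta/se")
    out <- out[!bad, , drop = FALSE]
  }
  if (is.null(trait_label)) trait_label <- basename(path)
  ds <- summary_dataset(out, trait_label = trait_label)
  attr(ds, "n_dropped") <- sum(bad)
  ds
}

#' Write summary statistics to a delimited text file
#'
#' @param dataset A [summary_dataset()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path, delim = "\t") {
  utils::write.table(as.data.frame(dataset), path, sep = delim,
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns outcome (and any additional exposure) effects to the effect allele
#' of the first exposure for a given set of instruments, following the
#' standard two-sample MR convention:
#' \itemize{
#'   \item alleles identical: keep as-is;
#'   \item alleles swapped (EA/OA exchanged): negate beta, `eaf -> 1 - eaf`;
#'   \item complementary-strand match: map alleles through A<->T / C<->G,
#'     then apply the same rule;
#'   \item palindromic variants (A/T or C/G) with `eaf` within
#'     `palindromic_eaf_window` of 0.5 in any dataset, or with missing
#'     `eaf`, are dropped (`"palindromic_ambiguous"`); unambiguous
#'     palindromic variants are oriented by allele-frequency concordance;
#'   \item variants absent from any dataset are dropped (`"missing"`);
#'   \item irreconcilable alleles are dropped (`"allele_mismatch"`).
#' }
#'
#' @param exposures A single `summary_dataset` or a list of them (first one
#'   defines the reference effect allele).
#' @param outcome A `summary_dataset`.
#' @param instrument_ids Character vector of instrument variant ids; must be
#'   a subset of the first exposure's variants.
#' @param palindromic_eaf_window Half-width of the ambiguity window around
#'   eaf = 0.5 (default 0.08, i.e. drop when eaf in \[0.42, 0.58\]).
#' @return A `harmonised_set`: list with `exposure_labels`, `outcome_label`,
#'   `rows` (variant_id, alleles), exposure effect matrices `bx`/`sx`,
#'   outcome vectors `by`/`sy`, and a `dropped` data frame
#'   (variant_id, reason).
#' @export
harmonise <- function(exposures, outcome, instrument_ids,
                      palindromic_eaf_window = 0.08) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1L,
            palindromic_eaf_window >= 0, palindromic_eaf_window <= 0.5)
  instrument_ids <- unique(as.character(instrument_ids))
  ref <- exposures[[1L]]
  if (!all(instrument_ids %in% ref$variant_id)) {
    stop("instrument_ids must be a subset of the first exposure's variants")
  }
  k <- length(exposures)
  labels <- vapply(exposures, trait_label, character(1))

  n <- length(instrument_ids)
  keep <- logical(n)
  reason <- character(n)
  bx <- matrix(NA_real_, n, k)
  sx <- matrix(NA_real_, n, k)
  by <- sy <- rep(NA_real_, n)
  ea <- oa <- rep(NA_character_, n)
  eaf <- rep(NA_real_, n)

  # Align one record to reference alleles; returns list(beta, eaf, ok).
  align <- function(rec_ea, rec_oa, rec_beta, rec_eaf, ref_ea, ref_oa) {
    if (rec_ea == ref_ea && rec_oa == ref_oa) {
      return(list(beta = rec_beta, eaf = rec_eaf, ok = TRUE))
    }
    if (rec_ea == ref_oa && rec_oa == ref_ea) {
      return(list(beta = -rec_beta, eaf = 1 - rec_eaf, ok = TRUE))
    }
    cea <- .complement[[rec_ea]]; coa <- .complement[[rec_oa]]
    if (cea == ref_ea && coa == ref_oa) {
      return(list(beta = rec_beta, eaf = rec_eaf, ok = TRUE))
    }
    if (cea == ref_oa && coa == ref_ea) {
      return(list(beta = -rec_beta, eaf = 1 - rec_eaf, ok = TRUE))
    }
    list(beta = NA_real_, eaf = NA_real_, ok = FALSE)
  }

  idx_of <- function(ds) match(instrument_ids, ds$variant_id)
  ref_idx <- idx_of(ref)
  other_idx <- lapply(exposures[-1L][seq_len(k - 1L)], idx_of)
  out_idx <- idx_of(outcome)

  for (i in seq_len(n)) {
    ri <- ref_idx[i]
    present <- !is.na(out_idx[i]) &&
      all(vapply(other_idx, function(ix) !is.na(ix[i]), logical(1)))
    if (!present) { reason[i] <- "missing"; next }
    ea_i <- ref$effect_allele[ri]; oa_i <- ref$other_allele[ri]
    pal <- .is_palindromic(ea_i, oa_i)
    bx[i, 1L] <- ref$beta[ri]; sx[i, 1L] <- ref$se[ri]
    eafs <- ref$eaf[ri]
    aligned_eafs <- ref$eaf[ri]
    ok <- TRUE
    vals <- vector("list", k - 1L)
    for (j in seq_len(k - 1L)) {
      ds <- exposures[[j + 1L]]
      ix <- other_idx[[j]][i]
      a <- align(ds$effect_allele[ix], ds$other_allele[ix],
                 ds$beta[ix], ds$eaf[ix], ea_i, oa_i)
      if (!a$ok) { ok <- FALSE; break }
      vals[[j]] <- c(a$beta, ds$se[ix])
      eafs <- c(eafs, ds$eaf[ix])
      aligned_eafs <- c(aligned_eafs, a$eaf)
    }
    if (ok) {
      oi <- out_idx[i]
      a <- align(outcome$effect_allele[oi], outcome$other_allele[oi],
                 outcome$beta[oi], outcome$eaf[oi], ea_i, oa_i)
      ok <- a$ok
      if (ok) {
        by[i] <- a$beta; sy[i] <- outcome$se[oi]
        eafs <- c(eafs, outcome$eaf[oi])
        aligned_eafs <- c(aligned_eafs, a$eaf)
      }
    }
    if (!ok) { reason[i] <- "allele_mismatch"; next }
    if (pal) {
      # strand cannot be resolved from alleles; eaf must disambiguate
      if (anyNA(eafs) ||
          any(abs(eafs - 0.5) <= palindromic_eaf_window)) {
        reason[i] <- "palindromic_ambiguous"; next
      }
      # orient each aligned record by frequency concordance with reference
      ref_side <- sign(aligned_eafs[1L] - 0.5)
      flips <- sign(aligned_eafs - 0.5) != ref_side
      pos <- 2L
      for (j in seq_len(k - 1L)) {
        if (flips[pos]) vals[[j]][1L] <- -vals[[j]][1L]
        pos <- pos + 1L
      }
      if (flips[pos]) by[i] <- -by[i]
    }
    for (j in seq_len(k - 1L)) {
      bx[i, j + 1L] <- vals[[j]][1L]; sx[i, j + 1L] <- vals[[j]][2L]
    }
    ea[i] <- ea_i; oa[i] <- oa_i; eaf[i] <- ref$eaf[ri]
    keep[i] <- TRUE
  }

  rows <- data.frame(variant_id = instrument_ids[keep],
                     effect_allele = ea[keep],
                     other_allele = oa[keep],
                     eaf = eaf[keep],
                     stringsAsFactors = FALSE)
  dropped <- data.frame(variant_id = instrument_ids[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(exposure_labels = labels,
                 outcome_label = trait_label(outcome),
                 rows = rows,
                 bx = bx[keep, , drop = FALSE],
                 sx = sx[keep, , drop = FALSE],
                 by = by[keep],
                 sy = sy[keep],
                 dropped = dropped),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat("harmonised_set:", paste(x$exposure_labels, collapse = " + "),
      "->", x$outcome_label, "\n")
  cat(" ", nrow(x$rows), "instruments kept,", nrow(x$dropped), "dropped\n")
  invisible(x)
}

#' Number of instruments in a harmonised set
#' @param h A `harmonised_set`.
#' @return Integer count of retained instruments.
#' @export
n_instruments <- function(h) nrow(h$rows)

#' Subset a harmonised set by row index
#' @param h A `harmonised_set`.
#' @param idx Integer or logical index of rows to keep.
#' @return A `harmonised_set` with the selected rows.
#' @export
subset_harmonised <- function(h, idx) {
  h$rows <- h$rows[idx, , drop = FALSE]
  h$bx <- h$bx[idx, , drop = FALSE]
  h$sx <- h$sx[idx, , drop = FALSE]
  h$by <- h$by[idx]
  h$sy <- h$sy[idx]
  h
}

#' Re-orient rows so the first exposure's betas are non-negative
#'
#' Required before MR-Egger so the intercept is interpretable; all other
#' estimators are orientation-invariant.
#'
#' @param h A `harmonised_set`.
#' @param exposure Column index of the exposure to orient on (default 1).
#' @return A `harmonised_set` with rows flipped where needed.
#' @export
orient_positive <- function(h, exposure = 1L) {
  s <- sign(h$bx[, exposure])
  s[s == 0] <- 1
  h$bx <- h$bx * s
  h$by <- h$by * s
  h
}

#' Write the dropped-variant report
#' @param h A `harmonised_set`.
#' @param path Output path (tab-delimited `variant_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_dropped_report <- function(h, path) {
  utils::write.table(h$dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a log odds ratio to an odds ratio with confidence interval
#'
#' @param beta Log-odds effect estimate(s).
#' @param se Standard error(s), > 0 (0 allowed for degenerate CIs).
#' @param z Critical value (default 1.959964 for 95%).
#' @return Data frame with columns `or`, `ci_low`, `ci_high`.
#' @export
beta_to_or <- function(beta, se, z = 1.959964) {
  stopifnot(all(se >= 0))
  data.frame(or = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}
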