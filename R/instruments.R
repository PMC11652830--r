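# Instrument selection: significance filter, greedy LD clumping, F filter.

#' Construct an LD matrix object
#'
#' @param r2 Square numeric matrix of pairwise squared correlations with
#'   unit diagonal, values in \[0, 1\]; row/column names are variant ids
#'   (or supply `variant_ids`).
#' @param variant_ids Optional character vector of ids matching `r2`'s order.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("variant ids required for LD matrix")
  stopifnot(nrow(r2) == ncol(r2), length(variant_ids) == nrow(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("LD matrix must be symmetric")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from a tab-delimited file
#'
#' Expects a square matrix with a header row and a first column of variant
#' ids, as written by [write_ld_matrix()].
#'
#' @param path Path to the file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  ld_matrix(as.matrix(m))
}

#' Write an LD matrix to a tab-delimited file
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(ld$r2, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Genome-wide significance filter
#'
#' Returns the variants whose p-value is strictly below the threshold.
#'
#' @param dataset A [summary_dataset()].
#' @param p_threshold Significance level in (0, 1\]; default `5e-8`.
#' @return Character vector of variant ids (possibly empty, with a warning).
#' @export
genome_wide_filter <- function(dataset, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  ids <- dataset$variant_id[!is.na(dataset$pval) &
                              dataset$pval < p_threshold]
  if (length(ids) == 0L) {
    warning("no variants pass p < ", format(p_threshold))
  }
  ids
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken lexicographically by
#' variant id), then repeatedly takes the best remaining variant as an index
#' and removes every remaining variant on the same chromosome within
#' `window_kb` kilobases whose r-squared with the index is at least
#' `r2_max`.  Variants missing from the LD matrix are treated as
#' uncorrelated, with a warning.
#'
#' @param candidates Data frame with columns `variant_id`, `pval`, `chrom`,
#'   `pos` (a `summary_dataset` restricted to candidate rows works).
#' @param ld An [ld_matrix()], or `NULL` for identity LD (no correlation).
#' @param r2_max Exclusion threshold in (0, 1\]; default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000.
#' @return Character vector of index variant ids in selection order.
#' @export
ld_clump <- function(candidates, ld = NULL, r2_max = 0.001,
                     window_kb = 10000) {
  stopifnot(r2_max > 0, r2_max <= 1, window_kb > 0)
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) return(character(0))
  ord <- order(candidates$pval, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  ids <- as.character(cand$variant_id)
  if (!is.null(ld)) {
    absent <- setdiff(ids, ld$variant_ids)
    if (length(absent) > 0L) {
      warning(length(absent),
              " candidate(s) missing from LD matrix; treated as r2 = 0")
    }
  }
  r2_of <- function(a, b) {
    if (is.null(ld)) return(0)
    if (!(a %in% ld$variant_ids) || !(b %in% ld$variant_ids)) return(0)
    ld$r2[a, b]
  }
  selected <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    selected <- c(selected, ids[i])
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    same_chr <- cand$chrom[remaining] == cand$chrom[i] &
      abs(cand$pos[remaining] - cand$pos[i]) <= window_kb * 1000
    # unknown position: be conservative, treat as within the window
    same_chr[is.na(same_chr)] <- TRUE
    hit <- vapply(remaining, function(j) r2_of(ids[i], ids[j]) >= r2_max,
                  logical(1))
    remaining <- remaining[!(same_chr & hit)]
  }
  selected
}

#' Single-variant approximate F statistic
#'
#' Uses the squared Wald z, `F = (beta / se)^2`, which needs neither the
#' sample size nor the allele frequency.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), > 0.
#' @return Numeric F value(s).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Select genetic instruments
#'
#' Composition, in order, of the genome-wide significance filter, greedy LD
#' clumping, and the weak-instrument F filter.
#'
#' @param dataset A [summary_dataset()].
#' @param ld An [ld_matrix()] or `NULL` (identity LD).
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param r2_max Clumping exclusion threshold (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param f_min Minimum F statistic (default 10).
#' @return An `instrument_set`: list with `variant_ids`, per-variant
#'   `f_stats`, and `provenance` recording the four thresholds.
#' @export
select_instruments <- function(dataset, ld = NULL, p_threshold = 5e-8,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  ids <- suppressWarnings(genome_wide_filter(dataset, p_threshold))
  cand <- as.data.frame(dataset)[dataset$variant_id %in% ids, , drop = FALSE]
  clumped <- ld_clump(cand, ld, r2_max = r2_max, window_kb = window_kb)
  cand <- cand[match(clumped, cand$variant_id), , drop = FALSE]
  f <- f_statistic(cand$beta, cand$se)
  keep <- f > f_min
  if (!any(keep)) {
    stop("zero surviving instruments for ", trait_label(dataset),
         " (p < ", format(p_threshold), ", r2 < ", r2_max,
         ", window ", window_kb, " kb, F > ", f_min, ")")
  }
  structure(list(variant_ids = cand$variant_id[keep],
                 f_stats = stats::setNames(f[keep], cand$variant_id[keep]),
                 provenance = list(p_threshold = p_threshold,
                                   r2_max = r2_max,
                                   window_kb = window_kb,
                                   f_min = f_min)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  p <- x$provenance
  cat("instrument_set:", length(x$variant_ids), "instruments",
      sprintf("(p < %s, r2 < %s, window %s kb, F > %s)\n",
              format(p$p_threshold), p$r2_max, p$window_kb, p$f_min))
  invisible(x)
}
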