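#' Log2 transform with a pseudo-count
#'
#' @param raw nonnegative expression values (FPKM or TPM).
#' @param pseudocount positive pseudo-count added before the log.
#' @return `log2(raw + pseudocount)`.
#' @export
log2_with_pseudocount <- function(raw, pseudocount = 1) {
  if (!is.numeric(raw) || any(is.na(raw)) || any(raw < 0))
    stop("expression values must be nonnegative numbers")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  log2(raw + pseudocount)
}

#' Read a gene-expression table
#'
#' Tab-separated with columns `entity_id` (sample or cell line), `gene`,
#' `raw_value` and a `units` tag (e.g. `"FPKM"`, `"TPM"`,
#' `"log2(FPKM+1)"`); the units must be identical across rows.  A
#' `log_value` column is added (`log2(raw_value + pseudocount)`), unless
#' the declared units already say the values are log-transformed, in
#' which case `log_value = raw_value`.
#'
#' @param path TSV path.
#' @param pseudocount pseudo-count for the log transform.
#' @return Data frame with attribute `"units"`.
#' @export
read_expression_table <- function(path, pseudocount = 1) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entity_id", "gene", "raw_value", "units")
  if (!all(need %in% names(e)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  units <- unique(e$units)
  if (length(units) != 1L)
    stop("expression table mixes units: ", paste(units, collapse = ", "))
  if (grepl("^log2", units)) {
    e$log_value <- e$raw_value
  } else {
    e$log_value <- log2_with_pseudocount(e$raw_value, pseudocount)
  }
  attr(e, "units") <- units
  e
}

expression_units <- function(expr) {
  u <- attr(expr, "units")
  if (is.null(u)) u <- unique(expr$units)
  if (length(u) != 1L) stop("expression table mixes units")
  u
}

#' Calibrate the PTGR1 expression cutoff on cell lines
#'
#' The responder gate requires PTGR1 expression at the same or higher
#' level as a reference cell line (default A498, the line with the
#' highest PTGR1 protein expression and high irofulven sensitivity); the
#' cutoff is that line's expression value.  The cell-line table and the
#' cohort table must declare the same normalization.
#'
#' @param cellline_expr cell-line expression table (see
#'   [read_expression_table()]).
#' @param reference_line reference cell line name.
#' @param gene gene symbol of the gate.
#' @param cohort_units if given, the cohort table's declared units;
#'   a mismatch with the cell-line units is refused.
#' @return The cutoff on the log scale, with attribute `"units"`.
#' @export
calibrate_ptgr1_cutoff <- function(cellline_expr, reference_line = "A498",
                                   gene = "PTGR1", cohort_units = NULL) {
  units <- expression_units(cellline_expr)
  if (!is.null(cohort_units) && !identical(cohort_units, units))
    stop("cell-line units ('", units, "') differ from cohort units ('",
         cohort_units, "'); a common normalization is required")
  row <- cellline_expr[cellline_expr$entity_id == reference_line &
                       cellline_expr$gene == gene, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("reference line '", reference_line, "' has no ", gene,
         " entry in the cell-line table")
  structure(row$log_value[1], units = units)
}

#' Call NER deficiency and responder candidacy for samples
#'
#' A sample is NER-deficient (`nerd`) when its absolute ID8 exposure
#' strictly exceeds the threshold (default > 5), and a responder
#' candidate when additionally its PTGR1 expression is at or above the
#' cell-line-calibrated cutoff (inclusive).
#'
#' @param id8 numeric vector of absolute ID8 exposures (unrounded).
#' @param ptgr1 PTGR1 expression on the calibration scale.
#' @param id8_threshold NER-deficiency threshold (strict).
#' @param ptgr1_cutoff expression gate (inclusive), from
#'   [calibrate_ptgr1_cutoff()].
#' @param sample_id optional sample ids.
#' @param ercc_status optional per-sample ERCC status labels (see
#'   [ercc_mutation_status()]).
#' @return Data frame of class `"cohort_calls"` with columns
#'   `sample_id`, `id8`, `ptgr1`, `ercc_status`, `nerd`, `responder`.
#' @export
call_samples <- function(id8, ptgr1, ptgr1_cutoff, id8_threshold = 5,
                         sample_id = NULL, ercc_status = NULL) {
  if (any(!is.finite(id8)) || any(!is.finite(ptgr1)))
    stop("id8 and ptgr1 must be finite")
  if (is.null(sample_id))
    sample_id <- if (!is.null(names(id8))) names(id8)
                 else sprintf("sample%03d", seq_along(id8))
  if (is.null(ercc_status)) ercc_status <- rep(NA_character_, length(id8))
  nerd <- id8 > id8_threshold
  responder <- nerd & ptgr1 >= ptgr1_cutoff
  structure(data.frame(sample_id = sample_id, id8 = as.numeric(id8),
                       ptgr1 = as.numeric(ptgr1),
                       ercc_status = as.character(ercc_status),
                       nerd = nerd, responder = responder,
                       stringsAsFactors = FALSE, row.names = NULL),
            id8_threshold = id8_threshold,
            ptgr1_cutoff = as.numeric(ptgr1_cutoff),
            class = c("cohort_calls", "data.frame"))
}

#' Fisher exact test of ERCC-mutation enrichment above the ID8 cutoff
#'
#' Builds the 2x2 table of (any deleterious ERCC-family mutation) by
#' (above/below the ID8 cutoff, i.e. the `nerd` flag) and performs the
#' exact test (two-sided by default).  Degenerate margins are allowed
#' and give p = 1 with an undefined odds ratio.
#'
#' @param calls a `cohort_calls` data frame with non-`NA` `ercc_status`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List of class `"ercc_enrichment"`: `table` (2x2 counts),
#'   `odds_ratio` (conditional MLE, `NA` when undefined), `p_value`.
#' @export
ercc_enrichment <- function(calls, alternative = "two.sided") {
  if (any(is.na(calls$ercc_status)))
    stop("ercc_status must be known for every sample")
  mut <- factor(calls$ercc_status != "none", levels = c(TRUE, FALSE))
  high <- factor(calls$nerd, levels = c(TRUE, FALSE))
  tab <- table(ercc_mutant = mut, above_cutoff = high)
  enrichment_from_table(tab, alternative)
}

# core shared by ercc_enrichment and tests on raw tables
enrichment_from_table <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    res <- list(table = tab, odds_ratio = NA_real_, p_value = 1)
  } else {
    ft <- stats::fisher.test(tab, alternative = alternative)
    res <- list(table = tab, odds_ratio = unname(ft$estimate),
                p_value = ft$p.value)
  }
  class(res) <- "ercc_enrichment"
  res
}

#' @export
print.ercc_enrichment <- function(x, ...) {
  cat("ERCC-family mutation enrichment above the ID8 cutoff\n")
  print(x$table)
  cat("  odds ratio: ", format(x$odds_ratio, digits = 4),
      ",  Fisher p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Summarize a called cohort
#'
#' Reports totals and fractions (rounded to 0.1%) of NER-deficient and
#' responder-candidate samples, plus counts by ERCC status.  When the
#' cohort analyzed for mutations is a quality-controlled subset of a
#' larger expression cohort, `n_full` gives the full denominator and the
#' responder fraction is additionally reported against it.
#'
#' @param calls a `cohort_calls` data frame.
#' @param n_full optional full-cohort denominator.
#' @return List of class `"cohort_summary"`: `n_total`, `n_nerd`,
#'   `n_responder`, `pct_nerd`, `pct_responder`, `ercc_counts`, and
#'   (when `n_full` is given) `n_full`, `pct_responder_full`.
#' @export
summarize_cohort <- function(calls, n_full = NULL) {
  if (nrow(calls) == 0L) stop("empty cohort")
  pct <- function(n, d) round(100 * n / d, 1)
  n_total <- nrow(calls)
  n_nerd <- sum(calls$nerd)
  n_responder <- sum(calls$responder)
  out <- list(n_total = n_total, n_nerd = n_nerd, n_responder = n_responder,
              pct_nerd = pct(n_nerd, n_total),
              pct_responder = pct(n_responder, n_total),
              ercc_counts = table(calls$ercc_status, useNA = "no"))
  if (!is.null(n_full)) {
    out$n_full <- n_full
    out$pct_responder_full <- pct(n_responder, n_full)
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$n_total, " samples)\n", sep = "")
  cat("  NER-deficient (ID8 above threshold): ", x$n_nerd, " (",
      x$pct_nerd, "%)\n", sep = "")
  cat("  responder candidates (+ PTGR1 gate): ", x$n_responder, " (",
      x$pct_responder, "%)\n", sep = "")
  if (!is.null(x$n_full))
    cat("  responder fraction of full cohort (n = ", x$n_full, "): ",
        x$pct_responder_full, "%\n", sep = "")
  if (length(x$ercc_counts)) {
    nz <- x$ercc_counts[x$ercc_counts > 0]
    cat("  ERCC status: ",
        paste(sprintf("%s=%d", names(nz), as.integer(nz)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
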