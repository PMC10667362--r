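#' Run the full NER-deficiency calling pipeline on a cohort
#'
#' Chains the pipeline stages: somatic-variant and sample-level
#' filtering, annotation, ID-83 catalog construction, NNLS signature
#' refitting, PTGR1 cutoff calibration, per-sample NER-deficiency /
#' responder calling, ERCC-family enrichment testing, and cohort
#' summarization.
#'
#' @param variants variant table covering all samples (e.g. rbind of
#'   [read_somatic_vcf()] outputs, or `simulate_cohort()$variants`).
#' @param meta sample metadata table.
#' @param genome reference accessor.
#' @param signatures a `signature_matrix` containing `"ID8"`.
#' @param expression cohort expression table (data frame or TSV path).
#' @param cellline_expr cell-line expression table for cutoff
#'   calibration (data frame or TSV path).
#' @param annotations optional annotation table for ERCC status.
#' @param thresholds a [filter_thresholds()] object.
#' @param id8_threshold strict NER-deficiency threshold on ID8.
#' @param ptgr1_reference_line calibration cell line.
#' @param fisher_sided `"two.sided"` (default), `"greater"` or `"less"`.
#' @param n_full optional full-cohort denominator for the summary.
#' @return List of class `"ner_cohort_result"`: `cohort` (the
#'   [select_cohort()] result), `catalog`, `fit`, `id8`,
#'   `ptgr1_cutoff`, `calls`, `enrichment` (when annotations given) and
#'   `summary`.
#' @export
ner_call_cohort <- function(variants, meta, genome, signatures,
                            expression, cellline_expr,
                            annotations = NULL,
                            thresholds = filter_thresholds(),
                            id8_threshold = 5,
                            ptgr1_reference_line = "A498",
                            fisher_sided = "two.sided",
                            n_full = NULL) {
  genome <- as_ref_genome(genome)
  if (is.character(expression)) expression <- read_expression_table(expression)
  if (is.character(cellline_expr))
    cellline_expr <- read_expression_table(cellline_expr)
  if (is.null(expression$log_value))
    expression$log_value <- if (grepl("^log2", expression_units(expression)))
      expression$raw_value else log2_with_pseudocount(expression$raw_value)
  if (is.null(cellline_expr$log_value))
    cellline_expr$log_value <- if (grepl("^log2",
                                         expression_units(cellline_expr)))
      cellline_expr$raw_value else
      log2_with_pseudocount(cellline_expr$raw_value)

  cohort <- select_cohort(variants, meta, thresholds)
  records <- cohort$records
  if (!is.null(annotations)) {
    if (is.character(annotations)) annotations <- read_annotation_table(annotations)
    records <- annotate_variants(records, annotations)
  }
  catalog <- build_catalog(records, genome, samples = cohort$samples)
  fit <- nnls_refit(catalog, signatures)
  id8 <- id8_exposure(fit)

  cutoff <- calibrate_ptgr1_cutoff(cellline_expr,
                                   reference_line = ptgr1_reference_line,
                                   cohort_units = expression_units(expression))
  pt <- expression[expression$gene == "PTGR1", , drop = FALSE]
  ptgr1 <- pt$log_value[match(cohort$samples, pt$entity_id)]
  if (any(is.na(ptgr1)))
    stop("PTGR1 expression missing for sample(s): ",
         paste(cohort$samples[is.na(ptgr1)], collapse = ", "))

  ercc <- if (!is.null(annotations))
    ercc_mutation_status(records, samples = cohort$samples) else NULL
  calls <- call_samples(id8, ptgr1, ptgr1_cutoff = cutoff,
                        id8_threshold = id8_threshold,
                        sample_id = cohort$samples, ercc_status = ercc)
  res <- list(cohort = cohort, catalog = catalog, fit = fit, id8 = id8,
              ptgr1_cutoff = as.numeric(cutoff), calls = calls,
              enrichment = if (!is.null(ercc))
                ercc_enrichment(calls, alternative = fisher_sided) else NULL,
              summary = summarize_cohort(calls, n_full = n_full))
  class(res) <- "ner_cohort_result"
  res
}

#' @export
print.ner_cohort_result <- function(x, ...) {
  cat("NER-deficiency cohort analysis\n")
  cat("  retained samples: ", length(x$cohort$samples), " (",
      nrow(x$cohort$exclusions), " excluded)\n", sep = "")
  cat("  PTGR1 cutoff (calibrated): ", format(x$ptgr1_cutoff, digits = 4),
      "\n", sep = "")
  print(x$summary)
  if (!is.null(x$enrichment))
    cat("  ERCC enrichment Fisher p = ",
        format(x$enrichment$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
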