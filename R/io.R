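#' Write a variant table as a MuTect2-dialect VCF
#'
#' Emits VCF 4.2 with `TLOD`/`NLOD` in INFO and `GT:AD:AF:DP` FORMAT
#' fields for a TUMOR and a NORMAL column, plus `##tumor_sample=` /
#' `##normal_sample=` header lines.  Output is deterministic (no
#' timestamps), so identical inputs give byte-identical files.
#'
#' @param records variant table for one sample (see
#'   [read_somatic_vcf()] for the columns).
#' @param path output VCF path.
#' @param genome reference accessor (for `##contig` header lines).
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(records, path, genome) {
  genome <- as_ref_genome(genome)
  fmt1 <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                   scientific = FALSE))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            nchar(unclass(genome))),
    "##tumor_sample=TUMOR",
    "##normal_sample=NORMAL",
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"Log odds that the variant exists in the tumor\">",
    "##INFO=<ID=NLOD,Number=A,Type=Float,Description=\"Log odds that the variant is absent from the normal\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "TUMOR", "NORMAL"), collapse = "\t"))
  ord <- order(match(records$chrom, names(genome)), records$pos)
  r <- records[ord, , drop = FALSE]
  tumor <- sprintf("0/1:%s,%s:%s:%s",
                   fmt1(r$tumor_depth - r$tumor_alt), fmt1(r$tumor_alt),
                   fmt1(r$tumor_af), fmt1(r$tumor_depth))
  normal <- sprintf("0/0:%s,%s:%s:%s",
                    fmt1(r$normal_depth - r$normal_alt), fmt1(r$normal_alt),
                    fmt1(ifelse(is.na(r$normal_depth) | r$normal_depth == 0,
                                NA, r$normal_alt / r$normal_depth)),
                    fmt1(r$normal_depth))
  body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter,
                sprintf("TLOD=%s;NLOD=%s", fmt1(r$tlod), fmt1(r$nlod)),
                "GT:AD:AF:DP", tumor, normal, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Materializes a [simulate_cohort()] result as the file set every
#' pipeline stage consumes: an indexed reference FASTA, one VCF per
#' sample, tab-separated metadata / annotation / expression / signature
#' tables, the per-variant and per-sample ground-truth ledgers, and the
#' configuration as JSON.
#'
#' @param sim a `ner_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; VCFs land in `file.path(dir, "vcf")`.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "ner_simulation"))
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_ref_fasta(sim$genome, file.path(dir, "reference.fa"))
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in sim$samples$sample_id) {
    rec <- sim$variants[sim$variants$sample_id == s, , drop = FALSE]
    write_somatic_vcf(rec, file.path(dir, "vcf", paste0(s, ".vcf")),
                      sim$genome)
  }
  wt(sim$meta, "metadata.tsv")
  wt(sim$annotations, "annotations.tsv")
  wt(sim$expression, "expression_cohort.tsv")
  wt(sim$cellline_expr, "expression_celllines.tsv")
  write_signature_matrix(sim$signatures, file.path(dir, "signatures.tsv"))
  wt(sim$variants, "ledger_variants.tsv")
  wt(sim$samples, "ledger_samples.tsv")
  cfg <- unclass(sim$config)
  cfg$signatures <- NULL; cfg$reference <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
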