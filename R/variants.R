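#' Somatic-variant filter thresholds
#'
#' Default values are the stringent post-caller thresholds applied to
#' MuTect2 somatic calls: TLOD >= 6, NLOD >= 3, normal depth >= 15,
#' tumor depth >= 20, tumor ALT reads >= 5, normal ALT reads = 0, tumor
#' allele fraction >= 0.05, and a minimum of 50 retained variants per
#' sample for signature analysis.  All comparisons are inclusive.
#'
#' @param min_tlod,min_nlod minimum tumor / normal log-odds.
#' @param min_normal_depth,min_tumor_depth minimum read depths.
#' @param min_tumor_alt minimum ALT-supporting tumor reads.
#' @param max_normal_alt maximum ALT-supporting normal reads.
#' @param min_tumor_af minimum tumor allele fraction.
#' @param min_variants_per_sample minimum post-filter variant count for a
#'   sample to be retained.
#' @return A list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_tlod = 6, min_nlod = 3,
                              min_normal_depth = 15L, min_tumor_depth = 20L,
                              min_tumor_alt = 5L, max_normal_alt = 0L,
                              min_tumor_af = 0.05,
                              min_variants_per_sample = 50L) {
  t <- list(min_tlod = min_tlod, min_nlod = min_nlod,
            min_normal_depth = min_normal_depth,
            min_tumor_depth = min_tumor_depth,
            min_tumor_alt = min_tumor_alt, max_normal_alt = max_normal_alt,
            min_tumor_af = min_tumor_af,
            min_variants_per_sample = min_variants_per_sample)
  if (!all(vapply(t, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all thresholds must be finite numbers")
  class(t) <- "filter_thresholds"
  t
}

# header meta lookup for MuTect2's ##tumor_sample= / ##normal_sample= lines
.vcf_meta_value <- function(hdr, key) {
  m <- VariantAnnotation::meta(hdr)
  for (nm in names(m)) {
    df <- m[[nm]]
    if (key %in% rownames(df)) return(as.character(df[key, 1]))
  }
  NA_character_
}

#' Read a MuTect2-dialect somatic VCF into a variant table
#'
#' Parses a tumor/normal pair VCF (INFO `TLOD`/`NLOD`; FORMAT `AD`, `DP`,
#' `AF`) and emits one row per ALT allele: multi-allelic sites are split,
#' with AD/AF/TLOD apportioned per allele.  Coordinates and alleles are
#' preserved verbatim; caller statistics absent from a record surface as
#' `NA`, never as zeros.  The tumor allele fraction is taken from
#' FORMAT/AF when present and otherwise computed as ALT reads / depth.
#'
#' @param path VCF 4.x file.
#' @param sample_id identifier recorded in the `sample_id` column.
#' @param tumor_sample,normal_sample names of the tumor and normal sample
#'   columns; defaults to the `##tumor_sample=`/`##normal_sample=` header
#'   lines, then to literal `TUMOR`/`NORMAL` columns.
#' @return A data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `filter`, `tlod`, `nlod`, `tumor_depth`, `normal_depth`,
#'   `tumor_alt`, `normal_alt`, `tumor_af`, `gene`, `consequence`,
#'   `pathogenicity_label`.
#' @export
read_somatic_vcf <- function(path, sample_id,
                             tumor_sample = NULL, normal_sample = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L || is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF line ", i, " in ", path)
  }
  v <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::header(v)
  smp <- VariantAnnotation::samples(hdr)
  if (is.null(tumor_sample)) tumor_sample <- .vcf_meta_value(hdr, "tumor_sample")
  if (is.null(normal_sample)) normal_sample <- .vcf_meta_value(hdr, "normal_sample")
  if (is.na(tumor_sample) && "TUMOR" %in% smp) tumor_sample <- "TUMOR"
  if (is.na(normal_sample) && "NORMAL" %in% smp) normal_sample <- "NORMAL"
  if (is.na(tumor_sample) || !tumor_sample %in% smp)
    stop("cannot identify the tumor sample column in ", path)
  if (is.na(normal_sample) || !normal_sample %in% smp)
    stop("cannot identify the normal sample column in ", path)

  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(v))
  alts <- VariantAnnotation::alt(v)
  filt <- as.character(rr$FILTER)
  inf <- VariantAnnotation::info(v)
  gen <- VariantAnnotation::geno(v)

  per_alt <- function(field, i, j) {
    # INFO fields declared Number=A come back as lists; scalars recycle
    if (is.null(field)) return(NA_real_)
    x <- if (is.list(field) || methods::is(field, "List")) field[[i]] else field[i]
    x <- as.numeric(x)
    if (length(x) == 0L || all(is.na(x))) return(NA_real_)
    if (length(x) >= j) x[j] else x[1]
  }
  geno_vec <- function(name, i, sample) {
    g <- gen[[name]]
    if (is.null(g)) return(NULL)
    x <- g[i, sample]
    if (is.list(x)) x <- x[[1]]
    as.numeric(x)
  }

  out <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    av <- as.character(alts[[i]])
    n_alt <- length(av)
    ad_t <- geno_vec("AD", i, tumor_sample)
    ad_n <- geno_vec("AD", i, normal_sample)
    dp_t <- geno_vec("DP", i, tumor_sample)
    dp_n <- geno_vec("DP", i, normal_sample)
    af_t <- geno_vec("AF", i, tumor_sample)
    rows <- lapply(seq_len(n_alt), function(j) {
      talt <- if (!is.null(ad_t) && length(ad_t) >= 1L + j) ad_t[1L + j] else NA_real_
      nalt <- if (!is.null(ad_n) && length(ad_n) >= 1L + j) ad_n[1L + j] else NA_real_
      tdep <- if (length(dp_t)) dp_t[1] else if (!is.null(ad_t)) sum(ad_t) else NA_real_
      ndep <- if (length(dp_n)) dp_n[1] else if (!is.null(ad_n)) sum(ad_n) else NA_real_
      taf <- if (!is.null(af_t) && length(af_t) >= j && !is.na(af_t[j])) af_t[j]
             else if (!is.na(talt) && !is.na(tdep) && tdep > 0) talt / tdep
             else NA_real_
      data.frame(sample_id = sample_id, chrom = chrom[i], pos = pos[i],
                 ref = refs[i], alt = av[j], filter = filt[i],
                 tlod = per_alt(inf$TLOD, i, j), nlod = per_alt(inf$NLOD, i, j),
                 tumor_depth = tdep, normal_depth = ndep,
                 tumor_alt = talt, normal_alt = nalt, tumor_af = taf,
                 gene = NA_character_, consequence = NA_character_,
                 pathogenicity_label = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_variant_table()
  rownames(res) <- NULL
  res
}

empty_variant_table <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), filter = character(),
             tlod = numeric(), nlod = numeric(), tumor_depth = numeric(),
             normal_depth = numeric(), tumor_alt = numeric(),
             normal_alt = numeric(), tumor_af = numeric(),
             gene = character(), consequence = character(),
             pathogenicity_label = character(), stringsAsFactors = FALSE)
}

#' Evaluate the eight somatic-variant filter predicates
#'
#' A variant passes when FILTER is exactly `PASS`, TLOD and NLOD meet
#' their minima, normal and tumor depths meet theirs, tumor ALT reads
#' reach the minimum, normal ALT reads do not exceed the maximum, and
#' the tumor allele fraction reaches its minimum — all comparisons
#' inclusive.  A record with any tested field missing is rejected with
#' the distinct reason `"unevaluable"` rather than silently failing.
#'
#' @param records variant table (see [read_somatic_vcf()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return A data frame with one row per record: `pass` (logical) and
#'   `reason` (`"pass"`, `"unevaluable"`, or the first failing predicate:
#'   `"non-pass-filter"`, `"low-tlod"`, `"low-nlod"`,
#'   `"low-normal-depth"`, `"low-tumor-depth"`, `"low-tumor-alt"`,
#'   `"high-normal-alt"`, `"low-tumor-af"`).
#' @export
variant_filters <- function(records, thresholds = filter_thresholds()) {
  t <- thresholds
  n <- nrow(records)
  tested <- records[c("filter", "tlod", "nlod", "normal_depth",
                      "tumor_depth", "tumor_alt", "normal_alt", "tumor_af")]
  unev <- Reduce(`|`, lapply(tested, is.na))
  reason <- rep("pass", n)
  fail_if <- function(reason, cond, code) ifelse(reason == "pass" & cond & !unev,
                                                 code, reason)
  reason <- fail_if(reason, records$filter != "PASS", "non-pass-filter")
  reason <- fail_if(reason, records$tlod < t$min_tlod, "low-tlod")
  reason <- fail_if(reason, records$nlod < t$min_nlod, "low-nlod")
  reason <- fail_if(reason, records$normal_depth < t$min_normal_depth,
                    "low-normal-depth")
  reason <- fail_if(reason, records$tumor_depth < t$min_tumor_depth,
                    "low-tumor-depth")
  reason <- fail_if(reason, records$tumor_alt < t$min_tumor_alt, "low-tumor-alt")
  reason <- fail_if(reason, records$normal_alt > t$max_normal_alt,
                    "high-normal-alt")
  reason <- fail_if(reason, records$tumor_af < t$min_tumor_af, "low-tumor-af")
  reason[unev] <- "unevaluable"
  data.frame(pass = reason == "pass", reason = reason, stringsAsFactors = FALSE)
}

#' @rdname variant_filters
#' @param v a single-row (or multi-row) variant table.
#' @return `pass_variant_filters` returns a logical vector with the
#'   per-record reason codes attached as attribute `"reason"`.
#' @export
pass_variant_filters <- function(v, thresholds = filter_thresholds()) {
  f <- variant_filters(v, thresholds)
  structure(f$pass, reason = f$reason)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `patient_id`, `is_wga`,
#' `is_ffpe`, `is_msi`, `preference_rank`.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "is_wga", "is_ffpe", "is_msi",
            "preference_rank")
  if (!all(need %in% names(m)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  for (f in c("is_wga", "is_ffpe", "is_msi")) m[[f]] <- as.logical(m[[f]])
  m
}

#' Select the analyzable cohort and its filtered variants
#'
#' Applies the sample-level exclusions (whole-genome-amplified, FFPE and
#' microsatellite-unstable samples are removed), keeps exactly one sample
#' per patient (lowest `preference_rank`, ties broken by lexicographic
#' `sample_id`), applies the variant-level filters, and drops samples
#' whose post-filter variant total falls below the per-sample minimum.
#'
#' @param records variant table covering all candidate samples.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return A list: `samples` (retained sample ids), `records` (their
#'   passing variants), `n_pass` (named per-sample passing counts over
#'   all samples), and `exclusions` (data frame `sample_id`, `reason`
#'   with reasons `"wga"`, `"ffpe"`, `"msi"`, `"duplicate-patient"`,
#'   `"below-min-variants"`).
#' @export
select_cohort <- function(records, meta, thresholds = filter_thresholds()) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  unknown <- setdiff(unique(records$sample_id), meta$sample_id)
  if (length(unknown))
    stop("samples absent from metadata: ", paste(unknown, collapse = ", "))

  excl <- data.frame(sample_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids))
      excl <<- rbind(excl, data.frame(sample_id = ids, reason = reason,
                                      stringsAsFactors = FALSE))
  }
  drop(meta$sample_id[meta$is_wga], "wga")
  keep <- meta[!meta$is_wga, , drop = FALSE]
  drop(keep$sample_id[keep$is_ffpe], "ffpe")
  keep <- keep[!keep$is_ffpe, , drop = FALSE]
  drop(keep$sample_id[keep$is_msi], "msi")
  keep <- keep[!keep$is_msi, , drop = FALSE]

  keep <- keep[order(keep$patient_id, keep$preference_rank, keep$sample_id), ,
               drop = FALSE]
  dup <- duplicated(keep$patient_id)
  drop(keep$sample_id[dup], "duplicate-patient")
  keep <- keep[!dup, , drop = FALSE]

  flt <- variant_filters(records, thresholds)
  passing <- records[flt$pass, , drop = FALSE]
  n_pass <- stats::setNames(integer(nrow(meta)), meta$sample_id)
  tab <- table(factor(passing$sample_id, levels = meta$sample_id))
  n_pass[names(tab)] <- as.integer(tab)
  low <- keep$sample_id[n_pass[keep$sample_id] < thresholds$min_variants_per_sample]
  drop(low, "below-min-variants")
  keep <- keep[!keep$sample_id %in% low, , drop = FALSE]

  list(samples = keep$sample_id,
       records = passing[passing$sample_id %in% keep$sample_id, , drop = FALSE],
       n_pass = n_pass,
       exclusions = excl[order(excl$sample_id), , drop = FALSE])
}

#' Read and join a variant pathogenicity annotation table
#'
#' The annotation table is tab-separated, keyed by
#' (`chrom`, `pos`, `ref`, `alt`), with columns `gene`, `consequence`
#' and `pathogenicity_label` (Intervar-style: Benign, Likely Benign,
#' Uncertain Significance, Likely Pathogenic, Pathogenic).
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "pathogenicity_label")
  if (!all(need %in% names(a)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  a
}

#' @rdname read_annotation_table
#' @param records variant table to annotate.
#' @param annotations annotation data frame.
#' @return `annotate_variants` returns `records` with `gene`,
#'   `consequence` and `pathogenicity_label` filled where an annotation
#'   matches.
#' @export
annotate_variants <- function(records, annotations) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  i <- match(key(records), key(annotations))
  hit <- !is.na(i)
  records$gene[hit] <- annotations$gene[i[hit]]
  records$consequence[hit] <- annotations$consequence[i[hit]]
  records$pathogenicity_label[hit] <- annotations$pathogenicity_label[i[hit]]
  records
}

#' Flag deleterious mutations
#'
#' A variant is deleterious when it is an exonic SNV labelled Pathogenic
#' or Likely Pathogenic, a nonsense SNV (regardless of label), or an
#' indel labelled Pathogenic or Likely Pathogenic.  Unannotated records
#' are not deleterious and are flagged `"unannotated"` in the `note`
#' attribute.
#'
#' @param records annotated variant table.
#' @return Logical vector with attribute `"note"` (`NA` or
#'   `"unannotated"` per record).
#' @export
is_deleterious <- function(records) {
  patho <- records$pathogenicity_label %in% c("Pathogenic", "Likely Pathogenic")
  is_snv <- nchar(records$ref) == nchar(records$alt)
  cons <- tolower(ifelse(is.na(records$consequence), "", records$consequence))
  nonsense <- is_snv & grepl("nonsense|stopgain", cons)
  exonic_snv <- is_snv & grepl("exonic|snv", cons)
  out <- (exonic_snv & patho) | nonsense | (!is_snv & patho)
  note <- ifelse(is.na(records$consequence) & is.na(records$pathogenicity_label),
                 "unannotated", NA_character_)
  structure(out, note = note)
}

#' Per-sample ERCC-family mutation status
#'
#' Reports, per sample, the ERCC-family gene carrying a deleterious
#' mutation: `"none"`, the single gene name, or `"multi"` when two or
#' more distinct family genes are hit.
#'
#' @param records annotated variant table.
#' @param genes ERCC-family genes considered.
#' @param samples optional sample ids to report (defaults to those in
#'   `records`).
#' @return Named character vector, one label per sample.
#' @export
ercc_mutation_status <- function(records,
                                 genes = c("ERCC2", "ERCC3", "ERCC6"),
                                 samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(as.character(records$sample_id)))
  del <- is_deleterious(records)
  hits <- records[del & records$gene %in% genes & !is.na(records$gene), ,
                  drop = FALSE]
  out <- stats::setNames(rep("none", length(samples)), samples)
  if (nrow(hits)) {
    by_sample <- split(hits$gene, factor(hits$sample_id, levels = samples))
    for (s in names(by_sample)) {
      g <- unique(by_sample[[s]])
      if (length(g) == 1L) out[s] <- g
      else if (length(g) >= 2L) out[s] <- "multi"
    }
  }
  out
}
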