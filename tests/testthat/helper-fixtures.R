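# Shared fixtures, built once per test run.

shared_ref <- generate_reference(seed = 101)

toy_sig_path <- system.file("extdata", "toy_signatures.tsv",
                            package = "nerdsig")
toy_sigs <- read_signature_matrix(toy_sig_path)

# one-row variant table at the filter boundary (all eight fields at their
# inclusive passing limits)
boundary_record <- function(...) {
  r <- data.frame(sample_id = "S", chrom = "chr1", pos = 10L,
                  ref = "A", alt = "T", filter = "PASS",
                  tlod = 6, nlod = 3, tumor_depth = 20, normal_depth = 15,
                  tumor_alt = 5, normal_alt = 0, tumor_af = 0.05,
                  gene = NA_character_, consequence = NA_character_,
                  pathogenicity_label = NA_character_,
                  stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) r[[nm]] <- over[[nm]]
  r
}

# hand-written MuTect2-dialect VCF text
write_fixture_vcf <- function(body_lines, path,
                              contigs = c(chr1 = 10000L),
                              samples = c("TUMOR", "NORMAL")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##tumor_sample=TUMOR",
    "##normal_sample=NORMAL",
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"t\">",
    "##INFO=<ID=NLOD,Number=A,Type=Float,Description=\"n\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

# equivalent VCF spellings of the same physical indel (shifted within a
# repeat tract, optionally padded with shared reference context)
shifted_spellings <- function(genome, locus, max_reps = 6L) {
  cs <- unclass(genome)[[locus$chrom]]
  L <- nchar(locus$seq)
  shifts <- if (L == 1L) {
    seq_len(max(1L, oracle_run_length(cs, locus$start, locus$seq))) - 1L
  } else {
    L * (seq_len(max(1L, oracle_repeat_count(cs, locus$start, locus$seq))) - 1L)
  }
  if (locus$kind == "insertion") shifts <- c(0L, shifts)
  out <- list()
  for (k in utils::head(shifts, max_reps)) {
    s <- locus$start + k
    anchor <- substr(cs, s, s)
    if (locus$kind == "deletion") {
      del <- substr(cs, s + 1, s + L)
      ref <- paste0(anchor, del); alt <- anchor
    } else {
      ref <- anchor; alt <- paste0(anchor, locus$seq)
    }
    pad <- substr(cs, s + nchar(ref), s + nchar(ref) + 1L)  # shared suffix
    out[[length(out) + 1L]] <- data.frame(
      chrom = locus$chrom, pos = s, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      chrom = locus$chrom, pos = s, ref = paste0(ref, pad),
      alt = paste0(alt, pad), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
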