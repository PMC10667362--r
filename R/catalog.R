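#' Normalize a VCF indel to its canonical left-aligned form
#'
#' Reduces a VCF REF/ALT pair to a pure insertion or deletion: shared
#' suffix and prefix bases (including the VCF anchor base) are stripped,
#' the event is checked against the reference, and the representation is
#' shifted to the smallest possible start coordinate (left alignment).
#' All equivalent VCF spellings of the same physical indel normalize to
#' the same `(start, seq, kind)`.
#'
#' @param chrom contig name.
#' @param pos 1-based VCF position.
#' @param ref,alt VCF REF and ALT alleles (uppercase DNA).
#' @param genome reference accessor, see [as_ref_genome()].
#' @return A list of class `"normalized_indel"` with fields `chrom`,
#'   `start` (0-based position of the first inserted/deleted base),
#'   `seq` (the inserted or deleted bases) and `kind` (`"insertion"` or
#'   `"deletion"`); or, for complex substitutions that are neither a pure
#'   insertion nor a pure deletion, a list with `classifiable = FALSE`
#'   and `reason = "complex"`.
#' @export
normalize_indel <- function(chrom, pos, ref, alt, genome) {
  genome <- as_ref_genome(genome)
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) < 1L || nchar(alt) < 1L || ref == alt)
    stop("REF and ALT must be nonempty and distinct")
  if (nchar(ref) == nchar(alt))
    stop("not an indel: REF and ALT have equal length")
  obs <- ref_window(genome, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop("REF allele '", ref, "' does not match the reference at ",
         chrom, ":", pos, " (found '", obs, "')")

  # strip shared suffix, then shared prefix (the usual VCF anchor)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }

  if (nchar(ref) > 1L && nchar(alt) > 1L)
    return(structure(list(classifiable = FALSE, reason = "complex"),
                     class = "normalized_indel"))
  if (substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    # prefix-anchored: anchor at pos, event starts at pos + 1 (1-based)
    if (nchar(ref) > nchar(alt)) {
      kind <- "deletion"; seq <- substr(ref, 2L, nchar(ref))
    } else {
      kind <- "insertion"; seq <- substr(alt, 2L, nchar(alt))
    }
    start0 <- pos            # 0-based: (pos + 1) - 1
  } else if (substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
    # suffix-anchored spelling (e.g. at a contig start)
    if (nchar(ref) > nchar(alt)) {
      kind <- "deletion"; seq <- substr(ref, 1L, nchar(ref) - 1L)
    } else {
      kind <- "insertion"; seq <- substr(alt, 1L, nchar(alt) - 1L)
    }
    start0 <- pos - 1L
  } else {
    return(structure(list(classifiable = FALSE, reason = "complex"),
                     class = "normalized_indel"))
  }

  cs <- contig_seq(genome, chrom)
  L <- nchar(seq)
  # left-align: while the base before the event equals the event's last
  # base, rotate the event one base left
  while (start0 >= 1L &&
         substr(cs, start0, start0) == substr(seq, L, L)) {
    seq <- paste0(substr(cs, start0, start0), substr(seq, 1L, L - 1L))
    start0 <- start0 - 1L
  }
  structure(list(chrom = chrom, start = start0, seq = seq, kind = kind,
                 classifiable = TRUE),
            class = "normalized_indel")
}

char_at <- function(s, i0) substr(s, i0 + 1L, i0 + 1L)  # 0-based lookup

#' Homopolymer run length at a 1 bp indel locus
#'
#' For a 1 bp deletion, the length of the reference run of the deleted
#' base (including the deleted base itself); for a 1 bp insertion, the
#' length of the pre-existing reference run of the inserted base at the
#' insertion point (0 when the neighbors differ).  Counted rightward from
#' the left-aligned locus.
#'
#' @param n a classifiable `normalized_indel` with `nchar(seq) == 1`.
#' @param genome reference accessor.
#' @return Integer run length.
#' @export
homopolymer_length <- function(n, genome) {
  genome <- as_ref_genome(genome)
  stopifnot(n$classifiable, nchar(n$seq) == 1L)
  cs <- contig_seq(genome, n$chrom)
  b <- n$seq
  i <- n$start
  len <- 0L
  while (i < nchar(cs) && char_at(cs, i) == b) {
    len <- len + 1L; i <- i + 1L
  }
  len
}

#' Tandem-copy count of a multi-base indel's unit at its locus
#'
#' Number of exact contiguous copies of the inserted/deleted sequence in
#' the reference, scanning rightward from the left-aligned start.  For
#' deletions the deleted copy (present in the reference) is included; for
#' insertions only pre-existing copies are counted.
#'
#' @inheritParams homopolymer_length
#' @return Integer copy count (>= 1 for deletions, >= 0 for insertions).
#' @export
repeat_unit_count <- function(n, genome) {
  genome <- as_ref_genome(genome)
  stopifnot(n$classifiable, nchar(n$seq) >= 2L)
  cs <- contig_seq(genome, n$chrom)
  L <- nchar(n$seq)
  k <- 0L; p <- n$start
  while (p + L <= nchar(cs) && substr(cs, p + 1L, p + L) == n$seq) {
    k <- k + 1L; p <- p + L
  }
  k
}

#' Flanking microhomology length of a deletion
#'
#' The longest partial copy of the deleted sequence in the immediate
#' flanks: the maximum over (i) the longest k < length(seq) such that the
#' first k deleted bases equal the k reference bases immediately after
#' the deleted segment and (ii) the symmetric match of the deletion's
#' last k bases against the bases immediately before it.  A full copy is
#' a tandem repeat, not microhomology, so k is capped at length(seq) - 1.
#'
#' @param n a classifiable deleted `normalized_indel` with
#'   `nchar(seq) >= 2`.
#' @param genome reference accessor.
#' @return Integer microhomology length (0 when no partial copy).
#' @export
microhomology_length <- function(n, genome) {
  genome <- as_ref_genome(genome)
  stopifnot(n$classifiable, n$kind == "deletion", nchar(n$seq) >= 2L)
  cs <- contig_seq(genome, n$chrom)
  L <- nchar(n$seq)
  right <- 0L
  for (k in seq_len(L - 1L)) {
    if (n$start + L + k <= nchar(cs) &&
        substr(n$seq, 1L, k) == substr(cs, n$start + L + 1L, n$start + L + k))
      right <- k else break
  }
  left <- 0L
  for (k in seq_len(L - 1L)) {
    if (n$start - k >= 0L &&
        substr(n$seq, L - k + 1L, L) == substr(cs, n$start - k + 1L, n$start))
      left <- k else break
  }
  max(left, right)
}

#' Assign a normalized indel to its ID-83 channel
#'
#' 1 bp indels go to homopolymer channels with the base expressed as its
#' pyrimidine representative (A as T, G as C).  Longer insertions go to
#' repeat channels keyed by the number of pre-existing tandem copies.
#' Longer deletions go to repeat channels when the reference holds >= 2
#' tandem copies of the deleted unit, to microhomology channels when a
#' single copy carries flanking partial homology, and otherwise to the
#' single-copy repeat bin.  Sizes and counts are capped at their top
#' catalog bins (5+ / 6+).
#'
#' @inheritParams homopolymer_length
#' @return A channel label from `id83_channels()$label`.
#' @export
assign_channel <- function(n, genome) {
  genome <- as_ref_genome(genome)
  stopifnot(n$classifiable)
  L <- nchar(n$seq)
  kind <- if (n$kind == "deletion") "Del" else "Ins"
  if (L == 1L) {
    pyr <- c(A = "T", G = "C", C = "C", T = "T")[[n$seq]]
    h <- homopolymer_length(n, genome)
    return(id83_label(kind, 1L, pyr, h))
  }
  u <- repeat_unit_count(n, genome)
  if (kind == "Ins")
    return(id83_label("Ins", L, "R", u))
  if (u >= 2L)
    return(id83_label("Del", L, "R", u))
  m <- microhomology_length(n, genome)
  if (m >= 1L)
    return(id83_label("Del", L, "M", m))
  id83_label("Del", L, "R", 1L)
}

#' Classify one VCF-style indel into its ID-83 channel
#'
#' Convenience wrapper: [normalize_indel()] then [assign_channel()].
#'
#' @inheritParams normalize_indel
#' @return A channel label, or `NA_character_` for complex
#'   (unclassifiable) events.
#' @export
classify_indel <- function(chrom, pos, ref, alt, genome) {
  n <- normalize_indel(chrom, pos, ref, alt, genome)
  if (!isTRUE(n$classifiable)) return(NA_character_)
  assign_channel(n, genome)
}

#' Build per-sample ID-83 indel catalogs
#'
#' SNVs are ignored; every classifiable indel increments exactly one of
#' the 83 channels.  Complex events are excluded and counted per sample.
#'
#' @param records data frame of variants with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt` (typically the filtered output of the
#'   variants module).
#' @param genome reference accessor.
#' @param samples optional character vector of sample ids to include
#'   (samples with no indels get all-zero rows); defaults to the sorted
#'   sample ids present in `records`.
#' @return An integer matrix of class `"indel_catalog"`, samples x 83,
#'   columns in canonical channel order, with attribute `"unclassified"`
#'   (named per-sample counts of complex events).
#' @export
build_catalog <- function(records, genome, samples = NULL) {
  genome <- as_ref_genome(genome)
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt") %in% names(records)))
  if (is.null(samples)) samples <- sort(unique(as.character(records$sample_id)))
  channels <- .id83_table$label
  mat <- matrix(0L, nrow = length(samples), ncol = length(channels),
                dimnames = list(samples, channels))
  unclassified <- stats::setNames(integer(length(samples)), samples)
  is_indel <- nchar(records$ref) != nchar(records$alt)
  idx <- which(is_indel & records$sample_id %in% samples)
  for (i in idx) {
    lab <- classify_indel(records$chrom[i], records$pos[i],
                          records$ref[i], records$alt[i], genome)
    sid <- as.character(records$sample_id[i])
    if (is.na(lab)) {
      unclassified[sid] <- unclassified[sid] + 1L
    } else {
      mat[sid, lab] <- mat[sid, lab] + 1L
    }
  }
  structure(mat, unclassified = unclassified, class = "indel_catalog")
}

#' @export
print.indel_catalog <- function(x, ...) {
  cat("ID-83 indel catalog: ", nrow(x), " sample(s), ",
      sum(x), " classified indel(s)\n", sep = "")
  uc <- attr(x, "unclassified")
  if (!is.null(uc) && sum(uc) > 0)
    cat("  complex (unclassified) events: ", sum(uc), "\n", sep = "")
  top <- sort(colSums(unclass(x)), decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5L, sum(top > 0)))]
  if (length(top))
    cat("  top channels: ",
        paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Write / read a catalog matrix as TSV
#'
#' Samples in rows, the 83 channels in canonical order in columns.
#'
#' @param catalog an `indel_catalog` matrix.
#' @param path TSV path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog`
#'   returns an `indel_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(sample_id = rownames(catalog),
                   unclass(catalog)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- normalize_channel_label(setdiff(names(df), "sample_id"))
  mat <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  colnames(mat) <- labs
  missing <- setdiff(.id83_table$label, labs)
  if (length(missing))
    stop("catalog file missing channel(s): ", paste(missing, collapse = ", "))
  mat <- mat[, .id83_table$label, drop = FALSE]
  rownames(mat) <- df$sample_id
  storage.mode(mat) <- "integer"
  structure(mat, unclassified = stats::setNames(integer(nrow(mat)), df$sample_id),
            class = "indel_catalog")
}
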