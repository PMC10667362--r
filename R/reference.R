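#' Load a reference genome as an in-memory accessor
#'
#' Catalog construction needs fast random access to small reference contigs
#' (synthetic contigs or exome-scale subsets).  The accessor is a named
#' character vector of uppercase contig sequences; it can be built from an
#' (indexed) FASTA file, a [Biostrings::DNAStringSet], or a named character
#' vector.
#'
#' @param x FASTA path, `DNAStringSet`, or named character vector.
#' @return Named uppercase character vector of contig sequences, class
#'   `"ref_genome"`.
#' @export
as_ref_genome <- function(x) {
  if (inherits(x, "ref_genome")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
    # FASTA headers may carry descriptions after the contig name
    names(seqs) <- sub("\\s.*$", "", names(x))
    x <- seqs
  }
  if (!is.character(x) || is.null(names(x)) || any(names(x) == ""))
    stop("reference must be a FASTA path, DNAStringSet, or named character vector")
  x <- toupper(x)
  class(x) <- "ref_genome"
  x
}

contig_seq <- function(genome, chrom) {
  i <- match(chrom, names(genome))
  if (is.na(i))
    stop("contig '", chrom, "' absent from the reference")
  genome[[i]]
}

# Extract ref[start..end] (1-based, inclusive); clips at contig ends.
ref_window <- function(genome, chrom, start, end) {
  seq <- contig_seq(genome, chrom)
  n <- nchar(seq)
  if (start > end || end < 1L || start > n) return("")
  substr(seq, max(start, 1L), min(end, n))
}

contig_length <- function(genome, chrom) {
  nchar(contig_seq(genome, chrom))
}

#' Write a reference genome to an indexed FASTA file
#'
#' @param genome a `ref_genome` accessor (see [as_ref_genome()]).
#' @param path output FASTA path; a `.fai` index is created alongside.
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(genome, path) {
  genome <- as_ref_genome(genome)
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
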