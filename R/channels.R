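#' The COSMIC ID-83 indel channel catalog
#'
#' Small insertions and deletions are classified into 83 channels by type
#' (deletion/insertion), size (1, 2, 3, 4 or 5+ bp), sequence context
#' (homopolymer for 1 bp events, tandem repeat or flanking microhomology for
#' longer ones) and a context count.  The table is returned in the canonical
#' COSMIC row order used by published ID signature matrices, which is also
#' the row order of every catalog and signature matrix in this package.
#'
#' Channel labels follow the `size:kind:context:n` convention
#' (e.g. `"1:Del:C:0"`, `"5:Del:M:2"`).  The trailing number is the
#' zero-based COSMIC label; the columns `context_count` / `count_display`
#' carry the display semantics: for 1 bp deletions the homopolymer length
#' including the deleted base (1..6+), for 1 bp insertions the length of the
#' pre-existing run (0..5+), for >=2 bp deletions the number of tandem copies
#' of the deleted unit including the deleted copy (1..6+), for >=2 bp
#' insertions the number of pre-existing copies (0..5+), and for
#' microhomology deletions the length of the flanking homology (1..5+).
#'
#' @return A data frame with 83 rows and columns `label`, `kind`
#'   (`"Del"`/`"Ins"`), `size` (`"1"`,`"2"`,`"3"`,`"4"`,`"5+"`), `context`
#'   (`"C"`, `"T"`, `"R"`, `"M"`), `context_count` (integer, display
#'   semantics) and `count_display` (character, e.g. `"6+"`).
#' @examples
#' ch <- id83_channels()
#' nrow(ch)           # 83
#' head(ch$label)
#' @export
id83_channels <- function() {
  .id83_table
}

# Built once at load time; canonical COSMIC row order:
# 1bp del C/T, 1bp ins C/T, del repeats 2..5+, ins repeats 2..5+, del MH.
.build_id83_table <- function() {
  rows <- list()
  add <- function(kind, size, context, n, count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = sprintf("%s:%s:%s:%d", size, kind, context, n),
      kind = kind, size = size, context = context,
      context_count = count, stringsAsFactors = FALSE)
  }
  for (b in c("C", "T")) for (n in 0:5) add("Del", "1", b, n, n + 1L)
  for (b in c("C", "T")) for (n in 0:5) add("Ins", "1", b, n, n)
  for (s in c("2", "3", "4", "5+")) for (n in 0:5)
    add("Del", s, "R", n, n + 1L)
  for (s in c("2", "3", "4", "5+")) for (n in 0:5)
    add("Ins", s, "R", n, n)
  mh <- list(`2` = 1L, `3` = 1:2, `4` = 1:3, `5+` = 1:5)
  for (s in names(mh)) for (m in mh[[s]])
    add("Del", s, "M", m, m)
  out <- do.call(rbind, rows)
  # label uses "5" not "5+" in the size slot, per COSMIC convention
  out$label <- sub("^5\\+", "5", out$label)
  top <- with(out, (kind == "Del" & context %in% c("C", "T") & context_count == 6L) |
                   (kind == "Ins" & context %in% c("C", "T") & context_count == 5L) |
                   (kind == "Del" & context == "R" & context_count == 6L) |
                   (kind == "Ins" & context == "R" & context_count == 5L) |
                   (context == "M" & context_count == 5L))
  out$count_display <- ifelse(top, paste0(out$context_count, "+"),
                              as.character(out$context_count))
  stopifnot(nrow(out) == 83L, !anyDuplicated(out$label))
  rownames(out) <- NULL
  out
}

.id83_table <- .build_id83_table()

#' Construct an ID-83 channel label from display semantics
#'
#' @param kind `"Del"` or `"Ins"`.
#' @param size indel length in bp (capped at 5 for the label).
#' @param context one of `"C"`, `"T"`, `"R"`, `"M"`; 1 bp events use the
#'   pyrimidine base, longer events `"R"` (repeat) or `"M"` (microhomology).
#' @param count display count: homopolymer length / repeat copies /
#'   microhomology length (capped at the channel's top bin).
#' @return A channel label present in `id83_channels()$label`.
#' @keywords internal
id83_label <- function(kind, size, context, count) {
  size_lab <- if (size >= 5L) "5" else as.character(size)
  n <- if (kind == "Del" && context != "M") count - 1L else count
  cap <- if (context == "M") 5L else 5L
  n <- min(n, cap)
  lab <- sprintf("%s:%s:%s:%d", size_lab, kind, context, n)
  if (!lab %in% .id83_table$label)
    stop("internal error: invalid ID-83 channel ", lab)
  lab
}

#' Normalize an externally spelled channel label to canonical form
#'
#' Published ID signature files spell channels either as `1:Del:C:0`
#' (COSMIC website) or as `DEL_C_1_0` / `DEL_repeats_2_1` / `DEL_MH_5_2` /
#' `INS_T_1_4` (the signature-matrix releases).  Both are accepted.
#'
#' @param x character vector of channel labels.
#' @return Canonical labels matching `id83_channels()$label`.
#' @export
normalize_channel_label <- function(x) {
  x <- trimws(as.character(x))
  out <- x
  underscored <- grepl("^(DEL|INS)_", x, ignore.case = TRUE)
  if (any(underscored)) {
    parts <- strsplit(x[underscored], "_", fixed = TRUE)
    out[underscored] <- vapply(parts, function(p) {
      if (length(p) != 4L) return(NA_character_)
      kind <- c(DEL = "Del", INS = "Ins")[toupper(p[1])]
      ctx <- p[2]
      context <- if (toupper(ctx) %in% c("C", "T")) toupper(ctx)
                 else if (tolower(ctx) == "repeats") "R"
                 else if (toupper(ctx) == "MH") "M" else NA_character_
      size <- sub("\\+$", "", p[3])
      sprintf("%s:%s:%s:%s", size, kind, context, sub("\\+$", "", p[4]))
    }, character(1))
  }
  bad <- !out %in% .id83_table$label
  if (any(bad))
    stop("unknown ID-83 channel label(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}
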