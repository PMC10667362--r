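# Independent oracles: deliberately different mechanisms from the package
# implementation (whole-string edit comparison, rle runs, strrep scans,
# log-choose hypergeometric enumeration, projected-gradient NNLS).

# Canonical indel by exhaustive search: apply the edit to the whole contig
# and find the smallest start whose removal/insertion reproduces it.
oracle_normalize <- function(chrom, pos, ref, alt, genome) {
  cs <- unclass(as_ref_genome(genome))[[chrom]]
  n <- nchar(cs)
  edited <- paste0(substr(cs, 1, pos - 1), alt,
                   substr(cs, pos + nchar(ref), n))
  L <- abs(nchar(edited) - n)
  stopifnot(L > 0)
  win <- max(0L, pos - 120L):(pos + 120L)
  if (nchar(edited) < n) {
    for (s in win) {                       # deletion at 0-based s
      if (s < 0L || s + L > n) next
      cand <- paste0(substr(cs, 1, s), substr(cs, s + L + 1, n))
      if (cand == edited)
        return(list(chrom = chrom, start = s,
                    seq = substr(cs, s + 1, s + L), kind = "deletion"))
    }
  } else {
    for (s in win) {                       # insertion before 0-based s
      if (s < 0L || s > n) next
      ins <- substr(edited, s + 1, s + L)
      cand <- paste0(substr(edited, 1, s), substr(edited, s + L + 1, n + L))
      if (cand == cs)
        return(list(chrom = chrom, start = s, seq = ins, kind = "insertion"))
    }
  }
  stop("oracle: no representation found")
}

oracle_run_length <- function(cs, start0, base) {
  tail <- substr(cs, start0 + 1, min(nchar(cs), start0 + 60))
  r <- rle(strsplit(tail, "")[[1]])
  if (length(r$values) && r$values[1] == base) r$lengths[1] else 0L
}

oracle_repeat_count <- function(cs, start0, unit) {
  k <- 0L
  while (startsWith(substr(cs, start0 + 1, nchar(cs)), strrep(unit, k + 1L)))
    k <- k + 1L
  k
}

oracle_mh <- function(cs, start0, seq) {
  L <- nchar(seq)
  right <- 0L
  for (k in (L - 1L):1L) {
    if (substr(seq, 1, k) == substr(cs, start0 + L + 1, start0 + L + k)) {
      right <- k; break
    }
  }
  left <- 0L
  for (k in (L - 1L):1L) {
    if (start0 - k >= 0L &&
        substr(seq, L - k + 1, L) == substr(cs, start0 - k + 1, start0)) {
      left <- k; break
    }
  }
  max(left, right)
}

# Independent channel decision, written from the catalog definition.
oracle_channel <- function(chrom, pos, ref, alt, genome) {
  cs <- unclass(as_ref_genome(genome))[[chrom]]
  nrm <- oracle_normalize(chrom, pos, ref, alt, genome)
  L <- nchar(nrm$seq)
  if (L == 1L) {
    b <- c(A = "T", T = "T", G = "C", C = "C")[[nrm$seq]]
    run <- oracle_run_length(cs, nrm$start, nrm$seq)
    if (nrm$kind == "deletion")
      return(sprintf("1:Del:%s:%d", b, min(run, 6L) - 1L))
    return(sprintf("1:Ins:%s:%d", b, min(run, 5L)))
  }
  size <- min(L, 5L)
  u <- oracle_repeat_count(cs, nrm$start, nrm$seq)
  if (nrm$kind == "insertion")
    return(sprintf("%d:Ins:R:%d", size, min(u, 5L)))
  if (u >= 2L)
    return(sprintf("%d:Del:R:%d", size, min(u, 6L) - 1L))
  m <- oracle_mh(cs, nrm$start, nrm$seq)
  if (m >= 1L) return(sprintf("%d:Del:M:%d", size, min(m, 5L)))
  sprintf("%d:Del:R:0", size)
}

# Projected-gradient NNLS with fixed step 1/||S'S||.
oracle_nnls <- function(S, y, max_iter = 200000L, tol = 1e-13) {
  StS <- crossprod(S)
  Sty <- crossprod(S, y)
  step <- 1 / max(eigen(StS, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(0, ncol(S))
  for (i in seq_len(max_iter)) {
    xn <- pmax(0, x - step * (StS %*% x - Sty))
    if (max(abs(xn - x)) < tol) return(as.numeric(xn))
    x <- xn
  }
  as.numeric(x)
}

# Two-sided Fisher p by full enumeration over the hypergeometric support,
# densities from log-choose, with the standard relative tie tolerance.
oracle_fisher2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  ldens <- lchoose(c1, supp) + lchoose(n - c1, r1 - supp) - lchoose(n, r1)
  dens <- exp(ldens)
  pobs <- dens[supp == a]
  min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
}

# Straightforward re-application of the eight filter predicates.
oracle_filter_pass <- function(r, t = filter_thresholds()) {
  r$filter == "PASS" &
    r$tlod >= t$min_tlod & r$nlod >= t$min_nlod &
    r$normal_depth >= t$min_normal_depth &
    r$tumor_depth >= t$min_tumor_depth &
    r$tumor_alt >= t$min_tumor_alt &
    r$normal_alt <= t$max_normal_alt &
    r$tumor_af >= t$min_tumor_af
}

revcomp <- function(s) {
  vapply(s, function(x)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}
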