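#' Synthetic ID-signature definitions
#'
#' A small synthetic signature set for simulation and refitting tests.
#' The `ID8` column concentrates on deletions longer than 5 bp with no
#' or short (1-2 bp) flanking microhomology — the defining feature of
#' the NER-deficiency-associated signature; `ID1`/`ID2` put their mass
#' on 1 bp insertions/deletions at long homopolymers, and the optional
#' `ID5` column is a diffuse background over short-indel channels.
#' These are synthetic stand-ins, not the published COSMIC columns;
#' [read_signature_matrix()] accepts the published file for real use.
#'
#' @param include_background include the diffuse `ID5` column.
#' @return A `signature_matrix` (83 x 3 or 83 x 4).
#' @export
synthetic_id_signatures <- function(include_background = TRUE) {
  channels <- .id83_table$label
  col <- function(w) {
    v <- stats::setNames(numeric(83), channels)
    v[names(w)] <- w
    v
  }
  id1 <- col(c("1:Ins:T:5" = 0.55, "1:Ins:T:4" = 0.30,
               "1:Ins:C:5" = 0.10, "1:Ins:C:4" = 0.05))
  id2 <- col(c("1:Del:T:5" = 0.65, "1:Del:T:4" = 0.20,
               "1:Del:C:5" = 0.10, "1:Del:T:3" = 0.05))
  id8 <- col(c("5:Del:R:0" = 0.30, "5:Del:M:1" = 0.25, "5:Del:M:2" = 0.20,
               "4:Del:R:0" = 0.10, "5:Del:M:3" = 0.05, "3:Del:R:0" = 0.05,
               "2:Del:R:0" = 0.05))
  mat <- cbind(ID1 = id1, ID2 = id2, ID8 = id8)
  if (include_background) {
    bg <- sprintf("%s:%s:%s:%d",
                  c(rep("1", 12), rep("2", 5), rep("3", 4), rep("4", 4)),
                  c(rep(c("Del", "Del", "Del", "Ins", "Ins", "Ins"), each = 1,
                        times = 2),
                    rep(c("Del", "Del", "Del", "Ins", "Ins"), 1),
                    rep(c("Del", "Del", "Ins", "Ins"), 2)),
                  c(rep(c("T", "C"), each = 6), rep("R", 13)),
                  c(0:2, 0:2, 0:2, 0:2, 0:2, 0:1, 0:1, 0:1, 0:1, 0:1))
    id5 <- col(stats::setNames(rep(0.04, 25), bg))
    mat <- cbind(mat[, c("ID1", "ID2"), drop = FALSE], ID5 = id5,
                 ID8 = mat[, "ID8"])
  }
  rownames(mat) <- channels
  as_signature_matrix(mat)
}

#' Simulation configuration for synthetic cohorts
#'
#' The defaults describe the study conditions emulated by the
#' synthetic-data generator: a ccRCC-like whole-exome cohort with a
#' Poisson indel burden, a NER-deficient subgroup carrying a high ID8
#' exposure share, planted filter failures, group-dependent deleterious
#' ERCC-family mutation rates, and PTGR1 expression (simulated directly
#' in log2(FPKM+1) units) straddling a cell-line-calibrated cutoff.
#'
#' @param seed integer master seed; all randomness derives from it, with
#'   independent sub-streams per purpose (reference sequence, burden,
#'   channels, caller statistics, expression, annotations).
#' @param n_samples number of tumor samples.
#' @param n_contigs,contig_length synthetic reference layout (each
#'   contig at least `contig_length` bases, >= 10 kb).
#' @param loci_per_channel engineered loci per ID-83 channel (a subset
#'   is reserved for planting annotated mutations at unique positions).
#' @param mean_burden Poisson mean somatic-indel burden per sample.
#' @param nerd_fraction fraction of samples planted as NER-deficient.
#' @param nerd_profile,background_profile signature-mixture weights
#'   (named by signature, summing to 1) for the two groups.
#' @param fraction_filter_fail fraction of each sample's records planted
#'   to fail exactly one named filter predicate (planned exact counts,
#'   not sampled).
#' @param ptgr1_means high/low group means of PTGR1 log2 expression.
#' @param ptgr1_sd within-group standard deviation.
#' @param ptgr1_high_fraction probability a sample belongs to the
#'   high-expression group.
#' @param ercc_rate_nerd,ercc_rate_other per-group probabilities of a
#'   planted deleterious ERCC-family mutation.
#' @param ercc_multi_fraction fraction of ERCC hits carrying mutations
#'   in multiple family genes.
#' @param n_wga,n_ffpe,n_msi numbers of samples flagged for the
#'   corresponding metadata exclusions.
#' @param n_duplicate_patients patients contributing a second (extra,
#'   lower-preference) sample.
#' @param n_low_burden samples planted with too few variants to pass the
#'   per-sample minimum.
#' @param signatures `signature_matrix` used both to draw channels and
#'   (by default) to refit.
#' @param reference optional pre-built reference from
#'   [generate_reference()] (reused across cohorts for speed).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 40L,
                              n_contigs = 4L, contig_length = 10000L,
                              loci_per_channel = 26L,
                              mean_burden = 150,
                              nerd_fraction = 0.3,
                              nerd_profile = c(ID1 = 0.28, ID2 = 0.25,
                                               ID5 = 0.17, ID8 = 0.30),
                              background_profile = c(ID1 = 0.40, ID2 = 0.35,
                                                     ID5 = 0.24, ID8 = 0.01),
                              fraction_filter_fail = 0.15,
                              ptgr1_means = c(high = 6.5, low = 3.5),
                              ptgr1_sd = 0.5,
                              ptgr1_high_fraction = 0.6,
                              ercc_rate_nerd = 0.25, ercc_rate_other = 0.02,
                              ercc_multi_fraction = 0.15,
                              n_wga = 0L, n_ffpe = 0L, n_msi = 0L,
                              n_duplicate_patients = 0L, n_low_burden = 0L,
                              signatures = synthetic_id_signatures(),
                              reference = NULL) {
  stopifnot(contig_length >= 10000L,
            fraction_filter_fail >= 0, fraction_filter_fail < 1,
            nerd_fraction >= 0, nerd_fraction <= 1,
            ptgr1_high_fraction >= 0, ptgr1_high_fraction <= 1,
            abs(sum(nerd_profile) - 1) < 1e-9,
            abs(sum(background_profile) - 1) < 1e-9,
            all(names(nerd_profile) %in% colnames(signatures)),
            all(names(background_profile) %in% colnames(signatures)))
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

.bases <- c("A", "C", "G", "T")
rand_base <- function(exclude = character()) {
  sample(setdiff(.bases, exclude), 1L)
}
rand_seq <- function(n) paste(sample(.bases, n, replace = TRUE), collapse = "")

# a primitive (non-periodic), non-homopolymer unit of length L
rand_unit <- function(L) {
  repeat {
    s <- rand_seq(L)
    ok <- length(unique(strsplit(s, "")[[1]])) >= 2L
    if (ok) {
      for (d in seq_len(L - 1L)) {
        if (L %% d == 0L &&
            s == strrep(substr(s, 1L, d), L %/% d)) { ok <- FALSE; break }
      }
    }
    if (ok) return(s)
  }
}

# Build one engineered locus block for a channel; returns the block
# sequence, the 0-based event start *within the block*, the event
# sequence and kind.  Guard bases inside the block insulate the context
# from whatever sequence surrounds it.
.build_locus <- function(ch) {
  top <- endsWith(ch$count_display, "+")
  if (ch$size == "1") {
    b <- sample(if (ch$context == "T") c("T", "A") else c("C", "G"), 1L)
    h <- if (ch$kind == "Del") {
      if (top) sample(6:8, 1L) else ch$context_count
    } else {
      if (top) sample(5:7, 1L) else ch$context_count
    }
    block <- paste0(rand_base(b), strrep(b, h), rand_base(b))
    if (ch$kind == "Del")
      return(list(block = block, start = 1L, seq = b, kind = "deletion"))
    # insertion of b immediately before the run (or between the guards)
    return(list(block = block, start = 1L, seq = b, kind = "insertion"))
  }
  L <- if (ch$size == "5+") sample(5:7, 1L) else as.integer(ch$size)
  if (ch$context == "M") {
    m <- ch$context_count
    if (ch$size == "5+") L <- max(L, m + 1L)
    S <- rand_unit(L)
    g1 <- rand_base(substr(S, L, L))
    x <- rand_base(substr(S, m + 1L, m + 1L))
    block <- paste0(g1, S, substr(S, 1L, m), x)
    return(list(block = block, start = 1L, seq = S, kind = "deletion"))
  }
  # tandem-repeat context
  u <- if (ch$kind == "Del") {
    if (top) sample(6:7, 1L) else ch$context_count
  } else {
    if (top) sample(5:6, 1L) else ch$context_count
  }
  S <- rand_unit(L)
  g1 <- rand_base(substr(S, L, L))
  g2 <- rand_base(substr(S, 1L, 1L))
  if (ch$kind == "Del") {
    block <- paste0(g1, strrep(S, u), g2)
    return(list(block = block, start = 1L, seq = S, kind = "deletion"))
  }
  block <- paste0(g1, strrep(S, u), g2)
  list(block = block, start = 1L, seq = S, kind = "insertion")
}

#' Generate an engineered synthetic reference genome
#'
#' Contigs of roughly uniform base composition carrying engineered loci
#' sufficient to realize all 83 indel channels: homopolymers up to
#' length 8, tandem repeats of unit sizes 2-7, and microhomology-flanked
#' unique segments.  The locus registry (channel, contig, 0-based event
#' start, event sequence, kind, reserved flag) is attached as attribute
#' `"loci"`; reserved loci are kept aside for planting annotated
#' mutations at globally unique coordinates.  Fully reproducible: the
#' same seed gives a byte-identical FASTA.
#'
#' @param seed integer seed.
#' @param n_contigs,contig_length layout (contigs at least
#'   `contig_length` bases; minimum 10 kb).
#' @param loci_per_channel engineered loci per channel.
#' @param n_reserved_per_channel loci per channel reserved for
#'   annotation planting.
#' @return A `ref_genome` with attribute `"loci"` (data frame).
#' @export
generate_reference <- function(seed = 1L, n_contigs = 4L,
                               contig_length = 10000L,
                               loci_per_channel = 26L,
                               n_reserved_per_channel = 6L) {
  stopifnot(contig_length >= 10000L,
            n_reserved_per_channel < loci_per_channel)
  set.seed(seed)
  tab <- .id83_table
  jobs <- tab[rep(seq_len(nrow(tab)), each = loci_per_channel), , drop = FALSE]
  jobs$reserved <- rep(c(rep(FALSE, loci_per_channel - n_reserved_per_channel),
                         rep(TRUE, n_reserved_per_channel)), nrow(tab))
  ord <- sample.int(nrow(jobs))
  jobs <- jobs[ord, , drop = FALSE]
  contig_of <- rep_len(seq_len(n_contigs), nrow(jobs))

  parts <- vector("list", n_contigs)
  offsets <- integer(n_contigs)
  loci <- vector("list", nrow(jobs))
  for (k in seq_len(n_contigs)) parts[[k]] <- list(rand_seq(sample(12:20, 1L)))
  for (k in seq_len(n_contigs)) offsets[k] <- nchar(parts[[k]][[1]])
  for (i in seq_len(nrow(jobs))) {
    ci <- contig_of[i]
    loc <- .build_locus(jobs[i, ])
    loci[[i]] <- data.frame(
      channel = jobs$label[i], chrom = paste0("chr", ci),
      start = offsets[ci] + loc$start, seq = loc$seq, kind = loc$kind,
      reserved = jobs$reserved[i], stringsAsFactors = FALSE)
    spacer <- rand_seq(sample(12:20, 1L))
    parts[[ci]] <- c(parts[[ci]], list(loc$block, spacer))
    offsets[ci] <- offsets[ci] + nchar(loc$block) + nchar(spacer)
  }
  seqs <- vapply(parts, function(p) paste(unlist(p), collapse = ""), character(1))
  pad <- pmax(0L, contig_length - nchar(seqs))
  for (k in seq_len(n_contigs))
    if (pad[k] > 0L) seqs[k] <- paste0(seqs[k], rand_seq(pad[k]))
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  genome <- as_ref_genome(seqs)
  attr(genome, "loci") <- do.call(rbind, loci)
  genome
}

#' Audit the engineered loci of a synthetic reference
#'
#' @param genome a reference from [generate_reference()].
#' @return Named integer vector: realizable loci per channel.
#' @export
audit_reference_loci <- function(genome) {
  loci <- attr(genome, "loci")
  if (is.null(loci)) stop("reference carries no locus registry")
  table(factor(loci$channel, levels = .id83_table$label))
}

.fail_codes <- c("non-pass-filter", "low-tlod", "low-nlod",
                 "low-normal-depth", "low-tumor-depth", "low-tumor-alt",
                 "high-normal-alt", "low-tumor-af")

# vectorized caller-statistics draw; `fate` is "pass" or a .fail_codes entry
.draw_caller_stats <- function(n, fate) {
  filter <- rep("PASS", n)
  tlod <- round(stats::runif(n, 6, 60), 2)
  nlod <- round(stats::runif(n, 3, 40), 2)
  ndepth <- sample(20:80, n, replace = TRUE)
  tdepth <- sample(30:150, n, replace = TRUE)
  af_target <- stats::runif(n, 0.08, 0.6)
  talt <- pmin(pmax(pmax(5L, ceiling(0.05 * tdepth)),
                    round(af_target * tdepth)), tdepth)
  af <- round(talt / tdepth, 4)
  nalt <- rep(0L, n)

  i <- which(fate == "non-pass-filter")
  filter[i] <- sample(c("germline", "artifact_in_normal"), length(i), TRUE)
  i <- which(fate == "low-tlod"); tlod[i] <- round(stats::runif(length(i), 0, 5.99), 2)
  i <- which(fate == "low-nlod"); nlod[i] <- round(stats::runif(length(i), 0, 2.99), 2)
  i <- which(fate == "low-normal-depth")
  ndepth[i] <- sample(0:14, length(i), replace = TRUE)
  i <- which(fate == "low-tumor-depth")
  if (length(i)) {
    tdepth[i] <- sample(10:19, length(i), replace = TRUE)
    talt[i] <- pmin(talt[i], tdepth[i])
    talt[i] <- pmax(talt[i], 5L)
    af[i] <- round(talt[i] / tdepth[i], 4)
  }
  i <- which(fate == "low-tumor-alt")
  if (length(i)) {
    talt[i] <- sample(0:4, length(i), replace = TRUE)
    af[i] <- round(stats::runif(length(i), 0.05, 0.1), 4)
  }
  i <- which(fate == "high-normal-alt")
  nalt[i] <- sample(1:3, length(i), replace = TRUE)
  i <- which(fate == "low-tumor-af")
  af[i] <- round(stats::runif(length(i), 0.005, 0.049), 4)

  data.frame(filter = filter, tlod = tlod, nlod = nlod,
             tumor_depth = tdepth, normal_depth = ndepth,
             tumor_alt = talt, normal_alt = nalt, tumor_af = af,
             stringsAsFactors = FALSE)
}

# VCF-style alleles for a registry locus (prefix anchor base)
.locus_alleles <- function(genome, locus) {
  cs <- contig_seq(genome, locus$chrom)
  anchor <- substr(cs, locus$start, locus$start)  # base before the event
  if (locus$kind == "deletion") {
    list(pos = locus$start, ref = paste0(anchor, locus$seq), alt = anchor)
  } else {
    list(pos = locus$start, ref = anchor, alt = paste0(anchor, locus$seq))
  }
}

#' Realize one variant of a requested ID-83 channel
#'
#' Picks an engineered locus of the channel from the reference's
#' registry and emits a MuTect2-dialect variant record whose normalized,
#' classified form maps back to exactly the requested channel.  Caller
#' statistics are drawn to pass all filter predicates unless
#' `fail_predicate` names the single predicate to violate.
#'
#' @param channel an ID-83 channel label.
#' @param genome a reference from [generate_reference()].
#' @param sample_id sample identifier for the record.
#' @param fail_predicate `NULL`, or one of `"non-pass-filter"`,
#'   `"low-tlod"`, `"low-nlod"`, `"low-normal-depth"`,
#'   `"low-tumor-depth"`, `"low-tumor-alt"`, `"high-normal-alt"`,
#'   `"low-tumor-af"`.
#' @return One-row variant table (see [read_somatic_vcf()]) with extra
#'   columns `channel` and `fate`.
#' @export
realize_variant <- function(channel, genome, sample_id = "sample",
                            fail_predicate = NULL) {
  loci <- attr(genome, "loci")
  if (is.null(loci)) stop("reference carries no locus registry")
  channel <- normalize_channel_label(channel)
  cand <- which(loci$channel == channel & !loci$reserved)
  if (!length(cand)) stop("channel ", channel, " has no realizable locus")
  locus <- loci[sample(cand, 1L), ]
  fate <- if (is.null(fail_predicate)) "pass"
          else match.arg(fail_predicate, .fail_codes)
  al <- .locus_alleles(genome, locus)
  st <- .draw_caller_stats(1L, fate)
  cbind(data.frame(sample_id = sample_id, chrom = locus$chrom, pos = al$pos,
                   ref = al$ref, alt = al$alt, stringsAsFactors = FALSE),
        st,
        data.frame(gene = NA_character_, consequence = NA_character_,
                   pathogenicity_label = NA_character_,
                   channel = channel, fate = fate, stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic cohort with a ground-truth ledger
#'
#' Generates (or reuses) an engineered reference, draws per-sample indel
#' burdens from the Poisson burden law, draws channels multinomially
#' from each sample's signature mixture, realizes every variant as a
#' MuTect2-dialect record, plants an exact count of filter-failing
#' records (each violating exactly one named predicate, cycling through
#' all eight), plants deleterious ERCC-family annotations at
#' group-dependent rates on reserved (globally unique) loci, and draws
#' PTGR1 expression per group around a planted cell-line cutoff.
#' Everything is recorded in the ledger and fully reproducible from the
#' seed.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `"ner_simulation"`: `genome`, `variants`
#'   (all emitted records with planted `channel` and `fate`), `meta`
#'   (sample metadata table), `annotations`, `expression` (cohort PTGR1,
#'   log2(FPKM+1) units), `cellline_expr` (incl. the A498 calibration
#'   line), `signatures`, `samples` (per-sample ledger: group, planted
#'   mixture weights, planted PTGR1 and ERCC status, planned counts),
#'   `ptgr1_cutoff_planted`, and `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ss <- sample.int(.Machine$integer.max - 1L, 6L)

  genome <- cfg$reference
  if (is.null(genome))
    genome <- generate_reference(seed = ss[1], n_contigs = cfg$n_contigs,
                                 contig_length = cfg$contig_length,
                                 loci_per_channel = cfg$loci_per_channel)
  loci <- attr(genome, "loci")
  sigs <- cfg$signatures
  channels <- rownames(sigs)

  # --- sample sheet ---------------------------------------------------
  set.seed(ss[2])
  n <- cfg$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  patients <- sprintf("P%03d", seq_len(n))
  n_nerd <- round(cfg$nerd_fraction * n)
  group <- rep("background", n)
  group[sample.int(n, n_nerd)] <- "nerd"
  flag <- function(k, taken) {
    pool <- setdiff(seq_len(n), taken)
    sort(sample(pool, min(k, length(pool))))
  }
  i_wga <- flag(cfg$n_wga, integer())
  i_ffpe <- flag(cfg$n_ffpe, i_wga)
  i_msi <- flag(cfg$n_msi, c(i_wga, i_ffpe))
  i_low <- flag(cfg$n_low_burden, c(i_wga, i_ffpe, i_msi))
  samples <- data.frame(
    sample_id = ids, patient_id = patients,
    is_wga = seq_len(n) %in% i_wga, is_ffpe = seq_len(n) %in% i_ffpe,
    is_msi = seq_len(n) %in% i_msi, preference_rank = 1L,
    group = group, low_burden = seq_len(n) %in% i_low,
    stringsAsFactors = FALSE)
  if (cfg$n_duplicate_patients > 0L) {
    dup_of <- sample.int(n, cfg$n_duplicate_patients)
    extra <- samples[dup_of, , drop = FALSE]
    extra$sample_id <- paste0(extra$sample_id, "b")
    extra$preference_rank <- 2L
    extra$is_wga <- FALSE; extra$is_ffpe <- FALSE; extra$is_msi <- FALSE
    samples <- rbind(samples, extra)
  }
  m <- nrow(samples)
  burden <- stats::rpois(m, ifelse(samples$low_burden,
                                   min(20, cfg$mean_burden / 5),
                                   cfg$mean_burden))
  samples$n_records <- burden
  samples$n_fail_planned <- round(cfg$fraction_filter_fail * burden)

  # --- channel draws --------------------------------------------------
  set.seed(ss[3])
  profile_of <- function(g) {
    w <- if (g == "nerd") cfg$nerd_profile else cfg$background_profile
    full <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
    full[names(w)] <- w
    full
  }
  var_rows <- vector("list", m)
  for (i in seq_len(m)) {
    N <- burden[i]
    if (N == 0L) next
    p <- as.numeric(unclass(sigs) %*% profile_of(samples$group[i]))
    cnt <- as.integer(stats::rmultinom(1L, N, p))
    chv <- rep(channels, cnt)
    chv <- chv[sample.int(length(chv))]
    n_fail <- samples$n_fail_planned[i]
    fate <- rep("pass", N)
    if (n_fail > 0L)
      fate[seq_len(n_fail)] <- .fail_codes[(seq_len(n_fail) - 1L) %% 8L + 1L]
    var_rows[[i]] <- data.frame(sample_id = samples$sample_id[i],
                                channel = chv, fate = fate,
                                stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)

  # map each draw to a non-reserved engineered locus of its channel
  open_idx <- split(which(!loci$reserved), loci$channel[!loci$reserved])
  pick <- vapply(variants$channel,
                 function(ch) { ii <- open_idx[[ch]]; ii[sample.int(length(ii), 1L)] },
                 integer(1))
  locus <- loci[pick, , drop = FALSE]
  cs_by_chrom <- stats::setNames(as.list(unclass(genome)), names(genome))
  anchor <- vapply(seq_len(nrow(locus)), function(j)
    substr(cs_by_chrom[[locus$chrom[j]]], locus$start[j], locus$start[j]),
    character(1))
  is_del <- locus$kind == "deletion"
  variants$chrom <- locus$chrom
  variants$pos <- locus$start
  variants$ref <- ifelse(is_del, paste0(anchor, locus$seq), anchor)
  variants$alt <- ifelse(is_del, anchor, paste0(anchor, locus$seq))

  # --- caller statistics ----------------------------------------------
  set.seed(ss[4])
  variants <- cbind(variants[c("sample_id", "chrom", "pos", "ref", "alt")],
                    .draw_caller_stats(nrow(variants), variants$fate),
                    data.frame(gene = NA_character_,
                               consequence = NA_character_,
                               pathogenicity_label = NA_character_,
                               stringsAsFactors = FALSE),
                    variants[c("channel", "fate")])
  ord <- order(variants$sample_id, variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  # --- expression -----------------------------------------------------
  set.seed(ss[5])
  cutoff <- mean(cfg$ptgr1_means)
  high <- stats::runif(m) < cfg$ptgr1_high_fraction
  ptgr1 <- stats::rnorm(m, ifelse(high, cfg$ptgr1_means[["high"]],
                                  cfg$ptgr1_means[["low"]]), cfg$ptgr1_sd)
  samples$ptgr1 <- round(ptgr1, 4)
  samples$ptgr1_high_planted <- high
  expression <- data.frame(entity_id = samples$sample_id, gene = "PTGR1",
                           raw_value = samples$ptgr1,
                           units = "log2(FPKM+1)", stringsAsFactors = FALSE)
  lines <- c("A498", "RXF393", "786O", "769P", "CAKI1", "ACHN", "SLR26")
  line_vals <- c(cutoff, round(stats::rnorm(length(lines) - 1L, cutoff, 1.2), 4))
  cellline_expr <- data.frame(entity_id = lines, gene = "PTGR1",
                              raw_value = line_vals, units = "log2(FPKM+1)",
                              stringsAsFactors = FALSE)

  # --- ERCC annotations on reserved loci ------------------------------
  set.seed(ss[6])
  ercc_genes <- c("ERCC2", "ERCC3", "ERCC6")
  reserved_pool <- which(loci$reserved)
  reserved_pool <- reserved_pool[sample.int(length(reserved_pool))]
  take_reserved <- function() {
    if (!length(reserved_pool)) stop("reserved locus pool exhausted")
    i <- reserved_pool[1]; reserved_pool <<- reserved_pool[-1]; i
  }
  ann <- list(); extra <- list()
  samples$ercc_status_planted <- "none"
  for (i in seq_len(m)) {
    rate <- if (samples$group[i] == "nerd") cfg$ercc_rate_nerd
            else cfg$ercc_rate_other
    if (stats::runif(1) >= rate) next
    multi <- stats::runif(1) < cfg$ercc_multi_fraction
    genes <- if (multi) sample(ercc_genes, sample(2:3, 1L)) else sample(ercc_genes, 1L)
    samples$ercc_status_planted[i] <- if (multi) "multi" else genes
    for (g in genes) {
      locus <- loci[take_reserved(), ]
      al <- .locus_alleles(genome, locus)
      extra[[length(extra) + 1L]] <- cbind(
        data.frame(sample_id = samples$sample_id[i], chrom = locus$chrom,
                   pos = al$pos, ref = al$ref, alt = al$alt,
                   stringsAsFactors = FALSE),
        .draw_caller_stats(1L, "pass"),
        data.frame(gene = NA_character_, consequence = NA_character_,
                   pathogenicity_label = NA_character_,
                   channel = locus$channel, fate = "pass",
                   stringsAsFactors = FALSE))
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = locus$chrom, pos = al$pos, ref = al$ref, alt = al$alt,
        gene = g, consequence = "frameshift deletion",
        pathogenicity_label = sample(c("Pathogenic", "Likely Pathogenic"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) variants <- rbind(variants, do.call(rbind, extra))
  # benign decoy annotations on a few shared passenger loci
  decoys <- variants[variants$fate == "pass", , drop = FALSE]
  if (nrow(decoys)) {
    decoys <- decoys[sample.int(nrow(decoys), min(10L, nrow(decoys))), ,
                     drop = FALSE]
    ann[[length(ann) + 1L]] <- data.frame(
      chrom = decoys$chrom, pos = decoys$pos, ref = decoys$ref,
      alt = decoys$alt,
      gene = sample(c("VHL", "PBRM1", "SETD2", "BAP1"), nrow(decoys), TRUE),
      consequence = "frameshift deletion",
      pathogenicity_label = sample(c("Benign", "Likely Benign",
                                     "Uncertain Significance"),
                                   nrow(decoys), TRUE),
      stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(),
               consequence = character(), pathogenicity_label = character(),
               stringsAsFactors = FALSE)
  annotations <- annotations[!duplicated(annotations[c("chrom", "pos",
                                                       "ref", "alt")]), ,
                             drop = FALSE]
  ord <- order(variants$sample_id, variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  for (nm in colnames(sigs))
    samples[[paste0("weight_", nm)]] <-
      vapply(samples$group, function(g) profile_of(g)[[nm]], numeric(1))

  meta <- samples[c("sample_id", "patient_id", "is_wga", "is_ffpe",
                    "is_msi", "preference_rank")]
  structure(list(genome = genome, variants = variants, meta = meta,
                 annotations = annotations, expression = expression,
                 cellline_expr = cellline_expr, signatures = sigs,
                 samples = samples, ptgr1_cutoff_planted = cutoff,
                 config = cfg),
            class = "ner_simulation")
}

#' @export
print.ner_simulation <- function(x, ...) {
  cat("Synthetic NER cohort: ", nrow(x$samples), " sample(s), ",
      nrow(x$variants), " variant record(s) (",
      sum(x$variants$fate != "pass"), " planted filter failures)\n", sep = "")
  cat("  planted NER-deficient: ", sum(x$samples$group == "nerd"),
      "; planted ERCC hits: ",
      sum(x$samples$ercc_status_planted != "none"), "\n", sep = "")
  invisible(x)
}
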