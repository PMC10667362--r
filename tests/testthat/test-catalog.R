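test_that("normalize_indel reduces VCF spellings to canonical events", {
  g <- as_ref_genome(c(chr1 = "GGGGATTG"))
  n <- normalize_indel("chr1", 5, "AT", "A", g)
  expect_equal(n[c("start", "seq", "kind")],
               list(start = 5, seq = "T", kind = "deletion"))

  g2 <- as_ref_genome(c(chr1 = "CCCGAAAT"))
  n2 <- normalize_indel("chr1", 4, "GA", "G", g2)
  expect_equal(n2[c("start", "seq", "kind")],
               list(start = 4, seq = "A", kind = "deletion"))

  g3 <- as_ref_genome(c(chr1 = "GCTGG"))
  n3 <- normalize_indel("chr1", 3, "T", "TCA", g3)
  expect_equal(n3[c("start", "seq", "kind")],
               list(start = 3, seq = "CA", kind = "insertion"))

  # same physical deletion spelled at the other end of the A-run
  n4 <- normalize_indel("chr1", 6, "AA", "A", g2)
  n5 <- normalize_indel("chr1", 4, "GA", "G", g2)
  expect_equal(n4[c("start", "seq")], n5[c("start", "seq")])

  # padded spelling with shared suffix
  n6 <- normalize_indel("chr1", 4, "GAA", "GA", g2)
  expect_equal(n6[c("start", "seq", "kind")], n5[c("start", "seq", "kind")])
})

test_that("normalize_indel rejects mismatches and flags complex events", {
  g <- as_ref_genome(c(chr1 = "CCCGAAAT"))
  expect_error(normalize_indel("chr1", 4, "GT", "G", g), "does not match")
  expect_error(normalize_indel("chr1", 4, "G", "G", g), "distinct")
  cx <- normalize_indel("chr1", 3, "CGA", "CTTT", g)
  expect_false(cx$classifiable)
  expect_equal(cx$reason, "complex")
})

test_that("homopolymer, repeat and microhomology contexts match direct counts", {
  g <- as_ref_genome(c(chr1 = "GGATTTTACAGCAGCAGTCCG"))
  # delete one T from the TTTT run -> run length 4
  n <- normalize_indel("chr1", 4, "TT", "T", g)
  expect_equal(homopolymer_length(n, g), 4L)
  expect_equal(homopolymer_length(n, g),
               oracle_run_length(unclass(g)[["chr1"]], n$start, n$seq))
  # insert C next to G (no C run) -> 0; insert T adjacent to the run -> 4
  ni <- normalize_indel("chr1", 1, "G", "GC", g)
  expect_equal(homopolymer_length(ni, g), 0L)
  nt <- normalize_indel("chr1", 7, "T", "TT", g)
  expect_equal(homopolymer_length(nt, g), 4L)
  g2 <- as_ref_genome(c(chr1 = "GGACTTAG"))
  nt2 <- normalize_indel("chr1", 6, "T", "TT", g2)
  expect_equal(homopolymer_length(nt2, g2), 2L)

  # delete CAG from a (CAG)x3 tract -> 3 copies
  nr <- normalize_indel("chr1", 8, "ACAG", "A", g)
  expect_equal(nr$seq, "CAG")
  expect_equal(repeat_unit_count(nr, g), 3L)
  # delete AT from ATAT -> 2; insert AT with no adjacent copy -> 0
  g3 <- as_ref_genome(c(chr1 = "GGCATATCC"))
  na <- normalize_indel("chr1", 3, "CAT", "C", g3)
  expect_equal(repeat_unit_count(na, g3), 2L)
  g4 <- as_ref_genome(c(chr1 = "GGCCGG"))
  nb <- normalize_indel("chr1", 3, "C", "CAT", g4)
  expect_equal(repeat_unit_count(nb, g4), 0L)

  # deleted TAGC followed by TA... -> microhomology 2
  g5 <- as_ref_genome(c(chr1 = "GGTAGCTACCG"))
  nm <- normalize_indel("chr1", 2, "GTAGC", "G", g5)
  expect_equal(repeat_unit_count(nm, g5), 1L)
  expect_equal(microhomology_length(nm, g5), 2L)
  # deleted ACGT with unrelated flanks -> 0
  g6 <- as_ref_genome(c(chr1 = "GGACGTCCG"))
  nm2 <- normalize_indel("chr1", 2, "GACGT", "G", g6)
  expect_equal(microhomology_length(nm2, g6), 0L)
  # deleted AAC followed by AA then a non-C base -> 2
  g7 <- as_ref_genome(c(chr1 = "GTGAACAATCG"))
  nm3 <- normalize_indel("chr1", 3, "GAAC", "G", g7)
  expect_equal(microhomology_length(nm3, g7), 2L)
})

test_that("assign_channel implements the catalog decision rules", {
  # 7 bp deletion, single copy, microhomology 2 -> the ID8-dominant class
  g <- as_ref_genome(c(chr1 = "GGTTCAGACTTACAAGGGG"))
  lab <- classify_indel("chr1", 2, "GTTCAGAC", "G", g)
  expect_equal(lab, "5:Del:M:2")
  # 1 bp deletion of A in a run of six As -> pyrimidine strand, 6+ bin
  g2 <- as_ref_genome(c(chr1 = "GCAAAAAAT"))
  expect_equal(classify_indel("chr1", 2, "CA", "C", g2), "1:Del:T:5")
  # 1 bp G insertion next to a single G -> C channel, one pre-existing copy
  expect_equal(classify_indel("chr1", 1, "G", "GG", g2), "1:Ins:C:1")
  # >=2 bp deletion, single copy, no homology -> repeat bin 1
  g3 <- as_ref_genome(c(chr1 = "GGACGTCCG"))
  expect_equal(classify_indel("chr1", 2, "GACGT", "G", g3), "4:Del:R:0")
})

test_that("classification agrees with the independent string-search oracle", {
  set.seed(202)
  labs <- sample(rep(id83_channels()$label, 3))
  for (lab in labs) {
    v <- realize_variant(lab, shared_ref)
    expect_equal(classify_indel(v$chrom, v$pos, v$ref, v$alt, shared_ref),
                 oracle_channel(v$chrom, v$pos, v$ref, v$alt, shared_ref),
                 info = lab)
  }
})

test_that("channel assignment is strand-symmetric", {
  set.seed(203)
  fwd <- unclass(shared_ref)
  rev_genome <- as_ref_genome(setNames(revcomp(fwd), names(fwd)))
  for (lab in sample(id83_channels()$label, 40)) {
    v <- realize_variant(lab, shared_ref)
    n <- normalize_indel(v$chrom, v$pos, v$ref, v$alt, shared_ref)
    L <- nchar(n$seq)
    cn <- nchar(fwd[[v$chrom]])
    cs2 <- unclass(rev_genome)[[v$chrom]]
    if (n$kind == "deletion") {
      s2 <- cn - (n$start + L)           # 0-based start on the - strand
      ref2 <- substr(cs2, s2, s2 + L); alt2 <- substr(cs2, s2, s2)
    } else {
      s2 <- cn - n$start
      ref2 <- substr(cs2, s2, s2)
      alt2 <- paste0(ref2, revcomp(n$seq))
    }
    expect_equal(classify_indel(v$chrom, s2, ref2, alt2, rev_genome), lab,
                 info = lab)
  }
})

test_that("build_catalog counts, conserves and ignores what it should", {
  g <- as_ref_genome(c(chr1 = "GGGGATTGCCCGAAAT"))
  no_rec <- data.frame(sample_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character())
  empty <- build_catalog(no_rec, g, samples = "S1")
  expect_equal(sum(empty), 0L)
  expect_equal(dim(empty), c(1L, 83L))

  rec <- data.frame(
    sample_id = c("A", "A", "A", "B"),
    chrom = "chr1",
    pos = c(5L, 5L, 3L, 12L),
    ref = c("AT", "A", "GGA", "GA"),
    alt = c("A", "T", "GT", "G"),    # del, SNV, complex, del
    stringsAsFactors = FALSE)
  cat1 <- build_catalog(rec, g)
  expect_equal(sum(cat1["A", ]), 1L)            # SNV ignored, complex excluded
  expect_equal(attr(cat1, "unclassified")[["A"]], 1L)
  expect_equal(sum(cat1["B", ]), 1L)
  # conservation: classified + unclassified == indels
  n_indel <- sum(nchar(rec$ref) != nchar(rec$alt))
  expect_equal(sum(cat1) + sum(attr(cat1, "unclassified")), n_indel)
  # order independence
  cat2 <- build_catalog(rec[rev(seq_len(nrow(rec))), ], g)
  expect_equal(unclass(cat1)[order(rownames(cat1)), ],
               unclass(cat2)[order(rownames(cat2)), ])
})

test_that("catalog TSV round-trips through write/read", {
  set.seed(11)
  sim <- simulate_cohort(simulation_config(seed = 8, n_samples = 3,
                                           mean_burden = 40,
                                           reference = shared_ref))
  cat1 <- build_catalog(sim$variants[sim$variants$fate == "pass", ],
                        sim$genome)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, p)
  cat2 <- read_catalog(p)
  expect_equal(unclass(cat1), unclass(cat2), ignore_attr = TRUE)
  expect_equal(colnames(cat2), id83_channels()$label)
})
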