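test_that("reference generation is seed-deterministic and channel-complete", {
  r1 <- generate_reference(seed = 77)
  r2 <- generate_reference(seed = 77)
  r3 <- generate_reference(seed = 78)
  expect_identical(unclass(r1), unclass(r2))
  expect_false(identical(unclass(r1), unclass(r3)))
  expect_true(all(nchar(unclass(r1)) >= 10000L))
  # base composition roughly uniform
  comp <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unclass(r1)))[, c("A", "C", "G", "T")])
  expect_true(all(abs(comp / sum(comp) - 0.25) < 0.05))
  # engineered locus audit: every channel has enough realizable positions
  expect_true(all(audit_reference_loci(r1) >= 20))
})

test_that("realize_variant inverts the classifier for requested channels", {
  set.seed(55)
  for (lab in sample(id83_channels()$label, 30)) {
    v <- realize_variant(lab, shared_ref, sample_id = "X")
    expect_equal(v$channel, lab)
    expect_equal(classify_indel(v$chrom, v$pos, v$ref, v$alt, shared_ref),
                 lab, info = lab)
    expect_true(pass_variant_filters(v))
  }
  v <- realize_variant("2:Del:R:1", shared_ref, fail_predicate = "low-tlod")
  f <- variant_filters(v)
  expect_false(f$pass)
  expect_equal(f$reason, "low-tlod")
})

test_that("cohorts are reproducible and filter failures are planned exactly", {
  cfg <- simulation_config(seed = 12, n_samples = 8, mean_burden = 100,
                           reference = shared_ref)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$samples, s2$samples)

  # planned, not sampled: per-sample failing counts equal round(frac * N)
  by_sample <- split(s1$variants$fate != "pass", s1$variants$sample_id)
  planted <- s1$samples[match(names(by_sample), s1$samples$sample_id), ]
  got_fail <- vapply(by_sample, sum, integer(1))
  # ERCC-planted extra records are always passing, so compare against the
  # ledger's planned counts
  expect_equal(unname(got_fail), planted$n_fail_planned)

  # every planted failure fails for exactly its intended predicate
  f <- variant_filters(s1$variants)
  fails <- s1$variants$fate != "pass"
  expect_equal(f$reason[fails], s1$variants$fate[fails])
  expect_true(all(f$pass[!fails]))
  expect_setequal(unique(s1$variants$fate[fails]), nerdsig:::.fail_codes)
})

test_that("the ledger reconciles with catalog construction", {
  sim <- simulate_cohort(simulation_config(seed = 13, n_samples = 5,
                                           mean_burden = 90,
                                           reference = shared_ref))
  passing <- sim$variants[sim$variants$fate == "pass", ]
  cat83 <- build_catalog(passing, sim$genome)
  # conservation: every passing record classified, none complex
  expect_equal(sum(cat83), nrow(passing))
  expect_equal(sum(attr(cat83, "unclassified")), 0L)
  # per-sample, per-channel counts equal the ledger's planted channels
  planted <- table(passing$sample_id,
                   factor(passing$channel, levels = colnames(cat83)))
  expect_equal(unclass(cat83)[rownames(planted), ],
               unclass(as.matrix(planted))[, colnames(cat83)],
               ignore_attr = TRUE)
})

test_that("written VCFs are byte-stable and round-trip the ledger verbatim", {
  cfg <- simulation_config(seed = 14, n_samples = 3, mean_burden = 50,
                           reference = shared_ref)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  v1 <- file.path(d1, "vcf", "S002.vcf")
  expect_identical(readLines(v1), readLines(file.path(d2, "vcf", "S002.vcf")))

  sim <- simulate_cohort(cfg)
  rec <- read_somatic_vcf(v1, "S002")
  led <- sim$variants[sim$variants$sample_id == "S002", ]
  key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
  expect_identical(key(rec), key(led))
})

test_that("planted expression straddles the calibrated cutoff as configured", {
  sim <- simulate_cohort(simulation_config(seed = 15, n_samples = 120,
                                           mean_burden = 30,
                                           ptgr1_high_fraction = 0.6,
                                           reference = shared_ref))
  cl <- sim$cellline_expr
  cl$log_value <- cl$raw_value
  attr(cl, "units") <- unique(cl$units)
  cut <- as.numeric(calibrate_ptgr1_cutoff(cl))
  expect_equal(cut, sim$ptgr1_cutoff_planted)
  frac_above <- mean(sim$samples$ptgr1 >= cut)
  expect_gt(frac_above, 0.45)
  expect_lt(frac_above, 0.75)
  # planted high/low grouping matches the realized values almost always
  expect_gt(mean((sim$samples$ptgr1 >= cut) == sim$samples$ptgr1_high_planted),
            0.95)
})

test_that("planted ERCC status survives the full annotation path", {
  sim <- simulate_cohort(simulation_config(seed = 16, n_samples = 30,
                                           ercc_rate_nerd = 0.6,
                                           ercc_rate_other = 0.1,
                                           reference = shared_ref))
  sel <- select_cohort(sim$variants, sim$meta)
  rec <- annotate_variants(sel$records, sim$annotations)
  st <- ercc_mutation_status(rec, samples = sel$samples)
  planted <- setNames(sim$samples$ercc_status_planted, sim$samples$sample_id)
  expect_equal(st, planted[names(st)])
  expect_gt(sum(st != "none"), 0)
})
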