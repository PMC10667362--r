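test_that("read_somatic_vcf splits multi-allelic sites and keeps fields verbatim", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(c(
    "chr1\t100\t.\tAT\tA\t.\tPASS\tTLOD=12.5;NLOD=8.1\tGT:AD:AF:DP\t0/1:40,10:0.2:50\t0/0:30,0:0.01:30",
    "chr1\t200\t.\tG\tGA,GAA\t.\tPASS\tTLOD=9,7;NLOD=6,5\tGT:AD:AF:DP\t0/1:40,6,5:0.12,0.1:51\t0/0:28,0,0:0,0:28",
    "chr1\t300\t.\tC\tT\t.\tgermline\tTLOD=5.5;NLOD=2.2\tGT:AD:AF:DP\t0/1:20,5:0.25:25\t0/0:15,1:0.06:16",
    "chr1\t400\t.\tC\tCA\t.\tPASS\tNLOD=9\tGT:AD:AF:DP\t0/1:30,9:0.3:39\t0/0:25,0:0:25"),
    p)
  r <- read_somatic_vcf(p, "S1")
  expect_equal(nrow(r), 5L)                 # 3 single-ALT + 2 from the split
  m <- r[r$pos == 200, ]
  expect_equal(m$alt, c("GA", "GAA"))
  expect_equal(m$tlod, c(9, 7))
  expect_equal(m$tumor_alt, c(6, 5))
  expect_equal(m$tumor_af, c(0.12, 0.1))
  expect_equal(r$filter[r$pos == 300], "germline")
  # absent TLOD surfaces as NA, not zero
  expect_true(is.na(r$tlod[r$pos == 400]))
  expect_equal(r$nlod[r$pos == 400], 9)
  expect_equal(r$tumor_depth[r$pos == 100], 50)
  expect_equal(r$normal_alt[r$pos == 300], 1)
})

test_that("malformed lines and missing sample columns raise named errors", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\tTLOD=9;NLOD=9\tGT:AD:AF:DP\t0/1:40,10:0.2:50\t0/0:30,0:0:30",
    "chr1\tnot_a_position\t.\tA\tT"),
    p)
  expect_error(read_somatic_vcf(p, "S1"), "malformed VCF line 13")

  p2 <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_fixture_vcf(
    "chr1\t100\t.\tA\tT\t.\tPASS\tTLOD=9;NLOD=9\tGT:AD:AF:DP\t0/1:40,10:0.2:50",
    p2, samples = "ONLYONE"))
  lines <- lines[!grepl("^##(tumor|normal)_sample", lines)]
  writeLines(lines, p2)
  expect_error(read_somatic_vcf(p2, "S1"), "tumor sample")
})

test_that("filter predicates are inclusive exactly as written", {
  thr <- filter_thresholds()
  # all eight fields at their boundary values pass
  expect_true(pass_variant_filters(boundary_record(), thr))
  expect_false(pass_variant_filters(boundary_record(normal_alt = 1), thr))
  expect_false(pass_variant_filters(boundary_record(tlod = 5.999), thr))
  expect_false(pass_variant_filters(boundary_record(nlod = 2.999), thr))
  expect_false(pass_variant_filters(boundary_record(normal_depth = 14), thr))
  expect_false(pass_variant_filters(boundary_record(tumor_depth = 19), thr))
  expect_false(pass_variant_filters(boundary_record(tumor_alt = 4), thr))
  expect_false(pass_variant_filters(boundary_record(tumor_af = 0.0499), thr))
  expect_false(pass_variant_filters(boundary_record(filter = "germline"), thr))
  expect_false(pass_variant_filters(boundary_record(filter = "PASS;clustered_events"), thr))
})

test_that("records with missing tested fields are unevaluable, not silently false", {
  f <- variant_filters(boundary_record(tlod = NA_real_))
  expect_false(f$pass)
  expect_equal(f$reason, "unevaluable")
  f2 <- variant_filters(rbind(boundary_record(), boundary_record(nlod = 1)))
  expect_equal(f2$reason, c("pass", "low-nlod"))
})

test_that("filtering is idempotent and monotone in the thresholds", {
  sim <- simulate_cohort(simulation_config(seed = 21, n_samples = 6,
                                           mean_burden = 80,
                                           reference = shared_ref))
  rec <- sim$variants
  thr <- filter_thresholds()
  once <- rec[variant_filters(rec, thr)$pass, ]
  twice <- once[variant_filters(once, thr)$pass, ]
  expect_identical(once, twice)

  n0 <- nrow(once)
  for (knob in list(list(min_tlod = 10), list(min_nlod = 10),
                    list(min_normal_depth = 40), list(min_tumor_depth = 60),
                    list(min_tumor_alt = 20), list(max_normal_alt = -1),
                    list(min_tumor_af = 0.3))) {
    thr2 <- do.call(filter_thresholds, knob)
    expect_lte(sum(variant_filters(rec, thr2)$pass), n0)
  }
})

test_that("select_cohort applies sample exclusions and the variant minimum", {
  sim <- simulate_cohort(simulation_config(
    seed = 33, n_samples = 20, mean_burden = 120, n_msi = 3, n_wga = 2,
    reference = shared_ref))
  sel <- select_cohort(sim$variants, sim$meta)
  expect_equal(length(sel$samples), 15L)
  expect_setequal(sel$exclusions$reason[sel$exclusions$reason %in%
                                          c("wga", "msi")],
                  c(rep("wga", 2), rep("msi", 3)))

  # one patient, two samples: the lower preference rank wins
  sim2 <- simulate_cohort(simulation_config(
    seed = 34, n_samples = 5, mean_burden = 120, n_duplicate_patients = 2,
    reference = shared_ref))
  sel2 <- select_cohort(sim2$variants, sim2$meta)
  dup <- sel2$exclusions[sel2$exclusions$reason == "duplicate-patient", ]
  expect_equal(nrow(dup), 2L)
  expect_true(all(grepl("b$", dup$sample_id)))

  # a sample with < 50 passing variants is dropped with the stated reason
  sim3 <- simulate_cohort(simulation_config(
    seed = 35, n_samples = 6, mean_burden = 120, n_low_burden = 1,
    reference = shared_ref))
  sel3 <- select_cohort(sim3$variants, sim3$meta)
  low_id <- sim3$samples$sample_id[sim3$samples$low_burden]
  expect_true(low_id %in%
                sel3$exclusions$sample_id[sel3$exclusions$reason ==
                                            "below-min-variants"])
  expect_lt(sel3$n_pass[[low_id]], 50)

  bad_meta <- rbind(sim3$meta, sim3$meta[1, ])
  expect_error(select_cohort(sim3$variants, bad_meta), "duplicate sample_id")
})

test_that("deleterious calls follow the exonic/nonsense/indel rule", {
  rec <- rbind(
    boundary_record(ref = "A", alt = "T", consequence = "exonic SNV",
                    pathogenicity_label = "Likely Pathogenic"),
    boundary_record(ref = "A", alt = "T", consequence = "nonsense SNV",
                    pathogenicity_label = "Uncertain Significance"),
    boundary_record(ref = "A", alt = "T", consequence = "exonic SNV",
                    pathogenicity_label = "Benign"),
    boundary_record(ref = "AT", alt = "A", consequence = "frameshift deletion",
                    pathogenicity_label = "Pathogenic"),
    boundary_record(ref = "AT", alt = "A", consequence = "frameshift deletion",
                    pathogenicity_label = "Uncertain Significance"),
    boundary_record(ref = "A", alt = "T"))
  d <- is_deleterious(rec)
  expect_equal(as.logical(d), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(d, "note")[6], "unannotated")
})

test_that("ERCC status distinguishes none, single-gene and multi", {
  rec <- rbind(
    boundary_record(sample_id = "S1", gene = "ERCC2",
                    consequence = "exonic SNV",
                    pathogenicity_label = "Pathogenic"),
    boundary_record(sample_id = "S2", gene = "ERCC2",
                    consequence = "exonic SNV",
                    pathogenicity_label = "Pathogenic"),
    boundary_record(sample_id = "S2", gene = "ERCC6", ref = "AT", alt = "A",
                    consequence = "frameshift deletion",
                    pathogenicity_label = "Likely Pathogenic"),
    boundary_record(sample_id = "S3", gene = "ERCC2",
                    consequence = "exonic SNV",
                    pathogenicity_label = "Benign"))
  st <- ercc_mutation_status(rec, samples = c("S1", "S2", "S3", "S4"))
  expect_equal(unname(st), c("ERCC2", "multi", "none", "none"))
})
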