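test_that("config validation names the offending field", {
  expect_error(simulation_config(subtype_proportions = c(a = 0.5, b = 0.4)),
               "subtype_proportions")
  expect_error(simulation_config(n_samples = 10, runs = data.frame(
    run_id = "run1", n_samples = 9L)), "runs")
  expect_error(simulation_config(germline_snps = data.frame(
    chrom = "JAK2syn", pos = 638L, ref = "G", alt = "A", carrier_rate = 1.2)),
    "carrier_rate")
  expect_error(simulation_config(depth_dispersion = 0), "depth_dispersion")
})

test_that("empty cohort and seed determinism", {
  cfg0 <- simulation_config(n_samples = 0L, runs = data.frame(
    run_id = character(), n_samples = integer()))
  b0 <- simulate_cohort(cfg0)
  expect_equal(nrow(b0$samples), 0L)
  expect_equal(nrow(b0$truth), 0L)
  expect_equal(nrow(b0$clinical), 0L)
  # same seed -> identical bundles and callsets
  cfg <- noiseless_cohort_config(seed = 7L)
  b1 <- simulate_cohort(cfg); b2 <- simulate_cohort(cfg)
  expect_identical(b1, b2)
  c1 <- emit_caller_callsets(b1, cfg, regions, ref)
  c2 <- emit_caller_callsets(b2, cfg, regions, ref)
  expect_identical(c1, c2)
  # different seed -> different draws
  b3 <- simulate_cohort(noiseless_cohort_config(seed = 8L))
  expect_false(identical(b1$depths, b3$depths))
})

test_that("depth medians land near their configured anchors", {
  cfg <- simulation_config(rng_seed = 12L)   # full 461-sample world
  b <- simulate_cohort(cfg)
  med <- tapply(b$depths$depth, b$depths$exon, median)
  # spec tolerance: within 10% of the configured median at n >= 100
  expect_equal(unname(med["16"] / 673), 1, tolerance = 0.10)
  expect_equal(unname(med["20"] / 577), 1, tolerance = 0.10)
  expect_equal(unname(med["21"] / 711), 1, tolerance = 0.10)
  expect_equal(unname(med["23"] / 944), 1, tolerance = 0.10)
  # exon 23 median within the printed band [850, 1039]
  expect_gte(unname(med["23"]), 850)
  expect_lte(unname(med["23"]), 1039)
})

test_that("truth composition: carriers, germline VAF, artifact confinement", {
  cfg <- simulation_config(rng_seed = 5L)
  b <- simulate_cohort(cfg)
  # all referenced samples exist; VAFs in (0, 1]
  expect_true(all(b$truth$sample_id %in% b$samples$sample_id))
  expect_true(all(b$truth$true_vaf > 0 & b$truth$true_vaf <= 1))
  # somatic carrier counts as configured
  som <- b$truth[b$truth$origin == "somatic", ]
  cnt <- table(som$label)
  expect_equal(unname(cnt[c("R683G", "R683T", "R867Q", "R923H")]),
               c(11L, 2L, 1L, 2L), ignore_attr = TRUE)
  # somatic carriers only in eligible subtypes
  st <- b$samples$subtype[match(som$sample_id, b$samples$sample_id)]
  expect_true(all(st %in% c("BCR_ABL1_like", "B_other", "high_hyperdiploid")))
  # germline SNP ~ heterozygous and common
  germ <- b$truth[b$truth$origin == "germline", ]
  expect_gt(nrow(germ), 100)           # rate 0.35 of 461
  expect_equal(mean(germ$true_vaf), 0.5, tolerance = 0.02)
  expect_true(all(abs(germ$true_vaf - 0.5) < 0.2))
  # artifacts confined to their run
  art <- b$truth[b$truth$origin == "artifact", ]
  runs <- b$samples$run_id[match(art$sample_id, b$samples$sample_id)]
  expect_true(all(runs == "run1"))
})

test_that("noiseless callsets equal the truth; binomial alt counts", {
  cfg <- noiseless_cohort_config(seed = 3L)
  b <- simulate_cohort(cfg)
  cs <- emit_caller_callsets(b, cfg, regions, ref)
  for (sid in b$samples$sample_id) {
    tv <- b$truth[b$truth$sample_id == sid, ]
    want <- sort(paste(tv$chrom, tv$pos, tv$ref, tv$alt))
    for (cl in caller_ids()) {
      got <- cs[[sid]][[cl]]
      expect_equal(sort(paste(got$chrom, got$pos, got$ref, got$alt)), want)
    }
  }
  # alt ~ Binomial(depth, vaf): empirical mean of replicated emissions
  cfg1 <- simulation_config(
    n_samples = 1L, subtype_proportions = c(B_other = 1),
    runs = data.frame(run_id = "run1", n_samples = 1L),
    exon_depth_medians = c("16" = 600, "20" = 600, "21" = 600, "23" = 600),
    depth_dispersion = 1e6,
    truth_variants = data.frame(chrom = "JAK2syn", pos = 325L, ref = "A",
                                alt = "G", label = "R683G", n_carriers = 1L,
                                vaf_min = 0.5, vaf_max = 0.5, subtypes = NA),
    germline_snps = data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               carrier_rate = numeric()),
    artifacts = data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           run_id = character(), n_carriers = integer(),
                           vaf = numeric()),
    caller_profiles = noiseless_caller_profiles()[1],
    rng_seed = 1L)
  vafs <- vapply(1:1000, function(i) {
    cfg_i <- cfg1; cfg_i$rng_seed <- i
    b1 <- simulate_cohort(cfg_i)
    call <- emit_caller_callsets(b1, cfg_i, regions, ref)[[1]][["A"]]
    call$alt_reads / call$depth
  }, 0)
  # binomial ratio at depth ~ 600: mean alt in [290, 310] scales to
  # mean VAF in [0.4833, 0.5167]
  expect_gte(mean(vafs), 290 / 600)
  expect_lte(mean(vafs), 310 / 600)
})

test_that("emitted VAF converges to the true VAF at extreme depth", {
  cfg <- simulation_config(
    n_samples = 4L, subtype_proportions = c(B_other = 1),
    runs = data.frame(run_id = "run1", n_samples = 4L),
    exon_depth_medians = c("16" = 1e5, "20" = 1e5, "21" = 1e5, "23" = 1e5),
    depth_dispersion = 1e6,
    truth_variants = data.frame(chrom = "JAK2syn", pos = 325L, ref = "A",
                                alt = "G", label = "R683G", n_carriers = 4L,
                                vaf_min = 0.2, vaf_max = 0.2, subtypes = NA),
    germline_snps = data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               carrier_rate = numeric()),
    artifacts = data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           run_id = character(), n_carriers = integer(),
                           vaf = numeric()),
    caller_profiles = noiseless_caller_profiles(),
    rng_seed = 77L)
  b <- simulate_cohort(cfg)
  m <- merge_bundle(b, cfg)
  expect_true(all(abs(m$vaf - 0.2) < 0.01))   # within 1 VAF point at 1e5 reads
})

test_that("fixture round-trips through the readers losslessly", {
  cfg <- noiseless_cohort_config(seed = 19L)
  b <- simulate_cohort(cfg)
  cs <- emit_caller_callsets(b, cfg, regions, ref)
  dir <- withr::local_tempdir()
  write_fixture(b, cs, dir)
  vcfs <- list_fixture_vcfs(dir)
  expect_equal(nrow(vcfs), nrow(b$samples) * length(caller_ids()))
  for (i in seq_len(nrow(vcfs))) {
    got <- read_caller_vcf(vcfs$path[i], vcfs$caller[i], ref)
    want <- cs[[vcfs$sample_id[i]]][[vcfs$caller[i]]]
    expect_equal(got[c("chrom", "pos", "ref", "alt", "depth", "alt_reads")],
                 want[c("chrom", "pos", "ref", "alt", "depth", "alt_reads")],
                 ignore_attr = TRUE)
  }
  # tables round-trip
  cl <- read.table(file.path(dir, "clinical.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(cl), nrow(b$clinical))
  # empty bundle still writes valid files with headers
  cfg0 <- simulation_config(n_samples = 0L, runs = data.frame(
    run_id = character(), n_samples = integer()))
  b0 <- simulate_cohort(cfg0)
  d0 <- withr::local_tempdir()
  write_fixture(b0, list(), d0)
  expect_true(file.exists(file.path(d0, "clinical.tsv")))
  expect_equal(nrow(read.table(file.path(d0, "samples.tsv"), header = TRUE,
                               sep = "\t")), 0L)
})
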