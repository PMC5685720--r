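# Small hand-built cohort rows used by several tests
mk_rows <- function(...) {
  base <- data.frame(sample_id = "S1", chrom = "JAK2syn", pos = 325L,
                     ref = "A", alt = "G", n_callers = 3L, agg_depth = 600L,
                     agg_alt = 60L, vaf = 0.10, callers = "A,B,C",
                     stringsAsFactors = FALSE)
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    x <- base
    for (nm in names(r)) x[[nm]] <- r[[nm]]
    x$vaf <- x$agg_alt / x$agg_depth
    x
  }))
  out
}
mk_samples <- function(n, runs = c("run1", "run2"))
  data.frame(sample_id = sprintf("S%d", 1:n),
             run_id = rep(runs, length.out = n), stringsAsFactors = FALSE)

test_that("site rules flip exactly at the printed boundaries", {
  th <- filter_thresholds()
  rows <- mk_rows(list(agg_depth = 99L, agg_alt = 30L),
                  list(agg_depth = 100L, agg_alt = 30L),
                  list(agg_depth = 600L, agg_alt = 9L),
                  list(agg_depth = 600L, agg_alt = 10L),
                  list(n_callers = 1L),
                  list(pos = 50L))   # outside all targeted regions
  v <- apply_site_filters(rows, regions, th)
  expect_equal(unname(v[, "DEPTH"]), c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(unname(v[, "ALTREADS"]), c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(v[, "MULTICALLER"]), c(rep(TRUE, 4), FALSE, TRUE))
  expect_equal(unname(v[, "REGION"]), c(rep(TRUE, 5), FALSE))
})

test_that("VAF presence is a cohort-level strict-> rule", {
  th <- filter_thresholds()
  # single carrier exactly at 2% is excluded
  t1 <- build_cohort_table(mk_rows(list(agg_depth = 1000L, agg_alt = 20L)),
                           mk_samples(2))
  expect_length(cohort_vaf_presence(t1, th), 0L)
  # 1% + 3% carriers: the key is retained (so both occurrences survive)
  rows <- mk_rows(list(sample_id = "S1", agg_depth = 1000L, agg_alt = 10L),
                  list(sample_id = "S2", agg_depth = 1000L, agg_alt = 30L))
  t2 <- build_cohort_table(rows, mk_samples(2))
  expect_length(cohort_vaf_presence(t2, th), 1L)
  res <- filter_cohort(t2, regions, cosmic, popfreq, model, ref, th)
  expect_equal(unique(res$audit$VAFPRESENCE), "pass")
  # just above the boundary passes
  t3 <- build_cohort_table(mk_rows(list(agg_depth = 10000L, agg_alt = 201L)),
                           mk_samples(2))
  expect_length(cohort_vaf_presence(t3, th), 1L)
})

test_that("run-balance chi-square matches the hand computation", {
  sizes <- c(run1 = 10L, run2 = 10L)
  b <- run_balance_test(c(run1 = 5L, run2 = 5L), sizes)
  expect_equal(b$chi2, 0); expect_equal(b$p, 1); expect_true(b$pass)
  b <- run_balance_test(c(run1 = 10L, run2 = 0L), sizes)
  expect_equal(b$chi2, 10)            # (10-5)^2/5 + (0-5)^2/5
  expect_equal(b$df, 1L)
  expect_equal(b$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(b$p, 5), 0.00157)
  expect_false(b$pass)
  # degenerate: one carrier, or one run -> not evaluated, passes
  b <- run_balance_test(c(run1 = 1L, run2 = 0L), sizes)
  expect_false(b$evaluated); expect_true(b$pass)
  b <- run_balance_test(c(run1 = 5L), c(run1 = 10L))
  expect_false(b$evaluated); expect_true(b$pass)
  # unequal run sizes weight the expectation
  b <- run_balance_test(c(run1 = 8L, run2 = 2L), c(run1 = 80L, run2 = 20L))
  expect_equal(b$chi2, 0)
})

test_that("germline heuristic needs the full conjunction", {
  mk <- function(n, vafs) {
    rows <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_rows(list(sample_id = sprintf("S%d", i), agg_depth = 1000L,
                   agg_alt = round(vafs[i] * 1000)))))
    build_cohort_table(rows, mk_samples(max(n, 2)))
  }
  th <- filter_thresholds()
  expect_length(germline_flag(mk(10, c(rep(0.45, 9), 0.41)), th), 1L)
  expect_length(germline_flag(mk(9, rep(0.50, 9)), th), 0L)   # count below 10
  # median below threshold defeats it despite high mean
  vafs <- c(rep(0.39, 7), rep(0.83, 5))
  expect_length(germline_flag(mk(12, vafs), th), 0L)
  expect_gt(mean(vafs), 0.40)
})

test_that("SNP rule: mean across three databases, inclusive boundary", {
  th <- filter_thresholds()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "JAK2syn", pos = c(325L, 326L), ref = c("A", "G"),
                         alt = c("G", "C"),
                         af_1000g_all = c(0.06, 0.10),
                         af_1000g_eur = c(0.05, 0.10),
                         af_esp_eur = c(0.04, 0.10)),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  fq <- read_popfreq_table(tmp, reference = ref)
  k <- variant_key("JAK2syn", c(325L, 326L, 918L), c("A", "G", "G"),
                   c("G", "C", "A"), ref)
  expect_equal(snp_flag(k, fq, th), c(TRUE, TRUE, FALSE))  # mean 0.05 flags
  th2 <- filter_thresholds(snp_rule = "each")
  expect_equal(snp_flag(k, fq, th2), c(FALSE, TRUE, FALSE))
})

test_that("cascade audit is complete, order-free and matches brute force", {
  set.seed(17)
  pool <- rbind(
    data.frame(pos = c(325L, 326L, 918L, 1211L, 606L, 942L),
               ref = c("A", "G", "G", "G", "G", "A"),
               alt = c("G", "C", "A", "A", "A", "G")),      # COSMIC set
    data.frame(pos = c(638L, 330L), ref = c("G", "C"), alt = c("A", "T")),
    data.frame(pos = c(50L, 1900L), ref = substring(ref$JAK2syn, c(50, 1900),
                                                    c(50, 1900)),
               alt = c("A", "C")))
  pool$alt[pool$alt == pool$ref] <- "T"
  for (rep in 1:25) {
    n_s <- sample(4:20, 1)
    samples <- mk_samples(n_s)
    n_rows <- sample(5:30, 1)
    rows <- do.call(rbind, lapply(seq_len(n_rows), function(i) {
      p <- pool[sample(nrow(pool), 1), ]
      dep <- sample(c(50L, 99L, 100L, 150L, 600L, 1200L), 1)
      alt <- min(dep, sample(c(5L, 9L, 10L, 25L, 60L, 300L, 550L), 1))
      mk_rows(list(sample_id = sample(samples$sample_id, 1), pos = p$pos,
                   ref = p$ref, alt = p$alt, agg_depth = dep, agg_alt = alt,
                   n_callers = sample(1:4, 1)))
    }))
    rows <- rows[!duplicated(paste(rows$sample_id, rows$pos, rows$alt)), ]
    tab <- build_cohort_table(rows, samples)
    res <- filter_cohort(tab, regions, cosmic, popfreq, model, ref)
    # audit completeness
    expect_equal(nrow(res$audit), nrow(rows))
    expect_equal(sum(res$audit$final == "kept") +
                   sum(res$audit$final == "excluded"), nrow(rows))
    expect_equal(nrow(res$kept), sum(res$audit$final == "kept"))
    # brute-force oracle agreement
    ora <- oracle_filter_kept(rows, samples, regions, cosmic, popfreq, model, ref)
    expect_setequal(paste(res$kept$sample_id, res$kept$pos, res$kept$alt),
                    paste(ora$sample_id, ora$pos, ora$alt))
    # row order invariance
    perm <- rows[sample(nrow(rows)), ]
    res2 <- filter_cohort(build_cohort_table(perm, samples), regions, cosmic,
                          popfreq, model, ref)
    expect_setequal(paste(res2$kept$sample_id, res2$kept$pos, res2$kept$alt),
                    paste(res$kept$sample_id, res$kept$pos, res$kept$alt))
  }
})

test_that("raising the depth threshold never adds kept variants", {
  set.seed(31)
  samples <- mk_samples(12)
  sites <- data.frame(pos = c(325L, 918L, 1211L), ref = c("A", "G", "G"),
                      alt = c("G", "A", "A"))
  rows <- do.call(rbind, lapply(1:25, function(i) {
    s <- sites[sample(3, 1), ]
    mk_rows(list(sample_id = sample(samples$sample_id, 1),
                 pos = s$pos, ref = s$ref, alt = s$alt,
                 agg_depth = sample(c(80L, 100L, 140L, 600L), 1),
                 agg_alt = sample(c(10L, 30L, 60L), 1),
                 n_callers = sample(2:4, 1)))
  }))
  rows <- rows[!duplicated(paste(rows$sample_id, rows$pos)), ]
  tab <- build_cohort_table(rows, samples)
  kept_at <- function(d) {
    r <- filter_cohort(tab, regions, cosmic, popfreq, model, ref,
                       filter_thresholds(min_depth = d))
    paste(r$kept$sample_id, r$kept$pos)
  }
  prev <- kept_at(50L)
  for (d in c(100L, 150L, 700L)) {
    cur <- kept_at(d)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("single-rule failure and empty input behave as specified", {
  # passes everything but is absent from the COSMIC fixture
  rows <- mk_rows(list(pos = 1210L, ref = "C", alt = "A", agg_depth = 600L,
                       agg_alt = 60L))
  tab <- build_cohort_table(rows, mk_samples(2))
  res <- filter_cohort(tab, regions, cosmic, popfreq, model, ref)
  expect_equal(res$audit$final, "excluded")
  expect_equal(res$audit$fail_reasons, "COSMIC")
  # empty table
  empty <- build_cohort_table(merge_callers(NULL, "S1")[0, ], mk_samples(2))
  res0 <- filter_cohort(empty, regions, cosmic, popfreq, model, ref)
  expect_equal(nrow(res0$kept), 0L)
  expect_equal(nrow(res0$audit), 0L)
})
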