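#' Default filter thresholds
#'
#' The cascade's printed defaults: coverage < 100 reads fails, < 10
#' alt reads fails, cohort-wide VAF presence strictly above 2%, run
#' balance tested at alpha 0.05, SNP mean population frequency >= 5%
#' (inclusive), germline heuristic >= 10 carriers with mean and median
#' VAF strictly above 40%.
#' @param ... overrides by name
#' @return named list of thresholds
#' @export
filter_thresholds <- function(...) {
  th <- list(min_depth = 100L, min_alt = 10L, vaf_presence = 0.02,
             alpha = 0.05, snp_af = 0.05, snp_rule = "mean",
             germline_carriers = 10L, germline_vaf = 0.40)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) stop_config(unknown[1], "unknown threshold")
  th[names(dots)] <- dots
  if (!th$snp_rule %in% c("mean", "each"))
    stop_config("snp_rule", "must be 'mean' or 'each'")
  th
}

filter_rules <- function() c("REGION", "MULTICALLER", "DEPTH", "ALTREADS",
                             "VAFPRESENCE", "RUNBALANCE", "COSMIC",
                             "AACHANGE", "SNP", "GERMLINE")

#' Build the cohort variant table
#'
#' Stacks per-sample merged variants, attaches run ids, and computes the
#' cohort-level annotations the cohort-scope rules need: carrier counts,
#' mean/median/max VAF per variant key, and per-run carrier counts.
#'
#' @param merged data.frame of merged variants (rows from
#'   \code{\link{merge_callers}}, any number of samples)
#' @param samples data.frame with sample_id, run_id (one row per cohort
#'   sample, carriers or not -- run sizes come from here)
#' @return list of class \code{jak_cohort_table}: \code{rows} (per
#'   occurrence), \code{keys} (per variant key summary), \code{samples}
#' @export
build_cohort_table <- function(merged, samples) {
  stopifnot(all(c("sample_id", "run_id") %in% names(samples)))
  if (nrow(merged) > 0 && !all(merged$sample_id %in% samples$sample_id))
    stop("integrity error: merged variants reference unknown samples", call. = FALSE)
  rows <- merged
  rows$run_id <- samples$run_id[match(rows$sample_id, samples$sample_id)]
  id <- key_id(rows)
  if (nrow(rows)) {
    keys <- do.call(rbind, lapply(split(seq_len(nrow(rows)), id), function(ix) {
      g <- rows[ix, ]
      data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1], alt = g$alt[1],
                 n_carriers = nrow(g), mean_vaf = mean(g$vaf),
                 median_vaf = median(g$vaf), max_vaf = max(g$vaf),
                 stringsAsFactors = FALSE)
    }))
    keys <- keys[order(keys$chrom, keys$pos, keys$ref, keys$alt), ]
    rownames(keys) <- NULL
  } else {
    keys <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), n_carriers = integer(), mean_vaf = numeric(),
                       median_vaf = numeric(), max_vaf = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(rows = rows, keys = keys, samples = samples),
            class = "jak_cohort_table")
}

#' Per-occurrence site rules
#'
#' Evaluates the four per-row rules of the cascade: REGION (variant in a
#' targeted region), MULTICALLER (reported by >= 2 callers), DEPTH
#' (aggregated coverage >= 100 reads) and ALTREADS (>= 10 reads
#' supporting the variant allele). Boundary semantics follow the printed
#' criteria: depth 100 and alt 10 pass.
#'
#' @param mv data.frame of merged variants
#' @param regions \code{jak_regions}
#' @param thresholds from \code{\link{filter_thresholds}}
#' @return logical matrix (rows x rules), TRUE = pass
#' @export
apply_site_filters <- function(mv, regions, thresholds = filter_thresholds()) {
  cbind(REGION = as.logical(in_region(mv, regions)),
        MULTICALLER = mv$n_callers >= 2L,
        DEPTH = mv$agg_depth >= thresholds$min_depth,
        ALTREADS = mv$agg_alt >= thresholds$min_alt)
}

#' Cohort VAF-presence rule
#'
#' A variant key is retained iff it occurs at least once, in any sample,
#' with VAF strictly above the presence threshold (2%). The rule acts on
#' the key: a 1% occurrence is kept when another sample carries the same
#' variant above 2%.
#' @param table \code{jak_cohort_table}
#' @param thresholds thresholds list
#' @return character vector of retained key ids
#' @export
cohort_vaf_presence <- function(table, thresholds = filter_thresholds()) {
  k <- table$keys
  key_id(k[k$max_vaf > thresholds$vaf_presence, , drop = FALSE])
}

#' Chi-square run-balance test for one variant key
#'
#' Compares carriers per sequencing run against expectation proportional
#' to run size (Pearson chi-square, df = runs - 1). Degenerate cases --
#' a single run, or fewer than 2 carriers -- cannot be assessed and are
#' passed as \code{not_evaluated}.
#'
#' @param carriers_by_run named integer: carriers per run (all runs)
#' @param run_sizes named integer: cohort samples per run
#' @param alpha significance level (fail iff p < alpha)
#' @return list(chi2, df, p, pass, evaluated)
#' @export
run_balance_test <- function(carriers_by_run, run_sizes, alpha = 0.05) {
  run_sizes <- run_sizes[run_sizes > 0]
  obs <- carriers_by_run[names(run_sizes)]
  obs[is.na(obs)] <- 0L
  total <- sum(obs)
  if (length(run_sizes) < 2L || total < 2L)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                pass = TRUE, evaluated = FALSE))
  expect <- total * run_sizes / sum(run_sizes)
  use <- expect > 0
  chi2 <- sum((obs[use] - expect[use])^2 / expect[use])
  df <- sum(use) - 1L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, pass = p >= alpha, evaluated = TRUE)
}

#' Cohort germline heuristic
#'
#' Flags variant keys found in >= 10 samples whose carrier VAFs have both
#' mean and median strictly above 40% -- the signature of an inherited
#' heterozygous polymorphism rather than a somatic mutation.
#' @param table \code{jak_cohort_table}
#' @param thresholds thresholds list
#' @return character vector of flagged key ids
#' @export
germline_flag <- function(table, thresholds = filter_thresholds()) {
  k <- table$keys
  flag <- k$n_carriers >= thresholds$germline_carriers &
    k$mean_vaf > thresholds$germline_vaf &
    k$median_vaf > thresholds$germline_vaf
  key_id(k[flag, , drop = FALSE])
}

#' Known-SNP rule
#'
#' A key is a known SNP when its mean population allele frequency across
#' the three databases (1000G all, 1000G EUR, ESP EUR; absent = 0) is
#' >= 5%. With \code{snp_rule = "each"} every database must individually
#' reach the threshold instead.
#' @param key data.frame of normalized keys
#' @param freqs population-frequency table
#' @param thresholds thresholds list
#' @return logical vector (TRUE = flagged as SNP)
#' @export
snp_flag <- function(key, freqs, thresholds = filter_thresholds()) {
  af <- lookup_population_frequency(key, freqs)
  if (thresholds$snp_rule == "mean") rowMeans(af) >= thresholds$snp_af
  else af[[1]] >= thresholds$snp_af & af[[2]] >= thresholds$snp_af &
    af[[3]] >= thresholds$snp_af
}

#' Run the full filter cascade over a cohort
#'
#' Evaluates all ten rules -- REGION, MULTICALLER, DEPTH, ALTREADS,
#' VAFPRESENCE, RUNBALANCE, COSMIC, AACHANGE, SNP, GERMLINE -- for every
#' occurrence, without short-circuiting, so the audit reports every rule
#' verdict per row. A row is kept iff no rule failed.
#'
#' @param table \code{jak_cohort_table}
#' @param regions \code{jak_regions}
#' @param cosmic COSMIC-like table
#' @param freqs population-frequency table
#' @param model transcript model
#' @param reference reference sequence
#' @param thresholds from \code{\link{filter_thresholds}}
#' @return list of class \code{jak_filter_result}: \code{kept} (rows that
#'   pass), \code{audit} (all rows, one column per rule: "pass"/"fail"/
#'   "not_evaluated", plus final and fail_reasons), \code{summary}
#'   (per-rule exclusion counts), \code{mutated_samples}
#' @export
filter_cohort <- function(table, regions, cosmic, freqs, model, reference,
                          thresholds = filter_thresholds()) {
  rows <- table$rows
  rules <- filter_rules()
  n <- nrow(rows)
  verdict <- matrix("pass", n, length(rules), dimnames = list(NULL, rules))
  if (n > 0L) {
    site <- apply_site_filters(rows, regions, thresholds)
    for (r in colnames(site)) verdict[, r] <- ifelse(site[, r], "pass", "fail")

    present <- cohort_vaf_presence(table, thresholds)
    verdict[, "VAFPRESENCE"] <- ifelse(key_id(rows) %in% present, "pass", "fail")

    run_sizes <- table(factor(table$samples$run_id))
    run_sizes <- setNames(as.integer(run_sizes), names(run_sizes))
    ids <- key_id(rows)
    for (kid in unique(ids)) {
      sel <- ids == kid
      carriers <- table(factor(rows$run_id[sel], levels = names(run_sizes)))
      rb <- run_balance_test(setNames(as.integer(carriers), names(carriers)),
                             run_sizes, thresholds$alpha)
      verdict[sel, "RUNBALANCE"] <-
        if (!rb$evaluated) "not_evaluated" else if (rb$pass) "pass" else "fail"
    }

    keys <- table$keys
    kid <- key_id(keys)
    in_cosmic <- lookup_cosmic(keys, cosmic)
    eff <- vapply(seq_len(nrow(keys)), function(i)
      annotate_effect(keys[i, ], model, reference)$effect, "")
    is_snp <- snp_flag(keys, freqs, thresholds)
    glf <- kid %in% germline_flag(table, thresholds)
    m <- match(ids, kid)
    verdict[, "COSMIC"] <- ifelse(in_cosmic[m], "pass", "fail")
    verdict[, "AACHANGE"] <- ifelse(aa_changing(eff[m]), "pass", "fail")
    verdict[, "SNP"] <- ifelse(is_snp[m], "fail", "pass")
    verdict[, "GERMLINE"] <- ifelse(glf[m], "fail", "pass")
  }
  failed <- verdict == "fail"
  final <- ifelse(rowSums(failed) == 0L, "kept", "excluded")
  fail_reasons <- apply(failed, 1L, function(fr) paste(rules[fr], collapse = ","))
  audit <- cbind(rows[, c("sample_id", "run_id", "chrom", "pos", "ref", "alt",
                          "n_callers", "agg_depth", "agg_alt", "vaf"), drop = FALSE],
                 as.data.frame(verdict, stringsAsFactors = FALSE),
                 final = final,
                 fail_reasons = if (n) fail_reasons else character(0),
                 stringsAsFactors = FALSE)
  kept <- rows[final == "kept", , drop = FALSE]
  rownames(kept) <- NULL
  summary <- data.frame(rule = rules,
                        n_failed = colSums(failed),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(kept = kept, audit = audit, summary = summary,
                 mutated_samples = sort(unique(kept$sample_id))),
            class = "jak_filter_result")
}
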