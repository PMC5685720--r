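# Independent oracles and fixture builders used across the suite.
# Each oracle recomputes an expected value by a route that does not share
# code with the implementation it checks.

ref <- read_reference()
model <- read_transcript_model()
regions <- read_regions(jak_extdata("targets.bed"))
cosmic <- read_cosmic_table(reference = ref)
popfreq <- read_popfreq_table(reference = ref)

# --- haplotype-substitution oracle -----------------------------------------
# Applies a variant to the raw contig string; two representations of the
# same variant must give identical alternate haplotypes.
apply_variant_to_seq <- function(seq, pos, refa, alta) {
  stopifnot(substr(seq, pos, pos + nchar(refa) - 1L) == refa)
  paste0(substr(seq, 1, pos - 1L), alta,
         substr(seq, pos + nchar(refa), nchar(seq)))
}

# --- effect oracle: translate the whole exon before/after ------------------
oracle_effect <- function(pos, refa, alta, model., ref.) {
  contig <- ref.[[model.$chrom]]
  ex <- model.$exons
  hit <- which(ex$start <= pos + nchar(refa) - 1L & ex$end >= pos)
  if (length(hit) == 0L) return("noncoding")
  if (nchar(refa) != nchar(alta))
    return(if (abs(nchar(refa) - nchar(alta)) %% 3L == 0L) "inframe_indel"
           else "frameshift")
  e <- ex[hit[1], ]
  if (pos < e$start || pos + nchar(refa) - 1L > e$end) return("noncoding")
  tr <- function(s) {
    x <- substr(s, e$start, e$end)
    if (model.$strand == "-")
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       no.init.codon = TRUE))
  }
  mut <- apply_variant_to_seq(contig, pos, refa, alta)
  # same-length substitution keeps exon coordinates valid
  ref_aa <- tr(contig); alt_aa <- tr(mut)
  if (ref_aa == alt_aa) return("synonymous")
  i <- which(strsplit(ref_aa, "")[[1]] != strsplit(alt_aa, "")[[1]])[1]
  if (substr(alt_aa, i, i) == "*") "nonsense" else "missense"
}

# --- brute-force filter oracle ---------------------------------------------
# Direct set comprehension of the ten predicates over the cohort rows.
oracle_filter_kept <- function(rows, samples, regions., cosmic., popfreq.,
                               model., ref., th = filter_thresholds()) {
  if (nrow(rows) == 0L) return(rows)
  rid <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")
  run_of <- setNames(samples$run_id, samples$sample_id)
  run_sizes <- table(samples$run_id)
  ok <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    inreg <- any(regions.$chrom == r$chrom & regions.$start < r$pos &
                   r$pos <= regions.$end)
    multi <- r$n_callers >= 2
    dep <- r$agg_depth >= th$min_depth
    altr <- r$agg_alt >= th$min_alt
    vafp <- max(rows$vaf[rid == rid[i]]) > th$vaf_presence
    carriers <- rows[rid == rid[i], ]
    obs <- table(factor(run_of[carriers$sample_id], levels = names(run_sizes)))
    tot <- sum(obs)
    if (length(run_sizes) < 2L || tot < 2L) runbal <- TRUE else {
      expd <- tot * as.numeric(run_sizes) / sum(run_sizes)
      use <- expd > 0
      chi2 <- sum((as.numeric(obs)[use] - expd[use])^2 / expd[use])
      runbal <- pchisq(chi2, sum(use) - 1L, lower.tail = FALSE) >= th$alpha
    }
    cos <- any(cosmic.$chrom == r$chrom & cosmic.$pos == r$pos &
                 cosmic.$ref == r$ref & cosmic.$alt == r$alt)
    aach <- oracle_effect(r$pos, r$ref, r$alt, model., ref.) %in%
      c("missense", "nonsense", "frameshift", "inframe_indel")
    hit <- which(popfreq.$chrom == r$chrom & popfreq.$pos == r$pos &
                   popfreq.$ref == r$ref & popfreq.$alt == r$alt)
    afs <- if (length(hit)) as.numeric(popfreq.[hit[1], c("af_1000g_all",
                                                          "af_1000g_eur",
                                                          "af_esp_eur")])
           else c(0, 0, 0)
    notsnp <- mean(afs) < th$snp_af
    nc <- sum(rid == rid[i])
    germ <- !(nc >= th$germline_carriers &
                mean(carriers$vaf) > th$germline_vaf &
                median(carriers$vaf) > th$germline_vaf)
    ok[i] <- inreg && multi && dep && altr && vafp && runbal && cos &&
      aach && notsnp && germ
  }
  rows[ok, , drop = FALSE]
}

# --- Fisher enumeration oracle ---------------------------------------------
# Probability of each margin-fixed table via binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  pr_of <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, pr_of, 0)
  pobs <- pr_of(a)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- Gray permutation oracle -----------------------------------------------
# Exhaustive relabeling of group assignments for small two-group data.
oracle_gray_permutation <- function(time, status, group) {
  obs <- gray_test(time, status, group)$statistic
  n <- length(time)
  idx_a <- which(group == unique(group)[1])
  combs <- utils::combn(n, length(idx_a))
  stats <- apply(combs, 2, function(ix) {
    g <- rep(2L, n); g[ix] <- 1L
    gray_test(time, status, g)$statistic
  })
  mean(stats >= obs - 1e-12)
}

# --- constructed noiseless cohort (truth recovery) -------------------------
# 20 samples in 2 runs; 3 somatic hotspot variants above all thresholds,
# one germline plant (COSMIC missense, absent from the SNP table) in
# >= 10 samples at VAF ~ 0.5, one artifact confined to run1.
noiseless_cohort_config <- function(seed = 424243L) {
  simulation_config(
    n_samples = 20L,
    subtype_proportions = c(B_other = 1),
    runs = data.frame(run_id = c("run1", "run2"), n_samples = c(10L, 10L)),
    depth_dispersion = 50,
    truth_variants = data.frame(
      chrom = "JAK2syn",
      pos = c(325L, 918L, 1211L), ref = c("A", "G", "G"),
      alt = c("G", "A", "A"), label = c("R683G", "R867Q", "R923H"),
      n_carriers = 3L, vaf_min = 0.10, vaf_max = 0.40,
      subtypes = NA, stringsAsFactors = FALSE),
    germline_snps = data.frame(chrom = "JAK2syn", pos = 606L, ref = "G",
                               alt = "A", carrier_rate = 0.7),
    artifacts = data.frame(chrom = "JAK2syn", pos = 942L, ref = "A",
                           alt = "G", run_id = "run1", n_carriers = 6L,
                           vaf = 0.05),
    caller_profiles = noiseless_caller_profiles(),
    rng_seed = seed)
}

# merge a bundle's callsets through the reader-free path (in memory)
merge_bundle <- function(bundle, config = bundle$config) {
  callsets <- emit_caller_callsets(bundle, config, regions, ref)
  merged <- do.call(rbind, lapply(names(callsets), function(sid) {
    calls <- do.call(rbind, lapply(names(callsets[[sid]]), function(cl) {
      cs <- callsets[[sid]][[cl]]
      if (nrow(cs) == 0L) return(NULL)
      cs$caller <- cl
      k <- variant_key(cs$chrom, cs$pos, cs$ref, cs$alt, ref)
      cbind(k, cs[c("caller", "depth", "alt_reads")])
    }))
    merge_callers(calls, sid)
  }))
  rownames(merged) <- NULL
  merged
}
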