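#' Build a simulation configuration
#'
#' The defaults describe the study design being emulated: 461 samples
#' representing the major childhood BCP-ALL cytogenetic subtypes (79
#' BCR-ABL1-like, 67 B-other, 124 high hyperdiploid, 15 KMT2A-AFF1, 26
#' BCR-ABL1, 124 ETV6-RUNX1, 26 TCF3-PBX1), sequenced in 4 runs over the
#' 4 hotspot exons at per-exon median depths 673 / 577 / 711 / 944, with
#' 16 somatic hotspot carriers (VAF 1-56%), one common germline SNP and
#' one run-restricted artifact. Depths are negative binomial (the median
#' is the anchor; the dispersion parameter is a design choice, see the
#' methods vignette). Caller profiles control false-negative behaviour
#' (logistic in log-VAF, so low-VAF variants are increasingly missed),
#' per-region false-positive rates, and count jitter.
#'
#' @param n_samples cohort size
#' @param subtype_proportions named fractions summing to 1
#' @param runs data.frame run_id, n_samples (sizes must sum to n_samples)
#' @param exon_depth_medians named per-exon target median depths
#' @param depth_dispersion negative binomial size parameter
#' @param truth_variants data.frame: chrom, pos, ref, alt, label,
#'   n_carriers, vaf_min, vaf_max, subtypes (comma-separated eligible
#'   subtypes or NA for all)
#' @param germline_snps data.frame: chrom, pos, ref, alt, carrier_rate
#' @param artifacts data.frame: chrom, pos, ref, alt, run_id, n_carriers,
#'   vaf
#' @param caller_profiles named list (one per caller) of lists with
#'   fp_rate, fn_v50, fn_width, depth_jitter, alt_jitter
#' @param clinical,expression,assay generator sub-configurations
#' @param rng_seed master seed (all randomness derives from it)
#' @return object of class \code{jak_sim_config}
#' @export
simulation_config <- function(
    n_samples = 461L,
    subtype_proportions = c(BCR_ABL1_like = 79, B_other = 67,
                            high_hyperdiploid = 124, KMT2A_AFF1 = 15,
                            BCR_ABL1 = 26, ETV6_RUNX1 = 124,
                            TCF3_PBX1 = 26) / 461,
    runs = data.frame(run_id = paste0("run", 1:4),
                      n_samples = c(116L, 115L, 115L, 115L)),
    exon_depth_medians = c("16" = 673, "20" = 577, "21" = 711, "23" = 944),
    depth_dispersion = 3,
    truth_variants = default_truth_variants(),
    germline_snps = data.frame(chrom = "JAK2syn", pos = 638L, ref = "G",
                               alt = "A", carrier_rate = 0.35),
    artifacts = data.frame(chrom = "JAK2syn", pos = 651L, ref = NA, alt = NA,
                           run_id = "run1", n_carriers = 25L, vaf = 0.03),
    caller_profiles = default_caller_profiles(),
    clinical = list(p_mrd_high = 0.25, p_mrd_missing = 0.30,
                    relapse_rate_low = 0.05, relapse_rate_high = 0.45,
                    death_rate = 0.03, p_nonresponse = 0.02,
                    censor_min = 3, censor_max = 10),
    expression = list(p_high_mutated = 0.875, p_high_wildtype = 0.08,
                      mean_high = 11, sd_high = 0.5,
                      mean_low = 7, sd_low = 0.8, ct_ref_mean = 18,
                      ct_ref_sd = 0.5),
    assay = list(concentrations = c(0.04, 0.12, 0.37, 1.1, 3.3, 10),
                 n_replicates = 2L, n_vehicle = 2L, n_wildtype_controls = 10L,
                 ic50_sensitive = 0.3, floor_sensitive = 0.2,
                 floor_resistant = 0.85, od_noise = 0.05),
    rng_seed = 20160916L) {
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_proportions = subtype_proportions, runs = runs,
              exon_depth_medians = exon_depth_medians,
              depth_dispersion = depth_dispersion,
              truth_variants = truth_variants, germline_snps = germline_snps,
              artifacts = artifacts, caller_profiles = caller_profiles,
              clinical = clinical, expression = expression, assay = assay,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "jak_sim_config")
}

#' Default somatic truth variants (hotspot set)
#'
#' 16 carriers over four recurrent hotspot substitutions, dominated by
#' the residue-683 analog, restricted to the subtypes that carry
#' mutations in this disease (BCR-ABL1-like, B-other, high hyperdiploid).
#' @return data.frame
#' @export
default_truth_variants <- function() {
  st <- "BCR_ABL1_like,B_other,high_hyperdiploid"
  data.frame(
    chrom = "JAK2syn",
    pos = c(325L, 326L, 918L, 1211L),
    ref = c("A", "G", "G", "G"),
    alt = c("G", "C", "A", "A"),
    label = c("R683G", "R683T", "R867Q", "R923H"),
    n_carriers = c(11L, 2L, 1L, 2L),
    vaf_min = 0.01, vaf_max = 0.56,
    subtypes = st, stringsAsFactors = FALSE)
}

#' Default caller noise profiles
#' @return named list of per-caller profiles
#' @export
default_caller_profiles <- function() {
  prof <- function(fp, v50, width, dj, aj)
    list(fp_rate = fp, fn_v50 = v50, fn_width = width,
         depth_jitter = dj, alt_jitter = aj)
  list(A = prof(0.010, 0.015, 0.35, 0.10, 0.05),
       B = prof(0.015, 0.020, 0.35, 0.12, 0.06),
       C = prof(0.008, 0.025, 0.40, 0.08, 0.05),
       D = prof(0.005, 0.010, 0.30, 0.05, 0.04))
}

#' Noise-free caller profiles (for the noiseless-limit identity)
#' @return named list of per-caller profiles
#' @export
noiseless_caller_profiles <- function() {
  prof <- list(fp_rate = 0, fn_v50 = 0, fn_width = 0.3,
               depth_jitter = 0, alt_jitter = 0)
  list(A = prof, B = prof, C = prof, D = prof)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 0L) stop_config("n_samples", "must be >= 0")
  sp <- cfg$subtype_proportions
  if (abs(sum(sp) - 1) > 1e-9 && cfg$n_samples > 0L)
    stop_config("subtype_proportions", sprintf("sum to %.12f, not 1", sum(sp)))
  if (cfg$n_samples > 0L && sum(cfg$runs$n_samples) != cfg$n_samples)
    stop_config("runs", "run sizes must sum to n_samples")
  if (any(cfg$germline_snps$carrier_rate < 0 | cfg$germline_snps$carrier_rate > 1))
    stop_config("germline_snps", "carrier_rate outside [0,1]")
  for (nm in names(cfg$caller_profiles)) {
    p <- cfg$caller_profiles[[nm]]
    if (p$fp_rate < 0 || p$fp_rate > 1)
      stop_config(paste0("caller_profiles$", nm, "$fp_rate"), "outside [0,1]")
  }
  if (cfg$depth_dispersion <= 0) stop_config("depth_dispersion", "must be > 0")
  invisible(cfg)
}

# negative binomial mean giving a target median at given size
nb_mu_for_median <- function(med, size) {
  if (med <= 0) return(0)
  lo <- med / 2; hi <- med * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (qnbinom(0.5, size = size, mu = mid) < med) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a full synthetic cohort
#'
#' Generates samples (subtype, run, per-exon depths), per-sample truth
#' variants (somatic carriers as configured, germline SNPs at
#' heterozygous VAF, artifacts confined to their run), and the clinical,
#' expression and assay-plate tables. Deterministic given the config
#' seed; every random stream is derived hierarchically so output does
#' not depend on iteration order.
#'
#' @param config \code{jak_sim_config}
#' @param reference \code{jak_reference} (for artifact allele fill-in)
#' @return object of class \code{jak_cohort_bundle}: list with samples,
#'   depths (long sample x exon), truth, clinical, expression, plates
#' @export
simulate_cohort <- function(config, reference = read_reference()) {
  validate_sim_config(config)
  n <- config$n_samples
  seed <- config$rng_seed
  empty <- function(...) {
    df <- data.frame(...)
    df[0, , drop = FALSE]
  }
  if (n == 0L) {
    bundle <- list(
      samples = empty(sample_id = "", subtype = "", run_id = ""),
      depths = empty(sample_id = "", exon = "", depth = 0L),
      truth = empty(sample_id = "", chrom = "", pos = 0L, ref = "", alt = "",
                    label = "", true_vaf = 0, origin = ""),
      clinical = empty(sample_id = "", mrd_level = 0, mrd_high = TRUE,
                       relapsed = TRUE, time = 0, event_type = 0L, group = ""),
      expression = empty(sample_id = "", probe_intensity = 0, ct_target = 0,
                         ct_reference = 0),
      plates = empty(sample_id = "", drug = "", condition = "",
                     concentration = 0, replicate = 0L, signal = 0,
                     well_type = ""),
      config = config)
    class(bundle) <- "jak_cohort_bundle"
    return(bundle)
  }

  # --- samples: subtype counts (largest-remainder), run assignment ---
  sp <- config$subtype_proportions
  raw <- sp * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  subtype <- rep(names(sp), cnt)
  sample_id <- sprintf("S%04d", seq_len(n))
  subtype <- with_seed(derive_seed(seed, "subtype"), sample(subtype))
  run_id <- rep(config$runs$run_id, config$runs$n_samples)
  samples <- data.frame(sample_id = sample_id, subtype = subtype,
                        run_id = run_id, stringsAsFactors = FALSE)

  # --- per-exon depths: negative binomial anchored at the target median ---
  exons <- names(config$exon_depth_medians)
  depths <- do.call(rbind, lapply(exons, function(ex) {
    mu <- nb_mu_for_median(config$exon_depth_medians[[ex]], config$depth_dispersion)
    d <- with_seed(derive_seed(seed, "depth", ex),
                   rnbinom(n, size = config$depth_dispersion, mu = mu))
    data.frame(sample_id = sample_id, exon = ex, depth = as.integer(d),
               stringsAsFactors = FALSE)
  }))

  # --- somatic truth ---
  truth <- list()
  tv <- config$truth_variants
  for (i in seq_len(nrow(tv))) {
    elig <- samples$sample_id
    if (!is.na(tv$subtypes[i])) {
      ok <- strsplit(tv$subtypes[i], ",", fixed = TRUE)[[1]]
      elig <- samples$sample_id[samples$subtype %in% ok]
    }
    k <- min(tv$n_carriers[i], length(elig))
    carriers <- with_seed(derive_seed(seed, "somatic", tv$label[i]),
                          sample(elig, k))
    vafs <- with_seed(derive_seed(seed, "somatic_vaf", tv$label[i]),
                      runif(k, tv$vaf_min[i], tv$vaf_max[i]))
    truth[[length(truth) + 1]] <- data.frame(
      sample_id = carriers, chrom = tv$chrom[i], pos = tv$pos[i],
      ref = tv$ref[i], alt = tv$alt[i], label = tv$label[i],
      true_vaf = vafs, origin = "somatic", stringsAsFactors = FALSE)
  }

  # --- germline SNPs: Bernoulli carriers at tight heterozygous VAF ---
  gs <- config$germline_snps
  for (i in seq_len(nrow(gs))) {
    lab <- sprintf("SNP_%s_%d", gs$chrom[i], gs$pos[i])
    is_carrier <- with_seed(derive_seed(seed, "germline", lab),
                            runif(n) < gs$carrier_rate[i])
    k <- sum(is_carrier)
    if (k == 0L) next
    vafs <- with_seed(derive_seed(seed, "germline_vaf", lab),
                      rbeta(k, 200, 200))
    truth[[length(truth) + 1]] <- data.frame(
      sample_id = samples$sample_id[is_carrier], chrom = gs$chrom[i],
      pos = gs$pos[i], ref = gs$ref[i], alt = gs$alt[i], label = lab,
      true_vaf = vafs, origin = "germline", stringsAsFactors = FALSE)
  }

  # --- run-restricted artifacts ---
  af <- config$artifacts
  for (i in seq_len(nrow(af))) {
    pool <- samples$sample_id[samples$run_id == af$run_id[i]]
    k <- min(af$n_carriers[i], length(pool))
    if (k == 0L) next
    ref_a <- af$ref[i]; alt_a <- af$alt[i]
    if (is.na(ref_a)) ref_a <- ref_base(reference, af$chrom[i], af$pos[i])
    if (is.na(alt_a)) {
      alt_a <- with_seed(derive_seed(seed, "artifact_alt", i),
                         sample(setdiff(c("A", "C", "G", "T"), ref_a), 1))
    }
    lab <- sprintf("ART_%s_%d", af$chrom[i], af$pos[i])
    carriers <- with_seed(derive_seed(seed, "artifact", lab), sample(pool, k))
    vafs <- with_seed(derive_seed(seed, "artifact_vaf", lab),
                      runif(k, af$vaf[i] * 0.7, af$vaf[i] * 1.3))
    truth[[length(truth) + 1]] <- data.frame(
      sample_id = carriers, chrom = af$chrom[i], pos = af$pos[i],
      ref = ref_a, alt = alt_a, label = lab, true_vaf = vafs,
      origin = "artifact", stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), label = character(),
               true_vaf = numeric(), origin = character(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$sample_id, truth$chrom, truth$pos, truth$alt), ]
  rownames(truth) <- NULL

  mutated <- samples$sample_id %in% truth$sample_id[truth$origin == "somatic"]

  # --- clinical: MRD linked to relapse hazard, death as competing risk ---
  cc <- config$clinical
  clinical <- with_seed(derive_seed(seed, "clinical"), {
    mrd_high <- runif(n) < cc$p_mrd_high
    mrd_level <- ifelse(mrd_high, 10^runif(n, -3, -1.3), 10^runif(n, -6, -3.001))
    mrd_level[runif(n) < cc$p_mrd_missing] <- NA
    rate_r <- ifelse(mrd_high, cc$relapse_rate_high, cc$relapse_rate_low)
    t_rel <- rexp(n, rate_r)
    t_death <- rexp(n, cc$death_rate)
    t_cens <- runif(n, cc$censor_min, cc$censor_max)
    nonresp <- runif(n) < cc$p_nonresponse
    time <- pmin(t_rel, t_death, t_cens)
    event_type <- ifelse(time == t_rel, 1L, ifelse(time == t_death, 2L, 0L))
    time[nonresp] <- 79 / 365.25
    event_type[nonresp] <- 1L
    data.frame(sample_id = sample_id, mrd_level = mrd_level,
               mrd_high = ifelse(is.na(mrd_level), NA, mrd_level >= 1e-3),
               relapsed = event_type == 1L, time = time,
               event_type = event_type,
               group = ifelse(mutated, "JAK2_mutated", "JAK2_wildtype"),
               stringsAsFactors = FALSE)
  })

  # --- expression: bimodal probe intensity; Ct pair consistent with it ---
  ec <- config$expression
  expression <- with_seed(derive_seed(seed, "expression"), {
    p_high <- ifelse(mutated, ec$p_high_mutated, ec$p_high_wildtype)
    hi <- runif(n) < p_high
    intensity <- ifelse(hi, rnorm(n, ec$mean_high, ec$sd_high),
                        rnorm(n, ec$mean_low, ec$sd_low))
    ct_ref <- rnorm(n, ec$ct_ref_mean, ec$ct_ref_sd)
    # higher expression -> smaller delta-Ct; anchor at the low-mode mean
    ct_tgt <- ct_ref - (intensity - ec$mean_low)
    data.frame(sample_id = sample_id, probe_intensity = intensity,
               ct_target = ct_tgt, ct_reference = ct_ref,
               stringsAsFactors = FALSE)
  })

  # --- assay plates: mutated carriers + wildtype controls, two drugs ---
  ac <- config$assay
  wt_pool <- samples$sample_id[!mutated]
  n_wt <- min(ac$n_wildtype_controls, length(wt_pool))
  wt_ctrl <- with_seed(derive_seed(seed, "assay_controls"),
                       if (n_wt > 0) sample(wt_pool, n_wt) else character(0))
  tested <- c(samples$sample_id[mutated], wt_ctrl)
  plates <- list()
  for (sid in tested) {
    sens <- mutated[match(sid, samples$sample_id)]
    for (drug in c("momelotinib", "ruxolitinib")) {
      pl <- with_seed(derive_seed(seed, "assay", sid, drug), {
        veh <- rnorm(ac$n_vehicle, 1, ac$od_noise)
        floor_v <- if (sens) ac$floor_sensitive else ac$floor_resistant
        rows <- expand.grid(concentration = ac$concentrations,
                            replicate = seq_len(ac$n_replicates))
        eff <- floor_v + (1 - floor_v) /
          (1 + (rows$concentration / ac$ic50_sensitive))
        sig <- mean(veh) * eff * (1 + rnorm(nrow(rows), 0, ac$od_noise))
        rbind(
          data.frame(sample_id = sid, drug = drug, condition = "none",
                     concentration = 0, replicate = seq_len(ac$n_vehicle),
                     signal = veh, well_type = "vehicle",
                     stringsAsFactors = FALSE),
          data.frame(sample_id = sid, drug = drug, condition = "none",
                     concentration = rows$concentration,
                     replicate = rows$replicate, signal = sig,
                     well_type = "treated", stringsAsFactors = FALSE))
      })
      plates[[length(plates) + 1]] <- pl
    }
  }
  plates <- if (length(plates)) do.call(rbind, plates) else
    data.frame(sample_id = character(), drug = character(), condition = character(),
               concentration = numeric(), replicate = integer(), signal = numeric(),
               well_type = character(), stringsAsFactors = FALSE)
  rownames(plates) <- NULL

  bundle <- list(samples = samples, depths = depths, truth = truth,
                 clinical = clinical, expression = expression, plates = plates,
                 config = config)
  class(bundle) <- "jak_cohort_bundle"
  bundle
}

#' Emit per-sample, per-caller call sets
#'
#' For every true variant of a sample and every caller: the caller
#' misses the variant with a probability that grows as VAF falls
#' (logistic in log-VAF around the caller's \code{fn_v50}); otherwise
#' the reported depth is the sample's exon depth with caller jitter and
#' the alt count is a binomial draw at the true VAF with alt jitter.
#' Caller-specific false positives are injected per targeted region at
#' the caller's \code{fp_rate}.
#'
#' @param bundle from \code{\link{simulate_cohort}}
#' @param config the same \code{jak_sim_config}
#' @param regions \code{jak_regions} (for exon lookup / false positives)
#' @param reference \code{jak_reference}
#' @return named list: callsets[[sample_id]][[caller]] = data.frame with
#'   chrom, pos, ref, alt, depth, alt_reads
#' @export
emit_caller_callsets <- function(bundle, config = bundle$config,
                                 regions = read_regions(jak_extdata("targets.bed")),
                                 reference = read_reference()) {
  seed <- config$rng_seed
  callers <- names(config$caller_profiles)
  out <- list()
  depth_of <- function(sid, exon) {
    d <- bundle$depths
    i <- which(d$sample_id == sid & d$exon == exon)
    if (length(i)) d$depth[i[1]] else 0L
  }
  exon_label <- function(chrom, pos) {
    hit <- in_region(data.frame(chrom = chrom, pos = pos), regions)
    lab <- attr(hit, "label")
    sub("^exon", "", ifelse(is.na(lab), NA, lab))
  }
  for (sid in bundle$samples$sample_id) {
    tv <- bundle$truth[bundle$truth$sample_id == sid, , drop = FALSE]
    per_caller <- list()
    for (cl in callers) {
      p <- config$caller_profiles[[cl]]
      calls <- with_seed(derive_seed(seed, "calls", sid, cl), {
        rows <- list()
        for (i in seq_len(nrow(tv))) {
          vaf <- tv$true_vaf[i]
          fn <- if (p$fn_v50 <= 0) 0 else
            stats::plogis((log(p$fn_v50) - log(vaf)) / p$fn_width)
          if (runif(1) < fn) next
          ex <- exon_label(tv$chrom[i], tv$pos[i])
          dep <- if (is.na(ex)) 150L else depth_of(sid, ex)
          if (p$depth_jitter > 0)
            dep <- max(0L, as.integer(round(dep * (1 + runif(1, -p$depth_jitter,
                                                             p$depth_jitter)))))
          alt <- rbinom(1, dep, vaf)
          if (p$alt_jitter > 0)
            alt <- as.integer(round(alt * (1 + runif(1, -p$alt_jitter,
                                                     p$alt_jitter))))
          alt <- min(max(alt, 0L), dep)
          if (dep == 0L) next
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tv$chrom[i], pos = tv$pos[i], ref = tv$ref[i],
            alt = tv$alt[i], depth = dep, alt_reads = alt,
            stringsAsFactors = FALSE)
        }
        # false positives per region
        if (p$fp_rate > 0) for (r in seq_len(nrow(regions))) {
          if (runif(1) >= p$fp_rate) next
          pos <- sample(seq.int(regions$start[r] + 1L, regions$end[r]), 1)
          rb <- ref_base(reference, regions$chrom[r], pos)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          ex <- sub("^exon", "", regions$label[r])
          dep <- depth_of(sid, ex)
          if (dep == 0L) next
          alt <- rbinom(1, dep, runif(1, 0.005, 0.02))
          if (alt == 0L) next
          rows[[length(rows) + 1]] <- data.frame(
            chrom = regions$chrom[r], pos = pos, ref = rb, alt = ab,
            depth = dep, alt_reads = alt, stringsAsFactors = FALSE)
        }
        if (length(rows)) do.call(rbind, rows) else
          data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), depth = integer(), alt_reads = integer(),
                     stringsAsFactors = FALSE)
      })
      # collapse duplicate sites (a false positive can hit a truth site)
      if (nrow(calls)) {
        id <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
        calls <- calls[!duplicated(id), , drop = FALSE]
        calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
        rownames(calls) <- NULL
      }
      per_caller[[cl]] <- calls
    }
    out[[sid]] <- per_caller
  }
  out
}

#' Write a cohort fixture to disk
#'
#' Emits one VCF per sample per caller (in each caller's dialect), the
#' targeted-regions BED, and the samples / truth / clinical / expression
#' / plates tables as TSV. Files round-trip losslessly through the
#' package readers.
#'
#' @param bundle \code{jak_cohort_bundle}
#' @param callsets from \code{\link{emit_caller_callsets}}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_fixture <- function(bundle, callsets, dir) {
  ok <- dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "vcf")))
    stop(sprintf("cannot create fixture directory '%s'", dir), call. = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(bundle$samples, "samples.tsv")
  tsv(bundle$depths, "depths.tsv")
  tsv(bundle$truth, "truth.tsv")
  tsv(bundle$clinical, "clinical.tsv")
  tsv(bundle$expression, "expression.tsv")
  tsv(bundle$plates, "plates.tsv")
  file.copy(jak_extdata("targets.bed"), file.path(dir, "targets.bed"),
            overwrite = TRUE)
  for (sid in names(callsets)) {
    for (cl in names(callsets[[sid]])) {
      write_caller_vcf(callsets[[sid]][[cl]], cl,
                       file.path(dir, "vcf", sprintf("%s__%s.vcf", sid, cl)),
                       sample_id = sid)
    }
  }
  invisible(dir)
}

#' List fixture VCFs by sample and caller
#' @param dir fixture directory written by \code{\link{write_fixture}}
#' @return data.frame: sample_id, caller, path
#' @export
list_fixture_vcfs <- function(dir) {
  files <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$", full.names = TRUE)
  base <- sub("\\.vcf$", "", basename(files))
  parts <- strsplit(base, "__", fixed = TRUE)
  data.frame(sample_id = vapply(parts, `[`, "", 1L),
             caller = vapply(parts, `[`, "", 2L),
             path = files, stringsAsFactors = FALSE)
}
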