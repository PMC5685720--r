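#' Build a pipeline configuration
#'
#' Bundles paths, thresholds and toggles for an end-to-end run. Defaults
#' are exactly the cascade's printed values (depth 100, alt reads 10,
#' VAF presence 2%, SNP 5%, germline 10 carriers / 40% VAF, chi-square
#' alpha 0.05, MRD 1e-3, percentile 90).
#'
#' @param out_dir artifact directory
#' @param fixture_dir input fixture directory; NULL to simulate one
#' @param seed master seed (simulation and manifest)
#' @param thresholds list from \code{\link{filter_thresholds}}
#' @param sim_config \code{jak_sim_config} used when simulating
#' @param mrd_threshold high-MRD cutoff
#' @param percentile CRLF2 "high" percentile
#' @param detect_vafs VAFs at which detection fractions are reported
#' @param welch use Welch t-test in the assay comparison
#' @return object of class \code{jak_pipeline_config}
#' @export
pipeline_config <- function(out_dir, fixture_dir = NULL, seed = 20160916L,
                            thresholds = filter_thresholds(),
                            sim_config = NULL, mrd_threshold = 1e-3,
                            percentile = 90,
                            detect_vafs = c(0.05, 0.01), welch = FALSE) {
  if (is.null(sim_config))
    sim_config <- simulation_config(rng_seed = as.integer(seed))
  structure(list(out_dir = out_dir, fixture_dir = fixture_dir,
                 seed = as.integer(seed), thresholds = thresholds,
                 sim_config = sim_config, mrd_threshold = mrd_threshold,
                 percentile = percentile, detect_vafs = detect_vafs,
                 welch = welch),
            class = "jak_pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stages: simulate (unless an existing fixture directory is given) ->
#' read caller VCFs -> merge -> filter cascade -> detection-limit
#' summary -> clinical statistics -> assay normalization. Writes all
#' tabular outputs as TSV plus a JSON manifest (config hash, seed,
#' package version, output checksums) so identical configurations give
#' identical artifacts.
#'
#' @param config \code{jak_pipeline_config}
#' @param quiet suppress per-stage record-count logging to stderr
#' @return invisibly, a list with the in-memory results of every stage
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[jakscreen] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- read_reference()
  model <- read_transcript_model()
  regions <- read_regions(jak_extdata("targets.bed"))
  cosmic <- read_cosmic_table(reference = reference)
  freqs <- read_popfreq_table(reference = reference)

  fdir <- config$fixture_dir
  if (is.null(fdir)) {
    fdir <- file.path(config$out_dir, "fixture")
    stage("simulate", {
      bundle <- simulate_cohort(config$sim_config, reference)
      callsets <- emit_caller_callsets(bundle, config$sim_config, regions, reference)
      write_fixture(bundle, callsets, fdir)
      say("simulate: %d samples, %d truth records", nrow(bundle$samples),
          nrow(bundle$truth))
    })
  }
  samples <- read.table(file.path(fdir, "samples.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  depths <- read.table(file.path(fdir, "depths.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  depths$exon <- as.character(depths$exon)
  clinical <- read.table(file.path(fdir, "clinical.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  expression <- read.table(file.path(fdir, "expression.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  plates <- read.table(file.path(fdir, "plates.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)

  merged <- stage("merge", {
    vcfs <- list_fixture_vcfs(fdir)
    res <- lapply(split(vcfs, vcfs$sample_id), function(g) {
      calls <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
        read_caller_vcf(g$path[i], g$caller[i], reference)))
      merge_callers(calls, g$sample_id[1])
    })
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  })
  say("merge: %d merged variant occurrences", nrow(merged))

  filt <- stage("filter", {
    tab <- build_cohort_table(merged, samples)
    filter_cohort(tab, regions, cosmic, freqs, model, reference,
                  config$thresholds)
  })
  say("filter: %d kept of %d; %d mutated samples", nrow(filt$kept),
      nrow(filt$audit), length(filt$mutated_samples))

  detect <- stage("detect-limit", {
    lapply(setNames(config$detect_vafs, paste0("vaf_", config$detect_vafs)),
           function(v) cohort_detection_summary(
             depths, v, config$thresholds$min_depth, config$thresholds$min_alt))
  })

  stats <- stage("stats", {
    crlf2 <- classify_crlf2(expression$probe_intensity, config$percentile)
    mrd <- mrd_relapse_association(clinical, config$mrd_threshold)
    ci <- cumulative_incidence(clinical$time, clinical$event_type)
    gr <- if (length(unique(clinical$group)) >= 2)
      gray_test(clinical$time, clinical$event_type, clinical$group) else NULL
    list(crlf2 = crlf2, mrd = mrd, cuminc = ci, gray = gr)
  })
  say("stats: MRD table n=%d, Fisher p=%.4g%s", stats$mrd$n, stats$mrd$p,
      if (is.null(stats$gray)) "" else
        sprintf(", Gray p=%.4g", stats$gray$p))

  assay <- stage("assay", {
    if (nrow(plates) == 0) NULL else {
      norm <- do.call(rbind, lapply(
        split(plates, list(plates$sample_id, plates$drug), drop = TRUE),
        function(pl) {
          veh <- pl$signal[pl$well_type == "vehicle"]
          tr <- pl[pl$well_type == "treated", , drop = FALSE]
          tr$viability <- normalize_viability(tr$signal, veh)
          tr
        }))
      rownames(norm) <- NULL
      curves <- lapply(split(norm, norm$drug), summarize_dose_response)
      list(normalized = norm, curves = curves)
    }
  })

  # --- write artifacts ---
  outs <- list(
    kept_variants.tsv = filt$kept,
    filter_audit.tsv = filt$audit,
    filter_summary.tsv = filt$summary,
    detection_by_exon.tsv = do.call(rbind, lapply(names(detect), function(nm) {
      d <- detect[[nm]]
      cbind(query = nm, rbind(d$by_exon,
                              data.frame(exon = "overall", fraction = d$overall)))
    }))
  )
  if (!is.null(assay))
    outs$dose_response.tsv <- do.call(rbind, lapply(names(assay$curves), function(d)
      cbind(drug = d, assay$curves[[d]])))
  for (nm in names(outs))
    write.table(outs[[nm]], file.path(config$out_dir, nm), sep = "\t",
                quote = FALSE, row.names = FALSE)

  stats_json <- list(
    crlf2_threshold = stats$crlf2$threshold,
    crlf2_n_high = sum(stats$crlf2$labels == "high"),
    mrd_table = as.vector(stats$mrd$table), mrd_p = stats$mrd$p,
    gray_stat = if (is.null(stats$gray)) NA else stats$gray$statistic,
    gray_p = if (is.null(stats$gray)) NA else stats$gray$p)
  jsonlite::write_json(stats_json, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  art <- c(names(outs), "stats.json")
  manifest <- list(
    package = "jakscreen",
    version = as.character(utils::packageVersion("jakscreen")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(vapply(art, function(f)
      unname(tools::md5sum(file.path(config$out_dir, f))), "")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: artifacts in %s", config$out_dir)
  invisible(list(merged = merged, filter = filt, detect = detect,
                 stats = stats, assay = assay, manifest = manifest,
                 fixture_dir = fdir))
}

# canonical, path-free view of the config for hashing
serialize_config <- function(config) {
  list(seed = config$seed, thresholds = config$thresholds,
       mrd_threshold = config$mrd_threshold, percentile = config$percentile,
       detect_vafs = config$detect_vafs, welch = config$welch,
       sim = unclass(config$sim_config))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{run-all}, \code{detect-limit},
#' \code{stats}. Invoked by the \code{inst/cli/jakscreen} script; exposed
#' as a function so it is testable.
#' @param args character vector of command-line arguments
#' @return exit code (0 on success), invisibly
#' @export
jakscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: jakscreen <command> [options]",
    "  run-all      --out DIR [--seed N] [--alt N] [--depth N] [--alpha X]",
    "  simulate     --out DIR [--seed N] [--n N]",
    "  detect-limit --depths depths.tsv --vaf X",
    "  stats        --clinical clinical.tsv", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  if (cmd == "run-all") {
    out <- opt("--out"); if (is.null(out)) { message(usage); return(invisible(1L)) }
    seed <- as.integer(opt("--seed", "20160916"))
    th <- filter_thresholds(
      min_alt = as.integer(opt("--alt", "10")),
      min_depth = as.integer(opt("--depth", "100")),
      alpha = as.numeric(opt("--alpha", "0.05")))
    run_pipeline(pipeline_config(out, seed = seed, thresholds = th))
  } else if (cmd == "simulate") {
    out <- opt("--out"); if (is.null(out)) { message(usage); return(invisible(1L)) }
    seed <- as.integer(opt("--seed", "20160916"))
    n <- as.integer(opt("--n", "461"))
    cfg <- simulation_config(n_samples = n, runs = data.frame(
      run_id = paste0("run", 1:4),
      n_samples = diff(round(seq(0, n, length.out = 5)))), rng_seed = seed)
    bundle <- simulate_cohort(cfg)
    callsets <- emit_caller_callsets(bundle, cfg)
    write_fixture(bundle, callsets, out)
  } else if (cmd == "detect-limit") {
    depths <- read.table(opt("--depths"), header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    v <- as.numeric(opt("--vaf", "0.05"))
    s <- cohort_detection_summary(depths, v)
    out <- rbind(s$by_exon, data.frame(exon = "overall", fraction = s$overall))
    write.table(out, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cmd == "stats") {
    clinical <- read.table(opt("--clinical"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    mrd <- mrd_relapse_association(clinical)
    cat(sprintf("mrd_fisher_p\t%g\n", mrd$p))
    if ("group" %in% names(clinical) && length(unique(clinical$group)) >= 2) {
      gr <- gray_test(clinical$time, clinical$event_type, clinical$group)
      cat(sprintf("gray_stat\t%g\ngray_p\t%g\n", gr$statistic, gr$p))
    }
  } else { message(usage); return(invisible(1L)) }
  invisible(0L)
}
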