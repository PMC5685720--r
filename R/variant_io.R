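#' Caller dialect table
#'
#' The four supported callers (A-D) emulate the tag conventions of
#' freebayes-, varscan-, bcftools- and GATK-style VCFs:
#' \describe{
#'   \item{A}{FORMAT \code{DP} depth, FORMAT \code{AO} per-alt count}
#'   \item{B}{FORMAT \code{DP} depth, FORMAT \code{AD} scalar alt count}
#'   \item{C}{INFO \code{DP4}=ref-fwd,ref-rev,alt-fwd,alt-rev; depth is the
#'     sum, alt reads the last two fields}
#'   \item{D}{FORMAT \code{AD}=ref,alt1[,alt2...] allelic depths, FORMAT
#'     \code{DP} total depth}
#' }
#' @return character vector of known caller ids
#' @export
caller_ids <- function() c("A", "B", "C", "D")

#' Read one caller's VCF into normalized calls
#'
#' Parses a (plain-text) VCF 4.2 file written in one of the known caller
#' dialects, splits multi-allelic records, extracts depth and alt-read
#' counts via the dialect rules, and normalizes each variant against the
#' reference. Records whose counts cannot be extracted are kept with
#' depth 0 / alt 0 and \code{counts_missing = TRUE}.
#'
#' @param path VCF file
#' @param caller one of \code{caller_ids()}
#' @param reference \code{jak_reference} used for normalization
#' @return data.frame: chrom, pos, ref, alt (normalized), caller, depth,
#'   alt_reads, raw_pos, counts_missing
#' @export
read_caller_vcf <- function(path, caller, reference) {
  if (!caller %in% caller_ids())
    stop_config("caller", sprintf("unknown caller dialect '%s'", caller))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), caller = character(), depth = integer(),
                      alt_reads = integer(), raw_pos = integer(),
                      counts_missing = logical(), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  out <- vector("list", length(body))
  lineno <- match(body, lines)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed VCF line %d in %s: expected >= 8 fields, got %d",
                   lineno[i], path, length(f)), call. = FALSE)
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos))
      stop(sprintf("malformed VCF line %d in %s: bad POS '%s'", lineno[i], path, f[2]),
           call. = FALSE)
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    counts <- extract_counts(caller, f, length(alts))
    rows <- lapply(seq_along(alts), function(a) {
      k <- normalize_variant(f[1], pos, f[4], alts[a], reference)
      data.frame(chrom = k$chrom, pos = k$pos, ref = k$ref, alt = k$alt,
                 caller = caller, depth = counts$depth,
                 alt_reads = counts$alt[a], raw_pos = pos,
                 counts_missing = counts$missing, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# depth / alt extraction per dialect; returns list(depth, alt[vector], missing)
extract_counts <- function(caller, fields, n_alt) {
  miss <- list(depth = 0L, alt = rep(0L, n_alt), missing = TRUE)
  get_fmt <- function(tag) {
    if (length(fields) < 10L) return(NA_character_)
    keys <- strsplit(fields[9], ":", fixed = TRUE)[[1]]
    vals <- strsplit(fields[10], ":", fixed = TRUE)[[1]]
    i <- match(tag, keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }
  get_info <- function(tag) {
    kv <- strsplit(fields[8], ";", fixed = TRUE)[[1]]
    hit <- kv[startsWith(kv, paste0(tag, "="))]
    if (length(hit) == 0L) NA_character_ else sub("^[^=]+=", "", hit[1])
  }
  int1 <- function(x) suppressWarnings(as.integer(x))
  ints <- function(x) suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))

  if (caller == "A") {
    dp <- int1(get_fmt("DP")); ao <- ints(get_fmt("AO") %||% NA_character_)
    if (is.na(dp) || anyNA(ao) || length(ao) < n_alt) return(miss)
    list(depth = dp, alt = ao[seq_len(n_alt)], missing = FALSE)
  } else if (caller == "B") {
    dp <- int1(get_fmt("DP")); ad <- int1(get_fmt("AD"))
    if (is.na(dp) || is.na(ad)) return(miss)
    # varscan-style scalar alt count applies to each alt of the record
    list(depth = dp, alt = rep(ad, n_alt), missing = FALSE)
  } else if (caller == "C") {
    dp4 <- ints(get_info("DP4") %||% NA_character_)
    if (anyNA(dp4) || length(dp4) != 4L) return(miss)
    # strand-split counts are not per-allele; total alt support is used
    list(depth = sum(dp4), alt = rep(dp4[3] + dp4[4], n_alt), missing = FALSE)
  } else { # D
    ad <- ints(get_fmt("AD") %||% NA_character_)
    dp <- int1(get_fmt("DP"))
    if (anyNA(ad) || length(ad) < n_alt + 1L) return(miss)
    if (is.na(dp)) dp <- sum(ad)
    list(depth = dp, alt = ad[1L + seq_len(n_alt)], missing = FALSE)
  }
}

#' Write calls as a caller-dialect VCF
#'
#' Inverse of \code{\link{read_caller_vcf}} for fixture generation; emits
#' a minimal valid VCF 4.2 with the caller's depth/alt tag convention.
#'
#' @param calls data.frame with chrom, pos, ref, alt, depth, alt_reads
#' @param caller dialect id
#' @param path output file
#' @param sample_id sample column name
#' @export
write_caller_vcf <- function(calls, caller, path, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=jakscreen-synthetic-caller-%s", caller),
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"ref-fwd,ref-rev,alt-fwd,alt-rev\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alt allele observations\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample_id, sep = "\t"))
  rows <- character(0)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      r <- calls[i, ]
      dd <- as.integer(r$depth); aa <- as.integer(r$alt_reads)
      if (caller == "A") {
        info <- "."; fmt <- "GT:DP:AO"; smp <- sprintf("0/1:%d:%d", dd, aa)
      } else if (caller == "B") {
        info <- "."; fmt <- "GT:DP:AD"; smp <- sprintf("0/1:%d:%d", dd, aa)
      } else if (caller == "C") {
        rf <- dd - aa
        info <- sprintf("DP4=%d,%d,%d,%d", ceiling(rf / 2), floor(rf / 2),
                        ceiling(aa / 2), floor(aa / 2))
        fmt <- "GT"; smp <- "0/1"
      } else {
        info <- "."; fmt <- "GT:AD:DP"; smp <- sprintf("0/1:%d,%d:%d", dd - aa, aa, dd)
      }
      rows <- c(rows, paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                            info, fmt, smp, sep = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read targeted regions from BED
#'
#' BED is 0-based half-open; intervals are sorted and overlapping
#' intervals on one chromosome are merged (labels joined).
#' @param path BED file (3 or 4 columns; column 4 is the exon label)
#' @return data.frame of class \code{jak_regions}: chrom, start, end, label
#' @export
read_regions <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  df <- data.frame(chrom = strip_chr(as.character(raw[[1]])),
                   start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                   label = if (ncol(raw) >= 4L) as.character(raw[[4]])
                           else paste0("region", seq_len(nrow(raw))),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stop("BED format error: start >= end", call. = FALSE)
  df <- df[order(df$chrom, df$start), ]
  merged <- df[0, ]
  for (i in seq_len(nrow(df))) {
    n <- nrow(merged)
    if (n > 0L && merged$chrom[n] == df$chrom[i] && df$start[i] < merged$end[n]) {
      merged$end[n] <- max(merged$end[n], df$end[i])
      merged$label[n] <- paste(merged$label[n], df$label[i], sep = "+")
    } else merged <- rbind(merged, df[i, ])
  }
  rownames(merged) <- NULL
  class(merged) <- c("jak_regions", "data.frame")
  merged
}

#' Test region membership of variant positions
#'
#' A 1-based variant position \code{pos} lies in 0-based half-open
#' \code{[start, end)} iff \code{start < pos <= end}. Indels are judged by
#' their (left-aligned) anchor position.
#' @param key data.frame with chrom, pos (a variant key)
#' @param regions \code{jak_regions}
#' @return logical vector; attribute \code{label} gives the matched region
#' @export
in_region <- function(key, regions) {
  n <- nrow(key)
  hit <- logical(n); lab <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    m <- regions$chrom == key$chrom[i] &
      regions$start < key$pos[i] & key$pos[i] <= regions$end
    hit[i] <- any(m)
    if (hit[i]) lab[i] <- regions$label[which(m)[1]]
  }
  structure(hit, label = lab)
}

#' Merge per-caller calls of one sample into consensus variants
#'
#' Groups calls by normalized variant key and aggregates the per-caller
#' evidence: the consensus depth and alt-read count are the medians across
#' reporting callers (for an even number of callers, the mean of the two
#' central values rounded half up). VAF is the ratio of the aggregated
#' counts. Output rows are sorted by key, so merging is invariant to the
#' input order.
#'
#' @param calls data.frame as from \code{\link{read_caller_vcf}} (one
#'   sample, any number of callers)
#' @param sample_id sample identifier attached to the output
#' @return data.frame: sample_id, chrom, pos, ref, alt, n_callers,
#'   agg_depth, agg_alt, vaf, callers (comma-joined)
#' @export
merge_callers <- function(calls, sample_id) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "n_callers",
            "agg_depth", "agg_alt", "vaf", "callers")
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- data.frame(sample_id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), n_callers = integer(),
                      agg_depth = integer(), agg_alt = integer(), vaf = numeric(),
                      callers = character(), stringsAsFactors = FALSE)
    return(out)
  }
  id <- key_id(calls)
  if (anyDuplicated(paste(calls$caller, id)))
    stop("integrity error: duplicate (caller, variant) pair", call. = FALSE)
  out <- lapply(split(seq_len(nrow(calls)), id), function(ix) {
    g <- calls[ix, ]
    dep <- median_half_up(g$depth)
    alt <- median_half_up(g$alt_reads)
    data.frame(sample_id = sample_id, chrom = g$chrom[1], pos = g$pos[1],
               ref = g$ref[1], alt = g$alt[1], n_callers = length(unique(g$caller)),
               agg_depth = dep, agg_alt = alt,
               vaf = if (dep > 0L) alt / dep else 0,
               callers = paste(sort(unique(g$caller)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$ref, res$alt), cols]
  rownames(res) <- NULL
  res
}
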