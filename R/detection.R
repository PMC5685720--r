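#' Deterministic detectability of a VAF at a given depth
#'
#' A variant is considered detectable when the coverage itself passes the
#' cascade's depth rule (>= 100 reads) and the expected number of
#' variant-supporting reads, \code{vaf * depth}, reaches the alt-read
#' rule (>= 10). At the deepest exon's printed median of 944 reads a 1%
#' variant expects 9.44 alt reads and is therefore not detectable under
#' the pipeline's own thresholds.
#'
#' @param depth read depth (vectorized)
#' @param vaf variant allele fraction in [0,1]
#' @param min_depth,alt_threshold the cascade thresholds
#' @return logical
#' @export
detectable <- function(depth, vaf, min_depth = 100L, alt_threshold = 10L) {
  stopifnot(all(depth >= 0), all(vaf >= 0 & vaf <= 1))
  depth >= min_depth & vaf * depth >= alt_threshold
}

#' Exact binomial detection probability
#'
#' Probability that at least \code{alt_threshold} of \code{depth} reads
#' support a variant present at fraction \code{vaf}, i.e. the exact
#' binomial upper tail; 0 when the depth rule already fails. No normal
#' approximation is used.
#'
#' @inheritParams detectable
#' @return probability in [0,1]
#' @export
detection_probability <- function(depth, vaf, alt_threshold = 10L, min_depth = 100L) {
  stopifnot(all(depth >= 0), all(vaf >= 0 & vaf <= 1))
  p <- pbinom(alt_threshold - 1L, size = depth, prob = vaf, lower.tail = FALSE)
  ifelse(depth < min_depth, 0, p)
}

#' Cohort-wide detectability summary
#'
#' Fraction of sample-exon pairs (and the per-exon breakdown, plus a
#' per-sample all-exons aggregation) where a variant at the given VAF
#' would be detectable.
#'
#' @param depths data.frame with sample_id, exon, depth
#' @param vaf query VAF
#' @param min_depth,alt_threshold cascade thresholds
#' @return list: overall (fraction over sample-exon pairs), by_exon
#'   (data.frame exon, fraction), by_sample_all_exons (fraction of
#'   samples detectable in every exon)
#' @export
cohort_detection_summary <- function(depths, vaf, min_depth = 100L,
                                     alt_threshold = 10L) {
  if (is.null(depths) || nrow(depths) == 0L)
    stop("empty depth table", call. = FALSE)
  det <- detectable(depths$depth, vaf, min_depth, alt_threshold)
  by_exon <- vapply(split(det, depths$exon), mean, 0)
  by_sample <- vapply(split(det, depths$sample_id), all, TRUE)
  list(overall = mean(det),
       by_exon = data.frame(exon = names(by_exon), fraction = unname(by_exon),
                            stringsAsFactors = FALSE),
       by_sample_all_exons = mean(by_sample))
}
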