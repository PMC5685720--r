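#' Classify CRLF2 expression by cohort percentile
#'
#' Samples with probe intensity strictly above the cohort's 90th
#' percentile (type-7 linear-interpolation quantile) are labelled
#' \code{high}; everything else \code{low}.
#'
#' @param intensities numeric vector of probe intensities
#' @param percentile percentile defining "high" (default 90)
#' @param type quantile algorithm (default 7)
#' @return list: labels (factor high/low), threshold
#' @export
classify_crlf2 <- function(intensities, percentile = 90, type = 7) {
  if (length(intensities) == 0L) stop("no intensities supplied", call. = FALSE)
  thr <- unname(quantile(intensities, percentile / 100, type = type, na.rm = TRUE))
  labels <- factor(ifelse(intensities > thr, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, threshold = thr)
}

#' Relative expression by the comparative Ct method
#'
#' \code{2^-(Ct_target - Ct_reference) * 100} percent. Missing Ct values
#' propagate to NA.
#' @param ct_target,ct_reference cycle-threshold values
#' @return percent relative expression
#' @export
relative_expression <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference)) * 100
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed
#' table (probability-ordering definition, with a small relative
#' tolerance for ties).
#'
#' @param a,b,c,d cell counts: rows are exposure (e.g. high/low MRD),
#'   columns outcome (e.g. relapse/remission)
#' @return list: p (two-sided), table
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  list(p = min(1, p), table = matrix(cells, 2, byrow = TRUE))
}

#' MRD / relapse association
#'
#' Cross-tabulates high MRD (level >= 1e-3) against relapse over the
#' records with MRD measurements and returns the two-sided Fisher exact
#' p-value.
#'
#' @param clinical data.frame with columns \code{mrd_level} (fraction or
#'   NA) and \code{relapsed} (logical); or columns \code{mrd_high} and
#'   \code{relapsed}
#' @param mrd_threshold high-MRD cutoff (default 1e-3)
#' @return list: table (2x2: rows high/low MRD, cols relapse/CCR), p, n
#' @export
mrd_relapse_association <- function(clinical, mrd_threshold = 1e-3) {
  if (!"mrd_high" %in% names(clinical)) {
    clinical$mrd_high <- clinical$mrd_level >= mrd_threshold
  }
  keep <- !is.na(clinical$mrd_high) & !is.na(clinical$relapsed)
  cl <- clinical[keep, , drop = FALSE]
  if (nrow(cl) < 2L) stop("fewer than 2 records with MRD data", call. = FALSE)
  a <- sum(cl$mrd_high & cl$relapsed)
  b <- sum(cl$mrd_high & !cl$relapsed)
  c <- sum(!cl$mrd_high & cl$relapsed)
  d <- sum(!cl$mrd_high & !cl$relapsed)
  ft <- fisher_exact_2x2(a, b, c, d)
  dimnames(ft$table) <- list(mrd = c("high", "low"),
                             outcome = c("relapse", "ccr"))
  list(table = ft$table, p = ft$p, n = nrow(cl))
}
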