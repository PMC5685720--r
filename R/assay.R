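#' Normalize well signals to vehicle-control viability
#'
#' Viability is the optical-density signal expressed as a percentage of
#' the mean vehicle-control signal on the same plate. Values are not
#' capped at 100% (cap with \code{cap = TRUE} if desired).
#'
#' @param signal numeric well signals
#' @param vehicle numeric vehicle-control signals (>= 1 well)
#' @param cap cap viability at 100?
#' @return viability percentages
#' @export
normalize_viability <- function(signal, vehicle, cap = FALSE) {
  if (length(vehicle) == 0L) stop("no vehicle wells", call. = FALSE)
  vm <- mean(vehicle)
  if (!is.finite(vm) || vm <= 0) stop("vehicle mean must be > 0", call. = FALSE)
  v <- 100 * signal / vm
  if (cap) pmin(v, 100) else v
}

#' Summarize dose-response over a group of samples
#'
#' Replicate wells are first averaged within each sample (technical
#' replicates), then the group mean and SEM are computed over the
#' sample-level means (biological replication). A concentration measured
#' in a single sample reports n = 1 and SEM NA.
#'
#' @param plates data.frame with sample_id, concentration, viability
#'   (per well, already normalized)
#' @return data.frame: concentration, mean_viability, sem, n
#' @export
summarize_dose_response <- function(plates) {
  stopifnot(all(c("sample_id", "concentration", "viability") %in% names(plates)))
  if (nrow(plates) == 0L)
    return(data.frame(concentration = numeric(), mean_viability = numeric(),
                      sem = numeric(), n = integer()))
  # collapse replicates within sample x concentration
  agg <- aggregate(viability ~ sample_id + concentration, plates, mean)
  out <- do.call(rbind, lapply(split(agg, agg$concentration), function(g) {
    n <- nrow(g)
    data.frame(concentration = g$concentration[1],
               mean_viability = mean(g$viability),
               sem = if (n >= 2L) sd(g$viability) / sqrt(n) else NA_real_,
               n = n)
  }))
  out <- out[order(out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Compare two groups' viabilities at one concentration
#'
#' Two-sided independent-samples t-test on the sample-level mean
#' viabilities (replicates collapsed within sample first). Equal-variance
#' (pooled) by default; \code{welch = TRUE} switches to unequal-variance.
#'
#' @param a,b data.frames with sample_id, concentration, viability
#' @param concentration concentration to compare at
#' @param welch use the Welch form?
#' @return list: t, df, p, mean_a, mean_b, signif ("**" p<0.01, "*" p<0.05,
#'   "" otherwise)
#' @export
compare_groups <- function(a, b, concentration, welch = FALSE) {
  pick <- function(d) {
    d <- d[d$concentration == concentration, , drop = FALSE]
    agg <- aggregate(viability ~ sample_id, d, mean)
    agg$viability
  }
  xa <- pick(a); xb <- pick(b)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need >= 2 samples per group at this concentration", call. = FALSE)
  na <- length(xa); nb <- length(xb)
  if (welch) {
    va <- var(xa) / na; vb <- var(xb) / nb
    t <- (mean(xa) - mean(xb)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2)
    t <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (!is.finite(t)) { t <- 0; p <- 1 } else p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = mean(xa), mean_b = mean(xb),
       signif = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' @importFrom stats aggregate pt
NULL
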