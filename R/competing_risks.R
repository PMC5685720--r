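#' Cumulative incidence under competing risks (Aalen-Johansen)
#'
#' Estimates the cumulative incidence function of each event type from
#' right-censored competing-risks data. At each distinct event time t the
#' incidence of cause k jumps by S(t-) d_k(t) / n(t), where S is the
#' all-cause Kaplan-Meier survivor evaluated just before t and n(t) the
#' number at risk; ties between event types at one time are processed
#' jointly from the same risk set, censoring at the same time is removed
#' after the events. With no competing events CIR(t) reduces exactly to
#' 1 - KM(t).
#'
#' @param time follow-up times (>= 0)
#' @param status event code per subject: 0 censored, 1..K event types
#'   (here 1 = relapse or non-response, 2 = death as competing event)
#' @return object of class \code{jak_cuminc}: data.frame with time,
#'   n_risk, n_event per type, surv (all-cause KM), and one \code{cir_k}
#'   column per event type; plus \code{cir_at(times, type)} lookup via
#'   \code{\link{cuminc_at}}
#' @export
cumulative_incidence <- function(time, status) {
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  stopifnot(length(time) == length(status))
  types <- sort(unique(status[status > 0]))
  if (length(types) == 0L) types <- 1L
  tt <- sort(unique(time[status > 0]))
  n <- length(time)
  surv <- 1
  cir <- setNames(numeric(length(types)), paste0("cir_", types))
  out <- data.frame(time = tt, n_risk = NA_integer_, surv = NA_real_)
  for (k in types) out[[paste0("n_event_", k)]] <- NA_integer_
  for (k in types) out[[paste0("cir_", k)]] <- NA_real_
  for (i in seq_along(tt)) {
    t <- tt[i]
    at_risk <- sum(time >= t)
    d <- vapply(types, function(k) sum(time == t & status == k), 0L)
    if (at_risk > 0L) {
      cir <- cir + surv * d / at_risk
      surv <- surv * (1 - sum(d) / at_risk)
    }
    out$n_risk[i] <- at_risk
    out$surv[i] <- surv
    for (j in seq_along(types)) {
      out[[paste0("n_event_", types[j])]][i] <- d[j]
      out[[paste0("cir_", types[j])]][i] <- cir[j]
    }
  }
  structure(list(est = out, types = types, n = n), class = "jak_cuminc")
}

#' Evaluate a cumulative incidence curve
#' @param fit \code{jak_cuminc} object
#' @param times evaluation times
#' @param type event type (default 1)
#' @return CIF values (right-continuous step function)
#' @export
cuminc_at <- function(fit, times, type = 1) {
  col <- paste0("cir_", type)
  est <- fit$est
  vapply(times, function(t) {
    i <- which(est$time <= t)
    if (length(i) == 0L) 0 else est[[col]][max(i)]
  }, 0)
}

#' Gray's K-sample test for equality of cumulative incidence
#'
#' Tests whether the cause-1 subdistribution hazards are equal across
#' groups (Gray 1988). The score compares, at each cause-1 event time,
#' each group's event count with its share of the weighted risk set
#' R_g(t) = Y_g(t) (1 - F_1g(t-)) / S_g(t-), which keeps subjects with an
#' earlier competing event "at risk" for the subdistribution. The
#' variance estimator accounts for the estimation of those weights via
#' the counting-process decomposition (the B-correction terms below) and
#' for group-specific competing-event hazards. With weight rho = 0 all
#' cause-1 event times contribute equally; rho > 0 downweights late times
#' by (1 - F_1(t-))^rho of the pooled incidence.
#'
#' @param time follow-up times
#' @param status 0 censored, 1 event of interest, 2 competing event
#'   (any positive code other than 1 is treated as competing)
#' @param group group labels (>= 2 groups)
#' @param rho weight exponent (default 0, the standard choice)
#' @return list: statistic, df, p, scores (per-group z), var (covariance
#'   of the first K-1 scores)
#' @export
gray_test <- function(time, status, group, rho = 0) {
  stopifnot(length(time) == length(status), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  group <- factor(group)
  K <- nlevels(group)
  if (K < 2L) stop("need >= 2 groups", call. = FALSE)
  g <- as.integer(group)
  status <- ifelse(status == 1, 1L, ifelse(status > 0, 2L, 0L))

  tt <- sort(unique(time[status > 0]))
  nt <- length(tt)
  if (nt == 0L)
    return(list(statistic = 0, df = K - 1L, p = 1,
                scores = setNames(numeric(K), levels(group)),
                var = matrix(0, K - 1L, K - 1L)))

  # per-group left-continuous S and F1, risk sets, event counts per time
  Y <- matrix(0L, nt, K); d1 <- matrix(0L, nt, K); d2 <- matrix(0L, nt, K)
  Sm <- matrix(1, nt, K)   # S_g(t-)
  F1m <- matrix(0, nt, K)  # F_1g(t-)
  s_run <- rep(1, K); f_run <- rep(0, K)
  # pooled for the rho-weight
  sp_run <- 1; fp_run <- 0; Kw <- numeric(nt)
  for (i in seq_len(nt)) {
    t <- tt[i]
    for (l in seq_len(K)) {
      Y[i, l] <- sum(time >= t & g == l)
      d1[i, l] <- sum(time == t & status == 1L & g == l)
      d2[i, l] <- sum(time == t & status == 2L & g == l)
      Sm[i, l] <- s_run[l]; F1m[i, l] <- f_run[l]
    }
    Kw[i] <- (1 - fp_run)^rho
    yp <- sum(Y[i, ]); dp <- sum(d1[i, ]) + sum(d2[i, ])
    if (yp > 0) {
      fp_run <- fp_run + sp_run * sum(d1[i, ]) / yp
      sp_run <- sp_run * (1 - dp / yp)
    }
    for (l in seq_len(K)) {
      if (Y[i, l] > 0L) {
        f_run[l] <- f_run[l] + s_run[l] * d1[i, l] / Y[i, l]
        s_run[l] <- s_run[l] * (1 - (d1[i, l] + d2[i, l]) / Y[i, l])
      }
    }
  }
  R <- matrix(0, nt, K)
  pos <- Sm > 0 & Y > 0
  R[pos] <- (Y * (1 - F1m) / Sm)[pos]
  Rtot <- rowSums(R)
  d1tot <- rowSums(d1)
  p <- R / pmax(Rtot, .Machine$double.eps)
  p[Rtot == 0, ] <- 0

  # scores
  z <- vapply(seq_len(K), function(j)
    sum(Kw * (d1[, j] - p[, j] * d1tot)), 0)

  # Estimating the weights w_l = (1-F_1l)/S_l perturbs the score; the
  # influence of the martingales of group l on log w_l(t) carries
  # coefficients F_2l(u-)/[(1-F_1l(t-)) Y_l(u)] (cause-1 martingale) and
  # (1-F_1l(u-))/[(1-F_1l(t-)) Y_l(u)] (cause-2 martingale).  Collecting
  # contributions of time u over all later cause-1 event times t gives
  # the reverse cumulative sums C below.
  F2m <- pmax(1 - F1m - Sm, 0)
  Cc <- array(0, c(nt, K, K))
  for (j in seq_len(K)) for (l in seq_len(K)) {
    a <- Kw * p[, j] * ((j == l) - p[, l]) * d1tot /
      ifelse(1 - F1m[, l] > 0, 1 - F1m[, l], Inf)
    cs <- rev(cumsum(rev(a)))
    Cc[, j, l] <- cs - a   # strictly future times only
  }

  V <- matrix(0, K, K)
  for (l in seq_len(K)) {
    invY <- ifelse(Y[, l] > 0, 1 / Y[, l], 0)
    # plug-in <dM_1l> under H0: common subdistribution hazard d1tot/Rtot
    dM1 <- ifelse(Rtot > 0, R[, l] * d1tot / Rtot, 0)
    for (j in seq_len(K)) {
      hj <- Kw * ((j == l) - p[, j]) - Cc[, j, l] * F2m[, l] * invY
      gj <- Cc[, j, l] * (1 - F1m[, l]) * invY
      for (jp in seq_len(j)) {
        hjp <- Kw * ((jp == l) - p[, jp]) - Cc[, jp, l] * F2m[, l] * invY
        gjp <- Cc[, jp, l] * (1 - F1m[, l]) * invY
        v <- sum(hj * hjp * dM1) + sum(gj * gjp * d2[, l])
        V[j, jp] <- V[j, jp] + v
        if (jp != j) V[jp, j] <- V[jp, j] + v
      }
    }
  }

  zr <- z[-K]; Vr <- V[-K, -K, drop = FALSE]
  stat <- tryCatch(drop(t(zr) %*% solve(Vr, zr)), error = function(e) {
    # singular covariance: generalized inverse
    ev <- eigen(Vr, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    if (!any(keep)) return(0)
    drop(t(zr) %*% ev$vectors[, keep, drop = FALSE] %*%
           diag(1 / ev$values[keep], sum(keep)) %*%
           t(ev$vectors[, keep, drop = FALSE]) %*% zr)
  })
  stat <- max(0, stat)
  df <- K - 1L
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       scores = setNames(z, levels(group)), var = Vr)
}
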