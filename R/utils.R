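#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pbinom pchisq dhyper quantile rnbinom rbinom
#'   runif rbeta rexp rnorm sd setNames uniroot var qnbinom plogis
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R rounds half to even; the aggregation rules here round half up,
#' which keeps integer read counts deterministic across platforms.
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Median with half-up integer rounding for even counts
#' @param x integer vector
#' @return integer scalar
#' @keywords internal
median_half_up <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 0L) return(NA_integer_)
  if (n %% 2L == 1L) as.integer(s[(n + 1L) / 2L])
  else round_half_up((s[n / 2L] + s[n / 2L + 1L]) / 2)
}

#' Derive a child seed from a master seed
#'
#' Splits one RNG stream hierarchically (per sample, per caller, per stage)
#' so simulation output does not depend on iteration order. Plain integer
#' mixing modulo a Mersenne prime; stays below 2^31.
#' @param seed master seed (integer)
#' @param ... integer or character labels identifying the child stream
#' @return integer seed in [1, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (part in list(...)) {
    if (is.character(part)) part <- utf8ToInt(paste(part, collapse = "/"))
    for (v in as.double(part)) {
      h <- (h * 48271 + (v %% m) + 11) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed}, pinning the generator kind so
#' results are stable across R versions.
#' @param seed integer seed
#' @param expr expression
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}
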