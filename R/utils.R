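#' Convert volume backscattering strength between dB and linear domains
#'
#' Acoustic convention: Sv values are averaged in the linear domain
#' (`10^(Sv/10)`) and converted back to dB, never averaged as decibels.
#'
#' @param sv_db Numeric vector of Sv in dB.
#' @return Linear-domain backscatter.
#' @export
db_to_linear <- function(sv_db) 10^(sv_db / 10)

#' @rdname db_to_linear
#' @param sv_linear Numeric vector of linear-domain backscatter.
#' @export
linear_to_db <- function(sv_linear) 10 * log10(sv_linear)

#' Mean of Sv values taken in the linear domain
#'
#' @param sv_db Sv values in dB.
#' @param na.rm Drop missing values.
#' @return Mean Sv in dB. Never exceeds `max(sv_db)`.
#' @export
mean_sv_db <- function(sv_db, na.rm = FALSE) {
  linear_to_db(mean(db_to_linear(sv_db), na.rm = na.rm))
}

#' Derive a stage seed from a root seed
#'
#' One root seed drives the whole pipeline; per-stage seeds are derived
#' deterministically so stages can be rerun in isolation. Results stay
#' below 2^31 so they remain valid R integers.
#'
#' @param seed Root integer seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample from a truncated normal by rejection
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Sample from a truncated lognormal by rejection
#' @noRd
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  out <- rlnorm(n, meanlog, sdlog)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in %s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
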