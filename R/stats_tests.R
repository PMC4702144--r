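#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of ECDF differences evaluated at all pooled
#' data points (so ties are handled exactly). `alternative = "greater"` uses
#' the signed supremum `max(F_x - F_y)` (the ECDF of `x` lies above that of
#' `y`), matching the usual convention. P-values are asymptotic.
#'
#' @param x,y Numeric samples, at least 3 values each.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return List of class `pf_test`: statistic `D`, `p_value`, `alternative`,
#'   sample sizes.
#' @export
ks_two_sample <- function(x, y,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("input error: need at least 3 values per sample", call. = FALSE)
  }
  n <- length(x); m <- length(y)
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  diffs <- fx - fy
  D <- switch(alternative,
              two_sided = max(abs(diffs)),
              greater = max(diffs),
              less = max(-diffs))
  D <- max(D, 0)
  t_stat <- sqrt(n * m / (n + m)) * D
  p <- if (alternative == "two_sided") {
    if (t_stat == 0) 1 else {
      j <- 1:100
      min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t_stat^2))))
    }
  } else {
    exp(-2 * t_stat^2)
  }
  structure(list(statistic = D, p_value = p, alternative = alternative,
                 n_x = n, n_y = m, method = "ks"), class = "pf_test")
}

#' Mann-Whitney U test
#'
#' Exact permutation p-value (which handles ties correctly) when the pooled
#' sample size is small; otherwise the tie-corrected normal approximation
#' with continuity correction. The reported U counts pairs where `x` exceeds
#' `y` (ties count one half), so complete separation with `x` above `y`
#' gives `U = n_x * n_y`.
#'
#' @param x,y Numeric samples, at least 3 values each.
#' @param exact_limit Use exact enumeration when `n_x + n_y` is at most this.
#' @return List of class `pf_test`: `statistic` (U), `z`, `p_value`, sizes.
#' @export
mann_whitney <- function(x, y, exact_limit = 18L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 3L || m < 3L) {
    stop("input error: need at least 3 values per sample", call. = FALSE)
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else if (N <= exact_limit) {
    idx <- utils::combn(N, n)
    rs <- matrix(r[idx], nrow = n)
    U_all <- colSums(rs) - n * (n + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  } else {
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = U, z = z, p_value = min(1, p),
                 alternative = "two_sided", n_x = n, n_y = m,
                 method = "mann_whitney"), class = "pf_test")
}

#' @export
print.pf_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, z = %s, p = %.4g (%s; n = %d, %d)\n",
              x$method, x$statistic,
              if (is.null(x$z)) "-" else sprintf("%.3f", x$z),
              x$p_value, x$alternative, x$n_x, x$n_y))
  invisible(x)
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimators: `ICC = sigma2_between / (sigma2_between + sigma2_within)`
#' with the between component from `(MSB - MSW) / n0` and negative estimates
#' truncated to zero.
#'
#' @param values Numeric vector.
#' @param cluster Cluster id per value.
#' @return ICC in `[0, 1]`.
#' @export
icc_oneway <- function(values, cluster) {
  ok <- is.finite(values) & !is.na(cluster)
  values <- values[ok]; cluster <- as.character(cluster[ok])
  k <- length(unique(cluster))
  if (k < 2L) stop("undefined result: need at least 2 clusters", call. = FALSE)
  N <- length(values)
  means <- tapply(values, cluster, mean)
  ns <- tapply(values, cluster, length)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ns^2) / N) / (k - 1)
  sb <- max(0, (msb - msw) / n0)
  if (sb + msw <= 0) return(0)
  sb / (sb + msw)
}

#' Depth-distribution comparison with the ICC gate
#'
#' Computes the intraclass correlation of the values over the clustering
#' variable; when it is below the cutoff (default 30%) clustering is ignored
#' and a two-sample K-S test compares the two groups, otherwise a linear
#' mixed model with a random intercept for the cluster is fit.
#'
#' @param values Numeric response.
#' @param group Two-level grouping factor.
#' @param cluster Cluster id (e.g. individual or day).
#' @param icc_cutoff Gate threshold on the ICC.
#' @return List: `icc`, `method` ("ks" or "lmm"), and the test/model result.
#' @export
gated_comparison <- function(values, group, cluster, icc_cutoff = 0.30) {
  stopifnot(length(unique(group)) == 2L)
  icc <- tryCatch(icc_oneway(values, cluster), error = function(e) 0)
  lv <- sort(unique(as.character(group)))
  if (icc < icc_cutoff) {
    res <- ks_two_sample(values[group == lv[1]], values[group == lv[2]])
    list(icc = icc, method = "ks", result = res)
  } else {
    dat <- data.frame(value = values, group = factor(group),
                      cluster = factor(cluster))
    fit <- fit_mixed("value ~ group + (1|cluster)", dat, family = "gaussian")
    list(icc = icc, method = "lmm", result = fit)
  }
}
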