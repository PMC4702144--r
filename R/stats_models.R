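#' Standardize predictor columns
#'
#' Centres and scales to unit SD; the transform parameters are stored for
#' reporting. Zero-SD columns are dropped with a warning.
#'
#' @param data Data frame.
#' @param cols Columns to standardize (default: all numeric).
#' @return List: `data`, `centers`, `scales`, `dropped`.
#' @export
standardize_predictors <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  centers <- scales <- stats::setNames(numeric(0), character(0))
  dropped <- character(0)
  for (cl in cols) {
    s <- stats::sd(data[[cl]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("constant column '%s' dropped from standardization", cl))
      data[[cl]] <- NULL
      dropped <- c(dropped, cl)
      next
    }
    m <- mean(data[[cl]], na.rm = TRUE)
    data[[cl]] <- (data[[cl]] - m) / s
    centers[cl] <- m; scales[cl] <- s
  }
  list(data = data, centers = centers, scales = scales, dropped = dropped)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on the others;
#' values below 4 are conventionally read as no multicollinearity. Perfect
#' collinearity reports `Inf`.
#'
#' @param data Data frame of numeric predictors (at least two columns, more
#'   rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(data) {
  data <- data[vapply(data, is.numeric, logical(1))]
  p <- ncol(data)
  if (p < 2L) stop("input error: need at least 2 predictors", call. = FALSE)
  if (nrow(data) <= p) stop("input error: need n > p", call. = FALSE)
  out <- stats::setNames(numeric(p), names(data))
  for (j in seq_len(p)) {
    fit <- stats::lm(data[[j]] ~ ., data = data[-j])
    r2 <- summary(fit)$r.squared
    out[j] <- if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  out
}

#' Fit a (generalized) linear mixed model from a formula string
#'
#' Formulas use the lme4 grammar, e.g. `y ~ x1 + x2 + (1|group)`. Gaussian
#' responses are fit by maximum likelihood (`REML = FALSE`) with
#' Satterthwaite-approximated p-values; binomial responses use the Laplace ML
#' approximation. Formulas without a random term fall back to `lm`/`glm`.
#' Optional response transforms (`"sqrt"`, `"log10"`) and predictor
#' z-standardization are applied before fitting.
#'
#' @param formula Model formula (string or formula).
#' @param data Data frame.
#' @param family `"gaussian"` or `"binomial"`.
#' @param response_transform `NULL`, `"sqrt"` or `"log10"`.
#' @param standardize Standardize numeric fixed-effect predictors first.
#' @return List of class `model_fit`: `formula`, `family`, `coefficients`
#'   (estimate, se, stat, p), `aic`, `re_variance`, `converged`, `model`,
#'   `n`.
#' @export
fit_mixed <- function(formula, data, family = c("gaussian", "binomial"),
                      response_transform = NULL, standardize = FALSE) {
  family <- match.arg(family)
  f <- stats::as.formula(formula)
  resp <- all.vars(f)[1]
  if (!is.null(response_transform)) {
    data[[resp]] <- switch(response_transform,
                           sqrt = sqrt(data[[resp]]),
                           log10 = log10(data[[resp]]),
                           stop("unknown response transform"))
  }
  bars <- lme4::findbars(f)
  has_random <- length(bars) > 0L
  if (standardize) {
    grp_vars <- unlist(lapply(bars, function(b) all.vars(b[[3]])))
    pred <- setdiff(all.vars(f), c(resp, grp_vars))
    pred <- pred[pred %in% names(data)]
    pred <- pred[vapply(data[pred], is.numeric, logical(1))]
    if (length(pred) > 0L) {
      data <- standardize_predictors(data, pred)$data
    }
  }
  if (family == "binomial" && !all(data[[resp]] %in% c(0, 1, NA))) {
    stop("input error: binomial responses must be 0/1", call. = FALSE)
  }

  converged <- TRUE
  if (has_random && family == "gaussian") {
    fit <- suppressMessages(lmerTest::lmer(f, data = data, REML = FALSE))
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("fail", msgs, ignore.case = TRUE))
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], stat = sm[, "t value"],
                        p = sm[, "Pr(>|t|)"], row.names = NULL,
                        stringsAsFactors = FALSE)
    re_var <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
  } else if (has_random) {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(f, data = data, family = stats::binomial())))
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("fail", msgs, ignore.case = TRUE))
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], stat = sm[, "z value"],
                        p = sm[, "Pr(>|z|)"], row.names = NULL,
                        stringsAsFactors = FALSE)
    re_var <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
  } else {
    fit <- if (family == "gaussian") stats::lm(f, data = data) else
      stats::glm(f, data = data, family = stats::binomial())
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], stat = sm[, 3], p = sm[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
    re_var <- 0
  }
  structure(list(formula = deparse(f), family = family,
                 coefficients = coefs,
                 aic = stats::AIC(fit), re_variance = re_var,
                 converged = converged, model = fit,
                 n = stats::nobs(fit)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s (%s), AIC %.1f, RE var %.3g%s\n", x$formula,
              x$family, x$aic, x$re_variance,
              if (x$converged) "" else " [not converged]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fit and rank a candidate model set by AIC
#'
#' Every candidate shares the response and data; non-converging fits are
#' excluded with a message. Models within 2 AIC units of the best
#' (strictly `delta_aic < 2`) are flagged as having substantial support.
#'
#' @param candidates Character vector of formulas.
#' @param data Data frame.
#' @param family Passed to [fit_mixed()].
#' @param ... Passed to [fit_mixed()].
#' @return List of class `model_set`: `table` (formula, aic, delta_aic,
#'   support), `fits`.
#' @export
model_set <- function(candidates, data, family = "gaussian", ...) {
  fits <- lapply(candidates, function(fm) {
    tryCatch(fit_mixed(fm, data, family = family, ...),
             error = function(e) NULL)
  })
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (!all(ok)) {
    message(sprintf("%d candidate(s) failed or did not converge; excluded",
                    sum(!ok)))
  }
  if (!any(ok)) stop("pipeline error: all candidate models failed", call. = FALSE)
  aic <- vapply(fits[ok], `[[`, numeric(1), "aic")
  delta <- aic - min(aic)
  tab <- data.frame(formula = candidates[ok], aic = aic, delta_aic = delta,
                    support = delta < 2, stringsAsFactors = FALSE)
  tab <- tab[order(tab$delta_aic), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ok]), class = "model_set")
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from average ranks (equivalent to the
#' Mann-Whitney statistic scaled by the number of pairs); invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 observed labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa from predictions and observations
#'
#' @param pred,obs 0/1 vectors.
#' @return Kappa (chance-corrected agreement).
#' @export
cohen_kappa <- function(pred, obs) {
  po <- mean(pred == obs)
  pe <- mean(pred == 1) * mean(obs == 1) + mean(pred == 0) * mean(obs == 0)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Repeated stratified k-fold cross-validation of a presence model
#'
#' Folds are stratified by the binary response. Within each repeat the
#' out-of-fold predicted probabilities are pooled, then kappa, percent
#' correctly classified, sensitivity and specificity are computed at the
#' threshold and AUC by rank statistic. Mixed-model predictions are
#' population-level (random effects set to zero). Reported as mean and SD
#' over repeats.
#'
#' @param formula Model formula (string), binomial response.
#' @param data Data frame.
#' @param folds,repeats Fold count and repeat count.
#' @param threshold Probability threshold for the confusion matrix.
#' @param seed Optional seed for the fold draws.
#' @return List of class `cv_report`: `per_repeat` data frame and
#'   `summary` (mean/sd per metric), `threshold`.
#' @export
cross_validate <- function(formula, data, folds = 10, repeats = 10,
                           threshold = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- stats::as.formula(formula)
  resp <- all.vars(f)[1]
  y <- data[[resp]]
  if (!all(y %in% c(0, 1))) stop("input error: response must be 0/1", call. = FALSE)
  if (sum(y == 1) < folds || sum(y == 0) < folds) {
    stop("input error: need at least `folds` cases of each class", call. = FALSE)
  }
  has_random <- length(lme4::findbars(f)) > 0L
  n <- nrow(data)
  per <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    # stratified fold assignment; redrawn if a training fold is single-class
    for (attempt in 1:10) {
      fold <- integer(n)
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      ok <- all(vapply(seq_len(folds), function(k) {
        length(unique(y[fold != k])) == 2L
      }, logical(1)))
      if (ok) break
      message("single-class fold encountered; refolding")
    }
    prob <- rep(NA_real_, n)
    for (k in seq_len(folds)) {
      train <- data[fold != k, , drop = FALSE]
      test <- data[fold == k, , drop = FALSE]
      fit <- fit_mixed(formula, train, family = "binomial")
      prob[fold == k] <- if (has_random) {
        stats::predict(fit$model, newdata = test, type = "response",
                       re.form = NA, allow.new.levels = TRUE)
      } else {
        stats::predict(fit$model, newdata = test, type = "response")
      }
    }
    pred <- as.integer(prob >= threshold)
    tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
    fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
    per[[rep_i]] <- data.frame(
      repeat_i = rep_i,
      kappa = cohen_kappa(pred, y),
      auc = auc_rank(prob, y),
      pcc = 100 * (tp + tn) / n,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  }
  per <- do.call(rbind, per)
  metrics <- c("kappa", "auc", "pcc", "sensitivity", "specificity")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(per_repeat = per, summary = summ, threshold = threshold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> threshold %.2f, %d repeats\n", x$threshold,
              nrow(x$per_repeat)))
  print(x$summary, digits = 3)
  invisible(x)
}
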