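#' Enumerate all candidate model formulas
#'
#' Candidate models are all non-empty subsets of the linear and quadratic
#' terms of the predictors: with 6 principal components there are
#' 2^12 - 1 = 4095 candidates. Order is deterministic (increasing bitmask
#' over the terms, linear terms first).
#'
#' @param n_vars number of predictor variables (>= 1).
#' @param names predictor names (default `PC1`, `PC2`, ...).
#' @return list of character vectors of term labels, e.g.
#'   `c("PC1", "I(PC1^2)")`.
#' @export
enumerate_formulas <- function(n_vars, names = paste0("PC", seq_len(n_vars))) {
  if (n_vars < 1) stop("n_vars must be >= 1")
  stopifnot(length(names) == n_vars)
  terms <- c(names, sprintf("I(%s^2)", names))
  nt <- length(terms)
  bits <- 2^(seq_len(nt) - 1)
  lapply(seq_len(2^nt - 1), function(mask) {
    terms[bitwAnd(mask, bits) > 0]
  })
}

# full design matrix: intercept, linear and quadratic columns for all
# predictors; candidate models select columns from it
term_matrix <- function(data, predictors) {
  X <- matrix(1, nrow(data), 1 + 2 * length(predictors))
  colnames(X) <- c("(Intercept)", predictors,
                   sprintf("I(%s^2)", predictors))
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop("predictor column missing: ", p)
    X[, p] <- v
    X[, sprintf("I(%s^2)", p)] <- v^2
  }
  X
}

clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# binomial GLM via stats::glm.fit on a precomputed design matrix
fit_logistic_mat <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  mu <- clamp_p(fit$fitted.values)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  k <- ncol(X)
  separated <- max(abs(mu - y)) < 1e-6
  w <- fit$fitted.values * (1 - fit$fitted.values)
  se <- tryCatch(sqrt(diag(solve(crossprod(X * sqrt(w))))),
                 error = function(e) rep(NA_real_, k))
  names(se) <- colnames(X)
  list(coefficients = beta, se = se, log_likelihood = ll,
       aic = 2 * k - 2 * ll,
       converged = isTRUE(fit$converged) && !anyNA(beta) && !separated)
}

#' Fit one candidate logistic model
#'
#' Binomial GLM with logit link; AIC is `2k - 2*logLik` with k counting the
#' intercept. Complete separation (a perfect fit) and aliased coefficients
#' are flagged as non-converged and excluded from selection downstream.
#'
#' @param terms character vector of term labels as from
#'   [enumerate_formulas()].
#' @param data data.frame with the predictor columns and a logical/0-1
#'   response.
#' @param response response column name.
#' @return object of class `fitted_logistic`: `terms`, named
#'   `coefficients` (including `(Intercept)`), `log_likelihood`, `aic`,
#'   `converged`.
#' @export
fit_logistic <- function(terms, data, response = "detected") {
  y <- as.numeric(data[[response]])
  stopifnot(all(y %in% 0:1))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one presence and one absence")
  predictors <- unique(gsub("^I\\((.*)\\^2\\)$", "\\1", terms))
  X <- term_matrix(data, predictors)[, c("(Intercept)", terms), drop = FALSE]
  out <- fit_logistic_mat(X, y)
  out$terms <- terms
  class(out) <- "fitted_logistic"
  out
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat("logistic model:", paste(x$terms, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.3f, AIC %.2f%s\n", x$log_likelihood, x$aic,
              if (x$converged) "" else " (non-converged)"))
  invisible(x)
}

#' @rdname fit_logistic
#' @param object a `fitted_logistic`.
#' @param newdata data.frame of predictor values.
#' @param ... unused.
#' @return `predict.fitted_logistic()` returns fitted probabilities.
#' @export
predict.fitted_logistic <- function(object, newdata, ...) {
  predictors <- unique(gsub("^I\\((.*)\\^2\\)$", "\\1", object$terms))
  X <- term_matrix(newdata, predictors)[, names(object$coefficients),
                                        drop = FALSE]
  beta <- object$coefficients
  beta[is.na(beta)] <- 0
  stats::plogis(drop(X %*% beta))
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen presence outscores a randomly chosen
#' absence, ties counted one half (Mann-Whitney formulation).
#'
#' @param scores numeric predictions.
#' @param labels logical (TRUE = presence) or 0/1.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("AUC undefined: one class only")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification threshold and confusion metrics
#'
#' `select_threshold()` returns the cutoff maximizing TSS (sensitivity +
#' specificity - 1) over the midpoints between consecutive sorted unique
#' predictions, ties broken toward the lowest such threshold. A score at or
#' above the threshold is a predicted presence.
#'
#' @param predictions numeric scores.
#' @param labels logical or 0/1 observed classes (both present).
#' @param threshold cutoff for `confusion_metrics()`.
#' @return `select_threshold()`: the threshold; `confusion_metrics()`: list
#'   `sensitivity`, `specificity`, `tss`.
#' @export
select_threshold <- function(predictions, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("threshold undefined: one class only")
  ord <- order(predictions)
  ps <- predictions[ord]
  ls <- labels[ord]
  n <- length(ps)
  cpos <- cumsum(ls)
  cneg <- cumsum(!ls)
  # cut after position i: predicted presence = scores > ps[i]
  i <- which(ps[-n] < ps[-1])
  if (length(i) == 0) return(ps[1])
  thr <- (ps[i] + ps[i + 1]) / 2
  tss <- (npos - cpos[i]) / npos + cneg[i] / nneg - 1
  thr[which.max(tss)]
}

#' @rdname select_threshold
#' @export
confusion_metrics <- function(predictions, labels, threshold) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("metrics undefined: one class only")
  pp <- predictions >= threshold
  sensitivity <- mean(pp[labels])
  specificity <- mean(!pp[!labels])
  list(sensitivity = sensitivity, specificity = specificity,
       tss = sensitivity + specificity - 1)
}

# class-stratified fold assignment; redraws if a training split would lose
# a class entirely
stratified_folds <- function(y, k, seed) {
  y <- as.logical(y)
  n <- length(y)
  set.seed(seed)
  for (try in 1:100) {
    fold <- integer(n)
    fold[y] <- sample(rep_len(seq_len(k), sum(y)))
    fold[!y] <- sample(rep_len(seq_len(k), sum(!y)))
    ok <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      any(y[tr]) && any(!y[tr])
    }, logical(1))
    if (all(ok)) return(fold)
  }
  stop("cannot build stratified folds with both classes in every training split")
}

#' k-fold cross-validated performance of a candidate model
#'
#' Folds are class-stratified with a recorded seed. For each fold the model
#' is refitted on the remaining folds, the held-out records are scored, and
#' AUC plus sensitivity/specificity/TSS at the training-data maxTSS
#' threshold are computed. Reported metrics are fold means; the reported
#' `threshold` is the maxTSS threshold of the full-data fit. Folds whose
#' held-out part contains a single class contribute no fold-level metrics;
#' if no fold has both classes (e.g. leave-one-out), metrics are computed
#' once on the pooled held-out predictions, with the full-data threshold.
#'
#' @inheritParams fit_logistic
#' @param k number of folds (default 10).
#' @param seed seed for the fold draw.
#' @param folds optional precomputed fold assignment (overrides `k`/`seed`).
#' @return object of class `cv_metrics`: `auc`, `sensitivity`,
#'   `specificity`, `tss`, `threshold`, `k`, `seed`, `folds_used`.
#' @export
kfold_evaluate <- function(terms, data, k = 10, seed = 1,
                           response = "detected", folds = NULL) {
  y <- as.numeric(data[[response]])
  predictors <- unique(gsub("^I\\((.*)\\^2\\)$", "\\1", terms))
  X <- term_matrix(data, predictors)[, c("(Intercept)", terms), drop = FALSE]
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  k <- max(folds)
  full <- fit_logistic_mat(X, y)
  beta_full <- full$coefficients
  beta_full[is.na(beta_full)] <- 0
  thr_full <- select_threshold(stats::plogis(drop(X %*% beta_full)), y)
  aucs <- sens <- spec <- tsss <- numeric(0)
  pooled_pred <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_logistic_mat(X[tr, , drop = FALSE], y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    p_tr <- stats::plogis(drop(X[tr, , drop = FALSE] %*% beta))
    p_te <- stats::plogis(drop(X[!tr, , drop = FALSE] %*% beta))
    pooled_pred[!tr] <- p_te
    y_te <- y[!tr]
    if (any(y_te == 1) && any(y_te == 0)) {
      thr <- select_threshold(p_tr, y[tr])
      cm <- confusion_metrics(p_te, y_te, thr)
      aucs <- c(aucs, auc_rank(p_te, y_te))
      sens <- c(sens, cm$sensitivity)
      spec <- c(spec, cm$specificity)
      tsss <- c(tsss, cm$tss)
    }
  }
  if (length(aucs) == 0) {
    cm <- confusion_metrics(pooled_pred, y, thr_full)
    out <- list(auc = auc_rank(pooled_pred, y), sensitivity = cm$sensitivity,
                specificity = cm$specificity, tss = cm$tss,
                threshold = thr_full, k = k, seed = seed, folds_used = 0L)
  } else {
    out <- list(auc = mean(aucs), sensitivity = mean(sens),
                specificity = mean(spec), tss = mean(tsss),
                threshold = thr_full, k = k, seed = seed,
                folds_used = length(aucs))
  }
  class(out) <- "cv_metrics"
  out
}

#' Akaike weights
#'
#' @param delta_aics numeric vector of AIC differences from the minimum.
#' @return weights `exp(-delta/2) / sum(exp(-delta/2))`, summing to 1.
#' @export
akaike_weights <- function(delta_aics) {
  stopifnot(all(is.finite(delta_aics)))
  w <- exp(-delta_aics / 2)
  w / sum(w)
}

#' Four-filter model selection cascade
#'
#' Sequentially retains candidates that (1) converged with all quadratic
#' coefficients strictly negative (unimodal responses; models with no
#' quadratic term pass vacuously), (2) have cross-validated AUC >=
#' `auc_min`, (3) cross-validated TSS >= `tss_min`, and (4) lie within
#' `delta_aic_max` AIC units of the minimum AIC among the survivors of
#' filters 1-3. Akaike weights are renormalized over the final set.
#'
#' @param candidates list of `list(fit = fitted_logistic, cv = cv_metrics)`.
#' @param auc_min,tss_min,delta_aic_max filter thresholds (defaults 0.5,
#'   0.4, 2).
#' @return object of class `model_selection`: indices of `selected`
#'   candidates (ordered by delta-AIC, then formula string), their
#'   `delta_aic` and `weights`, the `filter_counts` vector, and the full
#'   candidate `table`.
#' @export
filter_models <- function(candidates, auc_min = 0.5, tss_min = 0.4,
                          delta_aic_max = 2) {
  stopifnot(length(candidates) >= 1)
  tab <- data.frame(
    id = seq_along(candidates),
    predictors = vapply(candidates, function(c) paste(c$fit$terms,
                                                      collapse = ", "),
                        character(1)),
    threshold = vapply(candidates, function(c) c$cv$threshold, numeric(1)),
    auc = vapply(candidates, function(c) c$cv$auc, numeric(1)),
    sensitivity = vapply(candidates, function(c) c$cv$sensitivity, numeric(1)),
    specificity = vapply(candidates, function(c) c$cv$specificity, numeric(1)),
    tss = vapply(candidates, function(c) c$cv$tss, numeric(1)),
    aic = vapply(candidates, function(c) c$fit$aic, numeric(1)),
    converged = vapply(candidates, function(c) c$fit$converged, logical(1)))
  unimodal <- vapply(candidates, function(c) {
    quad <- c$fit$coefficients[grep("^I\\(.*\\^2\\)$", names(c$fit$coefficients))]
    c$fit$converged && (length(quad) == 0 || all(quad < 0))
  }, logical(1))
  pass2 <- unimodal & tab$auc >= auc_min
  pass3 <- pass2 & tab$tss >= tss_min
  if (!any(pass3)) stop("no admissible model: all candidates filtered out")
  aic_min <- min(tab$aic[pass3])
  delta <- tab$aic - aic_min
  pass4 <- pass3 & delta <= delta_aic_max
  sel <- which(pass4)
  sel <- sel[order(delta[sel], tab$predictors[sel])]
  tab$delta_aic <- delta
  tab$weight <- NA_real_
  tab$weight[sel] <- akaike_weights(delta[sel])
  tab$selected <- seq_len(nrow(tab)) %in% sel
  structure(list(
    selected = sel, delta_aic = delta[sel], weights = tab$weight[sel],
    filter_counts = c(candidates = length(candidates),
                      unimodal = sum(unimodal), auc = sum(pass2),
                      tss = sum(pass3), delta_aic = length(sel)),
    table = tab,
    thresholds = c(auc_min = auc_min, tss_min = tss_min,
                   delta_aic_max = delta_aic_max)),
    class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model selection:",
      paste(sprintf("%s=%d", names(x$filter_counts), x$filter_counts),
            collapse = " -> "), "\n")
  invisible(x)
}
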