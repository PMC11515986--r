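#' Calibrate a presence-absence ensemble niche model
#'
#' The central fitting function of the package. All non-empty combinations
#' of linear and quadratic responses of the predictors (4095 candidates for
#' 6 principal components) are fitted as binomial GLMs on the full data,
#' evaluated by class-stratified k-fold cross-validation (AUC and maxTSS
#' sensitivity/specificity/TSS), and passed through the four-filter
#' selection cascade of [filter_models()]. The surviving models form an
#' Akaike-weight ensemble whose consensus prediction is the weighted mean
#' of member probabilities.
#'
#' @param data annotated record data.frame (see [extract_at_records()])
#'   containing the predictor columns and a logical/0-1 response.
#' @param predictors predictor column names (default `PC1`..`PC6`).
#' @param response response column name.
#' @param k cross-validation folds (default 10). One stratified fold
#'   assignment, drawn from `seed`, is shared by all candidates.
#' @param seed master seed for fold assignment.
#' @param auc_min,tss_min,delta_aic_max selection thresholds (defaults 0.5,
#'   0.4, 2).
#' @param verbose print filter survivor counts.
#' @return an object of class `enm_ensemble` with components `models`
#'   (selected `fitted_logistic` objects), `weights`, `delta_aic`,
#'   `selection` (the full [filter_models()] result), `calibration`
#'   (per-predictor mean/sd/min/max of the training data plus class
#'   counts), and the call. Methods: [print()], [summary()], [coef()],
#'   [predict.enm_ensemble()], [plot.enm_ensemble()],
#'   [residuals.enm_ensemble()].
#' @seealso [response_curve()], [variable_contribution()],
#'   [predict_weekly()]
#' @export
enm_calibrate <- function(data, predictors = paste0("PC", 1:6),
                          response = "detected", k = 10, seed = 1,
                          auc_min = 0.5, tss_min = 0.4, delta_aic_max = 2,
                          verbose = FALSE) {
  y <- as.numeric(data[[response]])
  stopifnot(all(y %in% 0:1))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one presence and one absence")
  formulas <- enumerate_formulas(length(predictors), predictors)
  Xfull <- term_matrix(data, predictors)
  folds <- stratified_folds(y, k, seed)
  candidates <- vector("list", length(formulas))
  for (i in seq_along(formulas)) {
    terms <- formulas[[i]]
    cols <- c("(Intercept)", terms)
    fit <- fit_logistic_mat(Xfull[, cols, drop = FALSE], y)
    fit$terms <- terms
    class(fit) <- "fitted_logistic"
    cv <- kfold_evaluate(terms, data, response = response, folds = folds,
                         seed = seed)
    candidates[[i]] <- list(fit = fit, cv = cv)
  }
  selection <- filter_models(candidates, auc_min = auc_min,
                             tss_min = tss_min, delta_aic_max = delta_aic_max)
  if (verbose)
    message("candidate filtering: ",
            paste(sprintf("%s=%d", names(selection$filter_counts),
                          selection$filter_counts), collapse = " -> "))
  pm <- as.matrix(data[, predictors, drop = FALSE])
  calibration <- list(
    predictors = predictors, response = response,
    mean = colMeans(pm), sd = apply(pm, 2, stats::sd),
    min = apply(pm, 2, min), max = apply(pm, 2, max),
    n = length(y), n_presence = sum(y))
  structure(list(
    models = lapply(selection$selected, function(i) candidates[[i]]$fit),
    metrics = lapply(selection$selected, function(i) candidates[[i]]$cv),
    weights = selection$weights, delta_aic = selection$delta_aic,
    selection = selection, calibration = calibration,
    k = k, seed = seed, call = match.call()),
    class = "enm_ensemble")
}

#' @export
print.enm_ensemble <- function(x, ...) {
  fc <- x$selection$filter_counts
  cat("Presence-absence ensemble niche model\n")
  cat(sprintf("  calibration data: %d records (%d presences, %d absences)\n",
              x$calibration$n, x$calibration$n_presence,
              x$calibration$n - x$calibration$n_presence))
  cat("  candidate filtering:",
      paste(sprintf("%s=%d", names(fc), fc), collapse = " -> "), "\n")
  cat(sprintf("  ensemble: %d models, Akaike weights in [%.3f, %.3f] (sum %.3f)\n",
              length(x$models), min(x$weights), max(x$weights),
              sum(x$weights)))
  invisible(x)
}

#' @export
summary.enm_ensemble <- function(object, ...) {
  tab <- object$selection$table
  sel <- tab[tab$selected, c("id", "predictors", "threshold", "auc",
                             "sensitivity", "specificity", "tss", "aic",
                             "delta_aic", "weight")]
  sel <- sel[order(sel$delta_aic), ]
  rownames(sel) <- NULL
  structure(list(selected = sel,
                 filter_counts = object$selection$filter_counts,
                 calibration = object$calibration),
            class = "summary.enm_ensemble")
}

#' @export
print.summary.enm_ensemble <- function(x, ...) {
  cat("Selected models (ordered by delta-AIC):\n")
  out <- x$selected
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 3)
  print(out, row.names = FALSE)
  cat("\nFilter survivors:",
      paste(sprintf("%s=%d", names(x$filter_counts), x$filter_counts),
            collapse = " -> "), "\n")
  invisible(x)
}

#' @export
coef.enm_ensemble <- function(object, ...) {
  all_terms <- Reduce(union, lapply(object$models,
                                    function(m) names(m$coefficients)))
  out <- matrix(NA_real_, length(object$models), length(all_terms),
                dimnames = list(paste0("model", seq_along(object$models)),
                                all_terms))
  for (i in seq_along(object$models))
    out[i, names(object$models[[i]]$coefficients)] <-
      object$models[[i]]$coefficients
  out
}

#' Predict from an ensemble niche model
#'
#' The consensus prediction is the Akaike-weight-weighted mean of the
#' member model probabilities, so it always lies within the range of member
#' predictions.
#'
#' @param object an `enm_ensemble`.
#' @param newdata data.frame with the predictor columns, or a
#'   [weekly_env()] stack of principal components (dispatched to
#'   [predict_weekly()]).
#' @param type `"consensus"` (default) or `"members"` (matrix of per-model
#'   probabilities).
#' @param ... unused.
#' @return numeric vector of consensus probabilities, a matrix for
#'   `type = "members"`, or a `period_stack` of suitability when `newdata`
#'   is a stack.
#' @export
predict.enm_ensemble <- function(object, newdata,
                                 type = c("consensus", "members"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "weekly_env")) return(predict_weekly(object, newdata))
  members <- vapply(object$models, function(m) predict(m, newdata),
                    numeric(nrow(newdata)))
  members <- matrix(members, nrow = nrow(newdata))
  colnames(members) <- paste0("model", seq_along(object$models))
  if (type == "members") return(members)
  drop(members %*% object$weights)
}

#' @export
residuals.enm_ensemble <- function(object, data, ...) {
  y <- as.numeric(data[[object$calibration$response]])
  y - predict(object, data)
}

#' Ensemble response curve for one predictor
#'
#' The weighted-average predicted probability as one predictor varies over
#' its calibration range with all other predictors held at their
#' calibration means. With all quadratic coefficients negative every member
#' curve, and in practice the consensus, is unimodal.
#'
#' @param ensemble an `enm_ensemble`.
#' @param predictor predictor name (e.g. `"PC1"`).
#' @param n number of evaluation points.
#' @param range optional length-2 evaluation range (defaults to the
#'   predictor's calibration range).
#' @return data.frame with the predictor value, the `consensus` prediction
#'   and one column per member model.
#' @export
response_curve <- function(ensemble, predictor, n = 100, range = NULL) {
  cal <- ensemble$calibration
  stopifnot(predictor %in% cal$predictors)
  if (is.null(range)) range <- c(cal$min[predictor], cal$max[predictor])
  grid <- seq(range[1], range[2], length.out = n)
  nd <- as.data.frame(as.list(cal$mean))[rep(1, n), , drop = FALSE]
  names(nd) <- cal$predictors
  nd[[predictor]] <- grid
  members <- predict(ensemble, nd, type = "members")
  out <- data.frame(value = grid, consensus = drop(members %*% ensemble$weights))
  out <- cbind(out, as.data.frame(members))
  names(out)[1] <- predictor
  rownames(out) <- NULL
  out
}

#' Predictor contribution to the ensemble
#'
#' The contribution of a term is the sum of Akaike weights of the selected
#' models containing it (a weight-sum importance measure), reported
#' separately for the linear and quadratic form of each predictor.
#'
#' @param ensemble an `enm_ensemble`.
#' @return data.frame `predictor`, `form` (linear/quadratic),
#'   `contribution` in \[0, 1\].
#' @export
variable_contribution <- function(ensemble) {
  preds <- ensemble$calibration$predictors
  rows <- list()
  for (p in preds) {
    for (form in c("linear", "quadratic")) {
      lab <- if (form == "linear") p else sprintf("I(%s^2)", p)
      w <- sum(ensemble$weights[vapply(ensemble$models,
                                       function(m) lab %in% m$terms,
                                       logical(1))])
      rows[[length(rows) + 1L]] <-
        data.frame(predictor = p, form = form, contribution = w)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot ensemble response curves
#'
#' One panel per predictor: member curves in grey, weighted consensus in
#' black, over each predictor's calibration range.
#'
#' @param x an `enm_ensemble`.
#' @param predictors which predictors to plot (default all).
#' @param n evaluation points per curve.
#' @param ... passed to `plot()`.
#' @export
plot.enm_ensemble <- function(x, predictors = x$calibration$predictors,
                              n = 100, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(predictors)),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in predictors) {
    rc <- response_curve(x, p, n = n)
    graphics::plot(rc[[p]], rc$consensus, type = "n", ylim = c(0, 1),
                   xlab = p, ylab = "suitability", ...)
    for (j in seq_along(x$models))
      graphics::lines(rc[[p]], rc[[paste0("model", j)]], col = "grey70")
    graphics::lines(rc[[p]], rc$consensus, lwd = 2)
  }
  invisible(x)
}
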