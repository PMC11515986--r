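#' Univariate niche-signal randomization test
#'
#' Tests whether detections are environmentally biased relative to the
#' sampling universe. With N annotated sampling records of which x are
#' detections, the null distribution of a summary statistic (mean, median,
#' standard deviation, or range) of an environmental variable is built by
#' repeatedly drawing x records at random (without replacement within each
#' draw) from all N records. The observed statistic among the actual
#' detections is classified `"higher"` if it exceeds the upper 2.5% empirical
#' quantile of the null, `"lower"` if it falls below the lower 2.5% quantile,
#' and `"ns"` otherwise (ties resolve to `"ns"`).
#'
#' @param annotated annotated record data.frame (see [extract_at_records()])
#'   with a logical `detected` column.
#' @param variable name of the environmental column to test.
#' @param statistic one of `"mean"`, `"median"`, `"sd"`, `"range"` (range is
#'   max minus min).
#' @param n_rep number of null draws (default 1000).
#' @param seed RNG seed.
#' @param draws optional precomputed index matrix (`n_rep` x `x`) of row
#'   draws, so several variables/statistics share the same resamples.
#' @return object of class `univariate_signal`: `variable`, `statistic`,
#'   `observed`, `null_values`, `classification`, `N`, `x`.
#' @export
univariate_randomization <- function(annotated, variable,
                                     statistic = c("mean", "median", "sd",
                                                   "range"),
                                     n_rep = 1000, seed = 1, draws = NULL) {
  statistic <- match.arg(statistic)
  values <- annotated[[variable]]
  stopifnot(!is.null(values), is.logical(annotated$detected))
  N <- length(values)
  x <- sum(annotated$detected)
  if (x == 0 || x == N)
    stop("no contrast available: species detected in ", x, " of ", N,
         " sampling events")
  stat_fun <- switch(statistic, mean = mean, median = stats::median,
                     sd = stats::sd, range = function(v) diff(range(v)))
  if (is.null(draws)) draws <- randomization_draws(N, x, n_rep, seed)
  null_values <- apply(draws, 1, function(idx) stat_fun(values[idx]))
  observed <- stat_fun(values[annotated$detected])
  q <- stats::quantile(null_values, c(0.025, 0.975), type = 7, names = FALSE)
  classification <- if (observed > q[2]) "higher"
                    else if (observed < q[1]) "lower" else "ns"
  structure(list(variable = variable, statistic = statistic,
                 observed = observed, null_values = null_values,
                 classification = classification, N = N, x = x),
            class = "univariate_signal")
}

#' @rdname univariate_randomization
#' @param N,x universe size and number of detections.
#' @export
randomization_draws <- function(N, x, n_rep, seed) {
  set.seed(seed)
  t(replicate(n_rep, sample.int(N, x)))
}

#' @export
print.univariate_signal <- function(x, ...) {
  cat(sprintf("%s(%s): observed %.4g, null [%.4g, %.4g] (2.5/97.5%%) -> %s  (x=%d of N=%d)\n",
              x$statistic, x$variable, x$observed,
              stats::quantile(x$null_values, 0.025, type = 7),
              stats::quantile(x$null_values, 0.975, type = 7),
              x$classification, x$x, x$N))
  invisible(x)
}

#' Niche-signal summary table
#'
#' Runs the univariate randomization test for every variable and all four
#' statistics (mean and median characterize niche position; standard
#' deviation and range characterize niche breadth), sharing one set of row
#' draws so every cell of the table reflects the same resamples. Cells show
#' `"higher"`/`"lower"` or `"-"` when not significant.
#'
#' @inheritParams univariate_randomization
#' @param variables environmental columns to test.
#' @return data.frame with one row per variable and columns `mean`,
#'   `median`, `sd`, `range`.
#' @export
summarize_signals <- function(annotated, variables, n_rep = 1000, seed = 1) {
  N <- nrow(annotated)
  x <- sum(annotated$detected)
  draws <- randomization_draws(N, x, n_rep, seed)
  stats_all <- c("mean", "median", "sd", "range")
  out <- data.frame(variable = variables)
  for (s in stats_all) {
    out[[s]] <- vapply(variables, function(v) {
      r <- univariate_randomization(annotated, v, s, n_rep, seed, draws = draws)
      if (r$classification == "ns") "-" else r$classification
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Two-group PERMANOVA of detections versus non-detections
#'
#' Partitions squared Euclidean distances among standardized environmental
#' values into between- and within-group components for the two groups
#' (detected versus not detected), giving the pseudo-F statistic
#' `(SS_between/(g-1)) / (SS_within/(N-g))`. The p-value is obtained by
#' random relabeling: `p = (1 + #{permuted F >= observed F}) /
#' (1 + n_permutations)`. With `contrast = "vs_all"` the detections are
#' instead contrasted against the pooled universe (detections duplicated
#' into the reference group).
#'
#' @param annotated annotated record data.frame with `detected`.
#' @param variables environmental columns defining the space (standardized
#'   internally).
#' @param n_permutations number of permutations (default 999).
#' @param seed RNG seed.
#' @param contrast `"two_group"` (default) or `"vs_all"`.
#' @return object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `contrast`.
#' @export
permanova <- function(annotated, variables, n_permutations = 999, seed = 1,
                      contrast = c("two_group", "vs_all")) {
  contrast <- match.arg(contrast)
  X <- scale(as.matrix(annotated[, variables, drop = FALSE]))
  det <- annotated$detected
  if (contrast == "vs_all") {
    X <- rbind(X[det, , drop = FALSE], X)
    groups <- c(rep(TRUE, sum(det)), rep(FALSE, nrow(annotated)))
  } else {
    groups <- det
  }
  n1 <- sum(groups); n0 <- sum(!groups)
  if (n1 < 2 || n0 < 2)
    stop("each group needs at least 2 records (", n1, " detections, ",
         n0, " in reference group)")
  f_obs <- pseudo_f(X, groups)
  set.seed(seed)
  f_perm <- replicate(n_permutations, pseudo_f(X, sample(groups)))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = n_permutations, contrast = contrast,
                 seed = seed),
            class = "permanova_result")
}

# pseudo-F from the sums-of-squares partition; for Euclidean distance the
# distance-based partition equals the centroid-based one computed here
pseudo_f <- function(X, groups) {
  g <- 2L
  N <- nrow(X)
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- 0
  for (lv in c(TRUE, FALSE)) {
    Xi <- X[groups == lv, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (N - g))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$contrast, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}
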