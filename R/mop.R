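#' Mobility-oriented parity (MOP) extrapolation diagnostic
#'
#' For every projection point, the MOP distance is the mean Euclidean
#' distance to the nearest `percent`% of calibration points, computed in
#' predictor space standardized by the calibration means and standard
#' deviations. The strict extrapolation mask flags points with any
#' variable outside the calibration min-max range, and `n_vars_out` counts
#' how many variables are out of range.
#'
#' @param calibration_points numeric matrix/data.frame (n >= 2 rows) of the
#'   conditions used to fit the models (typically the annotated records'
#'   PC values).
#' @param projection numeric matrix/data.frame with the same columns.
#' @param percent fraction (in percent, default 5) of nearest calibration
#'   points over which the distance is averaged; 100 gives the mean
#'   distance to all calibration points.
#' @return object of class `mop_layer`: `distance`, `strict_mask`,
#'   `n_vars_out` per projection row, plus the parameters used.
#' @export
mop_layer <- function(calibration_points, projection, percent = 5) {
  C <- as.matrix(calibration_points)
  P <- as.matrix(projection)
  if (ncol(C) != ncol(P))
    stop("dimension mismatch: calibration has ", ncol(C),
         " variables, projection has ", ncol(P))
  stopifnot(nrow(C) >= 2, percent > 0, percent <= 100)
  mins <- apply(C, 2, min); maxs <- apply(C, 2, max)
  n_vars_out <- rowSums(sweep(P, 2, mins, "<") | sweep(P, 2, maxs, ">"))
  ctr <- colMeans(C); sds <- apply(C, 2, stats::sd)
  sds[sds == 0] <- 1
  Cz <- sweep(sweep(C, 2, ctr), 2, sds, "/")
  Pz <- sweep(sweep(P, 2, ctr), 2, sds, "/")
  k <- max(1L, ceiling(nrow(C) * percent / 100))
  d2 <- outer(rowSums(Pz^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(P)), rowSums(Cz^2)) - 2 * Pz %*% t(Cz)
  d2[d2 < 0] <- 0
  distance <- apply(sqrt(d2), 1, function(row) mean(sort(row)[seq_len(k)]))
  structure(list(distance = distance, strict_mask = n_vars_out >= 1,
                 n_vars_out = as.integer(n_vars_out),
                 percent = percent, k = k, n_calibration = nrow(C)),
            class = "mop_layer")
}

#' MOP analysis of a weekly PC stack
#'
#' Applies [mop_layer()] to every 8-day layer, producing a distance stack
#' and a strict-extrapolation mask stack.
#'
#' @inheritParams mop_layer
#' @param pc_stack a [weekly_env()] of the model's predictor space.
#' @param variables which bands to use (default: the calibration columns).
#' @return object of class `mop_stack`: `distance` and `strict` (0/1)
#'   matrices (cells x periods), `n_vars_out`, plus grid/period metadata.
#' @export
mop_stack <- function(calibration_points, pc_stack, percent = 5,
                      variables = colnames(calibration_points)) {
  stopifnot(inherits(pc_stack, "weekly_env"))
  C <- as.matrix(calibration_points)[, variables, drop = FALSE]
  np <- nrow(pc_stack$periods)
  nc <- n_cells(pc_stack$grid)
  dist <- strict <- nout <- matrix(NA_real_, nc, np)
  ji <- match(variables, pc_stack$variables)
  stopifnot(!anyNA(ji))
  for (i in seq_len(np)) {
    P <- pc_stack$values[, ji, i, drop = FALSE][, , 1]
    ml <- mop_layer(C, P, percent)
    dist[, i] <- ml$distance
    strict[, i] <- as.numeric(ml$strict_mask)
    nout[, i] <- ml$n_vars_out
  }
  colnames(dist) <- colnames(strict) <- pc_stack$periods$label
  structure(list(grid = pc_stack$grid, periods = pc_stack$periods,
                 distance = dist, strict = strict, n_vars_out = nout,
                 percent = percent, variables = variables),
            class = "mop_stack")
}

#' @export
print.mop_stack <- function(x, ...) {
  cat(sprintf("mop_stack: %d periods, %d cells, percent = %g; strict extrapolation in %.1f%% of cell-periods\n",
              nrow(x$periods), nrow(x$distance), x$percent,
              100 * mean(x$strict)))
  invisible(x)
}

#' Day-weighted monthly fraction of strict extrapolation
#'
#' Summarizes a MOP stack to months exactly as [monthly_average()] does for
#' suitability: per cell, the day-weighted fraction of the month spent
#' outside the calibration ranges, in \[0, 1\].
#'
#' @param mop a `mop_stack` covering complete years.
#' @return a `monthly_stack` of out-of-range fractions.
#' @export
monthly_mop_summary <- function(mop) {
  stopifnot(inherits(mop, "mop_stack"))
  stk <- period_stack(mop$grid, mop$periods, mop$strict, band = "mop_strict")
  monthly_average(stk)
}

#' Mask strict-extrapolation cells in a suitability stack
#'
#' @param suitability a [period_stack()] from [predict_weekly()].
#' @param mop a `mop_stack` on the same grid and periods.
#' @return the suitability stack with strictly extrapolated cell-periods
#'   set to `NA`; the number of masked cells is in attribute `n_masked`.
#' @export
mask_predictions <- function(suitability, mop) {
  stopifnot(inherits(suitability, "period_stack"), inherits(mop, "mop_stack"))
  if (!same_grid(suitability$grid, mop$grid) ||
      !identical(suitability$periods$label, mop$periods$label))
    stop("suitability and MOP stacks are not aligned")
  v <- suitability$values
  v[mop$strict == 1] <- NA_real_
  out <- period_stack(suitability$grid, suitability$periods, v,
                      band = suitability$band)
  attr(out, "n_masked") <- sum(mop$strict == 1)
  out
}
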