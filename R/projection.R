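#' Transfer the ensemble to every weekly layer
#'
#' For each 8-day period, each selected model is applied to the PC layer
#' and the consensus suitability is the Akaike-weight-weighted mean of the
#' member probabilities, per cell.
#'
#' @param ensemble an [enm_calibrate()] ensemble.
#' @param pc_stack a [weekly_env()] of principal components with the band
#'   order used in calibration.
#' @return a [period_stack()] of consensus suitability in \[0, 1\].
#' @export
predict_weekly <- function(ensemble, pc_stack) {
  stopifnot(inherits(pc_stack, "weekly_env"))
  preds <- ensemble$calibration$predictors
  miss <- setdiff(preds, pc_stack$variables)
  if (length(miss))
    stop("PC band(s) missing from the stack: ", paste(miss, collapse = ", "))
  np <- nrow(pc_stack$periods)
  out <- matrix(NA_real_, n_cells(pc_stack$grid), np)
  for (i in seq_len(np)) {
    nd <- as.data.frame(pc_stack$values[, preds, i, drop = FALSE][, , 1])
    names(nd) <- preds
    out[, i] <- predict(ensemble, nd)
  }
  period_stack(pc_stack$grid, pc_stack$periods, out, band = "suitability")
}

#' Three-period moving-window smoothing
#'
#' Recasts each period as the mean of the preceding, focal, and following
#' periods, in chronological order across year boundaries; the first and
#' last period of the series use the available two-period window.
#'
#' @param stack a [period_stack()].
#' @return the smoothed [period_stack()].
#' @export
smooth_moving_window <- function(stack) {
  stopifnot(inherits(stack, "period_stack"))
  v <- stack$values
  np <- ncol(v)
  out <- v
  if (np >= 2) {
    for (i in seq_len(np)) {
      win <- max(1, i - 1):min(np, i + 1)
      out[, i] <- rowMeans(v[, win, drop = FALSE])
    }
  }
  period_stack(stack$grid, stack$periods, out, band = stack$band)
}

#' Day-weighted monthly averages of a weekly stack
#'
#' The monthly value is the day-weighted mean of the periods overlapping
#' the month, honouring partial membership of periods that straddle month
#' boundaries; the weights of a month sum to its number of days.
#'
#' @param stack a [period_stack()] covering complete years.
#' @return object of class `monthly_stack`: `grid`, `months` data.frame
#'   (`year`, `month`, `ndays`), `values` matrix (cells x months), and
#'   `weights` (per month, the day overlap of each contributing period).
#' @export
monthly_average <- function(stack) {
  stopifnot(inherits(stack, "period_stack"))
  years <- sort(unique(stack$periods$year))
  full <- period_table(years)
  miss <- setdiff(full$label, stack$periods$label)
  if (length(miss))
    stop("incomplete year(s): missing periods ", paste(miss, collapse = ", "))
  months <- do.call(rbind, lapply(years, function(y)
    data.frame(year = y, month = 1:12, ndays = days_in_month(1:12, y))))
  vals <- matrix(NA_real_, nrow(stack$values), nrow(months))
  weights <- vector("list", nrow(months))
  for (mi in seq_len(nrow(months))) {
    y <- months$year[mi]; m <- months$month[mi]
    w <- numeric(0)
    for (st in period_starts()) {
      pmd <- period_month_days(st, y)
      d <- pmd[as.character(m)]
      if (!is.na(d)) {
        w <- c(w, stats::setNames(d, paste0(y, "_", period_label(st))))
      }
    }
    stopifnot(sum(w) == months$ndays[mi])
    idx <- match(names(w), stack$periods$label)
    vals[, mi] <- (stack$values[, idx, drop = FALSE] %*% w) / sum(w)
    weights[[mi]] <- w
  }
  names(weights) <- sprintf("%d_%02d", months$year, months$month)
  colnames(vals) <- names(weights)
  structure(list(grid = stack$grid, band = stack$band, months = months,
                 values = vals, weights = weights),
            class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf("monthly_stack [%s]: %d months (%s), %d cells, range [%.3g, %.3g]\n",
              x$band, nrow(x$months),
              paste(range(x$months$year), collapse = "-"),
              n_cells(x$grid),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Per-site time series from a period stack
#'
#' Extracts each site's cell series over all periods; optionally adds the
#' cross-site mean series of raw variables (e.g. temperature or vapor
#' pressure) for phenology overlays.
#'
#' @param stack a [period_stack()] (e.g. suitability).
#' @param sites data.frame with `site_id`, `lon`, `lat`.
#' @param raw_stack optional [weekly_env()] of raw variables on the same
#'   periods.
#' @param overlay_vars raw variables to average across sites.
#' @return data.frame in long format: `site_id`, `label`, `year`, `start`,
#'   `value`; overlay rows use `site_id = "mean(<var>)"`.
#' @export
site_time_series <- function(stack, sites, raw_stack = NULL,
                             overlay_vars = NULL) {
  cell <- cell_index(stack$grid, sites$lon, sites$lat)
  if (anyNA(cell))
    stop("site(s) outside the grid: ",
         paste(sites$site_id[is.na(cell)], collapse = ", "))
  np <- nrow(stack$periods)
  out <- data.frame(
    site_id = rep(sites$site_id, each = np),
    label = rep(stack$periods$label, nrow(sites)),
    year = rep(stack$periods$year, nrow(sites)),
    start = rep(stack$periods$start, nrow(sites)),
    value = as.vector(t(stack$values[cell, , drop = FALSE])))
  if (!is.null(raw_stack) && length(overlay_vars)) {
    stopifnot(identical(raw_stack$periods$label, stack$periods$label))
    for (v in overlay_vars) {
      j <- match(v, raw_stack$variables)
      stopifnot(!is.na(j))
      series <- colMeans(raw_stack$values[cell, j, , drop = FALSE][, 1, ])
      out <- rbind(out, data.frame(
        site_id = sprintf("mean(%s)", v), label = stack$periods$label,
        year = stack$periods$year, start = stack$periods$start,
        value = series))
    }
  }
  rownames(out) <- NULL
  out
}
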