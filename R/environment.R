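#' Composite daily fields to 8-day periods
#'
#' Each of the 46 periods per year is the arithmetic mean of the daily
#' values it covers (including precipitation, which is averaged rather than
#' summed). The last period of a year covers 5 days in a common year and 6
#' in a leap year.
#'
#' @param daily a `daily_env` from [generate_daily_environment()] (or the
#'   same structure built from real data).
#' @return a [weekly_env()] spanning all years of `daily` chronologically.
#' @export
composite_8day <- function(daily) {
  stopifnot(inherits(daily, "daily_env"))
  periods <- period_table(daily$years)
  nv <- length(daily$variables)
  nc <- n_cells(daily$grid)
  vals <- array(NA_real_, c(nc, nv, nrow(periods)))
  for (i in seq_len(nrow(periods))) {
    arr <- daily$data[[as.character(periods$year[i])]]
    nd <- days_in_year(periods$year[i])
    if (is.null(arr) || dim(arr)[3] != nd) {
      have <- if (is.null(arr)) 0L else dim(arr)[3]
      stop(sprintf("year %d has %d daily layers, expected %d",
                   periods$year[i], have, nd))
    }
    days <- periods$start[i] + seq_len(periods$ndays[i]) - 1L
    if (anyNA(arr[, , days]))
      stop(sprintf("missing daily values in year %d, days %d-%d",
                   periods$year[i], min(days), max(days)))
    vals[, , i] <- apply(arr[, , days, drop = FALSE], c(1, 2), mean)
  }
  weekly_env(daily$grid, daily$variables, periods, vals)
}

#' Pairwise Pearson correlation screen
#'
#' @param values numeric matrix or data.frame (n >= 3 rows, one column per
#'   variable).
#' @param threshold absolute correlation above which a pair is flagged as
#'   collinear (default 0.8).
#' @return object of class `correlation_report`: the symmetric correlation
#'   matrix `r` (unit diagonal) and a data.frame `flagged` of pairs with
#'   `|r| > threshold`. Zero-variance columns give `NA` correlations with a
#'   warning.
#' @export
correlation_screen <- function(values, threshold = 0.8) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(values)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(values))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(r)[idx[, 1]],
                        var2 = colnames(r)[idx[, 2]],
                        r = r[idx])
  structure(list(r = r, flagged = flagged, threshold = threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pearson correlation screen (|r| >", x$threshold, "flagged)\n")
  print(round(x$r, 3))
  if (nrow(x$flagged)) {
    cat("flagged pairs:\n")
    print(x$flagged, row.names = FALSE)
  } else cat("no pairs flagged\n")
  invisible(x)
}

#' Fit a principal components transform to a weekly stack
#'
#' A correlation-matrix PCA (variables centered and scaled to unit
#' variance, as they carry incommensurate units) fitted on the pooled
#' cell-by-period values of all years, optionally subsampled with a
#' recorded seed. Each loading column is sign-fixed so that its
#' largest-magnitude entry is positive, removing the sign ambiguity of
#' eigenvectors.
#'
#' @param stack a [weekly_env()] of raw variables.
#' @param subsample_n maximum pooled sample size (default 200000).
#' @param seed seed for the subsampling draw.
#' @return object of class `pca_transform`: `center`, `scale`, `loadings`
#'   (orthonormal columns), `variance_fraction` (non-increasing, sums
#'   to 1), plus the subsampling metadata.
#' @export
fit_pca <- function(stack, subsample_n = 200000, seed = 1) {
  stopifnot(inherits(stack, "weekly_env"))
  nv <- length(stack$variables)
  pooled <- matrix(aperm(stack$values, c(1, 3, 2)), ncol = nv)
  colnames(pooled) <- stack$variables
  stopifnot(nrow(pooled) >= nv)
  if (nrow(pooled) > subsample_n) {
    set.seed(seed)
    pooled <- pooled[sample.int(nrow(pooled), subsample_n), , drop = FALSE]
  }
  sds <- apply(pooled, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(stack$variables[sds == 0], collapse = ", "),
         " (scaling undefined)")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  for (j in seq_len(ncol(load)))
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, scale = pc$scale, loadings = load,
                 variance_fraction = vf, subsample_n = subsample_n,
                 seed = seed, n_used = nrow(pooled)),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("pca_transform on %d variables (n = %d pooled samples)\n",
              length(x$center), x$n_used))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Apply a PCA transform
#'
#' @param x numeric matrix/data.frame of raw variables, or a [weekly_env()]
#'   stack.
#' @param transform a `pca_transform` from [fit_pca()].
#' @return for a matrix, the matrix of scores (columns `PC1`, ...); for a
#'   stack, a [weekly_env()] whose bands are the principal components.
#' @export
project_pca <- function(x, transform) {
  apply_one <- function(m) {
    m <- as.matrix(m)[, names(transform$center), drop = FALSE]
    z <- scale(m, center = transform$center, scale = transform$scale)
    s <- z %*% transform$loadings
    colnames(s) <- paste0("PC", seq_len(ncol(s)))
    s
  }
  if (inherits(x, "weekly_env")) {
    np <- nrow(x$periods)
    nv <- length(x$variables)
    out <- array(NA_real_, c(n_cells(x$grid), nv, np))
    for (i in seq_len(np)) out[, , i] <- apply_one(x$values[, , i])
    weekly_env(x$grid, paste0("PC", seq_len(nv)), x$periods, out)
  } else {
    apply_one(x)
  }
}

#' Serialize a PCA transform to JSON
#' @param transform a `pca_transform`.
#' @param path file path.
#' @export
write_pca_json <- function(transform, path) {
  obj <- list(variables = names(transform$center),
              center = unname(transform$center),
              scale = unname(transform$scale),
              loadings = unname(as.matrix(transform$loadings)),
              variance_fraction = transform$variance_fraction,
              subsample_n = transform$subsample_n, seed = transform$seed,
              n_used = transform$n_used)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- as.matrix(obj$loadings)
  dimnames(load) <- list(obj$variables, paste0("PC", seq_len(ncol(load))))
  structure(list(center = stats::setNames(obj$center, obj$variables),
                 scale = stats::setNames(obj$scale, obj$variables),
                 loadings = load, variance_fraction = obj$variance_fraction,
                 subsample_n = obj$subsample_n, seed = obj$seed,
                 n_used = obj$n_used),
            class = "pca_transform")
}

#' Extract time-specific environmental values at records
#'
#' Annotates each presence-absence record with the raw variables and the
#' principal components of the 8-day period containing its date, at the
#' grid cell containing its coordinates.
#'
#' @param records record data.frame from [assemble_records()].
#' @param raw_stack [weekly_env()] of raw variables.
#' @param pc_stack [weekly_env()] of PCs on the same grid and periods.
#' @return the records with one column per raw variable and per PC added.
#' @export
extract_at_records <- function(records, raw_stack, pc_stack = NULL) {
  stopifnot(inherits(raw_stack, "weekly_env"))
  grid <- raw_stack$grid
  cell <- cell_index(grid, records$lon, records$lat)
  lab <- paste0(records$year, "_", records$julian_week)
  pidx <- match(lab, raw_stack$periods$label)
  bad <- is.na(cell) | is.na(pidx)
  if (any(bad))
    stop("records outside grid or period coverage: ",
         paste(sprintf("%s/%s/%s", records$site_id, records$date,
                       records$life_stage)[bad], collapse = ", "))
  out <- records
  for (j in seq_along(raw_stack$variables))
    out[[raw_stack$variables[j]]] <-
      raw_stack$values[cbind(cell, j, pidx)]
  if (!is.null(pc_stack)) {
    stopifnot(same_grid(grid, pc_stack$grid),
              identical(raw_stack$periods$label, pc_stack$periods$label))
    for (j in seq_along(pc_stack$variables))
      out[[pc_stack$variables[j]]] <-
        pc_stack$values[cbind(cell, j, pidx)]
  }
  out
}
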