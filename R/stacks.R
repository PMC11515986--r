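#' Regular lon/lat grid
#'
#' A lightweight in-memory raster geometry: a regular WGS84 lon/lat grid
#' with its origin at the upper-left corner. Cells are half-open intervals
#' (a point on a cell's east/south edge belongs to the next cell), matching
#' the usual raster convention.
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(nrow, ncol, xmin, xmax, ymin, ymax) {
  stopifnot(nrow >= 1, ncol >= 1, xmax > xmin, ymax > ymin)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 dx = (xmax - xmin) / ncol, dy = (ymax - ymin) / nrow),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

n_cells <- function(grid) grid$nrow * grid$ncol

#' Locate grid cells containing points
#'
#' @param grid an [env_grid()].
#' @param lon,lat coordinate vectors (degrees).
#' @return integer vector of cell indices in row-major order from the
#'   upper-left corner; points outside the grid give `NA`.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$dx) + 1
  row <- floor((grid$ymax - lat) / grid$dy) + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  idx <- (row - 1) * grid$ncol + col
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Coordinates of cell centers
#' @param grid an [env_grid()].
#' @param cell integer cell indices (row-major from upper-left).
#' @return data.frame with `lon`, `lat` of each cell center.
#' @export
cell_center <- function(grid, cell = seq_len(n_cells(grid))) {
  row <- (cell - 1L) %/% grid$ncol + 1L
  col <- (cell - 1L) %% grid$ncol + 1L
  data.frame(lon = grid$xmin + (col - 0.5) * grid$dx,
             lat = grid$ymax - (row - 0.5) * grid$dy)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("nrow", "ncol", "xmin", "xmax", "ymin", "ymax")],
                   unclass(b)[c("nrow", "ncol", "xmin", "xmax", "ymin", "ymax")]))
}

#' Multi-variable period stack constructors
#'
#' `weekly_env()` holds one multi-band layer per 8-day period (cells x
#' variables x periods); `period_stack()` holds a single-band layer per
#' period (e.g. suitability or a MOP mask). Periods are ordered
#' chronologically across years.
#'
#' @param grid an [env_grid()].
#' @param variables character vector of band names (ordered).
#' @param periods data.frame with columns `year`, `start`, `label`, `ndays`.
#' @param values numeric array `c(ncell, nvar, nperiod)` for `weekly_env`;
#'   numeric matrix `ncell x nperiod` for `period_stack`.
#' @param band name of the single band of a `period_stack`.
#' @return objects of class `weekly_env` / `period_stack`.
#' @export
weekly_env <- function(grid, variables, periods, values) {
  stopifnot(inherits(grid, "env_grid"),
            is.array(values), length(dim(values)) == 3,
            dim(values)[1] == n_cells(grid),
            dim(values)[2] == length(variables),
            dim(values)[3] == nrow(periods))
  dimnames(values) <- list(NULL, variables, periods$label)
  structure(list(grid = grid, variables = variables,
                 periods = periods, values = values),
            class = "weekly_env")
}

#' @rdname weekly_env
#' @export
period_stack <- function(grid, periods, values, band = "value") {
  stopifnot(inherits(grid, "env_grid"), is.matrix(values),
            nrow(values) == n_cells(grid), ncol(values) == nrow(periods))
  colnames(values) <- periods$label
  structure(list(grid = grid, band = band, periods = periods, values = values),
            class = "period_stack")
}

#' @export
print.weekly_env <- function(x, ...) {
  cat(sprintf("weekly_env: %d periods (%s), %d bands [%s], %d cells\n",
              nrow(x$periods),
              paste(range(x$periods$year), collapse = "-"),
              length(x$variables), paste(x$variables, collapse = ", "),
              n_cells(x$grid)))
  invisible(x)
}

#' @export
print.period_stack <- function(x, ...) {
  cat(sprintf("period_stack [%s]: %d periods (%s), %d cells, range [%.3g, %.3g]\n",
              x$band, nrow(x$periods),
              paste(range(x$periods$year), collapse = "-"),
              n_cells(x$grid),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

period_table <- function(years) {
  out <- do.call(rbind, lapply(years, function(y) {
    st <- period_starts()
    data.frame(year = y, start = st,
               label = paste0(y, "_", period_label(st)),
               ndays = period_length(st, y))
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a period stack to a plain-text table
#'
#' Long-format CSV (`label`, `cell`, one column per band) that round-trips
#' the stack losslessly together with the grid geometry stored in a header
#' comment line. Provided as the text interchange format for gridded
#' outputs.
#'
#' @param x a `weekly_env` or `period_stack`.
#' @param path file path.
#' @export
write_stack_csv <- function(x, path) {
  g <- x$grid
  hdr <- sprintf("# grid %d %d %.10g %.10g %.10g %.10g", g$nrow, g$ncol,
                 g$xmin, g$xmax, g$ymin, g$ymax)
  if (inherits(x, "weekly_env")) {
    np <- nrow(x$periods)
    df <- data.frame(label = rep(x$periods$label, each = n_cells(g)),
                     cell = rep(seq_len(n_cells(g)), np))
    for (j in seq_along(x$variables))
      df[[x$variables[j]]] <- as.vector(x$values[, j, ])
  } else {
    df <- data.frame(label = rep(x$periods$label, each = n_cells(g)),
                     cell = rep(seq_len(n_cells(g)), nrow(x$periods)))
    df[[x$band]] <- as.vector(x$values)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @param years the years the stack covers (to rebuild period metadata).
#' @export
read_stack_csv <- function(path, years) {
  hdr <- readLines(path, n = 1)
  g <- as.numeric(strsplit(sub("^# grid ", "", hdr), " ")[[1]])
  grid <- env_grid(g[1], g[2], g[3], g[4], g[5], g[6])
  df <- utils::read.csv(path, skip = 1)
  periods <- period_table(years)
  periods <- periods[periods$label %in% unique(df$label), , drop = FALSE]
  bands <- setdiff(names(df), c("label", "cell"))
  ord <- order(match(df$label, periods$label), df$cell)
  df <- df[ord, , drop = FALSE]
  if (length(bands) == 1L) {
    vals <- matrix(df[[bands]], nrow = n_cells(grid))
    period_stack(grid, periods, vals, band = bands)
  } else {
    arr <- array(NA_real_, c(n_cells(grid), length(bands), nrow(periods)))
    for (j in seq_along(bands))
      arr[, j, ] <- matrix(df[[bands[j]]], nrow = n_cells(grid))
    weekly_env(grid, bands, periods, arr)
  }
}
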