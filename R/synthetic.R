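#' Synthetic study configuration
#'
#' Defines the simulated study system used for testing the whole workflow
#' without climate downloads: a regular grid over the central Great Plains,
#' two to three study years, 10 longitudinally sampled sites, and
#' condition-gated sampling visits (field work only when the day's
#' temperature lies within 2-32 degrees C and no precipitation falls, the
#' practical window for questing-tick collection).
#'
#' Each temperature-like variable follows a sinusoidal seasonal curve plus
#' an east-west linear gradient and iid daily noise. `tmax` is generated as
#' `tmin` plus a strictly positive diurnal range, so `tmax >= tmin` holds by
#' construction. Precipitation is truncated at zero (dry days are common).
#' Vapor pressure is a saturation-pressure (Magnus) transform of `tmin`
#' plus noise and shortwave radiation a linear function of day length plus
#' noise, which reproduces the strong collinearity (|r| > 0.8) among
#' observed Daymet variables. Day length is computed deterministically from
#' latitude and day of year and is therefore noise free.
#'
#' @param grid an [env_grid()]; at least 4 x 4 cells.
#' @param years integer study years.
#' @param n_sites number of sampling sites.
#' @param visits_per_site_year target sampling visits per site and year.
#' @param visit_rules list with `tmin_ok`, `tmax_ok` (degrees C) and `dry`
#'   (logical: require zero precipitation); set to `NULL` to disable the
#'   gate.
#' @param tmin list `mean`, `amp`, `phase`, `grad`, `sd` for the seasonal
#'   minimum-temperature curve `mean + amp * sin(2*pi*(d - phase)/365)`
#'   (degrees C); `grad` is the total west-to-east increase; `sd` the daily
#'   noise standard deviation.
#' @param trange list `mean`, `sd` for the diurnal range (C, floored at 0.5).
#' @param prcp list `mean`, `amp`, `phase`, `grad`, `sd` for precipitation
#'   (mm/day, truncated at 0).
#' @param srad list `base`, `slope`, `sd`: shortwave radiation (W/m2) as a
#'   linear function of day length (h).
#' @param vp list `sd`: noise (Pa) around the Magnus saturation pressure at
#'   `tmin`.
#' @param seed RNG seed for the whole simulation.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(grid = env_grid(20, 20, -103, -94.43, 33.62, 40),
                       years = 2020:2021,
                       n_sites = 10,
                       visits_per_site_year = 9,
                       visit_rules = list(tmin_ok = 2, tmax_ok = 32, dry = TRUE),
                       tmin = list(mean = 9, amp = 12, phase = 105,
                                   grad = 2, sd = 3),
                       trange = list(mean = 11, sd = 2),
                       prcp = list(mean = 0.6, amp = 1.2, phase = 105,
                                   grad = 1, sd = 3),
                       srad = list(base = -120, slope = 28, sd = 25),
                       vp = list(sd = 60),
                       seed = 1) {
  if (!is.list(grid)) grid <- do.call(env_grid, as.list(grid))
  stopifnot(inherits(grid, "env_grid"), grid$nrow >= 4, grid$ncol >= 4,
            n_sites >= 1, visits_per_site_year >= 1)
  if (trange$mean <= 0)
    stop("diurnal range mean must be positive (tmax >= tmin by construction)")
  for (v in list(tmin, trange, prcp, srad, vp))
    if (v$sd < 0) stop("noise sd must be non-negative")
  structure(list(grid = grid, years = years, n_sites = n_sites,
                 visits_per_site_year = visits_per_site_year,
                 visit_rules = visit_rules, tmin = tmin, trange = trange,
                 prcp = prcp, srad = srad, vp = vp, seed = seed),
            class = "sim_config")
}

seasonal_curve <- function(day, mean, amp, phase) {
  mean + amp * sin(2 * pi * (day - phase) / 365)
}

# total west->east increase `grad` across the grid, per cell
gradient_field <- function(grid, grad) {
  ctr <- cell_center(grid)
  grad * (ctr$lon - grid$xmin) / (grid$xmax - grid$xmin)
}

#' Generate daily environmental fields
#'
#' @param cfg a [sim_config()].
#' @return object of class `daily_env`: grid and variable metadata plus, per
#'   year, an array `c(ncell, 6, ndays)` of daily values for
#'   `tmax, tmin, prcp, srad, vp, dayl`.
#' @export
generate_daily_environment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "simulate"))
  grid <- cfg$grid
  nc <- n_cells(grid)
  vars <- c("tmax", "tmin", "prcp", "srad", "vp", "dayl")
  ctr <- cell_center(grid)
  g_tmin <- gradient_field(grid, cfg$tmin$grad)
  g_prcp <- gradient_field(grid, cfg$prcp$grad)
  data <- list()
  for (y in cfg$years) {
    nd <- days_in_year(y)
    arr <- array(NA_real_, c(nc, 6, nd), dimnames = list(NULL, vars, NULL))
    dayl <- t(vapply(seq_len(nd),
                     function(d) geosphere::daylength(ctr$lat, d),
                     numeric(nc)))            # nd x ncell
    for (d in seq_len(nd)) {
      tmin <- seasonal_curve(d, cfg$tmin$mean, cfg$tmin$amp, cfg$tmin$phase) +
        g_tmin + stats::rnorm(nc, 0, cfg$tmin$sd)
      tr <- pmax(0.5, cfg$trange$mean + stats::rnorm(nc, 0, cfg$trange$sd))
      prcp <- pmax(0, seasonal_curve(d, cfg$prcp$mean, cfg$prcp$amp,
                                     cfg$prcp$phase) +
                     g_prcp + stats::rnorm(nc, 0, cfg$prcp$sd))
      dl <- dayl[d, ]
      srad <- cfg$srad$base + cfg$srad$slope * dl +
        stats::rnorm(nc, 0, cfg$srad$sd)
      # Magnus saturation vapor pressure at tmin (Pa), the Daymet convention
      vp <- 610.94 * exp(17.625 * tmin / (tmin + 243.04)) +
        stats::rnorm(nc, 0, cfg$vp$sd)
      arr[, , d] <- cbind(tmin + tr, tmin, prcp, srad, pmax(0, vp), dl)
    }
    data[[as.character(y)]] <- arr
  }
  structure(list(grid = grid, variables = vars, years = cfg$years,
                 data = data), class = "daily_env")
}

#' @export
print.daily_env <- function(x, ...) {
  cat(sprintf("daily_env: years %s, %d cells, variables %s\n",
              paste(x$years, collapse = ", "), n_cells(x$grid),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Place sampling sites on the grid
#'
#' Sites are placed at the centers of distinct, randomly chosen grid cells.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `site_id`, `lon`, `lat`, `cell`.
#' @export
generate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nc <- n_cells(cfg$grid)
  stopifnot(cfg$n_sites <= nc)
  set.seed(stage_seed(cfg$seed, "sites"))
  cells <- sort(sample.int(nc, cfg$n_sites))
  ctr <- cell_center(cfg$grid, cells)
  data.frame(site_id = sprintf("site%02d", seq_len(cfg$n_sites)),
             lon = ctr$lon, lat = ctr$lat, cell = cells)
}

#' Days on which a cell passes the sampling-condition gate
#'
#' @param daily a `daily_env`.
#' @param cell grid cell index.
#' @param year study year.
#' @param rules the `visit_rules` list of [sim_config()]; `NULL` disables
#'   the gate (all days eligible).
#' @return logical vector over the days of `year`.
#' @export
visit_eligibility <- function(daily, cell, year, rules) {
  arr <- daily$data[[as.character(year)]]
  if (is.null(arr)) stop("year ", year, " not simulated")
  nd <- dim(arr)[3]
  if (is.null(rules)) return(rep(TRUE, nd))
  ok <- arr[cell, "tmin", ] >= rules$tmin_ok &
    arr[cell, "tmax", ] <= rules$tmax_ok
  if (isTRUE(rules$dry)) ok <- ok & arr[cell, "prcp", ] == 0
  ok
}

#' Draw condition-gated sampling visits
#'
#' For each site and year, visit dates are drawn uniformly without
#' replacement from the days passing the sampling-condition gate at the
#' site's cell. This reproduces the sampling-universe bias that the niche
#' signal tests must account for: the universe of sampled days is itself
#' environmentally non-random.
#'
#' @param sites data.frame from [generate_sites()].
#' @param daily a `daily_env`.
#' @param cfg the [sim_config()].
#' @return data.frame `site_id`, `lon`, `lat`, `date` (a visit table for
#'   [assemble_records()]). Sites with no eligible day in a year are dropped
#'   from that year with a warning.
#' @export
simulate_visits <- function(sites, daily, cfg) {
  set.seed(stage_seed(cfg$seed, "visits"))
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (y in cfg$years) {
      ok <- which(visit_eligibility(daily, sites$cell[i], y, cfg$visit_rules))
      if (length(ok) == 0) {
        warning("site ", sites$site_id[i], " has no eligible sampling day in ",
                y, "; dropped for that year")
        next
      }
      n <- min(cfg$visits_per_site_year, length(ok))
      days <- sort(sample(ok, n))
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sites$site_id[i], lon = sites$lon[i], lat = sites$lat[i],
        date = as.Date(sprintf("%d-01-01", y)) + days - 1L)
    }
  }
  if (length(rows) == 0) stop("no eligible sampling days at any site")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' A known unimodal niche on principal-component space
#'
#' Detection probability is `plogis(intercept + sum(linear * pc) +
#' sum(quadratic * pc^2))`. All quadratic coefficients must be non-positive
#' so every response curve is unimodal, mirroring the retention filter used
#' in calibration.
#'
#' @param intercept scalar.
#' @param linear,quadratic numeric vectors over the PCs (recycled names
#'   `PC1`, `PC2`, ...).
#' @return object of class `true_niche`.
#' @export
true_niche <- function(intercept, linear, quadratic) {
  stopifnot(length(linear) == length(quadratic))
  if (any(quadratic > 0))
    stop("quadratic coefficients must be <= 0 (unimodal niche)")
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic), class = "true_niche")
}

#' @rdname true_niche
#' @param x a `true_niche`.
#' @param pc matrix of PC values (columns = PCs).
#' @return `niche_probability()` returns the detection probability per row.
#' @export
niche_probability <- function(x, pc) {
  pc <- as.matrix(pc)
  k <- length(x$linear)
  stopifnot(ncol(pc) >= k)
  eta <- x$intercept + pc[, seq_len(k), drop = FALSE] %*% x$linear +
    pc[, seq_len(k), drop = FALSE]^2 %*% x$quadratic
  stats::plogis(drop(eta))
}

#' Default per-stage niches for the synthetic study
#'
#' Stage-specific intercept offsets on a shared warm-season niche, chosen
#' so that a default simulation yields roughly the study-scale prevalence
#' (about 70 percent of visits with at least one detection at species
#' level, nymphs most frequently collected, larvae least).
#'
#' @param n_pc number of PCs the niche spans.
#' @return named list of [true_niche()] objects for larva, nymph, adult.
#' @export
default_true_niche <- function(n_pc = 6) {
  lin <- c(1.1, rep(0, n_pc - 1))
  quad <- c(-0.25, rep(0, n_pc - 1))
  list(larva = true_niche(-0.4, lin, quad),
       nymph = true_niche(1.4, lin, quad),
       adult = true_niche(0.4, lin, quad))
}

#' Simulate detection events at visits from a known niche
#'
#' @param visits visit table from [simulate_visits()].
#' @param pc_stack a `weekly_env` of principal components (from
#'   [project_pca()]).
#' @param truth a single [true_niche()] (events are emitted as stage
#'   `"nymph"`) or a named list of per-stage niches.
#' @param seed RNG seed.
#' @return data.frame of raw detection events (`site_id`, `date`,
#'   `life_stage`), suitable for [assemble_records()].
#' @export
simulate_detections <- function(visits, pc_stack, truth, seed) {
  if (inherits(truth, "true_niche")) truth <- list(nymph = truth)
  set.seed(seed)
  grid <- pc_stack$grid
  cell <- cell_index(grid, visits$lon, visits$lat)
  jday <- julian_day(visits$date)
  year <- as.integer(format(visits$date, "%Y"))
  lab <- paste0(year, "_", period_label(period_of_day(jday)))
  pidx <- match(lab, pc_stack$periods$label)
  if (anyNA(cell) || anyNA(pidx))
    stop("visits outside the PC stack coverage: ",
         paste(sprintf("%s/%s", visits$site_id, visits$date)[is.na(cell) | is.na(pidx)],
               collapse = ", "))
  k <- length(truth[[1]]$linear)
  pc <- t(vapply(seq_along(cell),
                 function(i) pc_stack$values[cell[i], seq_len(k), pidx[i]],
                 numeric(k)))
  rows <- list()
  for (st in names(truth)) {
    p <- niche_probability(truth[[st]], pc)
    hit <- stats::rbinom(length(p), 1, p) == 1
    if (any(hit))
      rows[[st]] <- data.frame(site_id = visits$site_id[hit],
                               date = visits$date[hit], life_stage = st)
  }
  if (length(rows) == 0)
    return(data.frame(site_id = character(), date = as.Date(character()),
                      life_stage = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
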