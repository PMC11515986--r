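#' Assemble presence-absence records from visits and detection events
#'
#' Every sampling visit (one site on one date) yields exactly one record per
#' life stage: a presence if at least one matching detection event occurred
#' during that visit, otherwise an absence. The pooled stage `"all"` matches
#' events of any stage. Duplicate events for the same (site, date, stage)
#' collapse to a single presence, so a presence record is a unique
#' combination of site, date and life stage.
#'
#' @param events data.frame of raw detection events with columns `site_id`,
#'   `date`, `life_stage` (one of `"larva"`, `"nymph"`, `"adult"`). May have
#'   zero rows.
#' @param visits data.frame of all sampling visits with columns `site_id`,
#'   `lon`, `lat`, `date`.
#' @param window optional length-2 `Date` vector; visits outside it are an
#'   error (the study window).
#' @return data.frame of records with columns `site_id`, `lon`, `lat`,
#'   `date`, `year`, `julian_week` (zero-padded starting Julian day of the
#'   8-day period containing `date`), `life_stage`, `detected` (logical);
#'   one row per visit per stage in `c("all", "larva", "nymph", "adult")`.
#' @export
assemble_records <- function(events, visits, window = NULL) {
  stopifnot(all(c("site_id", "lon", "lat", "date") %in% names(visits)))
  visits$date <- as.Date(visits$date)
  if (anyDuplicated(visits[c("site_id", "date")]))
    stop("duplicate (site_id, date) rows in visits")
  if (!is.null(window)) {
    window <- as.Date(window)
    out <- visits$date < window[1] | visits$date > window[2]
    if (any(out))
      stop("visits outside the study window: ",
           paste(sprintf("%s/%s", visits$site_id[out], visits$date[out]),
                 collapse = ", "))
  }
  stages <- c("all", "larva", "nymph", "adult")
  if (nrow(events) > 0) {
    stopifnot(all(c("site_id", "date", "life_stage") %in% names(events)))
    events$date <- as.Date(events$date)
    if (!all(events$life_stage %in% stages[-1]))
      stop("unknown life_stage in events: ",
           paste(unique(setdiff(events$life_stage, stages[-1])), collapse = ", "))
    vkey <- paste(visits$site_id, visits$date)
    ekey <- paste(events$site_id, events$date)
    orphan <- !(ekey %in% vkey)
    if (any(orphan))
      stop("detection events reference unknown visits: ",
           paste(unique(ekey[orphan]), collapse = ", "))
  }
  out <- do.call(rbind, lapply(stages, function(st) {
    rec <- visits
    rec$life_stage <- st
    if (nrow(events) == 0) {
      rec$detected <- FALSE
    } else {
      ev <- if (st == "all") events else events[events$life_stage == st, , drop = FALSE]
      rec$detected <- paste(rec$site_id, rec$date) %in% paste(ev$site_id, ev$date)
    }
    rec
  }))
  out$year <- as.integer(format(out$date, "%Y"))
  out$julian_week <- period_label(period_of_day(julian_day(out$date)))
  rownames(out) <- NULL
  out[c("site_id", "lon", "lat", "date", "year", "julian_week",
        "life_stage", "detected")]
}

#' Read and write presence-absence record tables
#'
#' The CSV format uses the column layout produced by [assemble_records()].
#' `detected` accepts `TRUE`/`FALSE` as well as the `"yes"`/`"no"` dialect
#' (case-insensitive); it is always written back as `TRUE`/`FALSE`. The
#' uniqueness of (site_id, date, life_stage) is enforced on read.
#'
#' @param path CSV file path.
#' @param records a record data.frame as from [assemble_records()].
#' @return `read_records_csv()` returns the record data.frame.
#' @export
read_records_csv <- function(path) {
  need <- c("site_id", "lon", "lat", "date", "year", "julian_week",
            "life_stage", "detected")
  df <- utils::read.csv(path, colClasses = c(julian_week = "character"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("records CSV is missing columns: ", paste(miss, collapse = ", "))
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop("malformed date in records CSV at row(s): ",
         paste(which(is.na(date)), collapse = ", "))
  df$date <- date
  det <- tolower(as.character(df$detected))
  map <- c("true" = TRUE, "false" = FALSE, "yes" = TRUE, "no" = FALSE)
  if (!all(det %in% names(map)))
    stop("unrecognized detected values: ",
         paste(unique(det[!det %in% names(map)]), collapse = ", "))
  df$detected <- unname(map[det])
  key <- paste(df$site_id, df$date, df$life_stage)
  if (anyDuplicated(key))
    stop("duplicate (site_id, date, life_stage) records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df[need]
}

#' @rdname read_records_csv
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of the modelling workflow with the defaults used
#' throughout: 10-fold cross-validation, 1000 randomization draws, 999
#' PERMANOVA permutations, AUC >= 0.5 and TSS >= 0.4 performance filters,
#' delta-AIC <= 2 retention, and the |r| > 0.8 collinearity flag.
#'
#' @param study_extent named list or vector with `xmin`, `xmax`, `ymin`,
#'   `ymax` (lon/lat degrees).
#' @param years integer vector of study years.
#' @param variables ordered names of the six climate variables.
#' @param k_folds folds for cross-validation.
#' @param n_randomization draws for the univariate randomization null.
#' @param n_permutation PERMANOVA permutations.
#' @param auc_min,tss_min,delta_aic_max model-selection filter thresholds.
#' @param correlation_flag absolute Pearson r above which a variable pair
#'   is flagged collinear.
#' @param seed master RNG seed, recorded in all outputs.
#' @return a list of class `run_config`.
#' @export
run_config <- function(study_extent = c(xmin = -103, xmax = -94.43,
                                        ymin = 33.62, ymax = 40),
                       years = 2020:2022,
                       variables = c("tmax", "tmin", "prcp", "srad", "vp", "dayl"),
                       k_folds = 10, n_randomization = 1000,
                       n_permutation = 999, auc_min = 0.5, tss_min = 0.4,
                       delta_aic_max = 2, correlation_flag = 0.8, seed = 1) {
  stopifnot(length(variables) >= 1, k_folds >= 2, n_randomization >= 1,
            n_permutation >= 1)
  structure(list(study_extent = as.list(study_extent), years = years,
                 variables = variables, k_folds = k_folds,
                 n_randomization = n_randomization,
                 n_permutation = n_permutation, auc_min = auc_min,
                 tss_min = tss_min, delta_aic_max = delta_aic_max,
                 correlation_flag = correlation_flag, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path a YAML file whose keys override the defaults (a `simulation:`
#'   block, if present, is passed to [sim_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation
  y$simulation <- NULL
  args <- y[names(y) %in% names(formals(run_config))]
  cfg <- do.call(run_config, args)
  if (!is.null(sim)) cfg$simulation <- do.call(sim_config, sim)
  cfg
}

# deterministic per-stage sub-seed from the master seed; keeps every stage
# independently reproducible and all seeds below 2^31
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "sites", "visits", "detect", "pca",
                        "folds", "signal", "permanova", "subsample"))
  stopifnot(!is.na(idx))
  as.integer((as.numeric(seed) * 48271 + idx * 1000003) %% 2147483647)
}
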