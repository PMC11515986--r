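#' Run the complete modelling workflow on synthetic data
#'
#' Executes the five workflow steps end to end: (1) simulate daily
#' environment, sites and condition-gated visits and assemble
#' presence-absence records; (2) composite to 8-day periods, screen
#' correlations, fit and apply the PCA, and annotate records; (3) run the
#' niche-signal tests; (4) calibrate the ensemble per requested life
#' stage; (5) project weekly suitability, smooth, aggregate to months,
#' extract site series, and run the MOP extrapolation analysis. Every
#' random draw derives deterministically from `config$seed` via per-stage
#' sub-seeds, so any stage is independently reproducible.
#'
#' @param config a [run_config()]; its `simulation` entry (a
#'   [sim_config()]) defines the synthetic study; if absent, defaults are
#'   used with the config's seed.
#' @param stages life stages to calibrate and project
#'   (subset of `c("all", "larva", "nymph", "adult")`).
#' @param truth per-stage [true_niche()] list (default
#'   [default_true_niche()]).
#' @param mop_percent MOP nearest-fraction parameter (percent).
#' @param n_pc number of leading principal components used as model
#'   predictors (default: all six, as in the full workflow).
#' @param verbose log stage progress.
#' @return a list of class `enm_run`: `manifest` (a `run_manifest` of
#'   seeds, counts and output fingerprints), `data` (records, annotated
#'   records, stacks, PCA, correlation report), `signal` (univariate table
#'   and PERMANOVA), and per-stage `models` and `projections`.
#' @export
run_pipeline <- function(config = run_config(), stages = "all",
                         truth = default_true_niche(), mop_percent = 5,
                         n_pc = length(config$variables), verbose = FALSE) {
  stopifnot(all(stages %in% c("all", "larva", "nymph", "adult")))
  say <- function(...) if (verbose) message(sprintf(...))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage [%s] failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sim <- config$simulation
  if (is.null(sim)) sim <- sim_config(years = config$years, seed = config$seed)
  seeds <- vapply(c("simulate", "sites", "visits", "detect", "pca", "folds",
                    "signal", "permanova"),
                  function(s) stage_seed(sim$seed, s), integer(1))

  say("step 1: simulating environment, sites and visits")
  daily <- step("simulate", generate_daily_environment(sim))
  sites <- step("sites", generate_sites(sim))
  visits <- step("visits", simulate_visits(sites, daily, sim))

  say("step 2: compositing, PCA, extraction")
  weekly <- step("composite", composite_8day(daily))
  pooled <- matrix(aperm(weekly$values, c(1, 3, 2)),
                   ncol = length(weekly$variables),
                   dimnames = list(NULL, weekly$variables))
  correlation <- step("correlation", correlation_screen(
    pooled, threshold = config$correlation_flag))
  pca <- step("pca", fit_pca(weekly, seed = seeds[["pca"]]))
  pc_weekly <- step("pca", project_pca(weekly, pca))

  events <- step("detect", simulate_detections(visits, pc_weekly, truth,
                                               seed = seeds[["detect"]]))
  records <- step("assemble", assemble_records(events, visits))
  annotated <- step("extract", extract_at_records(records, weekly, pc_weekly))

  say("step 3: niche-signal tests")
  ann_all <- annotated[annotated$life_stage == "all", , drop = FALSE]
  signal <- step("signal", summarize_signals(
    ann_all, config$variables, n_rep = config$n_randomization,
    seed = seeds[["signal"]]))
  perm <- step("permanova", permanova(
    ann_all, config$variables, n_permutations = config$n_permutation,
    seed = seeds[["permanova"]]))

  models <- list()
  projections <- list()
  for (st in stages) {
    say("step 4: calibrating stage %s", st)
    ann <- annotated[annotated$life_stage == st, , drop = FALSE]
    pcs <- paste0("PC", seq_len(n_pc))
    ens <- step(paste0("calibrate/", st), enm_calibrate(
      ann, predictors = pcs, k = config$k_folds, seed = seeds[["folds"]],
      auc_min = config$auc_min, tss_min = config$tss_min,
      delta_aic_max = config$delta_aic_max))
    models[[st]] <- ens
    say("step 5: projecting stage %s", st)
    suit <- step(paste0("predict/", st), predict_weekly(ens, pc_weekly))
    smoothed <- step(paste0("smooth/", st), smooth_moving_window(suit))
    monthly <- step(paste0("monthly/", st), monthly_average(suit))
    series <- step(paste0("series/", st), site_time_series(
      suit, sites, raw_stack = weekly, overlay_vars = c("tmax", "vp")))
    mop <- step(paste0("mop/", st), mop_stack(
      ann[, pcs, drop = FALSE], pc_weekly, percent = mop_percent))
    mop_monthly <- step(paste0("mop/", st), monthly_mop_summary(mop))
    masked <- step(paste0("mop/", st), mask_predictions(suit, mop))
    projections[[st]] <- list(weekly = suit, smoothed = smoothed,
                              monthly = monthly, series = series, mop = mop,
                              mop_monthly = mop_monthly, masked = masked)
  }

  manifest <- structure(list(
    config = config, sim = sim, seeds = seeds, stages = stages,
    counts = list(
      visits = nrow(visits),
      records = nrow(records),
      presences = vapply(split(records$detected, records$life_stage), sum,
                         integer(1)),
      filter_counts = lapply(models, function(m) m$selection$filter_counts)),
    fingerprints = c(
      list(weekly_env = fingerprint(weekly$values),
           pc_weekly = fingerprint(pc_weekly$values)),
      stats::setNames(lapply(stages, function(st) fingerprint(
        projections[[st]]$weekly$values)), paste0("suitability_", st = stages))),
    timestamp_free = TRUE), class = "run_manifest")

  structure(list(manifest = manifest,
                 data = list(daily = daily, sites = sites, visits = visits,
                             records = records, annotated = annotated,
                             weekly = weekly, pc_weekly = pc_weekly,
                             pca = pca, correlation = correlation),
                 signal = list(table = signal, permanova = perm),
                 models = models, projections = projections),
            class = "enm_run")
}

# deterministic numeric fingerprint of an array (content summary used for
# the reproducibility manifest)
fingerprint <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  sprintf("%.12g|%.12g|%d", sum(x), sum(x^2), length(x))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run manifest\n")
  cat("  seeds:", paste(sprintf("%s=%d", names(x$seeds), x$seeds),
                        collapse = " "), "\n")
  cat(sprintf("  visits: %d; records: %d; presences: %s\n",
              x$counts$visits, x$counts$records,
              paste(sprintf("%s=%d", names(x$counts$presences),
                            x$counts$presences), collapse = " ")))
  for (st in names(x$counts$filter_counts))
    cat(sprintf("  filters [%s]: %s\n", st,
                paste(sprintf("%s=%d", names(x$counts$filter_counts[[st]]),
                              x$counts$filter_counts[[st]]), collapse = " -> ")))
  invisible(x)
}

#' @export
print.enm_run <- function(x, ...) {
  print(x$manifest)
  invisible(x)
}
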