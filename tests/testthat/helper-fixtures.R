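# shared small synthetic study, built once per test run
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- sim_config(grid = env_grid(10, 10, -103, -94.43, 33.62, 40),
                        years = 2020:2021, seed = 7)
      daily <- generate_daily_environment(sim)
      sites <- generate_sites(sim)
      visits <- simulate_visits(sites, daily, sim)
      weekly <- composite_8day(daily)
      pca <- fit_pca(weekly, seed = 11)
      pc_weekly <- project_pca(weekly, pca)
      events <- simulate_detections(visits, pc_weekly, default_true_niche(),
                                    seed = 99)
      records <- assemble_records(events, visits)
      annotated <- extract_at_records(records, weekly, pc_weekly)
      cache <<- list(sim = sim, daily = daily, sites = sites,
                     visits = visits, weekly = weekly, pca = pca,
                     pc_weekly = pc_weekly, events = events,
                     records = records, annotated = annotated,
                     ann_all = annotated[annotated$life_stage == "all", ])
    }
    cache
  }
})

# small ensemble on two PCs (15 candidates), for method-level tests
small_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- small_run()
      cache <<- enm_calibrate(d$ann_all, predictors = c("PC1", "PC2"),
                              k = 5, seed = 3)
    }
    cache
  }
})

# tiny visit/event tables for record-assembly tests
toy_visits <- function(n = 5) {
  data.frame(site_id = paste0("s", seq_len(n)),
             lon = -100 + 0.1 * seq_len(n), lat = 35 + 0.1 * seq_len(n),
             date = as.Date("2021-06-01") + seq_len(n) - 1)
}
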