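test_that("compositing yields 46 periods per year with correct last-period lengths", {
  d <- small_run()
  w <- d$weekly
  expect_equal(nrow(w$periods), 92)
  for (y in 2020:2021)
    expect_equal(sum(w$periods$year == y), 46)
  expect_equal(w$periods$ndays[w$periods$year == 2020 & w$periods$start == 361], 6)
  expect_equal(w$periods$ndays[w$periods$year == 2021 & w$periods$start == 361], 5)
})

test_that("composite values are the arithmetic means of daily values", {
  d <- small_run()
  arr <- d$daily$data[["2021"]]
  # brute-force oracle at a few cell/period/variable combinations
  for (case in list(c(5, 1), c(77, 20), c(40, 46))) {
    cell <- case[1]; pi <- case[2]
    start <- period_starts()[pi]
    len <- period_length(start, 2021)
    days <- start:(start + len - 1)
    idx <- which(d$weekly$periods$year == 2021)[pi]
    for (v in seq_along(d$weekly$variables))
      expect_equal(d$weekly$values[cell, v, idx], mean(arr[cell, v, days]))
  }
})

test_that("a constant field composites to the same constant", {
  g <- env_grid(4, 4, 0, 4, 0, 4)
  daily <- structure(list(grid = g, variables = "x", years = 2021,
                          data = list("2021" = array(0.7, c(16, 1, 365)))),
                     class = "daily_env")
  w <- composite_8day(daily)
  expect_true(all(w$values == 0.7))
})

test_that("missing daily layers are reported", {
  g <- env_grid(4, 4, 0, 4, 0, 4)
  daily <- structure(list(grid = g, variables = "x", years = 2021,
                          data = list("2021" = array(1, c(16, 1, 360)))),
                     class = "daily_env")
  expect_error(composite_8day(daily), "expected 365")
})

test_that("correlation screen matches hand computation and flags collinearity", {
  # 5-point toy table, r computed by hand from the definition
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rep <- correlation_screen(cbind(a = x, b = y), threshold = 0.8)
  expect_equal(rep$r["a", "b"], r_hand)
  expect_equal(diag(rep$r), c(a = 1, b = 1))
  expect_true(isSymmetric(rep$r))
  expect_equal(rep$flagged$r, r_hand)  # |r| ~ 0.83 > 0.8

  # duplicated column is flagged at r = 1
  rep2 <- correlation_screen(cbind(a = x, b = x + 0))
  expect_equal(rep2$r["a", "b"], 1)
  expect_equal(nrow(rep2$flagged), 1)

  # independent columns stay unflagged (Monte-Carlo)
  set.seed(42)
  z <- matrix(rnorm(2e4), ncol = 2, dimnames = list(NULL, c("u", "v")))
  rep3 <- correlation_screen(z)
  expect_lt(abs(rep3$r["u", "v"]), 0.05)
  expect_equal(nrow(rep3$flagged), 0)

  # zero-variance column: NA with warning
  expect_warning(rep4 <- correlation_screen(cbind(a = x, c = rep(1, 5))),
                 "zero-variance")
  expect_true(is.na(rep4$r["a", "c"]))
})

test_that("simulated variables reproduce the strong temperature/daylength collinearity", {
  d <- small_run()
  pooled <- matrix(aperm(d$weekly$values, c(1, 3, 2)), ncol = 6,
                   dimnames = list(NULL, d$weekly$variables))
  rep <- correlation_screen(pooled, threshold = 0.8)
  flagged_pairs <- paste(rep$flagged$var1, rep$flagged$var2)
  expect_true("tmax tmin" %in% flagged_pairs)
  expect_true(any(grepl("vp", flagged_pairs)))
})

test_that("PCA transform is orthonormal with normalized, non-increasing variance", {
  d <- small_run()
  p <- d$pca
  expect_equal(t(p$loadings) %*% p$loadings, diag(6), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_true(all(p$variance_fraction >= 0))
  # sign convention: dominant loading of each component is positive
  for (j in 1:6)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("projection back-rotates to the standardized values", {
  d <- small_run()
  pooled <- matrix(aperm(d$weekly$values, c(1, 3, 2)), ncol = 6,
                   dimnames = list(NULL, d$weekly$variables))
  sub <- pooled[seq(1, nrow(pooled), by = 37), ]
  scores <- project_pca(as.data.frame(sub), d$pca)
  z <- scale(sub, center = d$pca$center, scale = d$pca$scale)
  expect_equal(scores %*% t(d$pca$loadings), unclass(z), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("a dominant seasonal axis loads temperature, day length and vapor pressure", {
  d <- small_run()
  expect_gt(d$pca$variance_fraction[1], 2 * d$pca$variance_fraction[2])
  l1 <- d$pca$loadings[, 1]
  expect_true(all(abs(l1[c("tmin", "tmax", "dayl", "vp")]) > 0.3))
})

test_that("PCA serialization round-trips through JSON", {
  d <- small_run()
  path <- tempfile(fileext = ".json")
  write_pca_json(d$pca, path)
  back <- read_pca_json(path)
  expect_equal(back$center, d$pca$center)
  expect_equal(back$scale, d$pca$scale)
  expect_equal(back$loadings, d$pca$loadings, ignore_attr = TRUE)
  expect_equal(back$variance_fraction, d$pca$variance_fraction)
})

test_that("zero-variance variables make scaling fail loudly", {
  g <- env_grid(4, 4, 0, 4, 0, 4)
  periods <- data.frame(year = 2021, start = 1, label = "2021_001", ndays = 8)
  vals <- array(c(rnorm(16), rep(1, 16)), c(16, 2, 1))
  w <- weekly_env(g, c("a", "b"), periods, vals)
  expect_error(fit_pca(w), "zero-variance")
})

test_that("extraction picks the period containing the record's date", {
  d <- small_run()
  rec <- d$records[d$records$life_stage == "all", ][1:3, ]
  rec$date <- as.Date(c("2021-01-09", "2021-12-31", "2021-01-08"))
  rec$year <- 2021L
  rec$julian_week <- period_label(period_of_day(julian_day(rec$date)))
  expect_equal(rec$julian_week, c("009", "361", "001"))
  ann <- extract_at_records(rec, d$weekly, d$pc_weekly)
  cell <- cell_index(d$weekly$grid, rec$lon, rec$lat)
  for (i in 1:3) {
    pidx <- match(paste0("2021_", rec$julian_week[i]), d$weekly$periods$label)
    expect_equal(ann$tmax[i], d$weekly$values[cell[i], 1, pidx])
    expect_equal(ann$PC1[i], d$pc_weekly$values[cell[i], 1, pidx])
  }
})

test_that("extracted values equal the daily-data oracle (commutation)", {
  d <- small_run()
  ann <- d$ann_all[1:10, ]
  cell <- cell_index(d$weekly$grid, ann$lon, ann$lat)
  for (i in seq_len(nrow(ann))) {
    y <- ann$year[i]
    start <- as.integer(ann$julian_week[i])
    days <- start:(start + period_length(start, y) - 1)
    arr <- d$daily$data[[as.character(y)]]
    for (v in seq_along(d$weekly$variables))
      expect_equal(ann[[d$weekly$variables[v]]][i],
                   mean(arr[cell[i], v, days]))
  }
})

test_that("records outside coverage are listed in the error", {
  d <- small_run()
  rec <- d$records[1:2, ]
  rec$lon[1] <- -150
  expect_error(extract_at_records(rec, d$weekly, d$pc_weekly),
               "outside grid or period")
})

test_that("stack CSV serialization round-trips", {
  d <- small_run()
  path <- tempfile(fileext = ".csv")
  sub <- d$weekly
  keep <- 1:4
  sub <- weekly_env(sub$grid, sub$variables, sub$periods[keep, ],
                    sub$values[, , keep, drop = FALSE])
  write_stack_csv(sub, path)
  back <- read_stack_csv(path, years = 2020)
  expect_equal(back$values, sub$values, ignore_attr = TRUE)
  expect_equal(back$periods$label, sub$periods$label)
})
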