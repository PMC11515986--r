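test_that("formula enumeration covers all non-empty term subsets exactly once", {
  f1 <- enumerate_formulas(1, "x")
  expect_equal(length(f1), 3)
  expect_setequal(vapply(f1, paste, character(1), collapse = "+"),
                  c("x", "I(x^2)", "x+I(x^2)"))
  f2 <- enumerate_formulas(2)
  expect_equal(length(f2), 15)  # 2^4 - 1
  for (n in 1:3) {
    fn <- enumerate_formulas(n)
    expect_equal(length(fn), 2^(2 * n) - 1)
    keys <- vapply(fn, function(t) paste(sort(t), collapse = "|"), character(1))
    expect_false(any(duplicated(keys)))
  }
  expect_error(enumerate_formulas(0), ">= 1")
})

test_that("logistic fits match glm and the hand-evaluated Bernoulli likelihood", {
  set.seed(14)
  d <- data.frame(PC1 = rnorm(100))
  d$detected <- rbinom(100, 1, plogis(0.3 + 0.8 * d$PC1)) == 1
  fit <- fit_logistic(c("PC1", "I(PC1^2)"), d)
  ref <- glm(detected ~ PC1 + I(PC1^2), binomial(), d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  expect_true(fit$converged)

  # 6-row toy: log-likelihood is the Bernoulli sum at the fitted p
  toy <- data.frame(PC1 = c(-2, -1, 0, 1, 2, 3),
                    detected = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  ft <- fit_logistic("PC1", toy)
  p <- predict(ft, toy)
  expect_equal(ft$log_likelihood,
               sum(log(ifelse(toy$detected, p, 1 - p))))
  expect_equal(ft$aic, 2 * 2 - 2 * ft$log_likelihood)
})

test_that("null data give near-zero coefficients and separation is flagged", {
  set.seed(2)
  d <- data.frame(PC1 = rnorm(400),
                  detected = rep(c(TRUE, FALSE), 200))
  fit <- fit_logistic("PC1", d)
  expect_lt(abs(fit$coefficients["(Intercept)"]), 0.3)
  expect_lt(abs(fit$coefficients["PC1"]), 0.3)

  sep <- data.frame(PC1 = c(-2, -1, 1, 2),
                    detected = c(FALSE, FALSE, TRUE, TRUE))
  fs <- fit_logistic("PC1", sep)
  expect_false(fs$converged)
  expect_error(fit_logistic("PC1", data.frame(PC1 = 1:3,
                                              detected = c(TRUE, TRUE, TRUE))),
               "presence and one absence")
})

test_that("simulated quadratic niches are recovered within 2 SE in >= 90% of seeds", {
  hits <- t(vapply(1:100, function(s) {
    set.seed(1000 + s)
    pc <- rnorm(2000)
    p <- plogis(1 - 0.5 * pc^2)
    d <- data.frame(PC1 = pc, detected = rbinom(2000, 1, p) == 1)
    fit <- fit_logistic(c("PC1", "I(PC1^2)"), d)
    truth <- c(1, 0, -0.5)
    abs(fit$coefficients - truth) <= 2 * fit$se
  }, logical(3)))
  # each coefficient recovered within 2 SE in at least 90% of seeds
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  pairwise_auc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  s8 <- c(0.1, 0.4, 0.4, 0.5, 0.6, 0.6, 0.9, 0.2)
  l8 <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(auc_rank(s8, l8), pairwise_auc(s8, l8))
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(l) && !all(l))
      expect_equal(auc_rank(s, l), pairwise_auc(s, l))
  }
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "one class")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(60)
  l <- rbinom(60, 1, 0.5) == 1
  expect_equal(auc_rank(s, l),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s)))),
               tolerance = 1e-10)
})

test_that("maxTSS threshold matches an exhaustive cutpoint scan", {
  scan_oracle <- function(pred, lab) {
    u <- sort(unique(pred))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    tss <- vapply(cand, function(t) {
      sens <- mean(pred[lab] >= t)
      spec <- mean(pred[!lab] < t)
      sens + spec - 1
    }, numeric(1))
    list(thr = cand[which.max(tss)], tss = max(tss))
  }
  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    pred <- round(runif(n), 2)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    o <- scan_oracle(pred, lab)
    thr <- select_threshold(pred, lab)
    expect_equal(thr, o$thr)
    expect_equal(confusion_metrics(pred, lab, thr)$tss, o$tss)
  }
})

test_that("TSS is sensitivity plus specificity minus one", {
  # counts that reproduce the published per-model sensitivities exactly
  pred <- c(rep(0.9, 839), rep(0.1, 161), rep(0.1, 96), rep(0.9, 4))
  lab <- c(rep(TRUE, 1000), rep(FALSE, 100))
  cm <- confusion_metrics(pred, lab, 0.5)
  expect_equal(cm$sensitivity, 0.839)
  expect_equal(cm$specificity, 0.96)
  expect_equal(cm$tss, 0.799)
  expect_equal(confusion_metrics(c(1, 0), c(TRUE, FALSE), 0.5)$tss, 1)
})

test_that("cross-validation is deterministic and stratified", {
  d <- small_run()
  a <- kfold_evaluate(c("PC1", "I(PC1^2)"), d$ann_all, k = 10, seed = 42)
  b <- kfold_evaluate(c("PC1", "I(PC1^2)"), d$ann_all, k = 10, seed = 42)
  expect_identical(a, b)
  expect_equal(a$folds_used, 10)
  expect_true(a$auc > 0 && a$auc <= 1)
  expect_equal(a$tss, a$sensitivity + a$specificity - 1, tolerance = 1e-12)
  folds <- questenm:::stratified_folds(d$ann_all$detected, 10, 42)
  pos_per_fold <- table(folds[d$ann_all$detected])
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("leave-one-out evaluation equals the brute-force oracle", {
  set.seed(61)
  d <- data.frame(PC1 = rnorm(12),
                  detected = rep(c(TRUE, FALSE), 6))
  n <- nrow(d)
  res <- kfold_evaluate("PC1", d, k = n, seed = 1,
                        folds = seq_len(n))  # fold i = record i
  # oracle: refit with glm leaving each record out, pool predictions
  pooled <- vapply(seq_len(n), function(i) {
    g <- glm(detected ~ PC1, binomial(), d[-i, ])
    unname(predict(g, d[i, , drop = FALSE], type = "response"))
  }, numeric(1))
  gfull <- glm(detected ~ PC1, binomial(), d)
  thr <- select_threshold(predict(gfull, type = "response"), d$detected)
  expect_equal(res$auc, auc_rank(pooled, d$detected), tolerance = 1e-8)
  cm <- confusion_metrics(pooled, d$detected, thr)
  expect_equal(res$sensitivity, cm$sensitivity, tolerance = 1e-8)
  expect_equal(res$tss, cm$tss, tolerance = 1e-8)
  expect_equal(res$folds_used, 0)
})

test_that("Akaike weights follow the exponential delta rule", {
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  set.seed(1)
  for (i in 1:20) {
    w <- akaike_weights(runif(sample(2:10, 1), 0, 10))
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
  }
  # weights are monotone decreasing in delta
  w <- akaike_weights(c(0, 1, 2, 5))
  expect_true(all(diff(w) < 0))
})

# stub candidates for the selection cascade
stub_candidate <- function(aic, quad = NULL, auc = 0.9, tss = 0.6,
                           converged = TRUE, terms = "PC1") {
  coefs <- c("(Intercept)" = 0.1, stats::setNames(0.5, terms[1]))
  if (!is.null(quad)) {
    terms <- c(terms, "I(PC1^2)")
    coefs <- c(coefs, "I(PC1^2)" = quad)
  }
  list(fit = list(terms = terms, coefficients = coefs, aic = aic,
                  converged = converged),
       cv = list(threshold = 0.5, auc = auc, sensitivity = 0.8,
                 specificity = 0.8, tss = tss))
}

test_that("the four filters apply sequentially with the documented boundaries", {
  cands <- list(stub_candidate(100, quad = -0.2),
                stub_candidate(101.9, quad = -0.1),
                stub_candidate(99, quad = 0.3),        # positive quadratic
                stub_candidate(98, quad = -0.5, auc = 0.45),  # fails AUC
                stub_candidate(97, quad = -0.5, tss = 0.3),   # fails TSS
                stub_candidate(96, quad = -0.5, converged = FALSE))
  sel <- filter_models(cands)
  expect_equal(unname(sel$filter_counts["candidates"]), 6)
  expect_equal(unname(sel$filter_counts["unimodal"]), 4)  # 1,2,4,5 survive
  expect_equal(unname(sel$filter_counts["auc"]), 3)       # drop AUC 0.45
  expect_equal(unname(sel$filter_counts["tss"]), 2)       # drop TSS 0.3
  expect_equal(sel$selected, c(1, 2))                     # delta 0 and 1.9
  expect_equal(sel$delta_aic, c(0, 1.9))

  # 102.1 falls outside the delta-AIC <= 2 window
  cands2 <- list(stub_candidate(100, quad = -0.2),
                 stub_candidate(102.1, quad = -0.1))
  sel2 <- filter_models(cands2)
  expect_equal(sel2$selected, 1)
  expect_equal(sel2$weights, 1)

  # delta is computed relative to the minimum among filter-1..3 survivors
  cands3 <- list(stub_candidate(90, quad = 0.3),   # best AIC but bimodal
                 stub_candidate(100, quad = -0.2),
                 stub_candidate(101, quad = -0.1))
  sel3 <- filter_models(cands3)
  expect_equal(sel3$delta_aic, c(0, 1))

  expect_error(filter_models(list(stub_candidate(1, quad = 0.5))),
               "no admissible")
})

test_that("AIC ordering is invariant to consistent predictor rescaling", {
  d <- small_run()
  ann <- d$ann_all
  scaled <- ann
  scaled$PC1 <- 2 * scaled$PC1
  scaled$PC2 <- 0.5 * scaled$PC2
  for (terms in list("PC1", c("PC1", "I(PC1^2)"),
                     c("PC1", "PC2", "I(PC2^2)"))) {
    a <- fit_logistic(terms, ann)$aic
    b <- fit_logistic(terms, scaled)$aic
    expect_equal(a, b, tolerance = 1e-6)
  }
})
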