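test_that("Mann-Whitney U matches enumeration on the worked examples", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p, 0.1)   # 2 of the 20 labelings are as extreme
  expect_identical(m$method, "exact")

  # identical multisets tie everything; exchangeability forces p = 1
  m2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(m2$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, NA), c(2, 3)), "finite")
})

test_that("exact p is invariant under strictly monotone transforms", {
  set.seed(2)
  x <- rnorm(5); y <- rnorm(6)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  c3 <- mann_whitney_u(x^3, y^3)
  expect_equal(a$p, b$p)
  expect_equal(a$U, b$U)
  expect_equal(a$p, c3$p)
})

test_that("exact enumeration agrees with the combn brute-force oracle", {
  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    m <- mann_whitney_u(x, y)
    expect_identical(m$method, "exact")
    expect_equal(m$p, oracle_mwu_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p closely at n1=n2=8", {
  # the maximum deviation of the continuity-corrected normal approximation
  # from the exact two-sided p at n1 = n2 = 8 is 0.0109 (at U = 24),
  # computable by enumerating the null distribution; the band below is that
  # provable bound, not a fitted one
  set.seed(23)
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, -1, 1))
    exact <- mann_whitney_u(x, y)$p
    approx <- mann_whitney_u(x, y, exact_limit = 0L)$p
    expect_lt(abs(exact - approx), 0.011)
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  m <- mann_whitney_u(x, y)
  expect_identical(m$method, "normal")
  # base R with identical corrections is an independent oracle here
  w <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                           exact = FALSE))
  expect_equal(m$U, unname(w$statistic))
  expect_equal(m$p, w$p.value, tolerance = 1e-10)
})

test_that("screening flags only sub-alpha features and survives constants", {
  co <- bare_cohort(10, 10)
  set.seed(3)
  co$signal <- c(rnorm(10), rnorm(10, 5))
  co$noise <- rnorm(20)
  co$constant <- 1
  sc <- screen_features(co, alpha = 0.05)
  expect_true(sc$significant[sc$feature == "signal"])
  expect_false(sc$significant[sc$feature == "constant"])
  expect_equal(sc$p[sc$feature == "constant"], 1)
  # alpha = 0 flags nothing
  expect_false(any(screen_features(co, alpha = 0)$significant))
  # identical groups are never flagged
  co2 <- bare_cohort(5, 5)
  co2$f <- rep(c(1, 2, 3, 4, 5), 2)
  expect_false(screen_features(co2, alpha = 0.05)$significant)
})

test_that("lasso_select is reproducible, stratified, and shrinks to empty", {
  co <- generate_feature_cohort(seed = 2L)
  feats <- relative_feature_names()
  a <- lasso_select(co, feats, seed = 10L)
  b <- lasso_select(co, feats, seed = 10L)
  expect_identical(a$selected, b$selected)
  expect_identical(a$foldid, b$foldid)
  expect_true(all(a$selected %in% feats))
  # folds are outcome-stratified: every fold contains both classes
  for (f in unique(a$foldid)) {
    cls <- co$outcome[a$foldid == f]
    expect_identical(length(unique(as.character(cls))), 2L)
  }
  # at the top of the path the penalty dominates and the active set is empty
  top <- as.matrix(stats::coef(a$fit$glmnet.fit,
                               s = max(a$lambda_path)))[-1, 1]
  expect_true(all(top == 0))
  expect_error(lasso_select(co, feats[1]), "at least 2")
  expect_error(lasso_select(co, feats, n_folds = 25L), "fewer than n_folds")
})

test_that("a strongly separating feature is selected in nearly every seed", {
  hits <- vapply(1:40, function(s) {
    set.seed(s + 5000)
    co <- bare_cohort(20, 20)
    co$strong <- c(rnorm(20, 0), rnorm(20, 2))   # d ~ 2
    for (j in 1:9) co[[paste0("noise", j)]] <- rnorm(40)
    sel <- lasso_select(co, cohort_features <- setdiff(names(co),
                                                       c("subject_id",
                                                         "outcome")),
                        seed = s)
    "strong" %in% sel$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duplicating a selected feature leaves CV deviance unchanged", {
  set.seed(77)
  co <- bare_cohort(20, 20)
  co$a <- c(rnorm(20), rnorm(20, 1.5))
  co$b <- rnorm(40)
  co$c <- rnorm(40)
  s1 <- lasso_select(co, c("a", "b", "c"), seed = 4L)
  co$a2 <- co$a
  s2 <- lasso_select(co, c("a", "b", "c", "a2"), seed = 4L)
  cv1 <- s1$cvm[which.min(abs(s1$lambda_path - s1$lambda))]
  cv2 <- s2$cvm[which.min(abs(s2$lambda_path - s1$lambda))]
  expect_lte(cv2, cv1 + 1e-4)
})

test_that("logistic combination behaves on degenerate and separable data", {
  co <- bare_cohort(10, 10)
  co$flat <- 0
  m <- fit_logistic(co, "flat")
  expect_equal(m$intercept, 0, tolerance = 1e-9)
  expect_equal(m$fitted, rep(0.5, 20), tolerance = 1e-9)

  co$sep <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(co, "sep"), "complete separation")
  r <- fit_logistic(co, "sep", ridge_epsilon = 0.05)
  expect_true(r$ridged)
  expect_true(all(is.finite(r$scores)))
  expect_equal(roc_analysis(r$scores, co$outcome)$auc, 1)
})

test_that("a one-feature model score reproduces the raw feature's ROC", {
  set.seed(12)
  co <- bare_cohort(15, 15)
  co$f <- c(rnorm(15), rnorm(15, 1))
  m <- fit_logistic(co, "f")
  r1 <- roc_analysis(m$scores, co$outcome)
  r2 <- roc_analysis(co$f, co$outcome)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$specificity, r2$specificity)
})

test_that("ROC handles separation, ties and the worked pair-count example", {
  out <- c(rep("unfavorable", 2), rep("favorable", 2))
  r <- roc_analysis(c(0.9, 0.8, 0.7, 0.85), out)
  expect_equal(r$auc, 0.75)   # 3 wins of 4 pairs

  perf <- roc_analysis(c(5, 6, 1, 2), out)
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)

  ties <- roc_analysis(rep(1, 4), out)
  expect_equal(ties$auc, 0.5)

  expect_error(roc_analysis(1:3, rep("favorable", 3)), "both classes")
})

test_that("ROC internals: raw symmetry, DeLong SE, CI and Youden cutoff", {
  set.seed(6)
  out <- rep(c("unfavorable", "favorable"), c(12, 20))
  s <- c(rnorm(12, 1), rnorm(20))
  r <- roc_analysis(s, out)
  rn <- roc_analysis(-s, out)
  expect_equal(r$auc_raw + rn$auc_raw, 1)
  expect_identical(rn$direction, "<")
  expect_equal(rn$auc, r$auc)
  expect_gt(r$se, 0)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
  # Youden cutoff maximizes sens + spec over candidate thresholds
  j_best <- r$sensitivity + r$specificity
  for (t in unique(s)) {
    sens <- 100 * mean(s[out == "unfavorable"] >= t)
    spec <- 100 * mean(s[out == "favorable"] < t)
    expect_lte(sens + spec, j_best + 1e-9)
  }
  # closest-to-(0,1) rule is accepted and gives a valid operating point
  r2 <- roc_analysis(s, out, cutoff_rule = "closest01")
  expect_true(r2$sensitivity >= 0 && r2$sensitivity <= 100)
})

test_that("AUC agrees with exhaustive pair counting on random score sets", {
  set.seed(9)
  for (i in 1:60) {
    m <- sample(2:10, 1); n <- sample(2:10, 1)
    pos <- sample(seq(0, 1, 0.1), m, replace = TRUE)  # ties likely
    neg <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    r <- roc_analysis(c(pos, neg),
                      rep(c("unfavorable", "favorable"), c(m, n)))
    expect_equal(r$auc_raw, oracle_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("the permutation null control centres on one half", {
  set.seed(30)
  scores <- rnorm(58)
  out <- rep(c("favorable", "unfavorable"), c(18, 40))
  pc <- permutation_auc_control(scores, out, n_perm = 400, seed = 2L)
  expect_lt(abs(pc$mean_auc - 0.5), 0.03)
  expect_identical(length(pc$aucs), 400L)
})

test_that("run_full_analysis is deterministic and internally consistent", {
  co <- generate_feature_cohort(seed = 42L)
  cfg <- analysis_config(seed = 42L, ridge_epsilon = 0.01)
  a <- run_full_analysis(co, cfg)
  b <- run_full_analysis(co, cfg)
  expect_identical(a$roc_table, b$roc_table)
  expect_identical(a$selected, b$selected)
  # group summary covers all 20 features with finite moments
  expect_identical(nrow(a$group_summary), 20L)
  expect_true(all(is.finite(a$group_summary$mean_favorable)))
  # every selected feature and the combination appear in the ROC table
  expect_setequal(a$roc_table$variable, c(a$selected, "combination"))
  expect_true(all(a$roc_table$auc >= 0.5 & a$roc_table$auc <= 1))
  expect_true(all(a$roc_table$ci_lower <= a$roc_table$auc &
                    a$roc_table$auc <= a$roc_table$ci_upper))
})

test_that("zero-signal cohorts produce no model and an empty ROC table", {
  set.seed(55)
  co <- bare_cohort(18, 40)
  for (f in c("n1", "n2", "n3")) co[[f]] <- rnorm(58)
  rep0 <- run_full_analysis(co, analysis_config(alpha = 1e-6, seed = 1L))
  expect_null(rep0$model)
  expect_identical(nrow(rep0$roc_table), 0L)
})

test_that("AUC equals U/(n1 n2) from the Mann-Whitney statistic", {
  set.seed(13)
  for (i in 1:50) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    pos <- round(rnorm(n1), 1); neg <- round(rnorm(n2), 1)
    r <- roc_analysis(c(pos, neg),
                      rep(c("unfavorable", "favorable"), c(n1, n2)))
    u <- mann_whitney_u(pos, neg)$U
    expect_equal(r$auc_raw, u / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("active set size is non-increasing along increasing lambda", {
  for (sd in c(1L, 8L, 22L)) {
    co <- generate_feature_cohort(seed = sd)
    s <- lasso_select(co, relative_feature_names(), seed = sd)
    nz <- s$fit$nzero   # glmnet reports active-set size at each path knot
    sizes <- as.integer(nz[order(s$lambda_path)])  # increasing lambda
    # the active set of a coordinate-descent LASSO path may transiently
    # drop/re-admit one variable at a knot; monotonicity is asserted up to
    # that unit wiggle
    expect_true(all(sizes <= cummin(c(Inf, sizes))[-1] + 1))
    expect_true(all(diff(sizes) <= 1))
    expect_identical(sizes[length(sizes)], 0L)
  }
})
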