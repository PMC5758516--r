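test_that("the random forest separates well-separated classes", {
  set.seed(1)
  x <- data.frame(f1 = c(rnorm(30, 0), rnorm(30, 3)),
                  f2 = c(rnorm(30, 0), rnorm(30, 3)))
  y <- factor(rep(c("STS", "LTS"), each = 30), levels = c("STS", "LTS"))
  fit <- train_rf(x, y, seed = 2)
  expect_equal(fit$ntree, 50)
  acc <- mean(predict(fit, x) == y)
  expect_gte(acc, 0.95)
  expect_error(train_rf(x, factor(rep("STS", 60))), "single class")
  # deterministic given the seed
  f2 <- train_rf(x, y, seed = 2)
  expect_identical(predict(fit, x), predict(f2, x))
})

test_that("cross-validated predictions aggregate majority votes per patient", {
  set.seed(3)
  n <- 30
  ids <- sprintf("P%02d", seq_len(n))
  groups <- setNames(factor(rep(c("STS", "LTS"), each = 15),
                            levels = c("STS", "MTS", "LTS")), ids)
  ft <- tibble::tibble(patient_id = ids,
                       fA = ifelse(groups == "STS", 0, 5) + rnorm(n, 0, 0.1),
                       fB = rnorm(n))
  plan <- make_cv_plan(as.character(groups), ids = ids, n_folds = 3,
                       n_iterations = 10, seed = 4)
  cvp <- cross_validated_predictions(plan, ft, groups, c("STS", "LTS"),
                                     features = c("fA", "fB"), seed = 5)
  # every patient is tested exactly once per iteration
  expect_true(all(cvp$n_tested == 10))
  # a cleanly separable signal is recovered for every patient
  expect_equal(as.character(cvp$predicted), as.character(groups[cvp$patient_id]))
  # the plan identity guard
  other <- make_cv_plan(as.character(groups), ids = ids, seed = 99)
  expect_error(
    cross_validated_predictions(plan, ft, groups, c("STS", "LTS"),
                                features = c("fA", "fB"),
                                expected_hash = cv_plan_hash(other)),
    "hash")
})

test_that("Kaplan-Meier estimates match product-limit hand calculations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  # censoring at 2: risk set shrinks without a drop
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2/3)
  expect_equal(km2$survival[km2$time == 3], 0)
  # without censoring the KM curve is the empirical survival function
  set.seed(4)
  t <- sample(100, 60, replace = TRUE)
  km3 <- km_estimate(t, rep(1, 60))
  emp <- vapply(km3$time, function(u) mean(t > u), numeric(1))
  expect_equal(km3$survival, emp)
  expect_true(all(diff(km3$survival) <= 0))
  expect_true(all(km3$survival >= 0 & km3$survival <= 1))
})

test_that("log-rank test agrees with its permutation distribution", {
  # identical groups: no signal
  t0 <- c(3, 5, 8, 12, 20)
  lr0 <- logrank_test(rep(t0, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  expect_gte(lr0$chisq, 0)
  # disjoint supports: decisive separation
  lr1 <- logrank_test(c(1:20, 31:50), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_lt(lr1$p, 0.001)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "event")
  # chi-square p agrees with a label-permutation p within Monte-Carlo error
  set.seed(5)
  tt <- c(rexp(18, 1 / 10), rexp(18, 1 / 16))
  ev <- rbinom(36, 1, 0.9)
  gg <- rep(c("a", "b"), each = 18)
  obs <- logrank_test(tt, ev, gg)
  perm <- replicate(2000, logrank_test(tt, ev, sample(gg))$chisq)
  p_perm <- mean(perm >= obs$chisq - 1e-12)
  mc_err <- 4 * sqrt(max(p_perm, 0.01) * (1 - max(p_perm, 0.01)) / 2000)
  expect_lt(abs(obs$p - p_perm), mc_err + 0.02)
})

test_that("Cox fits report hazard ratios faithfully", {
  set.seed(6)
  n <- 200
  x <- rnorm(n)
  os <- rexp(n, rate = exp(0.7 * x) / 10)
  d <- data.frame(os_months = os, event = 1, x = x, x2 = 2 * x)
  fit <- cox_fit(d, "x")
  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_equal(td$estimate, 0.7, tolerance = 0.2)
  # reparameterization: doubling the covariate halves the coefficient
  fit2 <- cox_fit(d, "x2")
  expect_equal(tidy(fit2)$estimate, td$estimate / 2, tolerance = 1e-8)
  expect_equal(fit2$fit$loglik, fit$fit$loglik, tolerance = 1e-8)
  expect_equal(glance(fit)$n, n)
  expect_error(cox_fit(data.frame(os_months = 1:4, event = c(1, 1, 0, 0),
                                  z = c(1, 1, 2, 3)), "z"),
               "constant")
  # null coverage: CI covers zero for an unrelated covariate
  set.seed(7)
  cover <- vapply(seq_len(20), function(r) {
    dd <- data.frame(os_months = rexp(200, 0.1), event = 1,
                     z = rnorm(200))
    ci <- tidy(cox_fit(dd, "z"))
    ci$conf_low < 1 && ci$conf_high > 1  # HR interval covers 1 (coef 0)
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("concordance matches brute-force pair counting", {
  set.seed(8)
  n <- 200
  t <- rexp(n, 0.1)
  ev <- rbinom(n, 1, 0.7)
  risk <- -t + rnorm(n, 0, 5)
  expect_equal(concordance_index(risk, t, ev),
               oracle_concordance(risk, t, ev), tolerance = 1e-12)
  # perfect anti-ordering without censoring
  expect_equal(concordance_index(-t, t, rep(1, n)), 1)
  # symmetry under risk reversal
  c1 <- concordance_index(risk, t, rep(1, n))
  expect_equal(concordance_index(-risk, t, rep(1, n)), 1 - c1,
               tolerance = 1e-12)
  # ties in risk count one half
  tied <- rep(1, n)
  expect_equal(concordance_index(tied, t, rep(1, n)), 0.5)
  expect_equal(oracle_concordance(tied, t, rep(1, n)), 0.5)
  # random risks sit at chance level
  set.seed(9)
  expect_equal(concordance_index(rnorm(500), rexp(500), rep(1, 500)), 0.5,
               tolerance = 0.05)
})

test_that("the survival experiment reports all pairs on both cohorts", {
  set.seed(10)
  n <- 90
  ids <- sprintf("P%03d", seq_len(n))
  h <- runif(n)
  cfg <- cohort_config()
  sv <- lapply(h, generate_survival, config = cfg)
  clinical <- tibble::tibble(
    patient_id = ids,
    split = rep(c("train", "validation"), c(60, 30)),
    os_months = vapply(sv, `[[`, numeric(1), "os_months"),
    event = vapply(sv, `[[`, numeric(1), "event"),
    age = rnorm(n, 58, 12), sex = sample(c("M", "F"), n, TRUE),
    kps = sample(seq(40, 100, 10), n, TRUE),
    group = assign_survival_group(vapply(sv, `[[`, numeric(1), "os_months")))
  # radiomic stand-ins: noisy readouts of h named like real features
  ret <- feature_names()[c(31, 62, 93, 124, 155, 186, 217, 248)]
  ft <- tibble::tibble(patient_id = ids, split = clinical$split)
  for (f in ret) ft[[f]] <- h + rnorm(n, 0, 0.15)
  labels <- setNames(sample(c("low", "mid", "high"), 60, TRUE), ids[1:60])
  plan <- make_cv_plan(labels, ids = ids[1:60], n_iterations = 10, seed = 11)
  rep2 <- suppressWarnings(run_experiment2(clinical, ft, ret, plan, seed = 12))
  expect_named(rep2$pairs, c("STS_vs_LTS", "STS_vs_MTS", "MTS_vs_LTS"))
  for (nm in names(rep2$pairs)) {
    expect_named(rep2$pairs[[nm]], c("training", "validation"))
    for (coh in c("training", "validation")) {
      res <- rep2$pairs[[nm]][[coh]]
      expect_s3_class(res$km, "tbl_df")
      expect_true(all(c("chisq", "p") %in% names(res$logrank)))
    }
  }
  expect_true(all(c("comparison", "feature_set", "hazard_ratio",
                    "c_index_train", "c_index_validation") %in%
                    names(rep2$cox)))
  expect_setequal(unique(rep2$cox$feature_set),
                  c("age", "sex", "kps", "radiomic", "radiomic_clinical"))
  # combined model at least matches radiomic-only when clinical signal exists
  cx <- rep2$cox[rep2$cox$comparison == "STS_vs_LTS", ]
  expect_true(is.finite(cx$c_index_train[cx$feature_set == "radiomic"]))
  p1 <- plot_km_curves(rep2, "STS_vs_LTS", "training")
  expect_s3_class(p1, "ggplot")
})
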