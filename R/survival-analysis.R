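#' Train the survival-group random forest
#'
#' Ensemble of 50 Gini-impurity decision trees on bootstrap resamples
#' (via \pkg{randomForest}), deterministic given the seed.
#'
#' @param features data frame / tibble of predictor columns (the retained
#'   radiomic features).
#' @param labels factor of survival-group labels (two classes for the
#'   pairwise comparisons).
#' @param n_trees number of trees (default 50).
#' @param seed integer seed.
#' @return A `randomForest` classifier.
#' @export
train_rf <- function(features, labels, n_trees = 50L, seed = 1L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("training set contains a single class")
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(features), y = labels,
                             ntree = n_trees)
}

#' Cross-validated per-patient survival-group predictions
#'
#' For one survival-group pair, trains the random forest on every split of
#' the plan and aggregates over all runs in which a patient was a test
#' sample: the patient's label is the majority vote, ties broken by the
#' higher mean predicted probability, then by the worse-prognosis label.
#' The plan must be the same plan used for feature selection (verified by
#' hash when `expected_hash` is given).
#'
#' @param plan a [make_cv_plan()] with patient-id splits.
#' @param feature_table imputed feature tibble with `patient_id`.
#' @param groups named factor of true survival groups per patient id.
#' @param pair character pair, e.g. `c("STS", "LTS")`.
#' @param features which feature columns to use (default: all present).
#' @param n_trees,seed forwarded to [train_rf()].
#' @param expected_hash optional hash the plan must match.
#' @return Tibble (`patient_id`, `predicted`, `votes`, `n_tested`).
#' @export
cross_validated_predictions <- function(plan, feature_table, groups, pair,
                                        features = NULL, n_trees = 50L,
                                        seed = 1L,
                                        expected_hash = NULL) {
  if (!is.null(expected_hash) && !identical(cv_plan_hash(plan), expected_hash))
    abort("CV plan hash mismatch: survival analysis must reuse the selection plan")
  if (is.null(features))
    features <- intersect(feature_names(), names(feature_table))
  ids <- feature_table$patient_id
  in_pair <- ids[groups[ids] %in% pair]
  votes <- matrix(0, nrow = length(in_pair), ncol = 2,
                  dimnames = list(in_pair, pair))
  prob_sum <- votes
  n_tested <- setNames(integer(length(in_pair)), in_pair)
  for (i in seq_len(nrow(plan))) {
    tr <- intersect(plan$train[[i]], in_pair)
    te <- intersect(plan$test[[i]], in_pair)
    if (length(te) == 0) next
    tr_rows <- match(tr, ids); te_rows <- match(te, ids)
    y <- factor(groups[tr], levels = pair)
    if (nlevels(droplevels(y)) < 2) next
    fit <- train_rf(feature_table[tr_rows, features, drop = FALSE], y,
                    n_trees = n_trees, seed = seed + i)
    pr <- predict(fit, as.data.frame(feature_table[te_rows, features,
                                                   drop = FALSE]),
                  type = "prob")
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    for (k in seq_along(te)) {
      votes[te[k], pred[k]] <- votes[te[k], pred[k]] + 1
      prob_sum[te[k], colnames(pr)] <- prob_sum[te[k], colnames(pr)] + pr[k, ]
    }
    n_tested[te] <- n_tested[te] + 1L
  }
  # worse-prognosis ordering for final tie-break
  worse_first <- pair[order(match(pair, c("STS", "MTS", "LTS")))]
  predicted <- vapply(in_pair, function(id) {
    v <- votes[id, ]
    if (v[1] != v[2]) return(names(v)[which.max(v)])
    p <- prob_sum[id, ]
    if (p[1] != p[2]) return(names(p)[which.max(p)])
    worse_first[1]
  }, character(1))
  tibble(patient_id = in_pair, predicted = factor(predicted, levels = pair),
         votes = apply(votes, 1, max), n_tested = as.integer(n_tested))
}

#' Kaplan-Meier product-limit curve
#'
#' Wraps [survival::survfit()]; censored subjects leave the risk set without
#' a drop in survival.
#'
#' @param times event/censoring times.
#' @param events event indicators (1 = event observed).
#' @param group optional grouping factor; when given, one curve per group.
#' @return Tibble (`group` if given, `time`, `n_risk`, `n_event`,
#'   `survival`).
#' @export
km_estimate <- function(times, events, group = NULL) {
  df <- data.frame(time = times, event = events)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
           survival = fit$surv)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    g <- if (is.null(fit$strata))
      rep(as.character(unique(df$group)), length(fit$time))
    else rep(sub("^group=", "", names(fit$strata)), fit$strata)
    tibble(group = g, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, survival = fit$surv)
  }
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance; the p-value comes
#' from the chi-square distribution with 1 degree of freedom.
#'
#' @param times,events survival data.
#' @param group two-level grouping factor.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  if (sum(events) < 1) abort("log-rank test needs at least one event")
  df <- data.frame(time = times, event = events, group = factor(group))
  if (nlevels(droplevels(df$group)) < 2)
    abort("log-rank test needs two groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chisq = fit$chisq, p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with hazard ratios
#'
#' Partial-likelihood Cox model (Efron tie handling), reporting per-covariate
#' hazard ratios with 95% confidence intervals and the model concordance.
#'
#' @param data data frame containing `os_months`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @return Object of class `hypoxrad_cox` wrapping the `coxph` fit; use
#'   [tidy()] / [glance()].
#' @export
cox_fit <- function(data, covariates) {
  for (cc in covariates) {
    v <- data[[cc]][data$event == 1]
    if (length(unique(v)) < 2)
      abort(sprintf("covariate '%s' is constant within events", cc))
  }
  f <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                               paste(sprintf("`%s`", covariates),
                                     collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    abort("Cox model did not converge")
  structure(list(fit = fit, covariates = covariates), class = "hypoxrad_cox")
}

#' @export
#' @method tidy hypoxrad_cox
tidy.hypoxrad_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(term = rownames(co),
         estimate = co[, "coef"],
         hazard_ratio = co[, "exp(coef)"],
         conf_low = ci[, "lower .95"],
         conf_high = ci[, "upper .95"],
         p_value = co[, "Pr(>|z|)"])
}

#' @export
#' @method glance hypoxrad_cox
glance.hypoxrad_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n_event = s$nevent,
         concordance = unname(s$concordance["C"]),
         logtest_p = unname(s$logtest["pvalue"]))
}

#' @export
print.hypoxrad_cox <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose risk ordering agrees with the
#' observed survival ordering (higher risk, shorter survival); ties in risk
#' count one half. Computed via [survival::concordance()].
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param times,events survival data.
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, times, events) {
  df <- data.frame(risk = risk, time = times, event = events)
  fit <- survival::concordance(survival::Surv(time, event) ~ risk, data = df,
                               reverse = TRUE)
  if (sum(fit$count[c("concordant", "discordant", "tied.x")]) == 0)
    abort("no comparable pair")
  unname(fit$concordance)
}

#' Run the survival experiment
#'
#' Uses the retained radiomic features to classify each survival-group pair
#' (STS vs LTS, STS vs MTS, MTS vs LTS) with the cross-validated random
#' forest on the training split (aggregated per-patient votes over the
#' selection plan) and a single classifier retrained on the full training
#' split for the held-out validation set. For every pair and cohort it
#' reports the KM curves of the predicted groups with the log-rank p, and
#' Cox hazard ratios / concordance for clinical-only, radiomic-only and
#' combined covariates.
#'
#' @param clinical tibble with `patient_id`, `split`, `os_months`, `event`,
#'   `group`, `age`, `sex`, `kps`.
#' @param feature_table imputed feature tibble.
#' @param retained character vector of the retained feature names.
#' @param plan the selection CV plan.
#' @param n_trees,seed forwarded to the classifiers.
#' @return List of class `experiment2_report`: `pairs` (named list with
#'   per-cohort predictions, KM tibbles, log-rank results) and `cox`
#'   (tibble in the layout of a hazard-ratio table).
#' @export
run_experiment2 <- function(clinical, feature_table, retained, plan,
                            n_trees = 50L, seed = 1L) {
  groups <- setNames(clinical$group, clinical$patient_id)
  surv <- clinical[, c("patient_id", "os_months", "event", "group", "split",
                       "age", "sex", "kps")]
  train_ids <- clinical$patient_id[clinical$split == "train"]
  val_ids <- clinical$patient_id[clinical$split == "validation"]
  pairs <- list(c("STS", "LTS"), c("STS", "MTS"), c("MTS", "LTS"))
  names(pairs) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  ft_train <- feature_table[feature_table$split == "train", , drop = FALSE]

  out_pairs <- list()
  for (nm in names(pairs)) {
    pair <- pairs[[nm]]
    cvp <- cross_validated_predictions(plan, ft_train, groups, pair,
                                       features = retained,
                                       n_trees = n_trees, seed = seed)
    # validation: one classifier retrained on the full training split
    tr_rows <- match(intersect(train_ids,
                               names(groups)[groups %in% pair]),
                     feature_table$patient_id)
    fit <- train_rf(feature_table[tr_rows, retained, drop = FALSE],
                    factor(groups[feature_table$patient_id[tr_rows]],
                           levels = pair),
                    n_trees = n_trees, seed = seed)
    val_pair <- intersect(val_ids, names(groups)[groups %in% pair])
    val_rows <- match(val_pair, feature_table$patient_id)
    val_pred <- predict(fit, as.data.frame(
      feature_table[val_rows, retained, drop = FALSE]))
    cohorts <- list(
      training = tibble(patient_id = cvp$patient_id,
                        predicted = cvp$predicted),
      validation = tibble(patient_id = val_pair,
                          predicted = factor(as.character(val_pred),
                                             levels = pair))
    )
    res <- list()
    for (coh in names(cohorts)) {
      d <- left_join(cohorts[[coh]], surv, by = "patient_id")
      lr <- if (nlevels(droplevels(d$predicted)) == 2 && sum(d$event) > 0)
        logrank_test(d$os_months, d$event, d$predicted)
      else list(chisq = NA_real_, p = NA_real_)
      res[[coh]] <- list(predictions = cohorts[[coh]],
                         km = km_estimate(d$os_months, d$event, d$predicted),
                         logrank = lr)
    }
    out_pairs[[nm]] <- res
  }
  cox_tab <- cox_table(clinical, feature_table, retained,
                       pairs = pairs[c("STS_vs_LTS", "MTS_vs_LTS")])
  structure(list(pairs = out_pairs, cox = cox_tab),
            class = "experiment2_report")
}

#' Hazard-ratio / concordance table for clinical and radiomic covariates
#'
#' For each survival-group pair: univariate Cox fits of age, sex and KPS; a
#' multivariate fit of the retained radiomic features (hazard ratios reported
#' as their min-max range); and the combined radiomic + clinical model.
#' Concordance is reported on the training fit and on the validation split
#' using the training model's linear predictor.
#'
#' @param clinical,feature_table,retained see [run_experiment2()].
#' @param pairs named list of group pairs.
#' @return Tibble (`comparison`, `feature_set`, `hazard_ratio`, `p_value`,
#'   `c_index_train`, `c_index_validation`).
#' @export
cox_table <- function(clinical, feature_table, retained,
                      pairs = list(STS_vs_LTS = c("STS", "LTS"),
                                   MTS_vs_LTS = c("MTS", "LTS"))) {
  dat <- left_join(clinical,
                   feature_table[, c("patient_id", retained)],
                   by = "patient_id")
  dat$sex_num <- as.integer(factor(dat$sex))
  rows <- list()
  sets <- c(list(age = "age", sex = "sex_num", kps = "kps",
                 radiomic = retained),
            list(radiomic_clinical = c(retained, "age", "sex_num", "kps")))
  for (nm in names(pairs)) {
    d <- dat[dat$group %in% pairs[[nm]], , drop = FALSE]
    dtr <- d[d$split == "train", , drop = FALSE]
    dva <- d[d$split == "validation", , drop = FALSE]
    for (fs in names(sets)) {
      cov <- sets[[fs]]
      fit <- cox_fit(as.data.frame(dtr), cov)
      td <- tidy(fit)
      hr <- if (length(cov) == 1) sprintf("%.4f", td$hazard_ratio) else
        sprintf("%.4f-%.4f", min(td$hazard_ratio), max(td$hazard_ratio))
      p <- glance(fit)$logtest_p
      lp_tr <- predict(fit$fit, newdata = as.data.frame(dtr), type = "lp")
      c_tr <- concordance_index(lp_tr, dtr$os_months, dtr$event)
      c_va <- if (nrow(dva) > 2 && sum(dva$event) > 0) {
        lp_va <- predict(fit$fit, newdata = as.data.frame(dva), type = "lp")
        concordance_index(lp_va, dva$os_months, dva$event)
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        comparison = nm, feature_set = fs, hazard_ratio = hr,
        p_value = p, c_index_train = c_tr, c_index_validation = c_va)
    }
  }
  bind_rows(rows)
}

#' Plot Kaplan-Meier curves of an experiment report
#'
#' @param report a [run_experiment2()] result.
#' @param pair which comparison, e.g. `"STS_vs_LTS"`.
#' @param cohort `"training"` or `"validation"`.
#' @return A ggplot object (step curves per predicted group, log-rank p in
#'   the subtitle).
#' @export
plot_km_curves <- function(report, pair = "STS_vs_LTS", cohort = "training") {
  res <- report$pairs[[pair]][[cohort]]
  km <- res$km
  km0 <- dplyr::bind_rows(
    tibble(group = unique(km$group), time = 0, survival = 1),
    km[, c("group", "time", "survival")])
  ggplot2::ggplot(km0, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s (%s)", gsub("_", " ", pair), cohort),
                  subtitle = sprintf("log-rank p = %.4g", res$logrank$p),
                  x = "months", y = "survival probability",
                  colour = "predicted group") +
    ggplot2::theme_minimal()
}

#' @export
print.experiment2_report <- function(x, ...) {
  cat("Survival stratification report\n")
  for (nm in names(x$pairs)) {
    for (coh in c("training", "validation")) {
      cat(sprintf("  %-12s %-10s log-rank p = %.4g\n", nm, coh,
                  x$pairs[[nm]][[coh]]$logrank$p))
    }
  }
  cat("\nCox table:\n")
  print(as.data.frame(x$cox), row.names = FALSE)
  invisible(x)
}
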