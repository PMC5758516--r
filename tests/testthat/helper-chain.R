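# End-to-end recovery chain used by the acceptance suite: generate a cohort,
# extract features, score and cluster HES, select features under the CV plan,
# and evaluate the predicted validation stratification (STS vs LTS).
run_recovery_chain <- function(cfg, seed, standardize = FALSE) {
  co <- generate_cohort(cfg)
  ft <- suppressMessages(impute_features(
    extract_cohort_features(co, standardize = standardize)))
  cl <- co$clinical
  tr_ids <- cl$patient_id[cl$split == "train"]
  hes <- cluster_hes(score_cohort(co$expression[, tr_ids]))
  labels <- setNames(hes$cluster, hes$sample)
  plan <- make_cv_plan(as.character(labels[tr_ids]), ids = tr_ids, seed = seed)
  sel <- selection_frequency(plan, ft[ft$split == "train", ], labels)
  ret <- attr(sel, "retained")
  tr <- cl$split == "train" & cl$group %in% c("STS", "LTS")
  va <- cl$split == "validation" & cl$group %in% c("STS", "LTS")
  fit <- train_rf(ft[match(cl$patient_id[tr], ft$patient_id), ret],
                  factor(cl$group[tr], levels = c("STS", "LTS")), seed = seed)
  pred <- predict(fit, as.data.frame(
    ft[match(cl$patient_id[va], ft$patient_id), ret]))
  p <- if (length(unique(pred)) < 2) NA_real_ else
    logrank_test(cl$os_months[va], cl$event[va], pred)$p
  list(retained = ret,
       planted = sum(grepl("__(enhancing|edema)__", ret)),
       hes_cor = cor(hes$hes,
                     cl$latent_h[match(hes$sample, cl$patient_id)],
                     method = "spearman"),
       logrank_p = p)
}
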