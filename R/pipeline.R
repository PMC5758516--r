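#' Run the full radiogenomic pipeline on a synthetic cohort
#'
#' End-to-end driver: generate (or accept) a synthetic cohort, extract the
#' 270-feature radiomic table from the standardized volumes, score the
#' training-split expression with the hypoxia signature and cluster the
#' scores into low/mid/high, select the radiomic features most informative
#' of the HES clusters under the repeated stratified CV plan, and evaluate
#' the retained subset as survival-group predictors.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optional pre-generated [generate_cohort()] result.
#' @param n_folds,n_iterations CV plan shape (default 3 x 50).
#' @param per_run_k,k_retain selection parameters (default 8 / 8).
#' @param alpha ssGSEA rank-weight exponent.
#' @param standardize landmark-standardize intensities before extraction.
#' @param seed seed for the CV plan and classifiers (defaults to the cohort
#'   seed).
#' @return List of class `hypoxrad_pipeline`: `cohort`, `features`
#'   (imputed), `hes`, `plan`, `selection`, `report`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         n_folds = 3L, n_iterations = 50L,
                         per_run_k = 8L, k_retain = 8L, alpha = 0.25,
                         standardize = TRUE, seed = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  if (is.null(seed)) seed <- cohort$config$seed
  clinical <- cohort$clinical

  features <- extract_cohort_features(cohort, standardize = standardize)
  features <- impute_features(features)

  train_ids <- clinical$patient_id[clinical$split == "train"]
  hes <- score_cohort(cohort$expression[, train_ids, drop = FALSE],
                      alpha = alpha)
  hes <- cluster_hes(hes)
  hes_labels <- setNames(hes$cluster, hes$sample)

  plan <- make_cv_plan(labels = as.character(hes_labels[train_ids]),
                       ids = train_ids, n_folds = n_folds,
                       n_iterations = n_iterations, seed = seed)
  ft_train <- features[features$split == "train", , drop = FALSE]
  selection <- selection_frequency(plan, ft_train, hes_labels,
                                   per_run_k = per_run_k,
                                   k_retain = k_retain)
  retained <- attr(selection, "retained")
  report <- run_experiment2(clinical, features, retained, plan, seed = seed)
  structure(list(cohort = cohort, features = features, hes = hes,
                 plan = plan, selection = selection, report = report),
            class = "hypoxrad_pipeline")
}

#' @export
print.hypoxrad_pipeline <- function(x, ...) {
  cat(sprintf("hypoxrad pipeline: %d studies (%d train / %d validation)\n",
              nrow(x$cohort$clinical),
              sum(x$cohort$clinical$split == "train"),
              sum(x$cohort$clinical$split == "validation")))
  cat("retained features:\n")
  cat(paste0("  ", attr(x$selection, "retained"), collapse = "\n"), "\n")
  print(x$report)
  invisible(x)
}
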