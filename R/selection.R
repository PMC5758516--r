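#' Build a repeated stratified cross-validation plan
#'
#' `n_iterations` repeats of `n_folds`-fold stratified cross-validation
#' (default 50 x 3 = 150 train/test sets, two-thirds train / one-third test),
#' seed-reproducible. Within an iteration the test sets partition the cohort,
#' and every training set preserves the stratum proportions within one
#' sample.
#'
#' @param labels stratification label vector (one per study).
#' @param ids optional identifiers; defaults to indices.
#' @param n_folds folds per iteration (default 3).
#' @param n_iterations repeats (default 50).
#' @param seed integer seed.
#' @return Tibble of class `cv_plan` (`iteration`, `fold`, `train`, `test`
#'   list-columns of ids) with attributes `seed` and `hash`.
#' @export
make_cv_plan <- function(labels, ids = NULL, n_folds = 3L, n_iterations = 50L,
                         seed = 1L) {
  n <- length(labels)
  if (is.null(ids)) ids <- seq_len(n)
  strata <- split(seq_len(n), labels, drop = TRUE)
  small <- names(strata)[lengths(strata) < n_folds]
  if (length(small) > 0)
    abort(paste0("stratum too small for ", n_folds, "-fold CV: ",
                 paste(small, collapse = ", ")))
  set.seed(seed)
  rows <- vector("list", n_iterations * n_folds)
  r <- 0L
  for (it in seq_len(n_iterations)) {
    fold_of <- integer(n)
    for (s in strata) {
      sh <- sample(s)
      fold_of[sh] <- rep_len(seq_len(n_folds), length(sh))
    }
    for (f in seq_len(n_folds)) {
      r <- r + 1L
      rows[[r]] <- tibble(iteration = it, fold = f,
                          train = list(ids[fold_of != f]),
                          test = list(ids[fold_of == f]))
    }
  }
  plan <- bind_rows(rows)
  class(plan) <- c("cv_plan", class(plan))
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "hash") <- cv_plan_hash(plan)
  plan
}

#' Hash of a CV plan's splits
#'
#' Used to verify that the survival experiment reuses exactly the splits of
#' the feature-selection experiment.
#'
#' @param plan a [make_cv_plan()] result.
#' @return Character hash.
#' @export
cv_plan_hash <- function(plan) {
  rlang::hash(list(plan$iteration, plan$fold, plan$train, plan$test))
}

#' Serialize / read a CV plan as JSON
#'
#' @param plan a [make_cv_plan()] result.
#' @param path file path.
#' @return `read_cv_plan()`: the plan tibble (hash recomputed).
#' @export
write_cv_plan <- function(plan, path) {
  jsonlite::write_json(
    list(seed = attr(plan, "seed"),
         splits = lapply(seq_len(nrow(plan)), function(i)
           list(iteration = plan$iteration[i], fold = plan$fold[i],
                train = plan$train[[i]], test = plan$test[[i]]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cv_plan
#' @export
read_cv_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  plan <- bind_rows(lapply(x$splits, function(s)
    tibble(iteration = s$iteration, fold = s$fold,
           train = list(unlist(s$train)), test = list(unlist(s$test)))))
  class(plan) <- c("cv_plan", class(plan))
  attr(plan, "seed") <- x$seed
  attr(plan, "hash") <- cv_plan_hash(plan)
  plan
}

#' Plug-in mutual information between a feature and class labels
#'
#' Discretizes `x` into quantile bins and estimates
#' `MI = sum p(x, y) log( p(x, y) / (p(x) p(y)) )` (nats) from the
#' contingency table. Nonnegative by construction; a constant `x` gives 0
#' with a warning.
#'
#' @param x numeric vector.
#' @param y class labels (factor or vector).
#' @param n_bins number of quantile bins for `x` (default 4).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = 4L) {
  if (length(x) < 10) abort("need at least 10 paired observations")
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) abort("need at least 2 classes in y")
  br <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) {
    warn("constant x: mutual information is 0")
    return(0)
  }
  xb <- cut(x, br, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank features by mutual information with the HES labels
#'
#' @param feature_table tibble whose feature columns follow the
#'   [feature_names()] grammar (extra columns ignored).
#' @param labels class labels, one per row (e.g. HES cluster low/mid/high).
#' @param n_bins quantile bins passed to [mutual_information()].
#' @return Tibble (`feature`, `mi`, `rank`) in descending MI; ties keep the
#'   deterministic column order.
#' @export
rank_features <- function(feature_table, labels, n_bins = 4L) {
  cols <- intersect(feature_names(), names(feature_table))
  mi <- vapply(cols, function(cc)
    suppressWarnings(mutual_information(feature_table[[cc]], labels, n_bins)),
    numeric(1))
  ord <- order(-mi, seq_along(cols))
  tibble(feature = cols[ord], mi = mi[ord], rank = seq_along(cols))
}

#' Selection frequency of features across the cross-validation plan
#'
#' For every train/test split of the plan, ranks the features by mutual
#' information with the labels on the training rows; a feature "occurs" in a
#' run when it ranks in the top `per_run_k`. Occurrences are accumulated over
#' all runs and the `k_retain` most frequent features are retained (ties
#' broken by mean rank, then name).
#'
#' @param plan a [make_cv_plan()] whose ids index `feature_table$patient_id`.
#' @param feature_table an imputed feature tibble with `patient_id`.
#' @param labels named vector/factor of HES cluster labels per patient id.
#' @param per_run_k per-run occurrence cutoff (default 8).
#' @param k_retain size of the retained subset (default 8).
#' @param n_bins quantile bins for the MI estimator.
#' @return Tibble of class `selection_result` (`feature`, `count`,
#'   `mean_rank`, `retained`), ordered by decreasing count; attribute
#'   `retained` holds the ordered retained feature names.
#' @export
selection_frequency <- function(plan, feature_table, labels, per_run_k = 8L,
                                k_retain = 8L, n_bins = 4L) {
  cols <- intersect(feature_names(), names(feature_table))
  if (any(vapply(cols, function(cc) all(is.na(feature_table[[cc]])),
                 logical(1))))
    abort("all-missing feature column: impute or drop before selection")
  counts <- setNames(numeric(length(cols)), cols)
  rank_sum <- counts
  for (i in seq_len(nrow(plan))) {
    tr <- match(plan$train[[i]], feature_table$patient_id)
    rk <- rank_features(feature_table[tr, , drop = FALSE],
                        labels[feature_table$patient_id[tr]], n_bins)
    rank_sum[rk$feature] <- rank_sum[rk$feature] + rk$rank
    counts[rk$feature[seq_len(min(per_run_k, nrow(rk)))]] <-
      counts[rk$feature[seq_len(min(per_run_k, nrow(rk)))]] + 1
  }
  res <- tibble(feature = cols, count = as.integer(counts),
                mean_rank = rank_sum / nrow(plan))
  res <- arrange(res, dplyr::desc(.data$count), .data$mean_rank, .data$feature)
  res$retained <- seq_len(nrow(res)) <= k_retain
  class(res) <- c("selection_result", class(res))
  attr(res, "retained") <- res$feature[res$retained]
  res
}

#' Plot selection frequencies
#'
#' @param selection a [selection_frequency()] result.
#' @param top_n number of features shown.
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(selection, top_n = 20) {
  df <- head(selection, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$feature,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "occurrences across CV runs", y = NULL,
                  fill = "retained") +
    ggplot2::theme_minimal()
}
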