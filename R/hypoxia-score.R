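#' Read and write GMT gene-set files
#'
#' Minimal GMT support: one set per line, `name <TAB> description <TAB>
#' gene...`.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 21-gene hypoxia signature
#'
#' Returns the gene symbols of the hypoxia signature shipped with the package
#' (`inst/extdata/hypoxia_genes.gmt`): a package-curated, representative
#' 21-gene set of HIF-pathway targets (including VEGFA, ANGPTL4 and LGALS3)
#' used both to score real expression matrices and as the planted signal genes
#' of the synthetic cohort. Replace the GMT to use a different signature.
#'
#' @return Character vector of 21 gene symbols.
#' @export
hypoxia_geneset <- function() {
  read_gmt(system.file("extdata", "hypoxia_genes.gmt",
                       package = "hypoxrad", mustWork = TRUE))[[1]]
}

#' Z-score normalize an expression matrix
#'
#' Scales each gene (row) to mean 0 and sample SD 1 across samples.
#' Zero-variance genes are dropped with a warning.
#'
#' @param mat genes x samples numeric matrix with rownames.
#' @return Matrix of the same shape (minus dropped rows).
#' @export
zscore_normalize <- function(mat) {
  if (ncol(mat) < 2) abort("z-scoring needs at least 2 samples")
  if (anyDuplicated(rownames(mat))) abort("duplicate gene symbols")
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (mat - rowMeans(mat)) / sds
}

#' Single-sample gene-set enrichment score
#'
#' Ranks all genes of one sample by descending expression and walks the ranked
#' list accumulating `ES = sum_i (P_hit(i) - P_miss(i))`, where `P_hit` steps
#' by the normalized weight `|x|^alpha` of in-set genes and `P_miss` steps
#' uniformly over out-of-set genes; the returned statistic is the running sum
#' (the single-sample enrichment convention), not the maximum deviation.
#' Ties in expression are broken by gene symbol for determinism.
#'
#' @param profile named numeric vector (one sample, typically z-scored).
#' @param gene_set character vector of set symbols; must intersect the profile
#'   genes and must not cover all of them.
#' @param alpha rank weight exponent; `alpha = 0` gives the unweighted
#'   (rank-only) statistic. Default 0.25.
#' @return A single numeric enrichment score.
#' @export
#' @examples
#' ssgsea_score(c(a = 3, b = 2, c = 1, d = 0), "a", alpha = 0)  # 2
ssgsea_score <- function(profile, gene_set, alpha = 0.25) {
  genes <- names(profile)
  inset <- genes %in% gene_set
  if (!any(inset)) abort("gene set does not intersect the profile genes")
  if (all(inset)) abort("gene set must not cover every gene in the profile")
  ord <- order(-profile, genes)
  inset <- inset[ord]
  w <- abs(profile[ord])^alpha
  w[!inset] <- 0
  tot_w <- sum(w)
  if (tot_w == 0) w[inset] <- 1 / sum(inset) else w <- w / tot_w
  p_hit <- cumsum(w)
  p_miss <- cumsum(!inset) / sum(!inset)
  sum(p_hit - p_miss)
}

#' Score a cohort: per-sample hypoxia enrichment
#'
#' Z-score normalizes the expression matrix across samples, then computes the
#' single-sample enrichment score of `gene_set` for every sample column.
#'
#' @param mat genes x samples matrix.
#' @param gene_set character vector (default the packaged hypoxia signature).
#' @param alpha rank weight exponent, see [ssgsea_score()].
#' @param rescale if `TRUE`, min-max rescale the scores across the cohort to
#'   \[0,1\] (off by default).
#' @return Tibble (`sample`, `hes`) of class `hes_table`.
#' @export
score_cohort <- function(mat, gene_set = hypoxia_geneset(), alpha = 0.25,
                         rescale = FALSE) {
  z <- zscore_normalize(mat)
  missing <- setdiff(gene_set, rownames(z))
  if (length(missing) == length(gene_set))
    abort("no gene of the set is present in the matrix")
  hes <- vapply(seq_len(ncol(z)), function(j)
    ssgsea_score(setNames(z[, j], rownames(z)), gene_set, alpha), numeric(1))
  if (rescale) hes <- (hes - min(hes)) / (max(hes) - min(hes))
  structure(tibble(sample = colnames(mat), hes = hes), class =
              c("hes_table", class(tibble())))
}

#' Cluster hypoxia enrichment scores into ordered low/mid/high groups
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average linkage)
#' of the 1D HES values, cut at `k` clusters, relabeled `low`/`mid`/`high` by
#' ascending cluster mean. Contiguity in HES is enforced post hoc: the final
#' assignment is by the thresholds separating the ordered clusters, so the
#' groups are intervals of the score.
#'
#' @param hes_table a [score_cohort()] result, or a tibble with an `hes`
#'   column.
#' @param k number of clusters (default 3).
#' @return The input tibble with a `cluster` factor column
#'   (`low < mid < high` for `k = 3`, else `c1..ck`).
#' @export
cluster_hes <- function(hes_table, k = 3) {
  hes <- hes_table$hes
  if (length(unique(hes)) < k)
    abort(sprintf("need at least %d distinct HES values", k))
  cl <- cutree(hclust(dist(hes), method = "average"), k = k)
  means <- tapply(hes, cl, mean)
  ord <- order(means)
  # interval thresholds between ordered clusters -> contiguous groups
  uppers <- vapply(ord[-k], function(g) max(hes[cl == g]), numeric(1))
  labels <- if (k == 3) c("low", "mid", "high") else paste0("c", seq_len(k))
  idx <- findInterval(hes, sort(uppers) + 1e-12) + 1L
  hes_table$cluster <- factor(labels[idx], levels = labels)
  hes_table
}

#' Plot the cohort HES distribution by cluster
#'
#' @param hes_table a clustered [cluster_hes()] result.
#' @return A ggplot object.
#' @export
plot_hes_distribution <- function(hes_table) {
  ggplot2::ggplot(hes_table,
                  ggplot2::aes(x = .data$hes,
                               fill = if ("cluster" %in% names(hes_table))
                                 .data$cluster else NULL)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "hypoxia enrichment score", y = "samples",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}
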