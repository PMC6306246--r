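#' Per-cluster gene detection profile
#'
#' Proportion of samples in each cluster expressing each gene above
#' background (CPM > `cpm_threshold`).
#'
#' @param x an [expression_matrix()].
#' @param labels named cluster assignment (or `cluster_assignment`).
#' @param cpm_threshold detection threshold on CPM (default 1).
#' @param reads read layer(s) used for expression.
#' @return gene x cluster matrix of detection proportions in `[0, 1]`.
#' @export
detection_profile <- function(x, labels, cpm_threshold = 1,
                              reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  cpm <- suppressWarnings(compute_cpm(x, reads))
  ids <- sort(unique(labels))
  out <- sapply(ids, function(k) {
    rowMeans(cpm[, names(labels)[labels == k], drop = FALSE] > cpm_threshold)
  })
  colnames(out) <- ids
  out
}

#' Beta marker-specificity score
#'
#' Measures how binary a gene's detection pattern is across clusters,
#' independent of how many clusters express it. For per-cluster detection
#' proportions x_1..x_n the score is the ratio of the double sum of squared
#' differences to the double sum of absolute differences plus a small
#' constant epsilon:
#' `beta = sum_ij (x_i - x_j)^2 / (sum_ij |x_i - x_j| + epsilon)`.
#' Scores range from 0 (uniform: ubiquitous or absent) to 1 (perfectly
#' binary detection in a subset of clusters).
#'
#' @param profile gene x cluster detection matrix from
#'   [detection_profile()], or a single numeric vector of proportions.
#' @param epsilon small constant avoiding division by zero (default 1e-6;
#'   the exact 0/1 endpoints are attained at `epsilon = 0`).
#' @return named numeric vector of beta scores in `[0, 1]`.
#' @export
beta_score <- function(profile, epsilon = 1e-6) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  if (ncol(profile) < 2) stop("at least 2 clusters are required")
  apply(profile, 1, function(p) {
    s <- sort(p)
    n <- length(s)
    num <- 2 * (n * sum(s^2) - sum(s)^2)
    den <- 2 * sum(s * (2 * seq_len(n) - n - 1)) + epsilon
    if (den == 0) 0 else num / den
  })
}

#' Dendrogram of clusters from top marker genes
#'
#' Average expression (log2 CPM + 1) of the top `n_markers` genes by beta
#' score is computed per cluster; clusters are then joined by
#' complete-linkage hierarchical clustering of a correlation-based distance.
#' The default distance is `(1 - rho) / 2`; `1 - rho` is selectable.
#'
#' @param x an [expression_matrix()].
#' @param labels named cluster assignment (or `cluster_assignment`).
#' @param n_markers number of top-beta genes used (fewer if fewer exist).
#' @param distance `"half"` for `(1 - rho)/2` or `"one_minus"` for `1 - rho`.
#' @param reads read layer(s) used for expression.
#' @return an `hclust` tree over the clusters.
#' @export
cluster_dendrogram <- function(x, labels, n_markers = 1200,
                               distance = c("half", "one_minus"),
                               reads = c("both", "exonic", "intronic")) {
  distance <- match.arg(distance)
  reads <- match.arg(reads)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  prof <- detection_profile(x, labels, reads = reads)
  beta <- beta_score(prof)
  top <- names(sort(beta, decreasing = TRUE))[seq_len(min(n_markers, length(beta)))]
  E <- suppressWarnings(log_cpm(x, reads))[top, , drop = FALSE]
  ids <- sort(unique(labels))
  means <- sapply(ids, function(k)
    rowMeans(E[, names(labels)[labels == k], drop = FALSE]))
  colnames(means) <- ids
  rho <- suppressWarnings(stats::cor(means))
  rho[is.na(rho)] <- 0
  d <- if (distance == "half") (1 - rho) / 2 else 1 - rho
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Match clusters across datasets by marker gene expression
#'
#' Filters to genes that are markers in both datasets (beta score above
#' `beta_min`) and expressed in the majority of samples of at least one but
#' no more than `max_clusters_expressed` clusters in each dataset, then
#' computes beta-weighted Pearson correlations between all cluster pairs of
#' the two detection profiles (gene weight: the smaller of the two beta
#' scores, so a gene uninformative in either dataset contributes nothing).
#' Reciprocal best matches are cluster pairs that are each other's argmax.
#'
#' @param profile_ref,profile_query gene x cluster detection matrices
#'   ([detection_profile()]) sharing gene names.
#' @param beta_ref,beta_query beta scores ([beta_score()]) for each profile
#'   (computed from the profiles if omitted).
#' @param beta_min minimum beta score in both datasets (default 0.3).
#' @param max_clusters_expressed maximum number of clusters (per dataset) in
#'   which a retained marker may be majority-expressed (default 5).
#' @param majority detection proportion defining "expressed in a cluster".
#' @return list with `correlation` (ref x query matrix), `matches`
#'   (data.frame of reciprocal best matches with their correlations), and
#'   `genes` (the filtered marker genes used).
#' @export
match_clusters <- function(profile_ref, profile_query, beta_ref = NULL,
                           beta_query = NULL, beta_min = 0.3,
                           max_clusters_expressed = 5, majority = 0.5) {
  shared <- intersect(rownames(profile_ref), rownames(profile_query))
  pr <- profile_ref[shared, , drop = FALSE]
  pq <- profile_query[shared, , drop = FALSE]
  br <- (beta_ref %||% beta_score(profile_ref))[shared]
  bq <- (beta_query %||% beta_score(profile_query))[shared]
  nr <- rowSums(pr > majority)
  nq <- rowSums(pq > majority)
  keep <- br > beta_min & bq > beta_min &
    nr >= 1 & nr <= max_clusters_expressed &
    nq >= 1 & nq <= max_clusters_expressed
  if (!any(keep)) stop("no shared marker genes pass the filters")
  pr <- pr[keep, , drop = FALSE]
  pq <- pq[keep, , drop = FALSE]
  w <- pmin(br[keep], bq[keep])
  R <- matrix(NA_real_, ncol(pr), ncol(pq),
              dimnames = list(colnames(pr), colnames(pq)))
  for (i in seq_len(ncol(pr))) {
    for (j in seq_len(ncol(pq))) {
      R[i, j] <- weighted_correlation(pr[, i], pq[, j], w)
    }
  }
  Rsafe <- R
  Rsafe[is.na(Rsafe)] <- -Inf
  best_q <- apply(Rsafe, 1, which.max)
  best_r <- apply(Rsafe, 2, which.max)
  recip <- which(best_r[best_q] == seq_len(nrow(R)))
  matches <- data.frame(ref = rownames(R)[recip],
                        query = colnames(R)[best_q[recip]],
                        correlation = R[cbind(recip, best_q[recip])],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(correlation = R, matches = matches, genes = rownames(pr))
}

#' Differential expression between nuclei and cells
#'
#' Per-gene Welch t-test on log2(CPM + 1) with Benjamini-Hochberg
#' correction; fold changes are computed on linear mean CPM. A gene is
#' called significant with adjusted P < `fdr` and a strictly greater than
#' `fold_threshold`-fold change in either direction.
#'
#' @param nuclei,cells [expression_matrix()] objects with a shared gene
#'   universe (each group needs at least 3 samples).
#' @param reads read layer(s) used for expression (`"both"` or `"exonic"`).
#' @param fold_threshold minimum fold change (default 1.5, strict).
#' @param fdr adjusted P-value cutoff (default 0.05, strict).
#' @return data.frame per gene: mean CPM in each group, `fold_change`
#'   (larger mean over smaller), `enriched_in`, `p`, `q`, `significant`.
#' @export
de_nuclei_vs_cells <- function(nuclei, cells,
                               reads = c("both", "exonic", "intronic"),
                               fold_threshold = 1.5, fdr = 0.05) {
  reads <- match.arg(reads)
  shared <- intersect(nuclei$genes, cells$genes)
  if (length(nuclei$samples) < 3 || length(cells$samples) < 3) {
    stop("at least 3 samples per group are required")
  }
  cpm_n <- suppressWarnings(compute_cpm(nuclei, reads))[shared, , drop = FALSE]
  cpm_c <- suppressWarnings(compute_cpm(cells, reads))[shared, , drop = FALSE]
  p <- welch_test_rows(log2(cpm_n + 1), log2(cpm_c + 1))
  q <- stats::p.adjust(p, "BH")
  mn <- rowMeans(cpm_n)
  mc <- rowMeans(cpm_c)
  fc <- pmax(mn, mc) / pmax(pmin(mn, mc), .Machine$double.xmin)
  fc[mn == 0 & mc == 0] <- 1
  data.frame(gene = shared,
             mean_cpm_nuclei = mn, mean_cpm_cells = mc,
             fold_change = fc,
             enriched_in = ifelse(mn >= mc, "nucleus", "cell"),
             p = p, q = q,
             significant = q < fdr & fc > fold_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare gene detection between nuclei and cells
#'
#' Classifies each gene by the difference in detection proportion
#' (proportion of samples with CPM > 0) between cells and nuclei:
#' `similar` when the absolute difference is below `similar_threshold`,
#' `cell_biased` when detection is at least `biased_threshold` higher in
#' cells, `nucleus_biased` for the reverse, `intermediate` otherwise.
#'
#' @param nuclei,cells [expression_matrix()] objects with shared genes.
#' @param similar_threshold,biased_threshold category cutoffs (defaults
#'   0.10 and 0.25).
#' @param reads read layer(s) used for expression.
#' @return data.frame per gene: `detection_nuclei`, `detection_cells`,
#'   `delta` (cells minus nuclei), `category`.
#' @export
compare_detection <- function(nuclei, cells, similar_threshold = 0.10,
                              biased_threshold = 0.25,
                              reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  shared <- intersect(nuclei$genes, cells$genes)
  dn <- rowMeans(suppressWarnings(compute_cpm(nuclei, reads))[shared, , drop = FALSE] > 0)
  dc <- rowMeans(suppressWarnings(compute_cpm(cells, reads))[shared, , drop = FALSE] > 0)
  delta <- dc - dn
  category <- ifelse(abs(delta) < similar_threshold, "similar",
                     ifelse(delta >= biased_threshold, "cell_biased",
                            ifelse(delta <= -biased_threshold,
                                   "nucleus_biased", "intermediate")))
  data.frame(gene = shared, detection_nuclei = dn, detection_cells = dc,
             delta = delta, category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Through-origin regression of cell on nucleus beta scores
#'
#' Least-squares slope, with intercept fixed at zero, of cell-cluster beta
#' marker scores on nucleus-cluster beta scores: `sum(xy) / sum(x^2)`.
#' Callers should restrict to genes expressed in at least one but not all
#' clusters in both datasets.
#'
#' @param beta_cells,beta_nuclei paired numeric vectors of beta scores.
#' @return list with `slope` and `n` (number of genes used).
#' @export
marker_score_regression <- function(beta_cells, beta_nuclei) {
  stopifnot(length(beta_cells) == length(beta_nuclei))
  ok <- is.finite(beta_cells) & is.finite(beta_nuclei)
  x <- beta_nuclei[ok]
  y <- beta_cells[ok]
  if (sum(x^2) == 0) stop("nucleus beta scores are all zero")
  list(slope = sum(x * y) / sum(x^2), n = sum(ok))
}
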