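#' Per-sample intronic read fraction
#'
#' @param x an [expression_matrix()].
#' @return named numeric vector: intronic / (exonic + intronic) reads per
#'   sample.
#' @export
intron_read_fraction <- function(x) {
  tot <- colSums(x$exonic) + colSums(x$intronic)
  tot[tot == 0] <- 1
  colSums(x$intronic) / tot
}

# Group a named per-sample statistic by type labels; returns mean, standard
# error and n per type.
group_stats <- function(values, labels) {
  labels <- labels[names(values)]
  ids <- sort(unique(labels))
  data.frame(type = ids,
             mean = vapply(ids, function(t) mean(values[labels == t]), numeric(1)),
             se = vapply(ids, function(t) {
               v <- values[labels == t]
               stats::sd(v) / sqrt(length(v))
             }, numeric(1)),
             n = vapply(ids, function(t) sum(labels == t), integer(1)),
             row.names = NULL)
}

#' Nuclear fraction from intronic read proportions
#'
#' Intronic reads are assumed to come exclusively from nuclear (unspliced)
#' transcripts, so a whole cell's intronic read proportion is its matched
#' nucleus's proportion diluted by cytoplasmic reads. Per cell type the
#' nuclear fraction is estimated as the mean intronic read proportion of
#' cells divided by that of matched nuclei; the standard deviation follows
#' by first-order (delta method) propagation of the two standard errors.
#' Estimates above 1 are capped at 1.
#'
#' @param cells,nuclei [expression_matrix()] objects.
#' @param labels_cells,labels_nuclei named type assignments for the samples.
#' @return data.frame per type: `estimate`, `sd`, per-compartment means and
#'   sample counts.
#' @export
fraction_from_introns <- function(cells, nuclei, labels_cells, labels_nuclei) {
  gc <- group_stats(intron_read_fraction(cells), labels_cells)
  gn <- group_stats(intron_read_fraction(nuclei), labels_nuclei)
  types <- intersect(gc$type, gn$type)
  gc <- gc[match(types, gc$type), ]
  gn <- gn[match(types, gn$type), ]
  if (any(gn$mean <= 0)) {
    stop("zero intronic read fraction in nuclei; estimator undefined")
  }
  est <- gc$mean / gn$mean
  sd <- est * sqrt((gc$se / gc$mean)^2 + (gn$se / gn$mean)^2)
  data.frame(type = types, estimate = pmin(est, 1), sd = sd,
             intron_fraction_cells = gc$mean, intron_fraction_nuclei = gn$mean,
             n_cells = gc$n, n_nuclei = gn$n, row.names = NULL)
}

#' Nuclear fraction from highly expressed nuclear genes
#'
#' For transcripts retained in the nucleus, exonic expression per million
#' total reads should be `F_t`-fold lower in whole cells than in nuclei,
#' since the same transcripts are diluted by cytoplasmic reads. Per cell
#' type the nuclear fraction is estimated as the average, over a small set
#' of highly expressed nuclear genes, of the ratio of mean cell to mean
#' nucleus exonic expression (exonic counts per million of total reads).
#' Standard deviations are propagated from the per-gene ratio standard
#' errors (delta method). Estimates above 1 are capped at 1.
#'
#' @param cells,nuclei [expression_matrix()] objects.
#' @param labels_cells,labels_nuclei named type assignments.
#' @param gene_set nuclear gene symbols (defaults `Malat1`, `Meg3`,
#'   `Snhg11`); missing genes are dropped with a warning.
#' @return data.frame per type: `estimate`, `sd`, `n_genes` used.
#' @export
fraction_from_nuclear_genes <- function(cells, nuclei, labels_cells,
                                        labels_nuclei,
                                        gene_set = c("Malat1", "Meg3", "Snhg11")) {
  present <- gene_set[gene_set %in% intersect(cells$genes, nuclei$genes)]
  if (length(present) == 0) stop("none of the nuclear genes are present")
  if (length(present) < length(gene_set)) {
    warning("dropping absent nuclear gene(s): ",
            paste(setdiff(gene_set, present), collapse = ", "))
  }
  cpm_c <- cpm_exonic_of_total(cells)[present, , drop = FALSE]
  cpm_n <- cpm_exonic_of_total(nuclei)[present, , drop = FALSE]
  types <- intersect(unique(labels_cells), unique(labels_nuclei))
  out <- lapply(types, function(t) {
    sc <- names(labels_cells)[labels_cells == t]
    sn <- names(labels_nuclei)[labels_nuclei == t]
    ratios <- vars <- numeric(length(present))
    for (g in seq_along(present)) {
      mc <- mean(cpm_c[g, sc])
      mn <- mean(cpm_n[g, sn])
      if (mn <= 0) stop(sprintf("gene %s has zero nuclear expression in type %s",
                                present[g], t))
      se_c <- stats::sd(cpm_c[g, sc]) / sqrt(length(sc))
      se_n <- stats::sd(cpm_n[g, sn]) / sqrt(length(sn))
      ratios[g] <- mc / mn
      vars[g] <- ratios[g]^2 * ((se_c / max(mc, .Machine$double.xmin))^2 +
                                  (se_n / mn)^2)
    }
    data.frame(type = t, estimate = pmin(mean(ratios), 1),
               sd = sqrt(sum(vars)) / length(present),
               n_genes = length(present), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-gene nuclear transcript fraction
#'
#' For each cell type, a gene's nuclear fraction is estimated as the ratio
#' of its mean nuclear to mean cell exonic expression (exonic counts per
#' million of total reads) multiplied by the type's overall nuclear
#' fraction; ratios above 1 are set to 1. A single per-gene estimate is the
#' weighted average across types with weights equal to the gene's average
#' log2(CPM + 1) expression in cells of that type. Genes not detected
#' (CPM > `cpm_threshold` in more than `detect_prop` of samples) in at
#' least one cluster of either dataset are excluded; types where a gene has
#' zero cell expression are skipped for that gene.
#'
#' @param cells,nuclei [expression_matrix()] objects.
#' @param labels_cells,labels_nuclei named type assignments.
#' @param type_fractions named per-type nuclear fractions `F_t` (e.g. from
#'   [fraction_from_nuclear_genes()]).
#' @param cpm_threshold,detect_prop expressed-gene rule (defaults: CPM > 1
#'   in more than 50% of samples of at least one cluster).
#' @return data.frame per retained gene: `pi_hat` in `[0, 1]`, `n_types`
#'   used; the per-type estimates are attached as attribute `"per_type"`.
#' @export
per_gene_nuclear_fraction <- function(cells, nuclei, labels_cells,
                                      labels_nuclei, type_fractions,
                                      cpm_threshold = 1, detect_prop = 0.5) {
  shared <- intersect(cells$genes, nuclei$genes)
  types <- intersect(unique(labels_cells), unique(labels_nuclei))
  if (!all(types %in% names(type_fractions))) {
    stop("type_fractions must cover every type")
  }
  cpm_c <- cpm_exonic_of_total(cells)[shared, , drop = FALSE]
  cpm_n <- cpm_exonic_of_total(nuclei)[shared, , drop = FALSE]
  det_c <- detection_profile(cells, labels_cells, cpm_threshold)[shared, , drop = FALSE]
  det_n <- detection_profile(nuclei, labels_nuclei, cpm_threshold)[shared, , drop = FALSE]
  expressed <- apply(det_c > detect_prop, 1, any) | apply(det_n > detect_prop, 1, any)
  lg_c <- log2(suppressWarnings(compute_cpm(cells))[shared, , drop = FALSE] + 1)
  pi_type <- w_type <- matrix(NA_real_, length(shared), length(types),
                              dimnames = list(shared, types))
  for (t in types) {
    sc <- names(labels_cells)[labels_cells == t]
    sn <- names(labels_nuclei)[labels_nuclei == t]
    mc <- rowMeans(cpm_c[, sc, drop = FALSE])
    mn <- rowMeans(cpm_n[, sn, drop = FALSE])
    ok <- mc > 0
    pi_type[ok, t] <- pmin(1, mn[ok] / mc[ok] * type_fractions[[t]])
    w_type[, t] <- rowMeans(lg_c[, sc, drop = FALSE])
  }
  w_type[is.na(pi_type)] <- NA
  wsum <- rowSums(w_type, na.rm = TRUE)
  pi_hat <- rowSums(pi_type * w_type, na.rm = TRUE) / wsum
  # genes with zero weight everywhere but a usable type: unweighted fallback
  flat <- wsum == 0 & rowSums(!is.na(pi_type)) > 0
  pi_hat[flat] <- rowMeans(pi_type[flat, , drop = FALSE], na.rm = TRUE)
  keep <- expressed & rowSums(!is.na(pi_type)) > 0
  out <- data.frame(gene = shared[keep], pi_hat = pi_hat[keep],
                    n_types = rowSums(!is.na(pi_type))[keep],
                    row.names = NULL)
  attr(out, "per_type") <- pi_type[keep, , drop = FALSE]
  out
}

#' Nuclear volume proportion from cross-sectional areas
#'
#' `(nucleus_area / soma_area)^(3/2)`: the 3/2 power converts an area ratio
#' to a volume ratio assuming the cross-sections reflect approximately
#' symmetric 3-D geometry.
#'
#' @param nucleus_area,soma_area positive areas (same units).
#' @return nuclear volume proportions.
#' @export
volume_proportion_from_area <- function(nucleus_area, soma_area) {
  if (any(nucleus_area <= 0) || any(soma_area <= 0)) {
    stop("areas must be positive")
  }
  (nucleus_area / soma_area)^(3 / 2)
}

#' Nuclear fraction from FISH spot counts
#'
#' Fits a linear regression of nuclear spot counts on whole-soma spot
#' counts; the slope estimates the nuclear proportion of transcripts (a
#' binomial thinning of soma counts has regression slope equal to the
#' thinning probability). The intercept is left free.
#'
#' @param table data.frame with columns `nuclear_count` and `soma_count`
#'   (at least 3 cells).
#' @param conf_level confidence level for the slope interval.
#' @return list with `slope`, `ci` (confidence interval), `n`.
#' @export
fish_nuclear_fraction <- function(table, conf_level = 0.95) {
  stopifnot(all(c("nuclear_count", "soma_count") %in% names(table)))
  if (nrow(table) < 3) stop("at least 3 cells are required")
  if (stats::var(table$soma_count) == 0) {
    stop("zero variance in soma counts; slope undefined")
  }
  fit <- stats::lm(nuclear_count ~ soma_count, data = table)
  # suppress the "essentially perfect fit" note on noiseless input
  ci <- suppressWarnings(stats::confint(fit, "soma_count", level = conf_level))
  list(slope = unname(stats::coef(fit)["soma_count"]),
       ci = unname(ci[1, ]), n = nrow(table))
}

#' Compare the two per-type nuclear-fraction estimators
#'
#' Spearman rank correlation and a least-squares linear relation between
#' the intron-ratio and nuclear-gene estimators across cell types.
#'
#' @param estimate_introns,estimate_genes per-type estimates: data.frames
#'   from [fraction_from_introns()] / [fraction_from_nuclear_genes()] or
#'   named numeric vectors.
#' @return list with `spearman`, `slope`, `intercept`, `n_types`, and
#'   `stable` (`FALSE`, with a warning, when fewer than 3 types are
#'   available).
#' @export
compare_estimators <- function(estimate_introns, estimate_genes) {
  as_vec <- function(e) {
    if (is.data.frame(e)) stats::setNames(e$estimate, e$type) else e
  }
  a <- as_vec(estimate_introns)
  b <- as_vec(estimate_genes)
  types <- intersect(names(a), names(b))
  a <- a[types]
  b <- b[types]
  stable <- length(types) >= 3
  if (!stable) {
    warning("fewer than 3 types; rank correlation is unstable")
  }
  fit <- stats::lm(b ~ a)
  list(spearman = suppressWarnings(stats::cor(a, b, method = "spearman")),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_types = length(types), stable = stable)
}
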