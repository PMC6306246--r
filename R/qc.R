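#' Quality-control filter for nuclei and cells
#'
#' Applies the per-sample QC thresholds used for library selection. Nuclei
#' pass with >500,000 genome-mapped reads, >75% reads aligned and >50% unique
#' reads; cells pass with >200,000 transcriptome-mapped reads and >1,000 genes
#' detected. All inequalities are strict. Thresholds are configurable;
#' defaults are the published ones.
#'
#' @param metrics data.frame with columns `sample_id`, `sample_kind`
#'   (`"nucleus"` or `"cell"`), `mapped_reads`, `pct_aligned`, `pct_unique`,
#'   `genes_detected`. Percentage columns are on the 0-100 scale.
#' @param nucleus_thresholds,cell_thresholds named lists overriding the
#'   default cutoffs.
#' @return character vector of passing sample identifiers (possibly empty).
#' @export
qc_filter <- function(metrics,
                      nucleus_thresholds = list(mapped_reads = 5e5,
                                                pct_aligned = 75,
                                                pct_unique = 50),
                      cell_thresholds = list(mapped_reads = 2e5,
                                             genes_detected = 1000)) {
  if (nrow(metrics) == 0) {
    return(character(0))
  }
  kind <- as.character(metrics$sample_kind)
  if (!all(kind %in% c("nucleus", "cell"))) {
    stop("unknown sample_kind: ", paste(unique(setdiff(kind, c("nucleus", "cell"))),
                                        collapse = ", "))
  }
  pass <- ifelse(kind == "nucleus",
                 metrics$mapped_reads > nucleus_thresholds$mapped_reads &
                   metrics$pct_aligned > nucleus_thresholds$pct_aligned &
                   metrics$pct_unique > nucleus_thresholds$pct_unique,
                 metrics$mapped_reads > cell_thresholds$mapped_reads &
                   metrics$genes_detected > cell_thresholds$genes_detected)
  as.character(metrics$sample_id[pass])
}

#' Gene-detection confidence band from a half-split of samples
#'
#' Estimates the variability of per-gene detection proportions expected from
#' population sampling alone. Samples are split at random into two halves;
#' genes are binned by their detection proportion in the first half and, per
#' bin, the upper quantile (default 97.5th percentile) of detection in the
#' second half is recorded. A two-sided band follows by reflecting the binned
#' quantiles across the line of unity: a point (x, y) lies inside the band
#' iff y <= upper(x) and x <= upper(y).
#'
#' @param x an [expression_matrix()] of the reference population (e.g. cells).
#' @param n_bins number of detection bins on `[0, 1]`.
#' @param quantile upper quantile per bin.
#' @param seed RNG seed for the random half-split.
#' @param split optional integer/logical index picking the first half
#'   explicitly (overrides the random split).
#' @return object of class `detection_band`: list with the bin `breaks`,
#'   per-bin `upper` bounds, the per-gene detection proportions in each half
#'   (`detection`), and the `quantile` used.
#' @export
detection_confidence_band <- function(x, n_bins = 50, quantile = 0.975,
                                      seed = 1, split = NULL) {
  n <- length(x$samples)
  if (n < 2) {
    stop("at least 2 samples are required for a half-split")
  }
  if (is.null(split)) {
    split <- with_seed(seed, sample.int(n, floor(n / 2)))
  }
  if (is.logical(split)) split <- which(split)
  detected <- suppressWarnings(compute_cpm(x) > 0)
  det1 <- rowMeans(detected[, split, drop = FALSE])
  det2 <- rowMeans(detected[, -split, drop = FALSE])
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(det1, breaks, include.lowest = TRUE, labels = FALSE)
  upper <- vapply(seq_len(n_bins), function(b) {
    v <- det2[bin == b]
    if (length(v) == 0) NA_real_ else stats::quantile(v, quantile, names = FALSE)
  }, numeric(1))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (anyNA(upper)) {
    # interpolate across empty bins so the band is defined on all of [0, 1]
    ok <- !is.na(upper)
    if (sum(ok) == 0) stop("no genes available to form the band")
    upper <- stats::approx(centers[ok], upper[ok], xout = centers, rule = 2)$y
  }
  upper <- cummax(upper) # detection quantiles are monotone in detection
  structure(list(breaks = breaks, centers = centers, upper = upper,
                 quantile = quantile,
                 detection = data.frame(gene = x$genes, det1 = det1, det2 = det2)),
            class = "detection_band")
}

band_upper <- function(band, x) {
  b <- findInterval(x, band$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  band$upper[b]
}

#' Test points against a detection confidence band
#'
#' @param band a [detection_confidence_band()].
#' @param x,y detection proportions (first and second half, or any paired
#'   detection measurements on `[0, 1]`).
#' @return logical vector: `TRUE` when (x, y) lies inside the (reflected,
#'   two-sided) band.
#' @export
in_band <- function(band, x, y) {
  y <= band_upper(band, x) & x <= band_upper(band, y)
}
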