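#' Fit per-sample logistic dropout models
#'
#' For each sample, the expected expression of every gene is taken as the
#' mean log2(CPM + 1) over the sample's `k_neighbors` most-correlated
#' samples (zeros in neighbors are treated as missing so the expectation
#' reflects expression magnitude when detected). A logistic regression of
#' the sample's detected/undetected indicator on this expected expression
#' gives the dropout-probability curve
#' `p(dropout | x) = 1 - plogis(intercept + slope * x)`.
#' Slopes are constrained non-negative so dropout probability is monotone
#' non-increasing in expression; samples with no zeros (or no detected
#' genes) get a flat curve clamped at probability 0.01 (or 0.99) with a
#' warning.
#'
#' @param x an [expression_matrix()].
#' @param k_neighbors number of nearest neighbors (by Pearson correlation of
#'   log expression) used to form expected expression; default 8.
#' @param reads read layer(s) used for expression.
#' @return object of class `noise_model`: per-sample logistic `intercept` and
#'   `slope`, the gene x sample matrix of neighborhood expected expression
#'   (`xbar`), and the neighbor sets used.
#' @export
fit_dropout_model <- function(x, k_neighbors = 8,
                              reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  E <- suppressWarnings(log_cpm(x, reads))
  n <- ncol(E)
  if (n < 2) stop("at least 2 samples are required")
  k <- min(k_neighbors, n - 1)
  cors <- suppressWarnings(stats::cor(E))
  cors[is.na(cors)] <- 0
  diag(cors) <- -Inf
  xbar <- matrix(0, nrow(E), n, dimnames = dimnames(E))
  intercept <- slope <- numeric(n)
  neighbors <- vector("list", n)
  for (s in seq_len(n)) {
    nb <- order(cors[, s], decreasing = TRUE)[seq_len(k)]
    neighbors[[s]] <- colnames(E)[nb]
    sub <- E[, nb, drop = FALSE]
    nz <- sub > 0
    xbar[, s] <- rowSums(sub) / pmax(rowSums(nz), 1)
    detected <- E[, s] > 0
    if (all(detected) || all(!detected)) {
      warning(sprintf("sample %s has no %s; dropout probability clamped",
                      colnames(E)[s], if (all(detected)) "zeros" else "detected genes"))
      slope[s] <- 0
      intercept[s] <- stats::qlogis(if (all(detected)) 0.99 else 0.01)
      next
    }
    fit <- suppressWarnings(stats::glm.fit(cbind(1, xbar[, s]), detected,
                                           family = stats::binomial()))
    co <- fit$coefficients
    if (anyNA(co)) co <- c(stats::qlogis(mean(detected)), 0)
    if (co[2] < 0) { # enforce monotone dropout; refit as intercept-only
      co <- c(stats::qlogis(mean(detected)), 0)
    }
    intercept[s] <- co[1]
    slope[s] <- co[2]
  }
  structure(list(samples = colnames(E), intercept = intercept, slope = slope,
                 xbar = xbar, k_neighbors = k, reads = reads,
                 neighbors = neighbors),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d samples, k = %d neighbors (%s reads)\n",
              length(x$samples), x$k_neighbors, x$reads))
  invisible(x)
}

#' Dropout probability at given expression values
#'
#' @param model a [fit_dropout_model()].
#' @param values log2(CPM + 1) expression values.
#' @param sample sample name or index whose curve to evaluate.
#' @return dropout probabilities in `[0, 1]`, non-increasing in `values`.
#' @export
predict_dropout <- function(model, values, sample) {
  if (is.character(sample)) sample <- match(sample, model$samples)
  1 - stats::plogis(model$intercept[sample] + model$slope[sample] * values)
}

#' Per-gene, per-sample dropout weights
#'
#' Combines the dropout probability at the observed expression, p(x_sg), and
#' at the neighborhood expected expression, p(xbar_g), into a confidence
#' weight. The default (`"printed"`) form is
#' `W_sg = 1 - p(x_sg) * p(x_sg) * p(xbar_g)`; the `"simple"` alternative
#' drops the squaring: `W_sg = 1 - p(x_sg) * p(xbar_g)`.
#'
#' @param model a [fit_dropout_model()].
#' @param x the [expression_matrix()] the model was fit to.
#' @param formula `"printed"` (default) or `"simple"`.
#' @return gene x sample matrix of weights in `[0, 1]`.
#' @export
dropout_weights <- function(model, x, formula = c("printed", "simple")) {
  formula <- match.arg(formula)
  E <- suppressWarnings(log_cpm(x, model$reads))
  E <- E[, model$samples, drop = FALSE]
  p_obs <- 1 - stats::plogis(sweep(sweep(E, 2, model$slope, "*"), 2,
                                   model$intercept, "+"))
  p_exp <- 1 - stats::plogis(sweep(sweep(model$xbar, 2, model$slope, "*"), 2,
                                   model$intercept, "+"))
  w <- if (formula == "printed") 1 - p_obs * p_obs * p_exp else 1 - p_obs * p_exp
  pmin(pmax(w, 0), 1)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation weights (weighted means,
#' variances and covariance). Reduces to the ordinary Pearson correlation
#' when all weights are equal; zero-weight observations are excluded
#' exactly.
#'
#' @param x,y numeric vectors.
#' @param w non-negative weights, same length.
#' @return correlation in `[-1, 1]`, or `NA` when a weighted variance is 0.
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  sw <- sum(w)
  if (sw <= 0) stop("weights must have positive sum")
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) {
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# Weighted correlations of one reference column against all columns of a
# matrix, with per-column weights (genes x columns). Vectorized counterpart
# of weighted_correlation() used by the matching step.
weighted_correlation_cols <- function(xref, wref, Y, W) {
  wp <- W * wref               # pairwise weights w_g = W_ref,g * W_col,g
  sw <- colSums(wp)
  mx <- colSums(wp * xref) / sw
  my <- colSums(wp * Y) / sw
  dx <- sweep(matrix(xref, nrow(Y), ncol(Y)), 2, mx, "-")
  dy <- sweep(Y, 2, my, "-")
  cov <- colSums(wp * dx * dy)
  vx <- colSums(wp * dx^2)
  vy <- colSums(wp * dy^2)
  out <- cov / sqrt(vx * vy)
  out[vx == 0 | vy == 0] <- NA_real_
  out
}

# Greedy extraction of best pairs from a (rows x cols) score matrix:
# repeatedly take the global maximum, emit it, and remove its row and
# column. Ties break on the lowest (row, column) index.
greedy_pairs <- function(score) {
  n <- min(nrow(score), ncol(score))
  rn <- rownames(score) %||% as.character(seq_len(nrow(score)))
  cn <- colnames(score) %||% as.character(seq_len(ncol(score)))
  out <- data.frame(row = character(n), col = character(n), score = numeric(n),
                    stringsAsFactors = FALSE)
  live_r <- seq_len(nrow(score))
  live_c <- seq_len(ncol(score))
  for (k in seq_len(n)) {
    sub <- score[live_r, live_c, drop = FALSE]
    best <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2])[1], , drop = FALSE]
    i <- live_r[best[1]]
    j <- live_c[best[2]]
    out$row[k] <- rn[i]
    out$col[k] <- cn[j]
    out$score[k] <- score[i, j]
    live_r <- setdiff(live_r, i)
    live_c <- setdiff(live_c, j)
  }
  out
}

#' Greedy nucleus-to-cell matching by dropout-weighted correlation
#'
#' Computes dropout-weighted Pearson correlations between every nucleus and
#' every cell over the genes expressed in at least one nucleus and one cell,
#' then repeatedly emits the globally best-correlated (nucleus, cell) pair
#' and removes both from further consideration, until the nuclei (or cells)
#' are exhausted. Pairwise gene weights are the product of the two samples'
#' dropout weights.
#'
#' @param nuclei,cells [expression_matrix()] objects sharing a gene universe.
#' @param weights_nuclei,weights_cells optional gene x sample dropout-weight
#'   matrices (from [dropout_weights()]); defaults are unit weights.
#' @param reads read layer(s) used for expression.
#' @return data.frame with columns `nucleus`, `cell`, `weighted_r`, `rank`,
#'   ordered by emission (non-increasing correlation).
#' @export
greedy_match <- function(nuclei, cells, weights_nuclei = NULL,
                         weights_cells = NULL,
                         reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  shared <- intersect(nuclei$genes, cells$genes)
  En <- suppressWarnings(log_cpm(nuclei, reads))[shared, , drop = FALSE]
  Ec <- suppressWarnings(log_cpm(cells, reads))[shared, , drop = FALSE]
  keep <- rowSums(En > 0) > 0 & rowSums(Ec > 0) > 0
  if (!any(keep)) stop("no genes expressed in at least one nucleus and one cell")
  En <- En[keep, , drop = FALSE]
  Ec <- Ec[keep, , drop = FALSE]
  Wn <- if (is.null(weights_nuclei)) matrix(1, nrow(En), ncol(En)) else
    weights_nuclei[shared, , drop = FALSE][keep, , drop = FALSE]
  Wc <- if (is.null(weights_cells)) matrix(1, nrow(Ec), ncol(Ec)) else
    weights_cells[shared, , drop = FALSE][keep, , drop = FALSE]
  R <- matrix(NA_real_, ncol(En), ncol(Ec),
              dimnames = list(colnames(En), colnames(Ec)))
  for (i in seq_len(ncol(En))) {
    R[i, ] <- weighted_correlation_cols(En[, i], Wn[, i], Ec, Wc)
  }
  pairs <- greedy_pairs(R)
  data.frame(nucleus = pairs$row, cell = pairs$col, weighted_r = pairs$score,
             rank = seq_len(nrow(pairs)), stringsAsFactors = FALSE)
}
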