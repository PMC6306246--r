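#' Select significantly variable genes
#'
#' The dropout-weighted variance of each gene's log2(CPM + 1) profile is
#' compared to a running-median mean-variance trend across genes — the
#' expected variance of an unstructured gene at that expression level. The
#' adjusted variance is the ratio of observed to trend-expected variance,
#' so 1 is the null expectation at every expression level. A gene is
#' selected when its adjusted variance exceeds `threshold` and is
#' significant under a chi-square test with Benjamini-Hochberg correction
#' at `fdr` — "significantly variable". Constant genes have adjusted
#' variance 0. Each gene is winsorized (`trim` most extreme values per tail
#' clamped) before the variance is computed, so one or two outlying samples
#' cannot make a gene "variable".
#'
#' @param x an [expression_matrix()].
#' @param model a [fit_dropout_model()] for the same samples.
#' @param threshold adjusted-variance cutoff (default 1.25).
#' @param fdr Benjamini-Hochberg false-discovery-rate cutoff.
#' @param weights optional precomputed [dropout_weights()] matrix.
#' @param trim number of samples winsorized per tail (default: 3, reduced on
#'   small subsets).
#' @param reads read layer(s) used for expression.
#' @return character vector of selected genes, with a `"stats"` attribute
#'   data.frame (`gene`, `adjusted_variance`, `p`, `q`).
#' @export
select_variable_genes <- function(x, model, threshold = 1.25, fdr = 0.05,
                                  weights = NULL, trim = NULL,
                                  reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  E <- suppressWarnings(log_cpm(x, reads))
  n <- ncol(E)
  if (n < 2) stop("at least 2 samples are required")
  trim <- trim %||% min(3, max(0, floor(n / 15)))
  if (trim > 0) {
    E <- t(apply(E, 1, function(v) {
      s <- sort(v)
      pmin(pmax(v, s[trim + 1]), s[n - trim])
    }))
  }
  W <- weights %||% dropout_weights(model, x)
  mu <- rowMeans(E)
  sds <- sqrt(rowSums((E - mu)^2) / (n - 1))
  ok <- sds > 0
  z <- E[ok, , drop = FALSE]
  Wk <- W[ok, , drop = FALSE]
  vw <- vapply(seq_len(nrow(z)), function(g) weighted_var(z[g, ], Wk[g, ]),
               numeric(1))
  mu <- mu[ok]
  # trend of weighted variance over mean expression (running median)
  ord <- order(mu)
  trend <- numeric(length(vw))
  bw <- min(101, 2 * floor(length(vw) / 4) + 1)
  trend[ord] <- if (length(vw) >= 5) {
    # endrule "constant" keeps full-window medians at the extremes, so a run
    # of genuinely variable genes at the edge of the expression range cannot
    # inflate its own null expectation
    stats::runmed(vw[ord], k = max(3, bw), endrule = "constant")
  } else {
    rep(stats::median(vw), length(vw))
  }
  trend[trend <= 0] <- stats::median(vw[vw > 0]) %||% 1
  adj <- vw / trend
  # empirical null calibration, local in expression: the spread of the
  # variance ratio among unstructured genes is much wider at low expression
  # (zero inflation), so the chi-square reference is widened per expression
  # stratum to match the robust (MAD) spread of the stratum's ratios
  n_strata <- max(1, min(20, floor(length(adj) / 50)))
  stratum <- ceiling(rank(mu, ties.method = "first") / length(mu) * n_strata)
  df_eff <- numeric(length(adj))
  for (b in seq_len(n_strata)) {
    in_b <- stratum == b
    sigma <- stats::mad(adj[in_b], center = stats::median(adj[in_b]))
    phi <- max(1, sigma^2 / (2 / (n - 1)))
    df_eff[in_b] <- (n - 1) / phi
  }
  p <- stats::pchisq(adj * df_eff, df = df_eff, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  adj_full <- stats::setNames(rep(0, length(x$genes)), x$genes)
  adj_full[rownames(z)] <- adj
  sel <- rownames(z)[adj > threshold & q < fdr]
  stats_df <- data.frame(gene = x$genes, adjusted_variance = adj_full,
                         p = NA_real_, q = NA_real_, row.names = NULL)
  stats_df$p[match(rownames(z), stats_df$gene)] <- p
  stats_df$q[match(rownames(z), stats_df$gene)] <- q
  structure(sel, stats = stats_df)
}

#' Dropout-weighted principal components analysis
#'
#' PCA in sample space with the sample-pair covariance adjusted for
#' dropouts: each entry of the sample x sample covariance matrix is a
#' weighted average over genes with pairwise weights `W_sg * W_tg`,
#' normalized by their sum and rescaled so that with unit weights the
#' eigenvalues equal those of standard PCA on the scaled expression matrix.
#'
#' @param x an [expression_matrix()].
#' @param weights gene x sample matrix from [dropout_weights()] (unit
#'   weights if `NULL`).
#' @param genes genes to use (e.g. from [select_variable_genes()]).
#' @param max_pc maximum number of component coordinate vectors returned.
#' @param reads read layer(s) used for expression.
#' @return object of class `pc_embedding`: `components` (sample x PC
#'   coordinates, at most `max_pc` columns) and `eigenvalues` (full
#'   non-negative spectrum, non-increasing).
#' @export
weighted_pca <- function(x, weights = NULL, genes = x$genes, max_pc = 20,
                         reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  E <- suppressWarnings(log_cpm(x, reads))[genes, , drop = FALSE]
  n <- ncol(E)
  if (length(genes) < 2) stop("at least 2 genes are required")
  mu <- rowMeans(E)
  sds <- sqrt(rowSums((E - mu)^2) / (n - 1))
  ok <- sds > 0
  z <- (E[ok, , drop = FALSE] - mu[ok]) / sds[ok]
  W <- if (is.null(weights)) matrix(1, nrow(z), n) else
    weights[genes, , drop = FALSE][ok, , drop = FALSE]
  p <- nrow(z)
  num <- crossprod(z * W) # t(WZ) %*% (WZ) has entries sum_g Wsg Wtg zgs zgt
  den <- crossprod(W)
  C <- num / den * p / (n - 1)
  C[den == 0] <- 0
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- min(max_pc, sum(ev > 1e-12), n)
  comp <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)] * (n - 1)), k)
  rownames(comp) <- colnames(E)
  colnames(comp) <- paste0("PC", seq_len(k))
  structure(list(components = comp, eigenvalues = ev), class = "pc_embedding")
}

#' Broken-stick principal-component retention
#'
#' Retains the leading run of components whose explained-variance proportion
#' exceeds the broken-stick expectation `b_k = (1/p) * sum_{i=k..p} 1/i`,
#' capped at `max_pc`. A conservative null for how much variance the k-th
#' largest of p random "stick pieces" should explain.
#'
#' @param eigenvalues non-negative eigenvalues sorted in decreasing order.
#' @param max_pc retention cap.
#' @return integer count of retained components (possibly 0).
#' @export
broken_stick_retention <- function(eigenvalues, max_pc = 20) {
  p <- length(eigenvalues)
  total <- sum(eigenvalues)
  if (p == 0 || total <= 0) {
    return(0L)
  }
  props <- eigenvalues / total
  sticks <- rev(cumsum(1 / rev(seq_len(p)))) / p
  above <- props > sticks
  r <- if (!above[1]) 0L else which.min(c(above, FALSE)) - 1L
  as.integer(min(r, max_pc))
}

#' Jaccard shared-nearest-neighbor graph
#'
#' Builds an undirected weighted graph over samples in which the edge weight
#' between two samples is the Jaccard similarity of their k-nearest-neighbor
#' sets (Euclidean distance in PC space, self excluded). Zero-weight edges
#' are omitted. `k` is reduced to `n - 1` when 15 or fewer samples are
#' available.
#'
#' @param embedding a [weighted_pca()] result, or a sample x coordinate
#'   matrix.
#' @param k number of nearest neighbors (default 15).
#' @param n_pc number of leading coordinate columns to use (default all).
#' @return an `igraph` undirected weighted graph with one vertex per sample.
#' @export
jaccard_graph <- function(embedding, k = 15, n_pc = NULL) {
  coords <- if (inherits(embedding, "pc_embedding")) embedding$components else
    as.matrix(embedding)
  if (!is.null(n_pc)) coords <- coords[, seq_len(min(n_pc, ncol(coords))), drop = FALSE]
  n <- nrow(coords)
  if (n < 2) stop("at least 2 samples are required")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn[i, order(d[i, ])[seq_len(k)]] <- TRUE
  }
  inter <- tcrossprod(nn * 1)
  jac <- inter / (2 * k - inter)
  diag(jac) <- 0
  ij <- which(upper.tri(jac) & jac > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name",
                               value = rownames(coords) %||% as.character(seq_len(n)))
  if (nrow(ij) > 0) {
    g <- igraph::add_edges(g, t(ij), weight = jac[ij])
  }
  g
}

#' Louvain community detection with a fixed seed
#'
#' @param graph an undirected weighted `igraph` graph.
#' @param seed RNG seed controlling the Louvain node order.
#' @return list with `labels` (named integer membership vector) and
#'   `modularity` (Q of the returned partition).
#' @export
louvain_split <- function(graph, seed = 1) {
  w <- igraph::E(graph)$weight
  if (igraph::ecount(graph) == 0) {
    labels <- stats::setNames(seq_len(igraph::vcount(graph)),
                              igraph::V(graph)$name)
    return(list(labels = labels, modularity = 0))
  }
  cl <- with_seed(seed, igraph::cluster_louvain(graph, weights = w))
  labels <- stats::setNames(as.integer(igraph::membership(cl)),
                            igraph::V(graph)$name)
  list(labels = labels,
       modularity = igraph::modularity(graph, igraph::membership(cl), weights = w))
}

#' Expected modularity of an Erdős–Rényi random graph
#'
#' Null expectation for the modularity a community-detection algorithm finds
#' on a structureless graph with `n_nodes` nodes and connection probability
#' `edge_probability`. Two estimators are available: `"analytic"` returns
#' the larger of two closed-form approximations of the maximal random-graph
#' modularity — the fluctuation estimate
#' `(1 - 2/sqrt(n)) * (2/(n p))^(2/3)` and the spin-glass ground-state
#' estimate `0.97 / sqrt(n p)` — and `"monte_carlo"` averages the Louvain
#' modularity over simulated G(n, p) graphs. When both are requested the
#' maximum is returned.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edge_probability connection probability in (0, 1].
#' @param method estimator(s) to use; default both.
#' @param n_rep Monte Carlo replicates (must be >= 1 when `"monte_carlo"` is
#'   selected).
#' @param seed RNG seed for the Monte Carlo estimator.
#' @return expected modularity (a single number: the max over estimators).
#' @export
expected_modularity <- function(n_nodes, edge_probability,
                                method = c("analytic", "monte_carlo"),
                                n_rep = 20, seed = 1) {
  method <- match.arg(method, several.ok = TRUE)
  stopifnot(n_nodes >= 2, edge_probability > 0, edge_probability <= 1)
  est <- numeric(0)
  if ("analytic" %in% method) {
    np <- n_nodes * edge_probability
    est <- c(est,
             (1 - 2 / sqrt(n_nodes)) * (2 / np)^(2 / 3),
             0.97 / sqrt(np))
  }
  if ("monte_carlo" %in% method) {
    if (n_rep < 1) stop("monte_carlo requires at least 1 replicate")
    qs <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
      g <- igraph::sample_gnp(n_nodes, edge_probability)
      if (igraph::ecount(g) == 0) return(0)
      cl <- igraph::cluster_louvain(g)
      igraph::modularity(g, igraph::membership(cl))
    }, numeric(1)))
    est <- c(est, mean(qs))
  }
  max(est)
}

#' Marker genes between a pair of clusters
#'
#' A gene is a marker for one cluster of a pair when it is significantly
#' differentially expressed (Welch t-test on log2(CPM + 1),
#' Benjamini-Hochberg FDR < `fdr`) and either shows binary detection
#' (CPM > 1 in more than 50% of samples of one cluster and less than 10% of
#' the other) or a greater-than-`fold`-fold difference in mean CPM.
#'
#' @param x an [expression_matrix()].
#' @param labels named cluster assignment covering the samples of both
#'   clusters.
#' @param cluster_a,cluster_b the two cluster identifiers to compare.
#' @param fdr,fold,detect_high,detect_low,cpm_threshold criteria parameters.
#' @param reads read layer(s) used for expression.
#' @return data.frame of markers: `gene`, `higher_in` (cluster id), `q`,
#'   `fold_change`, `route` (`"binary"` or `"fold"`, binary preferred when
#'   both hold).
#' @export
pairwise_markers <- function(x, labels, cluster_a, cluster_b, fdr = 0.05,
                             fold = 100, detect_high = 0.5, detect_low = 0.1,
                             cpm_threshold = 1,
                             reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  sa <- names(labels)[labels == cluster_a]
  sb <- names(labels)[labels == cluster_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("both clusters need at least 2 samples for differential expression")
  }
  cpm <- suppressWarnings(compute_cpm(x, reads))
  lg <- log2(cpm + 1)
  p <- welch_test_rows(lg[, sa, drop = FALSE], lg[, sb, drop = FALSE])
  q <- stats::p.adjust(p, "BH")
  ma <- rowMeans(cpm[, sa, drop = FALSE])
  mb <- rowMeans(cpm[, sb, drop = FALSE])
  da <- rowMeans(cpm[, sa, drop = FALSE] > cpm_threshold)
  db <- rowMeans(cpm[, sb, drop = FALSE] > cpm_threshold)
  fc <- pmax(ma, mb) / pmax(pmin(ma, mb), .Machine$double.xmin)
  fc[ma == 0 & mb == 0] <- 1
  binary <- (da > detect_high & db < detect_low) | (db > detect_high & da < detect_low)
  marker <- q < fdr & (binary | fc > fold)
  idx <- which(marker)
  data.frame(gene = x$genes[idx],
             higher_in = as.character(ifelse(ma[idx] >= mb[idx], cluster_a,
                                             cluster_b)),
             q = q[idx],
             fold_change = fc[idx],
             route = ifelse(binary[idx], "binary", "fold"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# TRUE when each cluster of the pair has at least one marker elevated in it.
pair_has_markers <- function(x, labels, a, b, ...) {
  mk <- pairwise_markers(x, labels, a, b, ...)
  any(mk$higher_in == as.character(a)) && any(mk$higher_in == as.character(b))
}

cluster_centroids <- function(x, labels, reads = "both") {
  E <- suppressWarnings(log_cpm(x, reads))
  ids <- sort(unique(labels))
  out <- sapply(ids, function(k)
    rowMeans(E[, names(labels)[labels == k], drop = FALSE]))
  colnames(out) <- as.character(ids)
  out
}

#' Merge clusters lacking pairwise markers
#'
#' Iteratively merges the most similar pair of clusters (highest centroid
#' Pearson correlation of mean log expression) among pairs in which either
#' cluster lacks a marker gene against the other, until every remaining
#' pair has at least one marker in each direction.
#'
#' @param labels named cluster assignment.
#' @param x the [expression_matrix()] the labels refer to.
#' @param ... marker criteria passed to [pairwise_markers()].
#' @return merged named cluster assignment (cluster ids renumbered 1..K in
#'   order of first appearance).
#' @export
merge_unmarked <- function(labels, x, ...) {
  labels <- labels[x$samples[x$samples %in% names(labels)]]
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2) break
    cent <- cluster_centroids(x[, names(labels)], labels)
    pairs <- utils::combn(ids, 2)
    failing <- list()
    for (pp in seq_len(ncol(pairs))) {
      a <- pairs[1, pp]
      b <- pairs[2, pp]
      if (!pair_has_markers(x[, names(labels)], labels, a, b, ...)) {
        failing[[length(failing) + 1]] <-
          list(a = a, b = b, cor = stats::cor(cent[, as.character(a)],
                                              cent[, as.character(b)]))
      }
    }
    if (length(failing) == 0) break
    cors <- vapply(failing, `[[`, numeric(1), "cor")
    m <- failing[[which.max(cors)]]
    labels[labels == m$b] <- m$a
  }
  ids <- unique(labels)
  stats::setNames(match(labels, ids), names(labels))
}

#' Default parameters for iterative clustering
#'
#' @param vg_threshold,vg_fdr variable-gene selection parameters.
#' @param max_pc PC retention cap.
#' @param k_jaccard nearest neighbors for the Jaccard graph.
#' @param k_neighbors nearest neighbors for the dropout model.
#' @param min_size minimum cluster size.
#' @param weight_formula dropout weight formula (`"printed"` or `"simple"`).
#' @param modularity_method estimator(s) for [expected_modularity()].
#' @param marker_fdr,marker_fold marker criteria for cluster merging.
#' @param reads read layer(s) used for expression.
#' @return list of parameters for [iterative_cluster()].
#' @export
cluster_config <- function(vg_threshold = 1.25, vg_fdr = 0.05, max_pc = 20,
                           k_jaccard = 15, k_neighbors = 8, min_size = 3,
                           weight_formula = "printed",
                           modularity_method = "analytic",
                           marker_fdr = 0.05, marker_fold = 100,
                           reads = "both") {
  list(vg_threshold = vg_threshold, vg_fdr = vg_fdr, max_pc = max_pc,
       k_jaccard = k_jaccard, k_neighbors = k_neighbors, min_size = min_size,
       weight_formula = weight_formula, modularity_method = modularity_method,
       marker_fdr = marker_fdr, marker_fold = marker_fold, reads = reads)
}

# Attach clusters smaller than min_size to the most correlated larger cluster.
absorb_small_clusters <- function(labels, x, min_size) {
  repeat {
    tab <- table(labels)
    small <- names(tab)[tab < min_size]
    if (length(small) == 0 || length(tab) < 2) break
    cent <- cluster_centroids(x[, names(labels)], labels)
    colnames(cent) <- names(tab)
    s <- small[1]
    others <- setdiff(names(tab), s)
    cors <- vapply(others, function(o) stats::cor(cent[, s], cent[, o]), numeric(1))
    labels[labels == as.integer(s)] <- as.integer(others[which.max(cors)])
  }
  labels
}

#' Iterative graph-based clustering
#'
#' One round consists of: refit the dropout model on the subset, select
#' significantly variable genes, dropout-weighted PCA with broken-stick PC
#' retention, Jaccard nearest-neighbor graph, Louvain community detection,
#' a modularity significance gate (the split is kept only when observed
#' modularity exceeds the Erdős–Rényi expectation for a graph of matching
#' density), and merging of cluster pairs lacking mutual marker genes.
#' Accepted clusters are re-clustered recursively until one of four stop
#' criteria fires: (1) fewer than six samples, (2) no significantly
#' variable genes, (3) no principal components retained, (4) no significant
#' split.
#'
#' @param x an [expression_matrix()].
#' @param config a [cluster_config()].
#' @param seed integer seed; child recursions derive their seeds
#'   deterministically from it.
#' @return object of class `cluster_assignment`: `labels` (named integer
#'   vector over samples), `tree_path` (per-sample recursion path string),
#'   and `splits`, a data.frame logging each attempted split (`path`, `n`,
#'   `modularity_observed`, `modularity_expected`, `accepted`,
#'   `stop_criterion`).
#' @export
iterative_cluster <- function(x, config = cluster_config(), seed = 1) {
  splits <- list()
  log_split <- function(path, n, q_obs, q_exp, accepted, stop_criterion) {
    splits[[length(splits) + 1]] <<- data.frame(
      path = path, n = n, modularity_observed = q_obs,
      modularity_expected = q_exp, accepted = accepted,
      stop_criterion = stop_criterion, stringsAsFactors = FALSE)
  }

  recurse <- function(samples, path, seed) {
    leaf <- stats::setNames(rep(path, length(samples)), samples)
    n <- length(samples)
    if (n < 6) {
      log_split(path, n, NA, NA, FALSE, "fewer than six samples")
      return(leaf)
    }
    sub <- x[, samples]
    model <- fit_dropout_model(sub, k_neighbors = min(config$k_neighbors, n - 1),
                               reads = config$reads)
    W <- dropout_weights(model, sub, formula = config$weight_formula)
    vg <- select_variable_genes(sub, model, threshold = config$vg_threshold,
                                fdr = config$vg_fdr, weights = W,
                                reads = config$reads)
    if (length(vg) < 2) {
      log_split(path, n, NA, NA, FALSE, "no significantly variable genes")
      return(leaf)
    }
    emb <- weighted_pca(sub, W, genes = vg, max_pc = config$max_pc,
                        reads = config$reads)
    npc <- broken_stick_retention(emb$eigenvalues, max_pc = config$max_pc)
    if (npc == 0) {
      log_split(path, n, NA, NA, FALSE, "no significantly variable PCs")
      return(leaf)
    }
    g <- jaccard_graph(emb, k = config$k_jaccard, n_pc = npc)
    ls <- louvain_split(g, seed = seed)
    labels <- ls$labels
    dens <- igraph::ecount(g) / (n * (n - 1) / 2)
    q_exp <- if (dens > 0) {
      expected_modularity(n, dens, method = config$modularity_method,
                          seed = derive_seed(seed, 7))
    } else {
      Inf
    }
    if (length(unique(labels)) < 2 || ls$modularity <= q_exp) {
      log_split(path, n, ls$modularity, q_exp, FALSE, "no significant clusters")
      return(leaf)
    }
    labels <- absorb_small_clusters(labels, sub, config$min_size)
    if (length(unique(labels)) > 1) {
      labels <- merge_unmarked(labels, sub, fdr = config$marker_fdr,
                               fold = config$marker_fold, reads = config$reads)
    }
    if (length(unique(labels)) < 2) {
      log_split(path, n, ls$modularity, q_exp, FALSE, "no significant clusters")
      return(leaf)
    }
    log_split(path, n, ls$modularity, q_exp, TRUE, "")
    ids <- sort(unique(labels))
    out <- character(0)
    for (i in seq_along(ids)) {
      child <- names(labels)[labels == ids[i]]
      out <- c(out, recurse(child, paste0(path, ".", i), derive_seed(seed, i)))
    }
    out[samples]
  }

  paths <- recurse(x$samples, "1", seed)
  ids <- unique(paths)
  structure(list(labels = stats::setNames(match(paths, ids), names(paths)),
                 tree_path = paths,
                 clusters = stats::setNames(seq_along(ids), ids),
                 splits = do.call(rbind, splits)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d cluster(s)\n",
              length(x$labels), length(unique(x$labels))))
  print(table(x$labels))
  invisible(x)
}
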