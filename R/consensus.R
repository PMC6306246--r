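#' Bootstrap co-clustering matrix
#'
#' Repeats the full iterative clustering on random subsets of the samples
#' (default 80%, without replacement) and records, for every pair of
#' samples, the proportion of iterations in which both were drawn that
#' assigned them to the same cluster. Conditioning on joint inclusion keeps
#' the entries interpretable as probabilities; pairs never co-sampled are
#' `NA`.
#'
#' @param x an [expression_matrix()].
#' @param config a [cluster_config()].
#' @param n_iter number of bootstrap iterations (default 100).
#' @param subsample_fraction fraction of samples drawn per iteration.
#' @param seed integer seed; per-iteration seeds are derived from it.
#' @return object of class `cocluster_matrix`: `M` (symmetric sample x
#'   sample proportions, unit diagonal), `co_sampled` (pair counts of joint
#'   inclusion), and `n_clusters_per_iter`.
#' @export
cocluster <- function(x, config = cluster_config(), n_iter = 100,
                      subsample_fraction = 0.8, seed = 1) {
  stopifnot(n_iter >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  n <- length(x$samples)
  together <- matrix(0, n, n, dimnames = list(x$samples, x$samples))
  co_sampled <- together
  n_clusters <- integer(n_iter)
  m <- max(2, floor(subsample_fraction * n))
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it)
    idx <- with_seed(it_seed, sort(sample.int(n, m)))
    ca <- iterative_cluster(x[, idx], config, seed = derive_seed(it_seed, 1))
    lab <- ca$labels[x$samples[idx]]
    same <- outer(lab, lab, "==") * 1
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    together[idx, idx] <- together[idx, idx] + same
    n_clusters[it] <- length(unique(lab))
  }
  M <- together / co_sampled
  M[co_sampled == 0] <- NA
  diag(M) <- 1
  structure(list(M = M, co_sampled = co_sampled,
                 n_clusters_per_iter = n_clusters, n_iter = n_iter),
            class = "cocluster_matrix")
}

#' Consensus clusters from a co-clustering matrix
#'
#' Applies average-linkage hierarchical clustering to the co-clustering
#' distance `1 - M`, then scans cut heights 0.01, 0.02, ..., 0.99 and keeps
#' the height whose cluster count is closest to the median per-iteration
#' cluster count (smallest height on ties). Clusters smaller than
#' `min_size` are absorbed into the cluster with the highest mean
#' co-clustering.
#'
#' @param cc a [cocluster()] result (or a bare symmetric matrix).
#' @param cluster_counts per-iteration cluster counts whose median anchors
#'   the cut (default: taken from `cc`).
#' @param min_size minimum cluster size.
#' @return a `cluster_assignment` with consensus `labels`, plus the chosen
#'   `cut_height` and the `hclust` tree.
#' @export
consensus_cut <- function(cc, cluster_counts = NULL, min_size = 3) {
  M <- if (inherits(cc, "cocluster_matrix")) cc$M else as.matrix(cc)
  cluster_counts <- cluster_counts %||%
    (if (inherits(cc, "cocluster_matrix")) cc$n_clusters_per_iter else
      stop("cluster_counts required when cc is a bare matrix"))
  if (anyNA(M)) {
    M[is.na(M)] <- mean(M, na.rm = TRUE) # rare never-co-sampled pairs
  }
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  heights <- seq(0.01, 0.99, by = 0.01)
  counts <- vapply(heights, function(h) {
    length(unique(stats::cutree(hc, h = h)))
  }, integer(1))
  target <- stats::median(cluster_counts)
  best <- which.min(abs(counts - target)) # ties: smallest height wins
  labels <- stats::cutree(hc, h = heights[best])
  if (length(unique(labels)) > 1) {
    labels <- absorb_small_by_coclustering(labels, M, min_size)
  }
  ids <- unique(labels)
  labels <- stats::setNames(match(labels, ids), rownames(M))
  structure(list(labels = labels,
                 tree_path = as.character(labels),
                 cut_height = heights[best],
                 hclust = hc,
                 splits = NULL),
            class = "cluster_assignment")
}

absorb_small_by_coclustering <- function(labels, M, min_size) {
  repeat {
    tab <- table(labels)
    small <- names(tab)[tab < min_size]
    if (length(small) == 0 || length(tab) < 2) break
    s <- small[1]
    members <- labels == s
    others <- setdiff(names(tab), s)
    means <- vapply(others, function(o) {
      mean(M[members, labels == o, drop = FALSE])
    }, numeric(1))
    labels[members] <- as.integer(others[which.max(means)])
  }
  labels
}

#' Cohesion and separation of consensus clusters
#'
#' Cohesion is the average within-cluster co-clustering; separation is
#' cohesion minus the maximum average between-cluster co-clustering. Both
#' are reported per cluster and, analogously, per sample (each sample's
#' average co-clustering with its own cluster minus its maximum average
#' with any other cluster). With a single cluster separation is undefined
#' and reported as `NA`.
#'
#' @param cc a [cocluster()] result or symmetric co-clustering matrix.
#' @param labels named cluster assignment (or `cluster_assignment`).
#' @return list with data.frames `cluster` (`cluster`, `n`, `cohesion`,
#'   `separation`) and `sample` (`sample`, `cluster`, `within`,
#'   `separation`).
#' @export
quality_metrics <- function(cc, labels) {
  M <- if (inherits(cc, "cocluster_matrix")) cc$M else as.matrix(cc)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- labels[rownames(M)]
  ids <- sort(unique(labels))
  single <- length(ids) < 2
  cohesion <- vapply(ids, function(k) {
    mem <- which(labels == k)
    if (length(mem) < 2) return(1)
    sub <- M[mem, mem]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  between <- function(a, b) {
    mean(M[labels == a, labels == b, drop = FALSE], na.rm = TRUE)
  }
  separation <- vapply(seq_along(ids), function(i) {
    if (single) return(NA_real_)
    cohesion[i] - max(vapply(ids[ids != ids[i]], function(b)
      between(ids[i], b), numeric(1)))
  }, numeric(1))
  sample_within <- vapply(seq_along(labels), function(s) {
    own <- which(labels == labels[s])
    own <- setdiff(own, s)
    if (length(own) == 0) return(1)
    mean(M[s, own], na.rm = TRUE)
  }, numeric(1))
  sample_sep <- vapply(seq_along(labels), function(s) {
    if (single) return(NA_real_)
    other <- ids[ids != labels[s]]
    sample_within[s] - max(vapply(other, function(b)
      mean(M[s, labels == b], na.rm = TRUE), numeric(1)))
  }, numeric(1))
  list(cluster = data.frame(cluster = ids,
                            n = as.integer(table(labels)[as.character(ids)]),
                            cohesion = cohesion, separation = separation,
                            row.names = NULL),
       sample = data.frame(sample = names(labels), cluster = labels,
                           within = sample_within, separation = sample_sep,
                           row.names = NULL))
}

#' Final separation- and marker-based cluster merge
#'
#' Iteratively merges cluster pairs that are insufficiently separated in
#' co-clustering (pair separation, the smaller of the two cohesions minus
#' the between-pair co-clustering, below `separation_threshold`) or in which
#' either cluster lacks a marker gene against the other. The failing pair
#' with the highest between-cluster co-clustering merges first; merging
#' stops when every remaining pair passes both criteria.
#'
#' @param labels named cluster assignment (or `cluster_assignment`).
#' @param cc a [cocluster()] result or co-clustering matrix.
#' @param x the [expression_matrix()] on which markers are recomputed.
#' @param separation_threshold minimum pair separation (default 0.25).
#' @param ... marker criteria passed to [pairwise_markers()].
#' @return merged named cluster assignment as a `cluster_assignment`.
#' @export
final_merge <- function(labels, cc, x, separation_threshold = 0.25, ...) {
  M <- if (inherits(cc, "cocluster_matrix")) cc$M else as.matrix(cc)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- labels[rownames(M)]
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2) break
    qm <- quality_metrics(M, labels)
    coh <- stats::setNames(qm$cluster$cohesion, qm$cluster$cluster)
    pairs <- utils::combn(ids, 2)
    failing <- list()
    for (pp in seq_len(ncol(pairs))) {
      a <- pairs[1, pp]
      b <- pairs[2, pp]
      btw <- mean(M[labels == a, labels == b, drop = FALSE], na.rm = TRUE)
      sep <- min(coh[as.character(a)], coh[as.character(b)]) - btw
      if (sep < separation_threshold ||
          !pair_has_markers(x[, names(labels)], labels, a, b, ...)) {
        failing[[length(failing) + 1]] <- list(a = a, b = b, between = btw)
      }
    }
    if (length(failing) == 0) break
    btws <- vapply(failing, `[[`, numeric(1), "between")
    m <- failing[[which.max(btws)]]
    labels[labels == m$b] <- m$a
  }
  ids <- unique(labels)
  labels <- stats::setNames(match(labels, ids), names(labels))
  structure(list(labels = labels, tree_path = as.character(labels),
                 splits = NULL),
            class = "cluster_assignment")
}
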