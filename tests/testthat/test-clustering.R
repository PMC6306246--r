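test_that("variable-gene selection excludes constants and recovers planted structure", {
  # planted bimodal genes among iid overdispersed noise genes
  set.seed(21)
  n <- 300
  G <- 1000
  mu_noise <- rlnorm(G, log(20), 1)   # spread of expression levels
  e <- matrix(rnbinom(G * n, mu = rep(mu_noise, n), size = 8), G, n)
  planted <- 1:100
  grp <- rep(c(0, 1), each = n / 2)
  mu_high <- exp(runif(length(planted), log(40), log(400)))
  for (g in planted) {
    e[g, ] <- rnbinom(n, mu = ifelse(grp == 1, mu_high[g], mu_high[g] / 60),
                      size = 8)
  }
  e[101, ] <- 0  # constant gene
  x <- expression_matrix(e, genes = paste0("g", 1:G),
                         samples = paste0("s", 1:n))
  model <- fit_dropout_model(x)
  vg <- select_variable_genes(x, model)
  stats_df <- attr(vg, "stats")
  expect_false("g101" %in% vg)
  expect_equal(stats_df$adjusted_variance[101], 0)
  expect_gte(mean(paste0("g", planted) %in% vg), 0.9)  # sensitivity
  expect_gte(mean(vg %in% paste0("g", planted)), 0.9)  # precision
  expect_true(all(stats_df$adjusted_variance[match(vg, stats_df$gene)] > 1.25))
})

test_that("weighted PCA with unit weights reproduces standard PCA", {
  set.seed(1)
  e <- matrix(rnbinom(300 * 40, mu = 20, size = 5), 300, 40)
  x <- expression_matrix(e, genes = paste0("g", 1:300),
                         samples = paste0("s", 1:40))
  emb <- weighted_pca(x, weights = NULL, genes = x$genes, max_pc = 20)
  lc <- log_cpm(x)
  z <- t(scale(t(lc)))
  pr <- prcomp(t(z), center = FALSE, scale. = FALSE)
  expect_lt(max(abs(emb$eigenvalues[1:20] - pr$sdev[1:20]^2)), 1e-8)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
})

test_that("duplicated samples receive identical embedding coordinates", {
  set.seed(2)
  e <- matrix(rpois(200 * 10, 15), 200, 10)
  e <- cbind(e, e[, 1])  # duplicate sample 1
  x <- expression_matrix(e, genes = paste0("g", 1:200),
                         samples = paste0("s", 1:11))
  emb <- weighted_pca(x, genes = x$genes, max_pc = 5)
  expect_equal(emb$components[1, ], emb$components[11, ], tolerance = 1e-6)
})

test_that("top PCs recover planted orthogonal signal directions", {
  # two orthogonal sample splits, each encoded by mass-balanced up/down gene
  # blocks so library composition stays constant
  set.seed(3)
  n <- 80
  split1 <- rep(c(0, 1), each = n / 2)
  split2 <- rep(rep(c(0, 1), each = n / 4), 2)
  e <- matrix(rpois(500 * n, 50), 500, n)
  for (i in 1:30)   e[i, ] <- rpois(n, 50 * ifelse(split1 == 1, 4, 0.25))
  for (i in 31:60)  e[i, ] <- rpois(n, 50 * ifelse(split1 == 1, 0.25, 4))
  for (i in 61:90)  e[i, ] <- rpois(n, 50 * ifelse(split2 == 1, 4, 0.25))
  for (i in 91:120) e[i, ] <- rpois(n, 50 * ifelse(split2 == 1, 0.25, 4))
  x <- expression_matrix(e, genes = paste0("g", 1:500),
                         samples = paste0("s", 1:n))
  emb <- weighted_pca(x, genes = x$genes, max_pc = 2)
  # principal angle between span(PC1,PC2) and the planted split directions
  S <- scale(cbind(split1, split2))
  P <- qr.Q(qr(emb$components[, 1:2]))
  Q <- qr.Q(qr(S))
  angle <- acos(min(svd(crossprod(Q, P))$d)) * 180 / pi
  expect_lt(angle, 5)
})

test_that("broken-stick retention matches the closed form", {
  # all-equal eigenvalues: no PC beats its stick
  expect_equal(broken_stick_retention(rep(2, 10)), 0L)
  expect_gte(broken_stick_retention(c(10, rep(1, 9))), 1L)
  # hand-computed 4-eigenvalue case: proportions .6 .2 .15 .05 versus
  # sticks .5208 .2708 .1458 .0625 -> only the first PC is retained
  ev <- c(.6, .2, .15, .05) * 42
  b <- sapply(1:4, function(k) sum(1 / (k:4)) / 4)
  expect_equal(round(b, 4), c(0.5208, 0.2708, 0.1458, 0.0625))
  expect_equal(broken_stick_retention(ev), 1L)
  expect_equal(broken_stick_retention(numeric(0)), 0L)
  expect_equal(broken_stick_retention(rep(1, 50), max_pc = 20), 0L)
})

test_that("jaccard graph weights equal brute-force Jaccard of k-NN sets", {
  set.seed(4)
  coords <- matrix(rnorm(12), 6, 2,
                   dimnames = list(paste0("s", 1:6), NULL))
  g <- jaccard_graph(coords, k = 2)
  # brute force
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  nn <- lapply(1:6, function(i) order(d[i, ])[1:2])
  am <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    jac <- length(intersect(nn[[i]], nn[[j]])) /
      length(union(nn[[i]], nn[[j]]))
    expect_equal(am[i, j], jac, tolerance = 1e-12)
  }
  # identical neighbor sets -> weight 1; disjoint -> no edge
  line <- cbind(c(0, 0.1, 0.2, 10, 10.1, 10.2), 0)
  rownames(line) <- paste0("p", 1:6)
  g2 <- jaccard_graph(line, k = 2)
  am2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(am2["p1", "p4"], 0)   # disjoint neighborhoods across the gap
  expect_equal(am2["p2", "p3"] > 0, TRUE)
})

test_that("louvain resolves two cliques joined by one edge and is seed-stable", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  g <- igraph::add_edges(g, c(1, 11))
  igraph::E(g)$weight <- 1
  ls <- louvain_split(g, seed = 1)
  expect_equal(length(unique(ls$labels)), 2)
  expect_equal(unname(ls$labels[1:10]), rep(ls$labels[[1]], 10))
  # exhaustive 2-partition check: no better 2-split than the cliques
  expect_gt(ls$modularity, 0.4)
  # complete graph: one community, Q ~ 0
  full <- igraph::make_full_graph(12)
  igraph::E(full)$weight <- 1
  lf <- louvain_split(full, seed = 2)
  expect_equal(length(unique(lf$labels)), 1)
  expect_lt(abs(lf$modularity), 1e-9)
  # determinism
  sim <- three_type_sim(seed = 7, cells = 10, genes = 600)
  emb <- weighted_pca(sim$cells, genes = sim$cells$genes, max_pc = 5)
  gg <- jaccard_graph(emb, k = 5)
  a <- louvain_split(gg, seed = 42)
  b <- louvain_split(gg, seed = 42)
  expect_identical(a$labels, b$labels)
})

test_that("expected modularity estimators agree and validate inputs", {
  expect_error(expected_modularity(100, 0.1, method = "monte_carlo", n_rep = 0),
               "at least 1 replicate")
  # complete graph: expected modularity near zero
  expect_lt(expected_modularity(100, 1), 0.15)
  # analytic and monte carlo agree within 0.1 at n=100, p=0.1
  qa <- expected_modularity(100, 0.1, method = "analytic")
  qm <- expected_modularity(100, 0.1, method = "monte_carlo", n_rep = 20,
                            seed = 6)
  expect_lt(abs(qa - qm), 0.1)
})

test_that("pairwise markers require significance plus binary or fold criteria", {
  set.seed(8)
  n <- 20
  e <- matrix(rpois(300 * 2 * n, 20), 300, 2 * n)
  # gene 1: binary route (60% vs 5% detection); gene 2: fold route
  e[1, ] <- c(rbinom(n, 1, 0.6) * 50, rbinom(n, 1, 0.05) * 50)
  e[2, ] <- c(rpois(n, 300), rpois(n, 2))
  x <- expression_matrix(e, genes = paste0("g", 1:300),
                         samples = paste0("s", 1:(2 * n)))
  labels <- setNames(rep(1:2, each = n), x$samples)
  mk <- pairwise_markers(x, labels, 1, 2)
  expect_true("g1" %in% mk$gene)
  expect_true("g2" %in% mk$gene)
  expect_equal(mk$higher_in[mk$gene %in% c("g1", "g2")], c("1", "1"))
  # identical clusters: no markers
  labels2 <- setNames(rep(1:2, n), x$samples)  # interleaved random split
  e2 <- matrix(rpois(300 * 2 * n, 20), 300, 2 * n)
  x2 <- expression_matrix(e2, genes = paste0("g", 1:300),
                          samples = paste0("s", 1:(2 * n)))
  expect_equal(nrow(pairwise_markers(x2, labels2, 1, 2)), 0)
})

test_that("clusters lacking mutual markers are merged back", {
  # random split of one homogeneous population collapses to one cluster
  sim0 <- noise_sim(seed = 13, cells = 30, genes = 500)
  labels <- setNames(rep(1:2, 15), sim0$cells$samples)
  merged <- merge_unmarked(labels, sim0$cells)
  expect_equal(length(unique(merged)), 1)
  # three planted types with strong markers survive unmerged
  sim <- three_type_sim(seed = 7, cells = 15, genes = 800)
  truth <- sim$truth$type_of_sample$cells
  labels3 <- setNames(match(truth, sort(unique(truth))), names(truth))
  merged3 <- merge_unmarked(labels3, sim$cells)
  expect_equal(length(unique(merged3)), 3)
  # determinism
  expect_identical(merge_unmarked(labels3, sim$cells), merged3)
})

test_that("iterative clustering obeys its stop criteria", {
  # fewer than six samples: single cluster
  sim <- three_type_sim(seed = 7, cells = 15, genes = 600)
  small <- sim$cells[, 1:5]
  ca <- iterative_cluster(small, seed = 1)
  expect_equal(length(unique(ca$labels)), 1)
  expect_match(ca$splits$stop_criterion[1], "fewer than six")
  # structureless data: single cluster across seeds
  sim0 <- noise_sim(seed = 3, cells = 60, genes = 1000)
  counts <- vapply(1:8, function(s)
    length(unique(iterative_cluster(sim0$cells, seed = s)$labels)), integer(1))
  expect_gte(mean(counts == 1), 0.95)
})

test_that("three well-separated planted types are recovered exactly", {
  sim <- three_type_sim(seed = 7, cells = 50, genes = 2000)
  ca <- iterative_cluster(sim$cells, seed = 11)
  truth <- sim$truth$type_of_sample$cells[names(ca$labels)]
  expect_equal(adjusted_rand_index(ca$labels, truth), 1.0)
  expect_equal(length(unique(ca$labels)), 3)
  # splits only accepted when observed modularity beats the null
  acc <- ca$splits[ca$splits$accepted, ]
  expect_true(all(acc$modularity_observed > acc$modularity_expected))
})

test_that("relabeling samples permutes cluster output identically", {
  sim <- three_type_sim(seed = 29, cells = 20, genes = 800)
  x <- sim$cells
  perm <- compartseq:::with_seed(2, sample.int(length(x$samples)))
  xp <- x[, perm]
  a <- iterative_cluster(x, seed = 5)
  b <- iterative_cluster(xp, seed = 5)
  # same partition of the same samples, up to label names
  expect_equal(adjusted_rand_index(a$labels[xp$samples], b$labels[xp$samples]), 1.0)
})
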