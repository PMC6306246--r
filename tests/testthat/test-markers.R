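test_that("beta score matches its closed-form anchor cases", {
  # uniform detection across clusters: score 0
  expect_equal(unname(beta_score(rep(0.7, 6), epsilon = 0)), 0)
  expect_equal(unname(beta_score(rep(0, 4), epsilon = 0)), 0)
  # perfectly binary marker: score 1 at epsilon = 0
  expect_equal(unname(beta_score(c(1, 0, 0, 0, 0), epsilon = 0)), 1)
  # explicit double-loop evaluation for (1, 0.5, 0)
  expect_equal(unname(beta_score(c(1, 0.5, 0), epsilon = 0)), 3 / 4)
  # general agreement with a brute-force double loop
  set.seed(6)
  for (i in 1:10) {
    p <- runif(5)
    num <- sum(outer(p, p, function(a, b) (a - b)^2))
    den <- sum(abs(outer(p, p, "-"))) + 1e-6
    expect_equal(unname(beta_score(p)), num / den, tolerance = 1e-12)
  }
})

test_that("beta is permutation invariant and respects the binary ordering", {
  set.seed(7)
  prof <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  b1 <- beta_score(prof)
  b2 <- beta_score(prof[, c(3, 1, 4, 2)])
  expect_equal(b1, b2)
  # a perfectly binary gene outranks any graded gene
  graded <- rbind(binary = c(1, 0, 0, 0), graded = c(1, .5, .3, 0))
  b <- beta_score(graded, epsilon = 0)
  expect_gt(b[["binary"]], b[["graded"]])
})

test_that("cluster dendrogram joins identical profiles first and matches hclust", {
  sim <- three_type_sim(seed = 9, cells = 10, genes = 600)
  truth <- sim$truth$type_of_sample$cells
  labels <- setNames(match(truth, sort(unique(truth))), names(truth))
  hc <- cluster_dendrogram(sim$cells, labels, n_markers = 1200)
  expect_s3_class(hc, "hclust")
  expect_equal(length(hc$order), 3)
  # brute-force linkage on a constructed toy with known correlations
  E <- rbind(c(10, 10, 0), c(0, 10, 10), c(5, 0, 10), c(10, 2, 3),
             matrix(rpois(40 * 3, 8), 40, 3))
  x <- expression_matrix(E, genes = paste0("g", 1:44),
                         samples = paste0("s", 1:3))
  lab1 <- setNames(1:3, x$samples)
  hc2 <- cluster_dendrogram(x, lab1, n_markers = 1200)
  prof <- detection_profile(x, lab1)
  beta <- beta_score(prof)
  top <- names(sort(beta, decreasing = TRUE))
  means <- sapply(1:3, function(k) log_cpm(x)[top, k])
  ref <- hclust(as.dist((1 - cor(means)) / 2), method = "complete")
  expect_equal(hc2$merge, ref$merge)
  expect_equal(hc2$height, ref$height, tolerance = 1e-12)
})

test_that("cluster matching recovers identity and permutations", {
  sim <- simulate_dataset(simulation_config(n_types = 5, cells_per_type = 12,
                                            nuclei_per_type = 4,
                                            n_genes = 800, seed = 33))
  truth <- sim$truth$type_of_sample$cells
  labels <- setNames(truth, names(truth))
  prof <- detection_profile(sim$cells, labels)
  beta <- beta_score(prof)
  self <- match_clusters(prof, prof, beta, beta)
  expect_equal(self$matches$ref, self$matches$query)
  expect_equal(nrow(self$matches), 5)
  expect_equal(unname(diag(self$correlation)), rep(1, 5), tolerance = 1e-12)
  # permuted cluster ids are recovered
  perm <- c(3, 5, 1, 2, 4)
  prof_p <- prof[, perm]
  colnames(prof_p) <- colnames(prof)
  mp <- match_clusters(prof, prof_p, beta, beta)
  expect_equal(mp$matches$query[match(colnames(prof)[perm], mp$matches$ref)],
               colnames(prof))
})

test_that("genes with zero beta weight drop out of cluster matching", {
  prof <- matrix(c(1, 0, 0,
                   0, 1, 0,
                   0.5, 0.5, 0.5), 3, 3, byrow = TRUE,
                 dimnames = list(c("m1", "m2", "flat"), paste0("c", 1:3)))
  beta <- beta_score(prof, epsilon = 0)
  expect_equal(unname(beta[["flat"]]), 0)
  m <- match_clusters(prof, prof, beta, beta, beta_min = -1,
                      max_clusters_expressed = 3)
  # the flat gene has weight min(0, 0) = 0: correlations computed on markers
  m2 <- match_clusters(prof[1:2, ], prof[1:2, ], beta[1:2], beta[1:2],
                       beta_min = -1, max_clusters_expressed = 3)
  expect_equal(m$correlation, m2$correlation)
})

test_that("nucleus-cell differential expression applies strict criteria", {
  set.seed(10)
  n <- 100
  base <- rpois(400, 20)
  en <- matrix(rpois(400 * n, base), 400, n)
  ec <- matrix(rpois(400 * n, base), 400, n)
  nuclei <- expression_matrix(en, genes = paste0("g", 1:400),
                              samples = paste0("n", 1:n))
  cells <- expression_matrix(ec, genes = paste0("g", 1:400),
                             samples = paste0("c", 1:n))
  de0 <- de_nuclei_vs_cells(nuclei, cells)
  expect_equal(sum(de0$significant), 0)
  # identical groups: no significant genes at all
  de_id <- de_nuclei_vs_cells(nuclei, nuclei)
  expect_equal(sum(de_id$significant), 0)
  # planted 3-fold genes are detected with high sensitivity
  ec3 <- ec
  planted <- 1:40
  ec3[planted, ] <- matrix(rpois(40 * n, base[planted] * 3), 40, n)
  cells3 <- expression_matrix(ec3, genes = paste0("g", 1:400),
                              samples = paste0("c", 1:n))
  de3 <- de_nuclei_vs_cells(nuclei, cells3)
  expect_gte(mean(de3$significant[planted]), 0.9)
  expect_true(all(de3$enriched_in[planted][de3$significant[planted]] == "cell"))
  # a gene at exactly 1.5-fold in mean CPM is not significant (strict >)
  expect_false(any(de3$significant & de3$fold_change <= 1.5))
})

test_that("detection comparison categories match a brute-force tally", {
  set.seed(11)
  pn <- runif(300)
  pc <- pmin(1, pmax(0, pn + sample(c(-0.3, 0, 0.3), 300, replace = TRUE) *
                          runif(300)))
  en <- matrix(rbinom(300 * 40, 1, pn) * 10, 300, 40)
  ec <- matrix(rbinom(300 * 40, 1, pc) * 10, 300, 40)
  nuclei <- expression_matrix(en, genes = paste0("g", 1:300),
                              samples = paste0("n", 1:40))
  cells <- expression_matrix(ec, genes = paste0("g", 1:300),
                             samples = paste0("c", 1:40))
  cmp <- compare_detection(nuclei, cells)
  dn <- rowMeans(en > 0)
  dc <- rowMeans(ec > 0)
  delta <- dc - dn
  brute <- ifelse(abs(delta) < 0.1, "similar",
                  ifelse(delta >= 0.25, "cell_biased",
                         ifelse(delta <= -0.25, "nucleus_biased", "intermediate")))
  expect_equal(cmp$category, brute)
  # identical matrices: everything similar
  cmp0 <- compare_detection(nuclei, nuclei)
  expect_true(all(cmp0$category == "similar"))
  # 80% of cells / 40% of nuclei -> cell biased
  en80 <- matrix(rep(c(rep(10, 16), rep(0, 24)), 2), 2, 40, byrow = TRUE)
  ec80 <- matrix(rep(c(rep(10, 32), rep(0, 8)), 2), 2, 40, byrow = TRUE)
  n80 <- expression_matrix(en80, genes = c("gA", "gB"),
                           samples = paste0("n", 1:40))
  c80 <- expression_matrix(ec80, genes = c("gA", "gB"),
                           samples = paste0("c", 1:40))
  expect_equal(compare_detection(n80, c80)$category, rep("cell_biased", 2))
})

test_that("through-origin beta regression equals the closed form", {
  set.seed(12)
  bn <- runif(200)
  expect_equal(marker_score_regression(bn, bn)$slope, 1.0)
  expect_equal(marker_score_regression(1.15 * bn, bn)$slope, 1.15,
               tolerance = 1e-12)
  bc <- 0.9 * bn + rnorm(200, 0, 0.05)
  expect_equal(marker_score_regression(bc, bn)$slope,
               sum(bn * bc) / sum(bn^2), tolerance = 1e-12)
})
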