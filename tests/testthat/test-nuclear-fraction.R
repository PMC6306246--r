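make_labeled_pair <- function(...) {
  sim <- simulate_dataset(simulation_config(...))
  list(sim = sim,
       lc = sim$truth$type_of_sample$cells,
       ln = sim$truth$type_of_sample$nuclei)
}

test_that("intron-ratio estimator follows its defining ratio", {
  # two constructed samples per compartment: cells 25% intronic, nuclei 50%
  ec <- matrix(c(75, 75), 1, 2)
  ic <- matrix(c(25, 25), 1, 2)
  en <- matrix(c(50, 50), 1, 2)
  in_ <- matrix(c(50, 50), 1, 2)
  cells <- expression_matrix(ec, ic, genes = "g1", samples = c("c1", "c2"))
  nuclei <- expression_matrix(en, in_, genes = "g1", samples = c("n1", "n2"))
  lab_c <- setNames(c("t1", "t1"), c("c1", "c2"))
  lab_n <- setNames(c("t1", "t1"), c("n1", "n2"))
  est <- fraction_from_introns(cells, nuclei, lab_c, lab_n)
  expect_equal(est$estimate, 0.5)
  # equal intron percentages give 1.0
  est1 <- fraction_from_introns(nuclei, nuclei, lab_n, lab_n)
  expect_equal(est1$estimate, 1.0)
  # zero nuclear intron fraction is an error
  dry <- expression_matrix(en, genes = "g1", samples = c("n1", "n2"))
  expect_error(fraction_from_introns(cells, dry, lab_c, lab_n),
               "zero intronic")
})

test_that("nuclear-gene estimator is exact on forced ratios", {
  # three nuclear genes with cell/nucleus exonic-CPM ratio exactly 0.3:
  # nuclei see only the nuclear compartment (30% of the cell library),
  # plus a filler gene holding the remaining cell reads
  genes <- c("Malat1", "Meg3", "Snhg11", "filler")
  ec <- matrix(c(30, 30, 30, 910), 4, 2)   # cell CPM of each marker: 30,000
  en <- matrix(c(100, 100, 100, 700), 4, 2) # nucleus CPM: 100,000 -> ratio 0.3
  cells <- expression_matrix(ec, genes = genes, samples = c("c1", "c2"))
  nuclei <- expression_matrix(en, genes = genes, samples = c("n1", "n2"))
  lab_c <- setNames(c("t1", "t1"), c("c1", "c2"))
  lab_n <- setNames(c("t1", "t1"), c("n1", "n2"))
  est <- fraction_from_nuclear_genes(cells, nuclei, lab_c, lab_n)
  expect_equal(est$estimate, 0.3, tolerance = 1e-9)
  # identical expression in both compartments: estimate 1
  est1 <- fraction_from_nuclear_genes(cells, cells, lab_c, lab_c)
  expect_equal(est1$estimate, 1.0)
  # missing genes are dropped with a warning; empty set errors
  nuc2 <- nuclei
  nuc2$genes[1] <- "Other"
  rownames(nuc2$exonic)[1] <- rownames(nuc2$intronic)[1] <- "Other"
  expect_warning(fraction_from_nuclear_genes(cells, nuc2, lab_c, lab_n),
                 "dropping")
  expect_error(fraction_from_nuclear_genes(cells, nuclei, lab_c, lab_n,
                                           gene_set = c("Xist")),
               "none of the nuclear genes")
})

test_that("both estimators recover generated per-type fractions", {
  pr <- make_labeled_pair(n_types = 3, cells_per_type = 100,
                          nuclei_per_type = 100, n_genes = 1500,
                          nuclear_fraction_per_type = c(0.2, 0.35, 0.5),
                          seed = 42)
  fi <- fraction_from_introns(pr$sim$cells, pr$sim$nuclei, pr$lc, pr$ln)
  fg <- fraction_from_nuclear_genes(pr$sim$cells, pr$sim$nuclei, pr$lc, pr$ln)
  truth <- pr$sim$truth$F_t[fi$type]
  expect_true(all(abs(fi$estimate - truth) < 0.05))
  expect_true(all(abs(fg$estimate - truth) < 0.05))
  expect_true(all(fi$sd >= 0) && all(fg$sd >= 0))
  cmpr <- compare_estimators(fi, fg)
  expect_equal(cmpr$spearman, 1.0)
  # ranking agrees with the planted truth
  expect_equal(order(fi$estimate), order(truth))
})

test_that("per-gene nuclear fractions are recovered and capped to [0, 1]", {
  pr <- make_labeled_pair(n_types = 3, cells_per_type = 100,
                          nuclei_per_type = 100, n_genes = 1500,
                          nuclear_fraction_per_type = c(0.2, 0.35, 0.5),
                          seed = 42)
  fg <- fraction_from_nuclear_genes(pr$sim$cells, pr$sim$nuclei, pr$lc, pr$ln)
  pg <- per_gene_nuclear_fraction(pr$sim$cells, pr$sim$nuclei, pr$lc, pr$ln,
                                  setNames(fg$estimate, fg$type))
  expect_true(all(pg$pi_hat >= 0 & pg$pi_hat <= 1))
  truth <- pr$sim$truth$pi_g[pg$gene]
  sub <- truth >= 0.1 & truth <= 0.9
  expect_lte(mean(abs(pg$pi_hat[sub] - truth[sub])), 0.1)
  # per-type values are capped at 1
  per_type <- attr(pg, "per_type")
  expect_true(all(per_type <= 1, na.rm = TRUE))
})

test_that("weighted cross-type averaging matches a double-loop oracle", {
  # two types with hand-set CPMs: gene g1 ratio*F = 0.8 and 0.4; weights from
  # mean log2(CPM+1) in cells of each type
  genes <- c("g1", "g2")
  cells_e <- cbind(t1a = c(200, 800), t1b = c(200, 800),
                   t2a = c(500, 500), t2b = c(500, 500))
  nuc_e <- cbind(t1a = c(400, 600), t1b = c(400, 600),
                 t2a = c(250, 750), t2b = c(250, 750))
  cells <- expression_matrix(cells_e, genes = genes)
  nuclei <- expression_matrix(nuc_e, genes = genes)
  lab_c <- setNames(c("t1", "t1", "t2", "t2"), colnames(cells_e))
  lab_n <- setNames(c("t1", "t1", "t2", "t2"), colnames(nuc_e))
  Fts <- c(t1 = 0.4, t2 = 0.8)
  pg <- per_gene_nuclear_fraction(cells, nuclei, lab_c, lab_n, Fts,
                                  cpm_threshold = 1, detect_prop = 0.5)
  # oracle, gene g1: type ratios (400/200)*0.4 = 0.8 (cap no), (250/500)*.8=0.4
  cpm <- function(v) v / sum(v) * 1e6
  w1 <- log2(cpm(c(200, 800))[1] + 1)
  w2 <- log2(cpm(c(500, 500))[1] + 1)
  expected_g1 <- (0.8 * w1 + 0.4 * w2) / (w1 + w2)
  expect_equal(pg$pi_hat[pg$gene == "g1"], expected_g1, tolerance = 1e-9)
  # capping: gene g2 type t2 ratio (750/500)*0.8 = 1.2 -> capped at 1
  per_type <- attr(pg, "per_type")
  expect_equal(per_type["g2", "t2"], 1)
})

test_that("area-to-volume conversion is exact and monotone", {
  expect_equal(volume_proportion_from_area(5, 5), 1.0)
  expect_equal(volume_proportion_from_area(1, 4), 0.125)
  r <- seq(0.1, 1, 0.1)
  props <- volume_proportion_from_area(r, rep(1, 10))
  expect_true(all(diff(props) > 0))
  expect_error(volume_proportion_from_area(-1, 2), "positive")
})

test_that("FISH slope estimator handles exact and degenerate inputs", {
  soma <- c(10, 20, 30, 40)
  exact <- data.frame(nuclear_count = 0.5 * soma, soma_count = soma)
  expect_equal(fish_nuclear_fraction(exact)$slope, 0.5, tolerance = 1e-12)
  zeros <- data.frame(nuclear_count = rep(0, 4), soma_count = soma)
  expect_equal(fish_nuclear_fraction(zeros)$slope, 0)
  flat <- data.frame(nuclear_count = c(1, 2, 3), soma_count = c(5, 5, 5))
  expect_error(fish_nuclear_fraction(flat), "zero variance")
  expect_error(fish_nuclear_fraction(exact[1:2, ]), "at least 3")
})

test_that("estimator comparison reports rank agreement and flags instability", {
  a <- c(t1 = 0.2, t2 = 0.3, t3 = 0.5)
  expect_equal(compare_estimators(a, a)$spearman, 1.0)
  expect_equal(compare_estimators(a, rev(unname(a)) * 1 + 0 * a)$spearman, -1.0)
  expect_warning(out <- compare_estimators(a[1:2], a[1:2]), "unstable")
  expect_false(out$stable)
})
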