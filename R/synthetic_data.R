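#' Configuration for the compartmentalized count simulator
#'
#' Describes a matched nucleus/cell study design with planted cell types.
#' The generative model distinguishes transcript compartments: every
#' transcript contributes exonic read mass, and unspliced (nuclear)
#' transcripts additionally contribute intronic read mass proportional to a
#' per-gene intron/exon length ratio. Nuclei carry only the nuclear
#' compartment; whole cells carry both. Consequently intronic reads arise
#' exclusively from nuclear transcripts, the assumption the downstream
#' nuclear-fraction estimators rely on.
#'
#' `nuclear_fraction_per_type` is interpreted at the read level: the expected
#' fraction of a whole cell's reads that derive from nuclear transcripts.
#' Per-gene transcript-level nuclear fractions are drawn from
#' `per_gene_nuclear_fraction_law` and rescaled per type (by root finding) so
#' the realized read-level fraction matches the requested value.
#'
#' @param n_types number of planted cell types.
#' @param cells_per_type,nuclei_per_type samples per type and compartment.
#' @param n_genes number of genes.
#' @param type_tree_depth depth of the binary relatedness hierarchy used to
#'   correlate type mean profiles.
#' @param marker_genes_per_type binary marker genes planted per type.
#' @param nuclear_fraction_per_type read-level nuclear fraction F_t, a single
#'   value in (0, 1] or one per type.
#' @param per_gene_nuclear_fraction_law list describing the distribution of
#'   per-gene transcript-level nuclear fractions pi_g; default
#'   `list(dist = "beta", shape1 = 2, shape2 = 2)`.
#' @param gene_length_law list describing the per-gene intron/exon read-mass
#'   ratio (a "length" factor: long genes yield relatively more intronic
#'   reads); default `list(dist = "lnorm", meanlog = log(0.8), sdlog = 0.8)`.
#'   Use `list(dist = "constant", value = r)` for a degenerate law.
#' @param library_size_law list for per-sample sequencing depth; default
#'   `list(dist = "lnorm", meanlog = log(5e5), sdlog = 0.3)`. Use
#'   `list(dist = "constant", value = N)` for equal depths.
#' @param dropout_midpoint,dropout_slope logistic dropout parameters: a gene
#'   with expected expression e is zeroed with probability
#'   `plogis(-dropout_slope * (log2(e + 1) - dropout_midpoint))`, so dropout
#'   probability is 0.5 at log2(CPM+1) = `dropout_midpoint` and decreases
#'   with expression. Set `dropout_midpoint = -Inf` to disable dropout.
#' @param count_dispersion negative-binomial size parameter; `Inf` gives
#'   Poisson counts.
#' @param count_law `"nbinom"` (default), `"poisson"`, or `"expected"`
#'   (deterministic rounded expected counts, the noiseless limit).
#' @param marker_fold fold elevation of a marker gene in its own type.
#' @param length_fraction_cor Gaussian-copula correlation coupling the gene
#'   length factor to the nuclear fraction (nucleus-enriched genes tend to be
#'   longer).
#' @param nuclear_genes names of planted highly expressed, purely nuclear
#'   genes (transcript-level pi = 1) mirroring canonical nuclear transcripts.
#' @param seed integer seed; fully determines the output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_types = 10,
                              cells_per_type = 20,
                              nuclei_per_type = 20,
                              n_genes = 2000,
                              type_tree_depth = 3,
                              marker_genes_per_type = 10,
                              nuclear_fraction_per_type = 0.35,
                              per_gene_nuclear_fraction_law = list(dist = "beta", shape1 = 2, shape2 = 2),
                              gene_length_law = list(dist = "lnorm", meanlog = log(0.8), sdlog = 0.8),
                              library_size_law = list(dist = "lnorm", meanlog = log(5e5), sdlog = 0.3),
                              dropout_midpoint = 1.5,
                              dropout_slope = 1,
                              count_dispersion = 10,
                              count_law = c("nbinom", "poisson", "expected"),
                              marker_fold = 50,
                              length_fraction_cor = 0.5,
                              nuclear_genes = c("Malat1", "Meg3", "Snhg11"),
                              seed = 1) {
  count_law <- match.arg(count_law)
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              nuclei_per_type = as.integer(nuclei_per_type),
              n_genes = as.integer(n_genes),
              type_tree_depth = as.integer(type_tree_depth),
              marker_genes_per_type = as.integer(marker_genes_per_type),
              nuclear_fraction_per_type = rep_len(nuclear_fraction_per_type, n_types),
              per_gene_nuclear_fraction_law = per_gene_nuclear_fraction_law,
              gene_length_law = gene_length_law,
              library_size_law = library_size_law,
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope,
              count_dispersion = count_dispersion,
              count_law = count_law,
              marker_fold = marker_fold,
              length_fraction_cor = length_fraction_cor,
              nuclear_genes = nuclear_genes,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_types >= 1, cells_per_type >= 1, nuclei_per_type >= 1,
              n_genes >= 1, marker_genes_per_type >= 0, type_tree_depth >= 0)
    if (any(nuclear_fraction_per_type <= 0 | nuclear_fraction_per_type > 1)) {
      stop("nuclear_fraction_per_type must lie in (0, 1]")
    }
    if (marker_genes_per_type * n_types + length(nuclear_genes) > n_genes) {
      stop("marker_genes_per_type x n_types exceeds the number of genes")
    }
  })
  class(cfg) <- "simulation_config"
  cfg
}

draw_law <- function(law, n) {
  switch(law$dist,
         constant = rep(law$value, n),
         lnorm = stats::rlnorm(n, law$meanlog, law$sdlog),
         beta = stats::rbeta(n, law$shape1, law$shape2),
         unif = stats::runif(n, law$min, law$max),
         stop("unknown distribution: ", law$dist))
}

# Quantile function of a law, for copula draws.
law_quantile <- function(law, p) {
  switch(law$dist,
         constant = rep(law$value, length(p)),
         lnorm = stats::qlnorm(p, law$meanlog, law$sdlog),
         beta = stats::qbeta(p, law$shape1, law$shape2),
         unif = stats::qunif(p, law$min, law$max),
         stop("unknown distribution: ", law$dist))
}

# Read-level nuclear fraction of a cell whose transcript-level per-gene
# nuclear fractions are pi, exonic read masses mu, intron/exon ratios r.
read_level_fraction <- function(mu, pi, r) {
  sum(mu * pi * (1 + r)) / sum(mu * (1 + pi * r))
}

# Rescale pi (capped at 1, fixed genes kept fixed) so the read-level nuclear
# fraction equals target.
calibrate_pi <- function(mu, pi_base, r, target, fixed = NULL) {
  f <- function(cc) {
    pi <- pmin(1, cc * pi_base)
    if (!is.null(fixed)) pi[fixed] <- pi_base[fixed]
    read_level_fraction(mu, pi, r) - target
  }
  if (f(1e6) < 0) {
    cc <- 1e6 # target unattainable even with pi == 1 everywhere; saturate
  } else if (f(1e-9) > 0) {
    cc <- 1e-9 # fixed purely nuclear genes already exceed the target
  } else {
    cc <- stats::uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
  }
  pi <- pmin(1, cc * pi_base)
  if (!is.null(fixed)) pi[fixed] <- pi_base[fixed]
  pi
}

#' Simulate a matched nucleus/cell dataset with known ground truth
#'
#' Draws per-type expected read-mass profiles (hierarchically related across
#' types, with planted binary marker genes), per-gene nuclear fractions and
#' intron/exon length factors, then samples negative-binomial counts for the
#' exonic and intronic layers with logistic expression-dependent dropout.
#' Whole cells carry nuclear plus cytoplasmic transcripts (intronic and
#' exonic reads); nuclei carry the nuclear compartment only.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cells` and `nuclei` (two
#'   [expression_matrix()] objects) and `truth`, a list holding
#'   `type_of_sample` (named character vectors for both compartments), `F_t`
#'   (read-level per-type nuclear fractions), `pi_g` (transcript-level
#'   per-gene nuclear fractions), `pi_gt` (per-type matrix), `marker_sets`,
#'   `mean_profiles` (expected per-layer read-mass matrices) and the length
#'   factors `r_g`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  G <- cfg$n_genes
  K <- cfg$n_types
  gene_ids <- sprintf("g%05d", seq_len(G))

  # baseline exonic read mass per gene (heavy-tailed, as in real libraries)
  mu_base <- stats::rlnorm(G, meanlog = 1, sdlog = 1.5)

  # hierarchical type profiles: shared lognormal perturbations applied to
  # progressively finer blocks of the type tree
  type_means <- matrix(mu_base, G, K)
  if (K > 1 && cfg$type_tree_depth > 0) {
    for (d in seq_len(cfg$type_tree_depth)) {
      blocks <- ceiling(seq_len(K) / (K / min(2^d, K)))
      for (b in unique(blocks)) {
        sel <- sample.int(G, max(1, round(0.05 * G)))
        fold <- stats::rlnorm(length(sel), 0, 0.6)
        type_means[sel, blocks == b] <- type_means[sel, blocks == b] * fold
      }
    }
  }

  # reserve genes for nuclear markers and type markers
  type_names <- paste0("type", seq_len(K))
  n_nuc <- length(cfg$nuclear_genes)
  reserved <- sample.int(G, n_nuc + cfg$marker_genes_per_type * K)
  nuc_idx <- if (n_nuc > 0) reserved[seq_len(n_nuc)] else integer(0)
  marker_sets <- stats::setNames(rep(list(character(0)), K), type_names)
  med <- stats::median(mu_base)
  if (cfg$marker_genes_per_type > 0) {
    for (t in seq_len(K)) {
      idx <- reserved[n_nuc + (t - 1) * cfg$marker_genes_per_type +
                        seq_len(cfg$marker_genes_per_type)]
      type_means[idx, ] <- med * 0.01
      type_means[idx, t] <- med * cfg$marker_fold
      marker_sets[[t]] <- gene_ids[idx]
    }
  }
  if (n_nuc > 0) {
    gene_ids[nuc_idx] <- cfg$nuclear_genes
    # highly expressed in every type (1-2% of baseline mass each), purely
    # nuclear
    type_means[nuc_idx, ] <- sum(mu_base) * stats::runif(n_nuc, 0.01, 0.02)
  }

  # per-gene nuclear fraction and length factor, coupled by a Gaussian copula
  z1 <- stats::rnorm(G)
  z2 <- stats::rnorm(G)
  rho <- cfg$length_fraction_cor
  pi_base <- law_quantile(cfg$per_gene_nuclear_fraction_law, stats::pnorm(z1))
  pi_base <- pmin(pmax(pi_base, 1e-4), 1)
  r_g <- law_quantile(cfg$gene_length_law,
                      stats::pnorm(rho * z1 + sqrt(1 - rho^2) * z2))
  if (n_nuc > 0) pi_base[nuc_idx] <- 1

  # calibrate per-type pi so realized read-level fraction matches F_t
  pi_gt <- matrix(NA_real_, G, K, dimnames = list(gene_ids, type_names))
  for (t in seq_len(K)) {
    pi_gt[, t] <- calibrate_pi(type_means[, t], pi_base, r_g,
                               cfg$nuclear_fraction_per_type[t],
                               fixed = nuc_idx)
  }

  # expected read masses per layer and compartment
  cell_exon <- type_means                      # all transcripts have exons
  cell_intron <- type_means * pi_gt * r_g      # nuclear transcripts only
  nuc_exon <- type_means * pi_gt
  nuc_intron <- cell_intron

  sample_counts <- function(mass_exon, mass_intron, n_samples, prefix, t) {
    total <- sum(mass_exon[, t]) + sum(mass_intron[, t])
    pe <- mass_exon[, t] / total
    pi_ <- mass_intron[, t] / total
    libs <- draw_law(cfg$library_size_law, n_samples)
    exonic <- matrix(0L, G, n_samples)
    intronic <- matrix(0L, G, n_samples)
    exp_cpm <- log2((pe + pi_) * 1e6 + 1)
    p_drop <- if (is.infinite(cfg$dropout_midpoint) && cfg$dropout_midpoint < 0) {
      rep(0, G)
    } else {
      stats::plogis(-cfg$dropout_slope * (exp_cpm - cfg$dropout_midpoint))
    }
    for (s in seq_len(n_samples)) {
      le <- libs[s] * pe
      li <- libs[s] * pi_
      if (cfg$count_law == "expected") {
        ce <- round(le)
        ci <- round(li)
      } else if (cfg$count_law == "poisson" || is.infinite(cfg$count_dispersion)) {
        ce <- stats::rpois(G, le)
        ci <- stats::rpois(G, li)
      } else {
        ce <- stats::rnbinom(G, mu = le, size = cfg$count_dispersion)
        ci <- stats::rnbinom(G, mu = li, size = cfg$count_dispersion)
      }
      if (cfg$count_law != "expected" && any(p_drop > 0)) {
        keep <- stats::runif(G) >= p_drop
        ce <- ce * keep
        ci <- ci * keep
      }
      exonic[, s] <- as.integer(ce)
      intronic[, s] <- as.integer(ci)
    }
    colnames(exonic) <- colnames(intronic) <-
      sprintf("%s_t%02d_%03d", prefix, t, seq_len(n_samples))
    list(exonic = exonic, intronic = intronic)
  }

  bind_type <- function(mass_exon, mass_intron, per_type, prefix) {
    parts <- lapply(seq_len(K), function(t)
      sample_counts(mass_exon, mass_intron, per_type, prefix, t))
    exonic <- do.call(cbind, lapply(parts, `[[`, "exonic"))
    intronic <- do.call(cbind, lapply(parts, `[[`, "intronic"))
    rownames(exonic) <- rownames(intronic) <- gene_ids
    expression_matrix(exonic, intronic)
  }

  cells <- bind_type(cell_exon, cell_intron, cfg$cells_per_type, "cell")
  nuclei <- bind_type(nuc_exon, nuc_intron, cfg$nuclei_per_type, "nuc")

  type_of <- function(samples) {
    stats::setNames(paste0("type", as.integer(sub(".*_t(\\d+)_.*", "\\1", samples))),
                    samples)
  }

  # overall per-gene transcript-level fraction: expression-weighted across types
  w <- log2(type_means + 1)
  pi_g <- rowSums(pi_gt * w) / rowSums(w)

  dimnames(cell_exon) <- dimnames(cell_intron) <- dimnames(nuc_exon) <-
    list(gene_ids, type_names)

  truth <- list(type_of_sample = list(cells = type_of(cells$samples),
                                      nuclei = type_of(nuclei$samples)),
                F_t = stats::setNames(cfg$nuclear_fraction_per_type, type_names),
                pi_g = stats::setNames(pi_g, gene_ids),
                pi_gt = pi_gt,
                marker_sets = marker_sets,
                mean_profiles = list(cell_exonic = cell_exon,
                                     cell_intronic = cell_intron,
                                     nucleus_exonic = nuc_exon,
                                     nucleus_intronic = cell_intron),
                r_g = stats::setNames(r_g, gene_ids))
  list(cells = cells, nuclei = nuclei, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes `cells/` and `nuclei/` expression directories (MTX + TSV) and a
#' `truth.json` with the ground-truth annotations.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$cells, file.path(dir, "cells"))
  write_expression(sim$nuclei, file.path(dir, "nuclei"))
  truth <- sim$truth
  # named vectors serialize as JSON objects so identifiers survive round-trips
  truth$type_of_sample <- lapply(truth$type_of_sample, as.list)
  truth$F_t <- as.list(truth$F_t)
  truth$pi_g <- as.list(truth$pi_g)
  truth$r_g <- as.list(truth$r_g)
  truth$pi_gt <- as.data.frame(truth$pi_gt)
  truth$mean_profiles <- NULL # large and reconstructible from the config
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate nucleus/soma cross-sectional area measurements
#'
#' Areas are drawn so that the derived volume proportion
#' `(nucleus_area / soma_area)^(3/2)` has mean approximately
#' `true_volume_ratio`; multiplicative lognormal noise with standard
#' deviation `noise_sd` (log scale) perturbs the per-cell area ratio.
#'
#' @param n_cells number of cells.
#' @param true_volume_ratio nuclear volume proportion in (0, 1].
#' @param noise_sd non-negative noise standard deviation (log scale).
#' @param seed RNG seed.
#' @return data.frame with columns `cell`, `nucleus_area`, `soma_area` (in
#'   arbitrary squared units).
#' @export
simulate_morphology <- function(n_cells, true_volume_ratio, noise_sd = 0, seed = 1) {
  stopifnot(n_cells >= 1, true_volume_ratio > 0, true_volume_ratio <= 1,
            noise_sd >= 0)
  with_seed(seed, {
    soma <- stats::rlnorm(n_cells, log(200), 0.2)
    area_ratio <- true_volume_ratio^(2 / 3) *
      exp(stats::rnorm(n_cells, 0, noise_sd))
    data.frame(cell = sprintf("cell_%04d", seq_len(n_cells)),
               nucleus_area = soma * pmin(area_ratio, 1),
               soma_area = soma)
  })
}

#' Simulate FISH spot counts in nucleus and soma
#'
#' Soma spot counts are Poisson with mean `mean_total`; nuclear counts are a
#' binomial thinning with probability `nuclear_fraction`, so the regression
#' slope of nuclear on soma counts equals the nuclear fraction.
#'
#' @param n_cells number of cells.
#' @param nuclear_fraction probability a spot lies in the nucleus, in `[0, 1]`.
#' @param mean_total mean total (soma) spot count per cell.
#' @param seed RNG seed.
#' @return data.frame with columns `cell`, `nuclear_count`, `soma_count`.
#' @export
simulate_fish_counts <- function(n_cells, nuclear_fraction, mean_total, seed = 1) {
  stopifnot(n_cells >= 1, nuclear_fraction >= 0, nuclear_fraction <= 1,
            mean_total > 0)
  with_seed(seed, {
    soma <- stats::rpois(n_cells, mean_total)
    nuc <- stats::rbinom(n_cells, soma, nuclear_fraction)
    data.frame(cell = sprintf("cell_%04d", seq_len(n_cells)),
               nuclear_count = nuc,
               soma_count = soma)
  })
}
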