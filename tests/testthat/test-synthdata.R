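test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 3, n_cpgs = 300, n_cases = 10,
                           n_controls = 10)
  g1 <- generate_paired_datasets(cfg)
  g2 <- generate_paired_datasets(cfg)
  expect_identical(g1$tissueA$beta, g2$tissueA$beta)
  expect_identical(g1$tissueB$detection_p, g2$tissueB$detection_p)
  expect_identical(g1$truth$causal_b, g2$truth$causal_b)
  g3 <- generate_paired_datasets(simulation_config(seed = 4, n_cpgs = 300,
                                                   n_cases = 10,
                                                   n_controls = 10))
  expect_false(identical(g1$tissueA$beta, g3$tissueA$beta))
})

test_that("beta values are strictly inside (0,1) and shapes are coherent", {
  cfg <- simulation_config(seed = 2, n_cpgs = 500, n_cases = 15,
                           n_controls = 15)
  g <- generate_paired_datasets(cfg)
  for (ds in list(g$tissueA, g$tissueB)) {
    expect_true(all(ds$beta > 0 & ds$beta < 1))
    expect_false(anyNA(ds$beta))
    expect_equal(nrow(ds$beta), nrow(ds$samples))
    expect_equal(ncol(ds$beta), nrow(ds$probes))
  }
  # 450K-within-EPIC: tissue A autosomes are a subset of tissue B's
  auto_a <- g$tissueA$probes$cpg[!g$tissueA$probes$chrom %in% c("chrX", "chrY")]
  auto_b <- g$tissueB$probes$cpg[!g$tissueB$probes$chrom %in% c("chrX", "chrY")]
  expect_true(all(auto_a %in% auto_b))
  expect_equal(length(auto_a), round(0.7 * length(auto_b)))
  # cell proportions sum to one exactly
  expect_equal(rowSums(g$truth$props_a), rep(1, nrow(g$tissueA$beta)))
})

test_that("causal sets respect the sharing fraction exactly", {
  cfg <- simulation_config(seed = 8, n_cpgs = 1000, frac_causal = 0.02,
                           cross_tissue_share = 0.8)
  g <- generate_paired_datasets(cfg)
  n_causal <- round(0.02 * 1000)
  expect_length(g$truth$causal_b, n_causal)
  expect_length(g$truth$causal_a, round(0.8 * n_causal))
  expect_true(all(g$truth$causal_a %in% g$truth$causal_b))
  expect_true(all(g$truth$causal_a %in% g$tissueA$probes$cpg))
})

test_that("no planted signal means equal group means within Monte-Carlo error", {
  cfg <- simulation_config(seed = 12, n_cpgs = 400, n_cases = 25,
                           n_controls = 25, effect_size_m = 0, slide_sd = 0,
                           n_celltypes = 1, frac_causal = 0,
                           dirichlet_conc_control = 5,
                           dirichlet_conc_case = 5,
                           confounders = lapply(default_confounders(),
                                                function(x) {
                                                  x$frac_causal <- 0; x
                                                }),
                           include_sex_chroms = FALSE)
  g <- generate_paired_datasets(cfg)
  dx <- g$tissueB$samples$diagnosis
  diff <- colMeans(g$tissueB$beta[dx == "case", ]) -
    colMeans(g$tissueB$beta[dx == "control", ])
  se <- sqrt(apply(g$tissueB$beta, 2, var) * (1 / 25 + 1 / 25))
  expect_lt(mean(abs(diff) > 3 * se), 0.02)
})

test_that("within-block Spearman correlation tracks block_rho", {
  cfg <- simulation_config(seed = 21, n_cpgs = 600, n_cases = 30,
                           n_controls = 30, block_rho = 0.5, slide_sd = 0,
                           frac_causal = 0, include_sex_chroms = FALSE)
  g <- generate_paired_datasets(cfg)
  blocks <- g$truth$blocks
  beta <- g$tissueB$beta
  mean_rho <- mean(vapply(split(blocks$cpg, blocks$block), function(ids) {
    if (length(ids) < 2) return(NA_real_)
    cm <- stats::cor(beta[, ids], method = "spearman")
    mean(cm[upper.tri(cm)])
  }, numeric(1)), na.rm = TRUE)
  expect_lt(abs(mean_rho - 0.5), 0.15)
})

test_that("reference panel profiles are valid and distinguishable", {
  cfg <- simulation_config(seed = 31, n_cpgs = 400, n_celltypes = 3)
  panel <- generate_reference_panel(cfg, min_separation = 0.1)
  expect_true(all(panel > 0 & panel < 1))
  pairs <- utils::combn(3, 2)
  seps <- apply(pairs, 2, function(ij)
    mean(abs(panel[ij[1], ] - panel[ij[2], ])))
  expect_true(all(seps >= 0.1))
  expect_identical(panel, generate_reference_panel(cfg, min_separation = 0.1))

  # single cell type: downstream deconvolution returns 1 for every sample
  cfg1 <- simulation_config(seed = 32, n_cpgs = 200, n_celltypes = 1,
                            dirichlet_conc_control = 5,
                            dirichlet_conc_case = 5)
  g1 <- generate_paired_datasets(cfg1)
  props <- estimate_cell_proportions(g1$tissueB, g1$panel)
  expect_equal(props$celltype1, rep(1, nrow(g1$tissueB$beta)))
})

test_that("simulated GWS loci stay inside chromosome bounds", {
  ann <- data.frame(chrom = rep(c("chr1", "chr2"), each = 500),
                    pos = rep(seq_len(500) * 1000L, 2),
                    cpg = sprintf("cg%06d", 1:1000))
  loci <- generate_gws_loci(ann, k = 64, seed = 4)
  expect_equal(nrow(loci), 64)
  expect_true(all(loci$start >= 1))
  spans <- tapply(ann$pos, ann$chrom, max)
  expect_true(all(loci$pos <= spans[loci$chrom]))
  expect_identical(loci, generate_gws_loci(ann, k = 64, seed = 4))

  empty <- generate_gws_loci(ann, k = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  sites <- ann$cpg[1:50]
  expect_equal(subset_by_loci(ann, sites, empty, "include"), character(0))
  expect_equal(subset_by_loci(ann, sites, empty, "exclude"), sites)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_cases = 0), "positive")
  expect_error(simulation_config(n_cpgs = 3, block_size = 10), "block_size")
  expect_error(simulation_config(frac_causal = 1.2), "fractions")
  expect_error(simulation_config(n_celltypes = 0), "n_celltypes")
})
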