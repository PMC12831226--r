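test_that("site intersection is plain set algebra in target order", {
  target <- make_fixture(n_cpgs = 4)
  target$probes$cpg <- c("b", "c", "d", "e")
  colnames(target$beta) <- target$probes$cpg
  disc <- make_weights(c("a", "b", "c"), effect = 1, p = 0.5)
  expect_equal(intersect_sites(disc, target), c("b", "c"))
  disc2 <- make_weights(c("b", "c", "d", "e"), effect = 1, p = 0.5)
  expect_equal(intersect_sites(disc2, target), target$probes$cpg)
  expect_error(intersect_sites(make_weights("zz", 1, 0.5), target),
               "overlap")
})

test_that("pruning merges correlated neighbours and respects the window", {
  # two CpGs 1000 bp apart with identical beta columns: one retained,
  # the one with the smaller discovery p
  base <- matrix(runif(20), 10, 2)
  base <- cbind(base[, 1], base[, 1])
  ds <- make_fixture(n_samples = 10, n_cpgs = 2, pos = c(1000L, 2000L),
                     beta = base)
  disc <- make_weights(ds$probes$cpg, effect = 1, p = c(0.9, 0.1))
  out <- comeback_prune(ds, ds$probes$cpg, disc)
  expect_equal(out$retained, ds$probes$cpg[2])
  expect_equal(out$clusters[[ds$probes$cpg[2]]], ds$probes$cpg[1])

  # identical columns 2000 bp apart: still within the (inclusive) window
  ds2 <- make_fixture(n_samples = 10, n_cpgs = 2, pos = c(1000L, 3000L),
                      beta = base)
  expect_length(comeback_prune(ds2, ds2$probes$cpg, disc)$retained, 1)

  # 2001 bp apart: outside the window, both retained
  ds3 <- make_fixture(n_samples = 10, n_cpgs = 2, pos = c(1000L, 3001L),
                      beta = base)
  expect_length(comeback_prune(ds3, ds3$probes$cpg, disc)$retained, 2)
})

test_that("pruning matches the brute-force transitive-closure oracle", {
  for (rep in 1:10) {
    set.seed(600 + rep)
    m <- 20
    pos <- sort(sample.int(20000, m))
    beta <- matrix(runif(15 * m, 0.2, 0.8), 15, m)
    # induce some correlated pairs
    for (k in sample(m - 1, 6))
      beta[, k + 1] <- pmin(pmax(beta[, k] + rnorm(15, sd = 0.05),
                                 0.01), 0.99)
    ds <- make_fixture(n_samples = 15, n_cpgs = m, pos = pos, beta = beta)
    p_disc <- runif(m)
    disc <- make_weights(ds$probes$cpg, effect = 1, p = p_disc)
    got <- sort(comeback_prune(ds, ds$probes$cpg, disc)$retained)
    want <- oracle_prune(ds$beta, ds$probes, p_disc)
    expect_equal(got, want)
  }
})

test_that("pruning is invariant to input site order", {
  set.seed(61)
  m <- 30
  ds <- make_fixture(n_samples = 12, n_cpgs = m,
                     pos = sort(sample.int(30000, m)))
  disc <- make_weights(ds$probes$cpg, effect = 1, p = runif(m))
  r1 <- comeback_prune(ds, ds$probes$cpg, disc)$retained
  r2 <- comeback_prune(ds, sample(ds$probes$cpg), disc)$retained
  expect_equal(sort(r1), sort(r2))
})

test_that("score arithmetic matches the hand-computed example", {
  beta1 <- m_to_beta(matrix(c(1, 2, -1), 1, 3))
  ds <- make_fixture(n_samples = 1, n_cpgs = 3, beta = beta1)
  w <- make_weights(ds$probes$cpg, effect = c(0.5, -1.0, 2.0),
                    p = c(0.005, 0.03, 0.4))
  expect_warning(mrs <- compute_mrs(ds, w, ds$probes$cpg),
                 "smallest threshold")
  s <- mrs$scores[1, ]
  expect_equal(unname(s["PT_0.01"]), 0.5)
  expect_equal(unname(s["PT_0.05"]), -1.5)
  expect_equal(unname(s["PT_1"]), -3.5)
  expect_equal(unname(mrs$site_counts), c(0, 1, 2, 2, 2, 3, 3))

  # single site: w * m at every admitting threshold
  ds1 <- make_fixture(n_samples = 2, n_cpgs = 1,
                      beta = m_to_beta(matrix(c(2, -2), 2, 1)))
  w1 <- make_weights(ds1$probes$cpg, effect = 0.7, p = 1e-5)
  s1 <- compute_mrs(ds1, w1, ds1$probes$cpg)$scores
  expect_equal(unname(s1[, "PT_0.001"]), c(1.4, -1.4))
  expect_equal(unname(s1[, "PT_1"]), c(1.4, -1.4))

  # a zero-effect site changes nothing
  ds2 <- make_fixture(n_samples = 2, n_cpgs = 2,
                      beta = m_to_beta(matrix(c(2, -2, 1, 1), 2, 2)))
  w2 <- make_weights(ds2$probes$cpg, effect = c(0.7, 0), p = c(1e-5, 1e-6))
  s2 <- compute_mrs(ds2, w2, ds2$probes$cpg)$scores
  expect_equal(unname(s2[, "PT_1"]), c(1.4, -1.4))
})

test_that("threshold nesting, additivity and linearity hold", {
  set.seed(62)
  m <- 40
  ds <- make_fixture(n_samples = 15, n_cpgs = m)
  w <- make_weights(ds$probes$cpg, effect = rnorm(m), p = runif(m))
  mrs <- suppressWarnings(compute_mrs(ds, w, ds$probes$cpg))
  expect_true(all(diff(mrs$site_counts) >= 0))
  # score difference between consecutive thresholds = sum of added terms
  M <- beta_to_m(ds$beta)
  for (j in 2:7) {
    lo <- PT_THRESHOLDS[j - 1]; hi <- PT_THRESHOLDS[j]
    added <- which(w$p >= lo & (if (hi >= 1) w$p <= 1 else w$p < hi))
    expect_equal(mrs$scores[, j] - mrs$scores[, j - 1],
                 as.numeric(M[, added, drop = FALSE] %*%
                              w$effect[added]),
                 ignore_attr = TRUE)
  }
  # doubling the weights doubles every score
  w2 <- w; w2$effect <- 2 * w$effect
  expect_equal(suppressWarnings(compute_mrs(ds, w2, ds$probes$cpg))$scores,
               2 * mrs$scores)
})

test_that("missing methylation is mean-imputed with a logged count", {
  set.seed(63)
  beta <- matrix(runif(30, 0.3, 0.7), 10, 3)
  beta[c(2, 15)] <- NA
  ds <- make_fixture(n_samples = 10, n_cpgs = 3, beta = beta)
  w <- make_weights(ds$probes$cpg, effect = 1, p = 0.5)
  mrs <- suppressWarnings(compute_mrs(ds, w, ds$probes$cpg))
  expect_equal(mrs$n_imputed, 2)
  expect_false(anyNA(mrs$scores))
})

test_that("locus subsetting is an exact partition with inclusive bounds", {
  ann <- data.frame(cpg = paste0("cg", 1:5), chrom = "chr1",
                    pos = c(50000L, 150000L, 250000L, 250001L, 400000L))
  loci <- loci_set(data.frame(chrom = "chr1", pos = 150001L))
  # window = [50001, 250001]
  expect_equal(subset_by_loci(ann, ann$cpg, loci, "include"),
               c("cg2", "cg3", "cg4"))
  expect_equal(subset_by_loci(ann, ann$cpg, loci, "exclude"),
               c("cg1", "cg5"))
  # boundary: lead + 100000 included, +100001 excluded
  expect_true("cg4" %in% subset_by_loci(ann, ann$cpg, loci, "include"))
  loci2 <- loci_set(data.frame(chrom = "chr1", pos = 150000L))
  expect_false("cg4" %in% subset_by_loci(ann, ann$cpg, loci2, "include"))

  # random instances: include/exclude partition verified exhaustively
  set.seed(64)
  for (r in 1:5) {
    annr <- data.frame(cpg = paste0("cg", 1:50),
                       chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       pos = sample.int(5e5, 50))
    locir <- loci_set(data.frame(chrom = sample(c("chr1", "chr2"), 3, TRUE),
                                 pos = sample.int(5e5, 3)))
    inc <- subset_by_loci(annr, annr$cpg, locir, "include")
    exc <- subset_by_loci(annr, annr$cpg, locir, "exclude")
    expect_setequal(c(inc, exc), annr$cpg)
    expect_length(intersect(inc, exc), 0)
    manual <- vapply(seq_len(50), function(i) any(
      locir$chrom == annr$chrom[i] & annr$pos[i] >= locir$start &
        annr$pos[i] <= locir$end), logical(1))
    expect_setequal(inc, annr$cpg[manual])
  }
  expect_error(subset_by_loci(ann, ann$cpg,
                              loci_set(data.frame(chrom = "chr9",
                                                  pos = 100L)),
                              "include"),
               "chr9")
})

test_that("include + exclude scores sum to the all-sites score", {
  set.seed(65)
  m <- 60
  ds <- make_fixture(n_samples = 12, n_cpgs = m,
                     pos = sort(sample.int(4e5, m)))
  w <- make_weights(ds$probes$cpg, effect = rnorm(m), p = runif(m))
  loci <- loci_set(data.frame(chrom = "chr1", pos = c(100000L, 300000L)))
  inc <- subset_by_loci(ds$probes, ds$probes$cpg, loci, "include")
  exc <- subset_by_loci(ds$probes, ds$probes$cpg, loci, "exclude")
  s_all <- suppressWarnings(compute_mrs(ds, w, ds$probes$cpg))$scores
  s_inc <- suppressWarnings(compute_mrs(ds, w, inc)$scores)
  s_exc <- suppressWarnings(compute_mrs(ds, w, exc)$scores)
  expect_equal(s_inc + s_exc, s_all)
})
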