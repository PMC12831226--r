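#' Simulation configuration for paired two-tissue methylation data
#'
#' Collects every knob of the generator. Defaults describe a small but
#' realistic two-tissue world: bimodal beta-value baselines, 2-kb
#' co-methylated CpG blocks realized through an equicorrelated Gaussian
#' copula on the M scale, diagnosis effects planted on the M scale at a
#' small fraction of CpGs with partial cross-tissue sharing, cell-type
#' mixing from a synthetic reference panel with mild case-control
#' composition shift, slide batch offsets, detection/bead failures and
#' sex-chromosome signal.
#'
#' @param seed Integer RNG seed; identical seeds give bitwise-identical data.
#' @param n_cases,n_controls Group sizes per tissue. Scalars apply to both
#'   tissues; length-2 vectors give tissue A and tissue B sizes.
#' @param n_cpgs Number of autosomal CpGs in the tissue-B (EPIC-like) universe.
#' @param chrom_layout Data frame with columns `chrom`, `n`, `spacing`
#'   (bp between consecutive probes); `NULL` splits `n_cpgs` evenly over
#'   four autosomes at 600-bp spacing.
#' @param frac_causal Fraction of CpGs carrying a diagnosis effect.
#' @param effect_size_m Mean absolute case shift on the M-value scale.
#' @param effect_size_m_a,effect_size_m_b Optional tissue-specific overrides
#'   of `effect_size_m` for shared causal sites (tissue-specific effect
#'   magnitude; used to emulate direction-asymmetric trans-tissue transfer).
#' @param cross_tissue_share Fraction of causal CpGs shared between tissues.
#' @param block_size CpGs per co-methylated block.
#' @param block_rho Target within-block correlation of the latent copula.
#' @param noise_sd_m Residual SD per probe on the M scale.
#' @param n_celltypes Number of cell types in the reference panel.
#' @param dirichlet_conc_control,dirichlet_conc_case Dirichlet concentration
#'   vectors (recycled to `n_celltypes`) for per-sample cell proportions; the
#'   defaults shift the last type upward in cases (composition confounding).
#' @param slide_count Number of slides; samples are assigned cyclically.
#' @param slide_sd SD of per-slide, per-probe batch offsets on the M scale.
#' @param missing_rates Named list: `detection` and `beads`, the per-cell
#'   probabilities of a detection failure and of a low bead count.
#' @param subset_frac_a Fraction of the tissue-B CpG universe also measured
#'   in tissue A (450K-within-EPIC emulation).
#' @param include_sex_chroms Add chrX/chrY probes with sex-determined signal.
#' @param n_sex_mislabels Number of samples per tissue whose recorded sex is
#'   flipped (planted QC mismatches).
#' @param confounders Named list per confounder (`smoking`, `bmi`, `suicide`)
#'   with elements `prevalence_control`, `prevalence_case` (binary ones),
#'   `mean`/`sd` per group (continuous), `frac_causal` and `effect_m`.
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              n_cases = 30, n_controls = 30,
                              n_cpgs = 5000,
                              chrom_layout = NULL,
                              frac_causal = 0.02,
                              effect_size_m = 1.0,
                              effect_size_m_a = NULL,
                              effect_size_m_b = NULL,
                              cross_tissue_share = 0.8,
                              block_size = 5,
                              block_rho = 0.5,
                              noise_sd_m = 0.5,
                              n_celltypes = 3,
                              dirichlet_conc_control = c(12, 8, 4),
                              dirichlet_conc_case = c(11, 8, 5),
                              slide_count = 4,
                              slide_sd = 0.3,
                              missing_rates = list(detection = 0.002,
                                                   beads = 0.002),
                              subset_frac_a = 0.7,
                              include_sex_chroms = TRUE,
                              n_sex_mislabels = 0,
                              confounders = default_confounders()) {
  n_cases <- rep_len(as.integer(n_cases), 2)
  n_controls <- rep_len(as.integer(n_controls), 2)
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("group sizes must be positive")
  if (is.null(chrom_layout)) {
    per <- ceiling(n_cpgs / 4)
    chrom_layout <- data.frame(chrom = paste0("chr", 1:4),
                               n = c(rep(per, 3), n_cpgs - 3 * per),
                               spacing = 600)
  }
  chrom_layout <- as.data.frame(chrom_layout)
  stopifnot(all(c("chrom", "n", "spacing") %in% names(chrom_layout)),
            all(chrom_layout$spacing > 0), sum(chrom_layout$n) == n_cpgs)
  fr <- c(frac_causal, cross_tissue_share, subset_frac_a,
          missing_rates$detection, missing_rates$beads)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (block_size > n_cpgs) stop("block_size exceeds n_cpgs")
  if (n_celltypes < 1) stop("n_celltypes must be >= 1")
  structure(list(seed = as.integer(seed), n_cases = n_cases,
                 n_controls = n_controls, n_cpgs = as.integer(n_cpgs),
                 chrom_layout = chrom_layout, frac_causal = frac_causal,
                 effect_size_m = effect_size_m,
                 effect_size_m_a = effect_size_m_a %||% effect_size_m,
                 effect_size_m_b = effect_size_m_b %||% effect_size_m,
                 cross_tissue_share = cross_tissue_share,
                 block_size = as.integer(block_size), block_rho = block_rho,
                 noise_sd_m = noise_sd_m, n_celltypes = as.integer(n_celltypes),
                 dirichlet_conc_control = rep_len(dirichlet_conc_control,
                                                  n_celltypes),
                 dirichlet_conc_case = rep_len(dirichlet_conc_case,
                                               n_celltypes),
                 slide_count = as.integer(slide_count), slide_sd = slide_sd,
                 missing_rates = missing_rates,
                 subset_frac_a = subset_frac_a,
                 include_sex_chroms = include_sex_chroms,
                 n_sex_mislabels = as.integer(n_sex_mislabels),
                 confounders = confounders),
            class = "simulation_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default confounder specification
#'
#' Prevalences mirror a postmortem psychiatric cohort: suicide essentially
#' absent in controls and common in cases, smoking enriched in cases, BMI
#' continuous with a small group difference. Each confounder drives its own
#' small causal CpG set so confounder-phenotype EWASs have signal.
#' @return Named list usable as `confounders` in [simulation_config()].
#' @export
default_confounders <- function() {
  list(smoking = list(type = "binary", prevalence_control = 0.13,
                      prevalence_case = 0.45,
                      frac_causal = 0.005, effect_m = 0.8),
       bmi = list(type = "continuous", mean_control = 33, mean_case = 29,
                  sd = 8, frac_causal = 0.005, effect_m = 0.03),
       suicide = list(type = "binary", prevalence_control = 0,
                      prevalence_case = 0.6,
                      frac_causal = 0.005, effect_m = 0.8))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# probe annotation for one tissue universe (autosomes + optional sex chroms)
build_annotation <- function(config) {
  lay <- config$chrom_layout
  ann <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    data.frame(chrom = lay$chrom[i],
               pos = seq_len(lay$n[i]) * lay$spacing[i],
               stringsAsFactors = FALSE)
  }))
  ann$cpg <- sprintf("cg%07d", seq_len(nrow(ann)))
  if (config$include_sex_chroms) {
    sex <- data.frame(
      chrom = c(rep("chrX", 60), rep("chrY", 30)),
      pos = c(seq_len(60) * 1000L, seq_len(30) * 1000L),
      stringsAsFactors = FALSE)
    sex$cpg <- sprintf("cgX%06d", seq_len(nrow(sex)))
    ann <- rbind(ann, sex)
  }
  ann[, c("cpg", "chrom", "pos")]
}

#' Generate a synthetic cell-type reference panel
#'
#' Builds `n_celltypes` beta-value profiles over the autosomal CpG universe:
#' a shared bimodal baseline plus cell-type-specific M-scale deviations at a
#' random 40% of CpGs. Deviations are rescaled until every pair of profiles
#' differs by at least `min_separation` in mean absolute beta difference, so
#' downstream deconvolution is identifiable.
#'
#' @param config A [simulation_config()].
#' @param min_separation Floor on pairwise mean `|delta beta|` between profiles.
#' @return Matrix (cell types x CpGs) of beta profiles in (0, 1), with an
#'   attribute `"baseline_m"` carrying the shared baseline M-values.
#' @export
generate_reference_panel <- function(config, min_separation = 0.05) {
  if (config$n_celltypes < 1) stop("n_celltypes must be >= 1")
  set.seed(config$seed + 1L)
  ann <- build_annotation(config)
  auto <- !is_sex_chrom(ann$chrom)
  m <- sum(auto)
  # bimodal baseline: mostly hypo- or hyper-methylated probes
  comp <- sample(c(-1, 1), m, replace = TRUE)
  base_m <- stats::rnorm(m, mean = 2.6 * comp, sd = 1.0)
  k <- config$n_celltypes
  prof_m <- matrix(rep(base_m, each = k), nrow = k)
  if (k > 1) {
    informative <- stats::runif(m) < 0.4
    dev <- matrix(0, k, m)
    dev[, informative] <- stats::rnorm(k * sum(informative), sd = 1.4)
    repeat {
      beta <- m_to_beta(prof_m + dev)
      sep <- min(utils::combn(k, 2, function(ij)
        mean(abs(beta[ij[1], ] - beta[ij[2], ]))))
      if (sep >= min_separation) break
      dev <- dev * 1.3
    }
    prof_m <- prof_m + dev
  }
  beta <- m_to_beta(prof_m)
  rownames(beta) <- paste0("celltype", seq_len(k))
  colnames(beta) <- ann$cpg[auto]
  attr(beta, "baseline_m") <- base_m
  beta
}

# Draw the causal CpG pool and its tissue-specific expression, honouring
# cross_tissue_share exactly (rounded). The disorder has one causal
# methylome (planted fully in tissue B); a share-fraction of it is also
# expressed in tissue A. share = 0 therefore leaves tissue A with no
# diagnosis signal at all -- the calibrated-null trans-tissue world.
draw_causal_sets <- function(config, auto_cpgs, universe_a) {
  n_causal <- round(config$frac_causal * length(auto_cpgs))
  if (n_causal == 0)
    return(list(a = character(0), b = character(0), shared = character(0)))
  n_shared <- round(config$cross_tissue_share * n_causal)
  common <- intersect(auto_cpgs, universe_a)
  shared <- sample(common, min(n_shared, length(common)))
  only_b <- sample(setdiff(auto_cpgs, shared), n_causal - length(shared))
  list(a = shared, b = c(shared, only_b), shared = shared)
}

# simulate one tissue cohort on a given CpG universe
simulate_tissue <- function(config, panel, ann, universe, tissue,
                            causal, causal_eff, conf_effects, seed_offset) {
  set.seed(config$seed + seed_offset)
  ti <- if (tissue == "A") 1L else 2L
  n_case <- config$n_cases[ti]; n_ctrl <- config$n_controls[ti]
  n <- n_case + n_ctrl
  diagnosis <- c(rep("case", n_case), rep("control", n_ctrl))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- round(stats::rnorm(n, mean = ifelse(diagnosis == "case", 46, 48),
                            sd = 10), 1)
  slide <- paste0("slide", (seq_len(n) - 1L) %% config$slide_count + 1L)

  # confounders
  meta_conf <- list()
  for (cn in names(config$confounders)) {
    sp <- config$confounders[[cn]]
    if (sp$type == "binary") {
      prev <- ifelse(diagnosis == "case", sp$prevalence_case,
                     sp$prevalence_control)
      meta_conf[[cn]] <- as.integer(stats::runif(n) < prev)
    } else {
      meta_conf[[cn]] <- round(stats::rnorm(
        n, mean = ifelse(diagnosis == "case", sp$mean_case, sp$mean_control),
        sd = sp$sd), 1)
    }
  }

  idx <- match(universe, colnames(panel))       # autosomal universe columns
  auto_univ <- universe[!is.na(idx)]
  props <- matrix(1, n, 1)
  if (config$n_celltypes >= 1) {
    props <- matrix(NA_real_, n, config$n_celltypes)
    props[diagnosis == "case", ] <-
      rdirichlet(n_case, config$dirichlet_conc_case)
    props[diagnosis == "control", ] <-
      rdirichlet(n_ctrl, config$dirichlet_conc_control)
  }
  colnames(props) <- rownames(panel)

  # cell-type mixture in beta space, then move to M
  mix_beta <- props %*% panel[, auto_univ, drop = FALSE]
  M <- beta_to_m(mix_beta)

  # diagnosis effects on the M scale (cases only), before noise
  is_case <- diagnosis == "case"
  ce <- causal_eff[match(auto_univ, names(causal_eff))]
  ce[is.na(ce)] <- 0
  M[is_case, ] <- M[is_case, ] + rep(ce, each = sum(is_case))

  # confounder effects
  for (cn in names(conf_effects)) {
    x <- meta_conf[[cn]]
    eff <- conf_effects[[cn]][match(auto_univ, names(conf_effects[[cn]]))]
    eff[is.na(eff)] <- 0
    M <- M + outer(x - mean(x), eff)
  }

  # slide batch offsets: per-slide per-probe shifts
  if (config$slide_sd > 0 && config$slide_count > 1) {
    shifts <- matrix(stats::rnorm(config$slide_count * length(auto_univ),
                                  sd = config$slide_sd),
                     nrow = config$slide_count)
    M <- M + shifts[as.integer(factor(slide, levels = paste0(
      "slide", seq_len(config$slide_count)))), , drop = FALSE]
  }

  # co-methylated blocks: equicorrelated Gaussian noise within each block
  m_auto <- length(auto_univ)
  blocks <- ceiling(seq_len(m_auto) / config$block_size)
  rho <- config$block_rho
  z_shared <- stats::rnorm(n * max(blocks))
  dim(z_shared) <- c(n, max(blocks))
  noise <- sqrt(rho) * z_shared[, blocks, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * m_auto), n, m_auto)
  M <- M + config$noise_sd_m * noise

  beta <- m_to_beta(M)

  # sex-chromosome probes
  sex_univ <- setdiff(universe, auto_univ)
  if (length(sex_univ)) {
    chs <- ann$chrom[match(sex_univ, ann$cpg)]
    on_y <- grepl("Y$", chs)
    male <- sex == "M"
    base <- matrix(rep(ifelse(on_y, 0, -1), each = n), n, length(sex_univ))
    # females: Y probes read background (very low M); males: clear Y signal
    base[, on_y] <- ifelse(rep(male, sum(on_y)), 1.5, -4.5)
    Msex <- base + matrix(stats::rnorm(n * length(sex_univ), sd = 0.4),
                          n, length(sex_univ))
    beta <- cbind(beta, m_to_beta(Msex))
    colnames(beta) <- c(auto_univ, sex_univ)
  }
  beta <- beta[, universe, drop = FALSE]
  # guard the open-interval contract
  beta[beta <= 0] <- 1e-6
  beta[beta >= 1] <- 1 - 1e-6

  # detection p-values and bead counts with planted failures
  p_fail <- matrix(stats::runif(n * length(universe)) <
                     config$missing_rates$detection, n, length(universe))
  detp <- matrix(stats::runif(n * length(universe), 0, 0.005),
                 n, length(universe))
  detp[p_fail] <- stats::runif(sum(p_fail), 0.01, 1)
  beads <- matrix(stats::rpois(n * length(universe), lambda = 15) + 3L,
                  n, length(universe))
  b_fail <- matrix(stats::runif(n * length(universe)) <
                     config$missing_rates$beads, n, length(universe))
  beads[b_fail] <- sample(0:2, sum(b_fail), replace = TRUE)
  dimnames(detp) <- dimnames(beads) <- dimnames(beta)

  recorded_sex <- sex
  if (config$n_sex_mislabels > 0) {
    flip <- sample(n, min(config$n_sex_mislabels, n))
    recorded_sex[flip] <- ifelse(sex[flip] == "M", "F", "M")
  }

  samples <- data.frame(id = sprintf("%s_s%03d", tissue, seq_len(n)),
                        diagnosis = diagnosis, age = age, sex = recorded_sex,
                        slide = slide, stringsAsFactors = FALSE)
  for (cn in names(meta_conf)) samples[[cn]] <- meta_conf[[cn]]
  rownames(beta) <- samples$id
  probes <- ann[match(universe, ann$cpg), ]
  rownames(probes) <- NULL

  list(dataset = methylation_dataset(beta, samples, probes,
                                     detection_p = detp, bead_count = beads),
       props = props, true_sex = sex)
}

#' Generate a paired two-tissue methylation dataset with ground truth
#'
#' Simulates two independent cohorts ("tissueA", 450K-like, a random subset
#' of the CpG universe; "tissueB", EPIC-like, the full universe) sharing a
#' configurable fraction of diagnosis-associated CpGs. Effects are planted on
#' the M scale before noise; co-methylated blocks are realized with an
#' equicorrelated Gaussian copula; cell-type mixing, slide offsets,
#' detection/bead failures and sex-chromosome signal follow the config.
#'
#' @param config A [simulation_config()].
#' @return List with elements `tissueA`, `tissueB` (each a
#'   [methylation_dataset()]), `panel` (reference beta profiles), and `truth`
#'   (causal ids and true effects per tissue, block membership, true cell
#'   proportions and true sex per sample).
#' @export
generate_paired_datasets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- generate_reference_panel(config)
  ann <- build_annotation(config)
  auto_cpgs <- colnames(panel)
  sex_cpgs <- setdiff(ann$cpg, auto_cpgs)

  set.seed(config$seed + 2L)
  n_a <- round(config$subset_frac_a * length(auto_cpgs))
  universe_a <- sort(sample(auto_cpgs, n_a))
  universe_a <- ann$cpg[ann$cpg %in% c(universe_a, sex_cpgs)]
  universe_b <- ann$cpg

  causal <- draw_causal_sets(config, auto_cpgs, universe_a)
  sgn <- function(ids) stats::setNames(
    sample(c(-1, 1), length(ids), replace = TRUE), ids)
  shared_sign <- sgn(causal$shared)
  eff_a <- c(shared_sign * config$effect_size_m_a,
             sgn(setdiff(causal$a, causal$shared)) * config$effect_size_m)
  eff_b <- c(shared_sign * config$effect_size_m_b,
             sgn(setdiff(causal$b, causal$shared)) * config$effect_size_m)

  conf_effects <- list()
  for (cn in names(config$confounders)) {
    sp <- config$confounders[[cn]]
    k <- round(sp$frac_causal * length(auto_cpgs))
    ids <- sample(auto_cpgs, k)
    conf_effects[[cn]] <- stats::setNames(
      sample(c(-1, 1), k, replace = TRUE) * sp$effect_m, ids)
  }

  ta <- simulate_tissue(config, panel, ann, universe_a, "A",
                        causal$a, eff_a, conf_effects, seed_offset = 10L)
  tb <- simulate_tissue(config, panel, ann, universe_b, "B",
                        causal$b, eff_b, conf_effects, seed_offset = 20L)

  blocks <- data.frame(cpg = auto_cpgs,
                       block = ceiling(seq_along(auto_cpgs) /
                                         config$block_size))
  truth <- list(causal_a = causal$a, causal_b = causal$b,
                shared = causal$shared,
                effects_a = eff_a, effects_b = eff_b,
                confounder_effects = conf_effects,
                blocks = blocks,
                props_a = ta$props, props_b = tb$props,
                true_sex_a = ta$true_sex, true_sex_b = tb$true_sex,
                universe_a = universe_a)
  list(tissueA = ta$dataset, tissueB = tb$dataset, panel = panel,
       truth = truth)
}

#' Generate synthetic genome-wide-significant loci
#'
#' Draws `k` lead positions uniformly on the simulated chromosomes and
#' expands each to a +-`window` bp interval (clipped at position 1).
#'
#' @param annotation Probe annotation data frame (`cpg`, `chrom`, `pos`).
#' @param k Number of loci.
#' @param seed RNG seed.
#' @param window Half-width of each locus window in bp (default 100000).
#' @return A [loci_set()] of `k` leads with windows.
#' @export
generate_gws_loci <- function(annotation, k, seed = 1, window = 100000) {
  stopifnot(k >= 0)
  set.seed(seed)
  auto <- annotation[!is_sex_chrom(annotation$chrom), , drop = FALSE]
  spans <- tapply(auto$pos, auto$chrom, max)
  if (k > 0 && sum(spans) < k) stop("k exceeds available span")
  chrom <- sample(names(spans), k, replace = TRUE,
                  prob = as.numeric(spans) / sum(spans))
  pos <- vapply(chrom, function(ch) sample.int(spans[[ch]], 1), integer(1))
  loci_set(data.frame(chrom = chrom, pos = as.integer(pos),
                      name = if (k > 0) paste0("locus", seq_len(k))
                             else character(0),
                      stringsAsFactors = FALSE),
           window = window)
}
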