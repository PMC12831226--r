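#' Run configuration for the end-to-end trans-tissue experiment
#'
#' Validates and normalizes every option of [run_pipeline()]: input mode,
#' QC thresholds, covariate construction, score thresholds, pruning
#' parameters, locus subsets and the confounder battery.
#'
#' @param mode `"simulate"` (default; generate paired tissues from `sim`) or
#'   `"load"` (read dataset directories from `paths`).
#' @param sim List of [simulation_config()] arguments (simulate mode).
#' @param paths List with `tissue_a`, `tissue_b`, optional `panel`
#'   (TSV, cell types x CpGs) and `loci` (BED or lead TSV) for load mode.
#' @param qc List of [qc_thresholds()] arguments.
#' @param covariates List: `max_pcs` (default 5), `n_sv` (default 0 or
#'   `"auto"`), `always_admit_a`, `always_admit_b` (cell types admitted
#'   unconditionally, e.g. a neuronal fraction), `alpha` (admission level).
#' @param thresholds Ascending score thresholds ending at 1.
#' @param prune List: `window` (bp, default 2000), `rho` (default 0.3),
#'   `strict_pairwise`.
#' @param loci List: `k` simulated loci (default 8) and `window`
#'   (default 100000); ignored when `paths$loci` is given.
#' @param subset_modes Locus subset modes to run, default
#'   `c("all", "exclude", "include")`.
#' @param directions Trans-tissue directions to run, default both
#'   (`"A_to_B"`, `"B_to_A"`).
#' @param confounder_phenotypes Confounder phenotypes for the control
#'   battery (EWAS in tissue B, scored in tissue A), default
#'   `c("suicide", "bmi", "smoking")`; `character(0)` disables.
#' @param adjust_diagnosis_in_confounder_ewas Add diagnosis to the
#'   confounder-EWAS covariates (default `TRUE`).
#' @param mrs_scale `"M"` or `"beta"` methylation scale for scores.
#' @param seed Integer master seed.
#' @param out Optional output directory for artifacts.
#' @param log_level `"info"` or `"quiet"`.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "load"), sim = list(),
                       paths = list(), qc = list(), covariates = list(),
                       thresholds = PT_THRESHOLDS,
                       prune = list(), loci = list(),
                       subset_modes = c("all", "exclude", "include"),
                       directions = c("A_to_B", "B_to_A"),
                       confounder_phenotypes = c("suicide", "bmi", "smoking"),
                       adjust_diagnosis_in_confounder_ewas = TRUE,
                       mrs_scale = "M", seed = 1, out = NULL,
                       log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  stopifnot(length(thresholds) >= 1, !is.unsorted(thresholds),
            thresholds[length(thresholds)] == 1)
  subset_modes <- match.arg(subset_modes, c("all", "exclude", "include"),
                            several.ok = TRUE)
  if (mode == "load" &&
      !all(c("tissue_a", "tissue_b") %in% names(paths)))
    stop("load mode requires paths$tissue_a and paths$tissue_b")
  cov_defaults <- list(max_pcs = 5, n_sv = 0, alpha = 0.05,
                       always_admit_a = character(0),
                       always_admit_b = character(0))
  covariates <- utils::modifyList(cov_defaults, covariates)
  prune <- utils::modifyList(list(window = 2000, rho = 0.3,
                                  strict_pairwise = FALSE), prune)
  loci <- utils::modifyList(list(k = 8, window = 100000), loci)
  sim$seed <- sim$seed %||% seed
  structure(list(mode = mode, sim = sim, paths = paths, qc = qc,
                 covariates = covariates, thresholds = thresholds,
                 prune = prune, loci = loci, subset_modes = subset_modes,
                 directions = match.arg(directions, c("A_to_B", "B_to_A"),
                                        several.ok = TRUE),
                 confounder_phenotypes = confounder_phenotypes,
                 adjust_diagnosis_in_confounder_ewas =
                   adjust_diagnosis_in_confounder_ewas,
                 mrs_scale = mrs_scale, seed = as.integer(seed), out = out,
                 log_level = log_level),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- unclass(config)
  stripped$out <- NULL; stripped$log_level <- NULL
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(config, stage, ...) {
  if (config$log_level == "quiet") return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# QC + covariate construction for one tissue cohort
prepare_tissue <- function(ds, panel, config, label) {
  qc <- run_qc(ds, do.call(qc_thresholds, config$qc))
  ds <- qc$dataset
  log_stage(config, paste0("qc:", label),
            nrow(ds$beta), " samples, ", ncol(ds$beta), " probes retained (",
            qc$report$counts["samples"], " samples / ",
            qc$report$counts["probes"], " probes excluded)")
  props <- NULL; admitted <- character(0); cell_tests <- NULL
  if (!is.null(panel)) {
    props <- estimate_cell_proportions(ds, panel)
    always <- config$covariates[[paste0("always_admit_",
                                        tolower(substr(label, 7, 7)))]]
    cmp <- compare_cell_proportions(ds, props,
                                    alpha = config$covariates$alpha,
                                    always_admit = always %||% character(0))
    admitted <- cmp$admitted
    cell_tests <- cmp$tests
  }
  pcs <- slide_associated_pcs(ds$beta, ds$samples$slide,
                              alpha = config$covariates$alpha,
                              max_pcs = config$covariates$max_pcs)
  covset <- build_covariate_set(ds, props, admitted, pcs)
  M <- beta_to_m(ds$beta)
  svs <- NULL
  if (!identical(config$covariates$n_sv, 0)) {
    svs <- estimate_surrogate_variables(M, ds$samples$diagnosis,
                                        covset$design,
                                        n_sv = config$covariates$n_sv)
    covset_ewas <- build_covariate_set(ds, props, admitted, pcs, svs)
  } else covset_ewas <- covset
  log_stage(config, paste0("covariates:", label),
            ncol(covset_ewas$design), " EWAS covariates (",
            paste(names(covset_ewas$design), collapse = ", "), ")")
  list(dataset = ds, M = M, qc = qc, props = props,
       cell_tests = cell_tests, admitted = admitted,
       covset = covset,              # target-model covariates (no SVs)
       covset_ewas = covset_ewas)    # discovery covariates (with SVs)
}

# discovery EWAS in `disc`, scoring + association in `target`
run_direction <- function(disc, target, config, loci, direction,
                          phenotype = "diagnosis",
                          extra_note = NA_character_) {
  pheno <- disc$dataset$samples[[phenotype]]
  if (is.null(pheno)) stop("phenotype column absent: ", phenotype)
  covs <- disc$covset_ewas
  if (phenotype != "diagnosis" &&
      config$adjust_diagnosis_in_confounder_ewas) {
    d <- covs$design
    d$diagnosis_adj <- as.integer(disc$dataset$samples$diagnosis == "case")
    covs <- structure(list(design = d, provenance = covs$provenance,
                           ids = covs$ids), class = "covariate_set")
  }
  res <- tryCatch(
    run_ewas(disc$M, pheno, covs, probes = disc$dataset$probes,
             model_id = paste0(phenotype, ":", direction)),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(rows = data.frame(), skip = conditionMessage(res)))
  sites0 <- intersect_sites(res, target$dataset)
  pruned <- comeback_prune(target$dataset, sites0, res,
                           window = config$prune$window,
                           rho = config$prune$rho,
                           strict_pairwise = config$prune$strict_pairwise)
  log_stage(config, paste0("score:", direction),
            length(sites0), " shared sites, ",
            length(pruned$retained), " after pruning")
  rows <- list()
  for (mode in config$subset_modes) {
    sites <- subset_by_loci(target$dataset$probes, pruned$retained, loci,
                            mode = mode)
    if (!length(sites)) {
      rows[[mode]] <- data.frame(
        direction = direction, phenotype = phenotype, subset = mode,
        threshold = paste0("PT_", config$thresholds),
        n_sites = 0L, p = NA_real_, p_wald = NA_real_, p_score = NA_real_,
        r2_covariates = NA_real_,
        r2_full = NA_real_, delta_r2 = NA_real_,
        direction_effect = NA_character_, separated = NA, best = FALSE,
        skip = "no sites in subset", stringsAsFactors = FALSE)
      next
    }
    mrs <- suppressWarnings(
      compute_mrs(target$dataset, res, sites,
                  thresholds = config$thresholds, scale = config$mrs_scale))
    assoc <- mrs_association(target$dataset$samples$diagnosis, mrs,
                             target$covset)
    tab <- assoc$table
    rows[[mode]] <- data.frame(
      direction = direction, phenotype = phenotype, subset = mode,
      threshold = tab$threshold, n_sites = tab$n_sites, p = tab$p,
      p_wald = tab$p_wald, p_score = tab$p_score,
      r2_covariates = tab$r2_covariates, r2_full = tab$r2_full,
      delta_r2 = tab$delta_r2, direction_effect = tab$direction,
      separated = tab$separated, best = tab$best, skip = NA_character_,
      stringsAsFactors = FALSE)
  }
  list(rows = do.call(rbind, rows), skip = NULL,
       ewas = res, pruned = pruned)
}

#' Run the end-to-end trans-tissue MRS experiment
#'
#' Simulates (or loads) two tissue cohorts, applies QC and covariate
#' construction to each, then runs both trans-tissue directions
#' (discovery EWAS in one tissue, score-and-test in the other), each under
#' the configured locus subset modes and score thresholds, plus the
#' confounder-score battery (confounder EWAS in tissue B, scored against
#' diagnosis in tissue A). Identical config and seed give an identical
#' report.
#'
#' @param config A [run_config()].
#' @return List of class `"run_report"`: `associations` (one row per
#'   direction x subset x threshold, plus confounder rows), `qc`,
#'   `cell_tests`, `site_counts`, `meta` (seed, config hash, versions),
#'   `skips`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (config$mode == "simulate") {
    sim_cfg <- do.call(simulation_config, config$sim)
    gen <- generate_paired_datasets(sim_cfg)
    ds_a <- gen$tissueA; ds_b <- gen$tissueB; panel <- gen$panel
    truth <- gen$truth
    loci <- generate_gws_loci(ds_b$probes, k = config$loci$k,
                              seed = config$seed + 99L,
                              window = config$loci$window)
  } else {
    ds_a <- read_dataset(config$paths$tissue_a)
    ds_b <- read_dataset(config$paths$tissue_b)
    panel <- if (!is.null(config$paths$panel)) {
      p <- read_matrix_tsv(config$paths$panel); p
    }
    truth <- NULL
    loci <- if (!is.null(config$paths$loci))
      read_loci(config$paths$loci, window = config$loci$window)
    else loci_set(data.frame(chrom = character(0), pos = integer(0)))
  }
  log_stage(config, "input", "tissue A: ", nrow(ds_a$beta), " x ",
            ncol(ds_a$beta), "; tissue B: ", nrow(ds_b$beta), " x ",
            ncol(ds_b$beta), "; ", nrow(loci), " loci")
  ta <- prepare_tissue(ds_a, panel, config, "tissueA")
  tb <- prepare_tissue(ds_b, panel, config, "tissueB")

  skips <- list()
  rows <- list()
  d1 <- d2 <- NULL
  if ("A_to_B" %in% config$directions) {
    d1 <- run_direction(ta, tb, config, loci, "A_to_B")
    rows$A_to_B <- d1$rows
    if (!is.null(d1$skip)) skips$A_to_B <- d1$skip
  }
  if ("B_to_A" %in% config$directions) {
    d2 <- run_direction(tb, ta, config, loci, "B_to_A")
    rows$B_to_A <- d2$rows
    if (!is.null(d2$skip)) skips$B_to_A <- d2$skip
  }

  for (cf in config$confounder_phenotypes) {
    if (is.null(tb$dataset$samples[[cf]])) {
      skips[[paste0("confounder_", cf)]] <- "phenotype column absent"
      next
    }
    dc <- run_direction(tb, ta, config, loci,
                        direction = paste0("B_to_A_", cf), phenotype = cf)
    if (!is.null(dc$skip)) skips[[paste0("confounder_", cf)]] <- dc$skip
    else {
      dc$rows <- dc$rows[dc$rows$subset == "all", , drop = FALSE]
      rows[[paste0("conf_", cf)]] <- dc$rows
    }
  }
  associations <- do.call(rbind, rows)
  rownames(associations) <- NULL
  report <- structure(list(
    associations = associations,
    qc = list(tissueA = ta$qc$report, tissueB = tb$qc$report),
    cell_tests = list(tissueA = ta$cell_tests, tissueB = tb$cell_tests),
    site_counts = list(
      A_to_B = if (!is.null(d1$pruned)) length(d1$pruned$retained),
      B_to_A = if (!is.null(d2$pruned)) length(d2$pruned$retained)),
    truth = truth,
    meta = list(seed = config$seed, config_hash = config_hash(config),
                package_version = as.character(
                  utils::packageVersion("transmrs")),
                thresholds = config$thresholds),
    skips = skips), class = "run_report")
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write_table_tsv(associations, file.path(config$out, "associations.tsv"))
    body <- report; body$truth <- NULL
    write_json_report(report_body(body), file.path(config$out, "report.json"))
  }
  report
}

# serializable report body (no matrices, no closures, timestamp-free)
report_body <- function(report) {
  list(associations = report$associations,
       qc = lapply(report$qc, function(r)
         list(excluded_samples = r$excluded_samples,
              excluded_probes = r$excluded_probes,
              counts = as.list(r$counts), order = r$order)),
       site_counts = report$site_counts,
       meta = report$meta,
       skips = report$skips)
}

#' One trans-tissue replicate for power and calibration studies
#'
#' Convenience wrapper used by simulation studies: simulates one paired
#' dataset, runs the chosen direction of the pipeline with subset mode
#' `"all"` and no confounder battery, and returns the association row at the
#' final threshold (all sites). `clean_null = TRUE` removes every
#' diagnosis-correlated nuisance pathway from the generator (confounder CpG
#' effects off, equal case/control cell-composition priors), which is the
#' appropriate world for type-I-error studies: confounder- or
#' composition-mediated signal is a true association, not a false positive.
#'
#' @param seed Replicate seed.
#' @param sim List of [simulation_config()] overrides.
#' @param direction `"B_to_A"` (default) or `"A_to_B"`.
#' @param clean_null Disable confounder effects and composition shift.
#' @return One-row data frame: the `PT_1` association row.
#' @export
trans_tissue_replicate <- function(seed, sim = list(),
                                   direction = c("B_to_A", "A_to_B"),
                                   clean_null = TRUE) {
  direction <- match.arg(direction)
  if (clean_null) {
    sim$confounders <- sim$confounders %||%
      lapply(default_confounders(), function(x) { x$frac_causal <- 0; x })
    sim$dirichlet_conc_case <- sim$dirichlet_conc_case %||% c(12, 8, 4)
    sim$dirichlet_conc_control <- sim$dirichlet_conc_control %||% c(12, 8, 4)
  }
  cfg <- run_config(sim = sim, subset_modes = "all", directions = direction,
                    confounder_phenotypes = character(0), seed = seed,
                    log_level = "quiet")
  a <- suppressWarnings(run_pipeline(cfg))$associations
  row <- a[!is.na(a$threshold) & a$threshold == "PT_1", , drop = FALSE]
  if (nrow(row) == 0)
    row <- data.frame(direction = direction, phenotype = "diagnosis",
                      subset = "all", threshold = "PT_1", n_sites = NA,
                      p = NA_real_, p_wald = NA_real_, p_score = NA_real_,
                      r2_covariates = NA_real_, r2_full = NA_real_,
                      delta_r2 = NA_real_, direction_effect = NA,
                      separated = NA, best = NA, skip = "stage skipped")
  row
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$meta$seed, "config", x$meta$config_hash, "\n")
  best <- x$associations[x$associations$best %in% TRUE, , drop = FALSE]
  cols <- c("direction", "phenotype", "subset", "threshold", "n_sites",
            "delta_r2", "p")
  print(best[, cols], row.names = FALSE, digits = 3)
  invisible(x)
}
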