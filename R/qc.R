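#' Assemble a methylation dataset for one tissue
#'
#' Bundles a normalized beta-value matrix with its matched detection p-value
#' and bead-count matrices, per-sample metadata and per-probe annotation into
#' a validated container used by every downstream stage.
#'
#' @param beta Numeric matrix, samples x CpGs, values strictly in (0, 1)
#'   (`NA` allowed for planted missingness). Row names are sample ids and
#'   column names CpG ids; when absent they are taken from `samples$id` /
#'   `probes$cpg`.
#' @param samples Data frame of per-sample metadata with at least columns
#'   `id` and `diagnosis` (`"case"`/`"control"`); typically also `sex`
#'   (`"M"`/`"F"`), `age`, `slide`, and optional confounders
#'   (`smoking`, `bmi`, `suicide`) or known cell proportions.
#' @param probes Data frame of probe annotation with columns `cpg`, `chrom`,
#'   `pos` (1-based).
#' @param detection_p Optional matrix of detection p-values matching `beta`.
#' @param bead_count Optional integer matrix of bead counts matching `beta`.
#'
#' @return An object of class `"methylation_dataset"`: a list with elements
#'   `beta`, `detection_p`, `bead_count`, `samples`, `probes`.
#' @export
methylation_dataset <- function(beta, samples, probes,
                                detection_p = NULL, bead_count = NULL) {
  beta <- as.matrix(beta)
  samples <- as.data.frame(samples)
  probes <- as.data.frame(probes)
  stopifnot(is.numeric(beta),
            all(c("id", "diagnosis") %in% names(samples)),
            all(c("cpg", "chrom", "pos") %in% names(probes)))
  if (is.null(rownames(beta))) rownames(beta) <- as.character(samples$id)
  if (is.null(colnames(beta))) colnames(beta) <- as.character(probes$cpg)
  if (nrow(beta) != nrow(samples))
    stop("beta has ", nrow(beta), " rows but samples has ", nrow(samples))
  if (ncol(beta) != nrow(probes))
    stop("beta has ", ncol(beta), " columns but probes has ", nrow(probes))
  if (anyDuplicated(probes$cpg))
    stop("probe annotation contains duplicated CpG ids")
  if (any(probes$pos < 0, na.rm = TRUE))
    stop("probe positions must be non-negative")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] <= 0 || rng[2] >= 1)
    stop("beta values must lie strictly inside (0, 1)")
  for (m in list(detection_p, bead_count))
    if (!is.null(m) && !identical(dim(m), dim(beta)))
      stop("detection_p / bead_count dimensions must match beta")
  structure(list(beta = beta,
                 detection_p = detection_p,
                 bead_count = bead_count,
                 samples = samples,
                 probes = probes),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("<methylation_dataset> %d samples x %d CpGs\n",
              nrow(x$beta), ncol(x$beta)))
  tab <- table(x$samples$diagnosis)
  cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(as.character(x$probes$chrom)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$beta)

# Subset a dataset by sample index and/or probe index, keeping all four
# slots aligned. Internal: QC filters and universe intersection use it.
subset_dataset <- function(ds, sample_idx = NULL, probe_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(ds$beta))
  if (is.null(probe_idx)) probe_idx <- seq_len(ncol(ds$beta))
  take <- function(m) if (is.null(m)) NULL else m[sample_idx, probe_idx, drop = FALSE]
  out <- ds
  out$beta <- take(ds$beta)
  out$detection_p <- take(ds$detection_p)
  out$bead_count <- take(ds$bead_count)
  out$samples <- ds$samples[sample_idx, , drop = FALSE]
  out$probes <- ds$probes[probe_idx, , drop = FALSE]
  rownames(out$samples) <- NULL
  rownames(out$probes) <- NULL
  out
}

#' Quality-control thresholds
#'
#' Default thresholds for sample- and probe-level filtering and sex-outlier
#' detection. A probe-sample measurement "fails detection" when its detection
#' p-value exceeds `probe_detection_p`, and "fails beads" when its bead count
#' is below `min_beads`. Samples (probes) are excluded when the fraction of
#' failing measurements strictly exceeds the corresponding 10% threshold.
#'
#' @param beadnum_samples Max allowed fraction of low-bead probes per sample.
#' @param detectionp_samples Max allowed fraction of undetected probes per sample.
#' @param beadnum_cpgs Max allowed fraction of low-bead samples per probe.
#' @param detectionp_cpgs Max allowed fraction of undetected samples per probe.
#' @param sex_outlier_sd Cluster-SD multiple beyond which a sample's
#'   sex-chromosome summary is flagged as an outlier.
#' @param probe_detection_p Detection p-value above which a measurement fails.
#' @param min_beads Bead count below which a measurement fails.
#'
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(beadnum_samples = 0.1, detectionp_samples = 0.1,
                          beadnum_cpgs = 0.1, detectionp_cpgs = 0.1,
                          sex_outlier_sd = 10, probe_detection_p = 0.01,
                          min_beads = 3) {
  stopifnot(beadnum_samples >= 0, detectionp_samples >= 0,
            beadnum_cpgs >= 0, detectionp_cpgs >= 0,
            sex_outlier_sd > 0, probe_detection_p > 0, probe_detection_p < 1,
            min_beads >= 0)
  structure(list(beadnum_samples = beadnum_samples,
                 detectionp_samples = detectionp_samples,
                 beadnum_cpgs = beadnum_cpgs,
                 detectionp_cpgs = detectionp_cpgs,
                 sex_outlier_sd = sex_outlier_sd,
                 probe_detection_p = probe_detection_p,
                 min_beads = min_beads),
            class = "qc_thresholds")
}

new_qc_report <- function(excluded_samples, excluded_probes, order) {
  structure(list(excluded_samples = excluded_samples,
                 excluded_probes = excluded_probes,
                 counts = c(samples = nrow(excluded_samples),
                            probes = nrow(excluded_probes)),
                 order = order),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$counts["samples"], "samples and",
      x$counts["probes"], "probes excluded; order:", x$order, "\n")
  invisible(x)
}

#' Filter samples on bead-count and detection failure fractions
#'
#' A sample is excluded when its fraction of probes with
#' `bead_count < min_beads` strictly exceeds `beadnum_samples`, or its
#' fraction of probes with `detection_p > probe_detection_p` strictly exceeds
#' `detectionp_samples`. Retained sample order is preserved. When a sample
#' fails both rules the primary recorded reason is detection.
#'
#' @param ds A [methylation_dataset()].
#' @param thresholds A [qc_thresholds()].
#' @return List with elements `dataset` (filtered) and `report` (a
#'   `qc_report` listing exclusions with reasons).
#' @export
filter_samples <- function(ds, thresholds = qc_thresholds()) {
  n_probe <- ncol(ds$beta)
  frac_bead <- if (is.null(ds$bead_count)) rep(0, nrow(ds$beta)) else
    rowMeans(ds$bead_count < thresholds$min_beads, na.rm = TRUE)
  frac_det <- if (is.null(ds$detection_p)) rep(0, nrow(ds$beta)) else
    rowMeans(ds$detection_p > thresholds$probe_detection_p, na.rm = TRUE)
  fail_bead <- frac_bead > thresholds$beadnum_samples
  fail_det <- frac_det > thresholds$detectionp_samples
  drop <- fail_bead | fail_det
  if (all(drop)) stop("sample QC removed every sample")
  excl <- data.frame(
    id = as.character(ds$samples$id[drop]),
    reason = ifelse(fail_det[drop], "detection", "beadcount"),
    reasons_all = vapply(which(drop), function(i)
      paste(c("detection"[fail_det[i]], "beadcount"[fail_bead[i]]),
            collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  list(dataset = subset_dataset(ds, sample_idx = which(!drop)),
       report = new_qc_report(excl, excl[0, ], "samples"))
}

#' Filter probes on detection and bead-count failure fractions
#'
#' A probe is excluded when the fraction of samples with
#' `detection_p > probe_detection_p` strictly exceeds `detectionp_cpgs`, or
#' the fraction with `bead_count < min_beads` strictly exceeds
#' `beadnum_cpgs`. The strict inequality means a probe failing in exactly
#' 10% of samples is kept. Both reasons are recorded when both rules fire;
#' the primary reason is detection.
#'
#' @inheritParams filter_samples
#' @return List with `dataset` and `report`, as [filter_samples()].
#' @export
filter_probes <- function(ds, thresholds = qc_thresholds()) {
  frac_det <- if (is.null(ds$detection_p)) rep(0, ncol(ds$beta)) else
    colMeans(ds$detection_p > thresholds$probe_detection_p, na.rm = TRUE)
  frac_bead <- if (is.null(ds$bead_count)) rep(0, ncol(ds$beta)) else
    colMeans(ds$bead_count < thresholds$min_beads, na.rm = TRUE)
  fail_det <- frac_det > thresholds$detectionp_cpgs
  fail_bead <- frac_bead > thresholds$beadnum_cpgs
  drop <- fail_det | fail_bead
  if (all(drop)) stop("probe QC removed every probe")
  excl <- data.frame(
    cpg = as.character(ds$probes$cpg[drop]),
    reason = ifelse(fail_det[drop], "detection", "beadcount"),
    reasons_all = vapply(which(drop), function(j)
      paste(c("detection"[fail_det[j]], "beadcount"[fail_bead[j]]),
            collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  list(dataset = subset_dataset(ds, probe_idx = which(!drop)),
       report = new_qc_report(excl[0, ], excl, "probes"))
}

# chromosome labels counted as sex chromosomes, accepting the common dialects
is_sex_chrom <- function(chrom) {
  ch <- toupper(sub("^CHR", "", toupper(as.character(chrom))))
  ch %in% c("X", "Y", "23", "24")
}

#' Predict sample sex from sex-chromosome methylation and flag outliers
#'
#' Computes per sample the contrast `s = mean(M on Y) - mean(M on X)`, splits
#' samples into two clusters by 2-means on `s` (collapsed to one cluster when
#' the cluster means are closer than `min_gap` on the M scale), and assigns
#' the higher-`s` cluster as male. A sample is flagged when it lies more than
#' `sex_outlier_sd` cluster standard deviations from its cluster mean, or when
#' predicted sex disagrees with recorded sex. Without sex-chromosome probes
#' every sample is returned as not evaluable (no error).
#'
#' @inheritParams filter_samples
#' @param min_gap Minimum between-cluster separation (M units) for the
#'   two-cluster solution to be accepted.
#' @return Data frame with columns `id`, `s`, `predicted_sex` (`"M"`, `"F"` or
#'   `NA` for not evaluable), `recorded_sex`, `outlier`, `mismatch`, `flagged`.
#' @export
predict_sex_and_flag_outliers <- function(ds, thresholds = qc_thresholds(),
                                          min_gap = 1) {
  ch <- as.character(ds$probes$chrom)
  on_y <- toupper(sub("^chr", "", ch, ignore.case = TRUE)) %in% c("Y", "24")
  on_x <- toupper(sub("^chr", "", ch, ignore.case = TRUE)) %in% c("X", "23")
  rec <- if ("sex" %in% names(ds$samples)) as.character(ds$samples$sex) else
    rep(NA_character_, nrow(ds$beta))
  out <- data.frame(id = as.character(ds$samples$id),
                    s = NA_real_, predicted_sex = NA_character_,
                    recorded_sex = rec, outlier = FALSE, mismatch = FALSE,
                    flagged = FALSE, stringsAsFactors = FALSE)
  if (!any(on_y) || !any(on_x)) return(out)  # not evaluable
  M <- beta_to_m(ds$beta)
  s <- rowMeans(M[, on_y, drop = FALSE], na.rm = TRUE) -
    rowMeans(M[, on_x, drop = FALSE], na.rm = TRUE)
  out$s <- s
  if (length(unique(s)) >= 2) {
    km <- stats::kmeans(s, centers = range(s), iter.max = 50)
    two_clusters <- abs(diff(km$centers[, 1])) > min_gap
  } else {
    two_clusters <- FALSE
  }
  if (two_clusters) {
    male_cluster <- which.max(km$centers[, 1])
    cl <- km$cluster
  } else {
    # single cluster: sign of the contrast decides (simulated/real male
    # contrasts sit well above zero, female well below)
    cl <- rep(1L, length(s))
    male_cluster <- if (mean(s) > 0) 1L else 0L
  }
  out$predicted_sex <- ifelse(cl == male_cluster, "M", "F")
  for (k in unique(cl)) {
    idx <- cl == k
    mu <- mean(s[idx]); sdev <- stats::sd(s[idx])
    if (!is.finite(sdev) || sdev == 0) next
    out$outlier[idx] <- abs(s[idx] - mu) > thresholds$sex_outlier_sd * sdev
  }
  out$mismatch <- !is.na(out$recorded_sex) &
    out$predicted_sex != out$recorded_sex
  out$flagged <- out$outlier | out$mismatch
  out
}

#' Remove sex-chromosome probes
#'
#' Drops every probe annotated to chromosome X or Y (accepting labels
#' `"X"`, `"chrX"`, `"23"`, and Y equivalents). Autosomal probes are
#' untouched. Dropping every probe leaves an empty probe set with a warning.
#'
#' @inheritParams filter_samples
#' @return The dataset restricted to autosomal probes.
#' @export
drop_sex_chromosomes <- function(ds) {
  keep <- !is_sex_chrom(ds$probes$chrom)
  if (!any(keep)) warning("all probes were sex-chromosomal; empty probe set")
  subset_dataset(ds, probe_idx = which(keep))
}

#' Convert methylation beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))`, elementwise. Values are clipped to
#' `[eps, 1 - eps]` before the logit to avoid infinities.
#'
#' @param beta Numeric vector or matrix with values in `[0, 1]`.
#' @param eps Clipping bound, default `1e-6`.
#' @return M-values with the same shape as `beta`.
#' @seealso [m_to_beta()] for the inverse.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`. Round-trip error away
#' from the clipping boundary is below 1e-10.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  dimnames(out) <- dimnames(m)
  out
}

#' Run the full sample/probe QC sequence
#'
#' Applies sample filtering then probe filtering (or the reverse when
#' `order = "probes_first"`), drops sex-outlier samples when requested, and
#' removes sex-chromosome probes. The report records the order used and every
#' exclusion with its reason.
#'
#' @inheritParams filter_samples
#' @param order `"samples_first"` (default) or `"probes_first"`.
#' @param drop_sex_outliers Remove samples whose predicted sex mismatches the
#'   recorded sex or whose sex contrast is an extreme outlier.
#' @return List with `dataset` (QC'd, autosomes only) and `report`.
#' @export
run_qc <- function(ds, thresholds = qc_thresholds(),
                   order = c("samples_first", "probes_first"),
                   drop_sex_outliers = TRUE) {
  order <- match.arg(order)
  sex_tab <- predict_sex_and_flag_outliers(ds, thresholds)
  if (drop_sex_outliers && any(sex_tab$flagged)) {
    keep <- which(!sex_tab$flagged)
    ds <- subset_dataset(ds, sample_idx = keep)
  }
  steps <- if (order == "samples_first") c("s", "p") else c("p", "s")
  excl_s <- NULL; excl_p <- NULL
  for (st in steps) {
    if (st == "s") {
      r <- filter_samples(ds, thresholds)
      excl_s <- r$report$excluded_samples
    } else {
      r <- filter_probes(ds, thresholds)
      excl_p <- r$report$excluded_probes
    }
    ds <- r$dataset
  }
  ds <- drop_sex_chromosomes(ds)
  flagged <- sex_tab[sex_tab$flagged, , drop = FALSE]
  if (nrow(flagged) && drop_sex_outliers) {
    excl_s <- rbind(excl_s,
                    data.frame(id = flagged$id,
                               reason = ifelse(flagged$mismatch,
                                               "sex_mismatch", "sex_outlier"),
                               reasons_all = ifelse(flagged$mismatch,
                                                    "sex_mismatch", "sex_outlier"),
                               stringsAsFactors = FALSE))
  }
  list(dataset = ds,
       report = new_qc_report(excl_s, excl_p, order),
       sex = sex_tab)
}
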