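#' Reference-based cell-type deconvolution
#'
#' Estimates per-sample cell-type proportions by constrained least squares:
#' each sample's beta vector over the panel CpGs is regressed on the
#' reference profiles subject to non-negativity and an exact sum-to-one
#' equality constraint. Solved with a small active-set scheme (solve the
#' equality-constrained problem, clamp negative coordinates to zero,
#' re-solve on the remaining support until feasible).
#'
#' @param ds A [methylation_dataset()].
#' @param panel Reference matrix (cell types x CpGs) of beta profiles; its
#'   CpG set must overlap the dataset's by at least 10 probes.
#' @return Data frame with one row per sample: `id`, one proportion column
#'   per cell type, and `residual_norm`.
#' @export
estimate_cell_proportions <- function(ds, panel) {
  common <- intersect(colnames(panel), colnames(ds$beta))
  if (length(common) < 10)
    stop("fewer than 10 CpGs shared between dataset and reference panel")
  A <- t(panel[, common, drop = FALSE])          # CpGs x celltypes
  B <- t(ds$beta[, common, drop = FALSE])        # CpGs x samples
  k <- ncol(A)
  fit1 <- function(b) {
    ok <- !is.na(b)
    sls_simplex(A[ok, , drop = FALSE], b[ok])
  }
  props <- t(apply(B, 2, fit1))
  if (k == 1) props <- matrix(1, ncol(B), 1)
  colnames(props) <- rownames(panel)
  res <- sqrt(colSums((B - A %*% t(props))^2, na.rm = TRUE))
  out <- data.frame(id = as.character(ds$samples$id), props,
                    residual_norm = res, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}

# min ||A p - b||^2  s.t.  sum(p) = 1, p >= 0   (active-set on the support)
sls_simplex <- function(A, b) {
  k <- ncol(A)
  if (k == 1) return(1)
  support <- rep(TRUE, k)
  for (iter in seq_len(2 * k)) {
    ks <- sum(support)
    As <- A[, support, drop = FALSE]
    # KKT system for equality-constrained least squares
    G <- crossprod(As)
    d <- crossprod(As, b)
    K <- rbind(cbind(G, 1), c(rep(1, ks), 0))
    sol <- tryCatch(solve(K, c(d, 1)), error = function(e) NULL)
    if (is.null(sol)) {  # singular support: fall back to ridge
      sol <- solve(K + diag(1e-8, ks + 1), c(d, 1))
    }
    p_s <- sol[seq_len(ks)]
    if (all(p_s >= -1e-10)) {
      p <- numeric(k)
      p[support] <- pmax(p_s, 0)
      return(p / sum(p))
    }
    drop_i <- which(support)[which.min(p_s)]
    support[drop_i] <- FALSE
    if (sum(support) == 1) {
      p <- numeric(k); p[support] <- 1
      return(p)
    }
  }
  p <- numeric(k); p[support] <- pmax(p_s, 0)
  p / sum(p)
}

#' Compare cell proportions between diagnostic groups
#'
#' Mann-Whitney U test per cell type between cases and controls. Cell types
#' whose proportions differ at `alpha` are admitted as covariates; for
#' brain-style two-type panels the neuronal column (named in
#' `always_admit`) is admitted unconditionally.
#'
#' @param ds A [methylation_dataset()] (supplies the diagnosis column).
#' @param proportions Output of [estimate_cell_proportions()].
#' @param alpha Admission threshold, default 0.05.
#' @param always_admit Character vector of cell-type names admitted
#'   regardless of the test (e.g. `"NeuN_pos"`).
#' @return List with `tests` (data frame: celltype, z, p, admitted) and
#'   `admitted` (character vector of admitted cell-type names).
#' @export
compare_cell_proportions <- function(ds, proportions, alpha = 0.05,
                                     always_admit = character(0)) {
  dx <- as.character(ds$samples$diagnosis)
  if (length(unique(dx)) < 2) stop("need both diagnostic groups")
  types <- setdiff(names(proportions), c("id", "residual_norm"))
  rows <- lapply(types, function(ct) {
    x <- proportions[[ct]]
    mw <- mann_whitney(x[dx == "control"], x[dx == "case"])
    data.frame(celltype = ct, z = mw$z, p = mw$p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$admitted <- (!is.na(tests$p) & tests$p < alpha) |
    tests$celltype %in% always_admit
  list(tests = tests, admitted = tests$celltype[tests$admitted])
}

#' Select principal components associated with slide
#'
#' PCA (economy SVD of the centered beta matrix, samples x CpGs); each of the
#' first `max_pcs` PC score vectors is tested against the slide factor by
#' one-way ANOVA, and PCs with p < `alpha` are returned in variance order.
#' With fewer than two slides the selection is empty.
#'
#' @param beta Numeric matrix, samples x CpGs.
#' @param slide Slide id per sample (factor or character).
#' @param alpha Selection threshold, default 0.05.
#' @param max_pcs Number of leading PCs to screen, default 10.
#' @return List with `scores` (matrix of selected PC scores, 0 columns when
#'   none selected), `tests` (pc, p), `selected` (PC indices).
#' @export
slide_associated_pcs <- function(beta, slide, alpha = 0.05, max_pcs = 10) {
  slide <- factor(slide)
  n <- nrow(beta)
  empty <- list(scores = matrix(numeric(0), n, 0),
                tests = data.frame(pc = integer(0), p = numeric(0)),
                selected = integer(0))
  if (nlevels(slide) < 2) return(empty)
  X <- scale(beta, center = TRUE, scale = FALSE)
  npc <- min(max_pcs, n - 1L)
  sv <- svd(X, nu = npc, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(npc)], npc)
  pvals <- vapply(seq_len(npc), function(j) {
    fit <- stats::aov(scores[, j] ~ slide)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  sel <- which(pvals < alpha)
  out_scores <- scores[, sel, drop = FALSE]
  colnames(out_scores) <- if (length(sel)) paste0("PC", sel) else character(0)
  list(scores = out_scores,
       tests = data.frame(pc = seq_len(npc), p = pvals),
       selected = sel)
}

#' Estimate surrogate variables from residual structure
#'
#' Residualizes the M-value matrix on the phenotype and known covariates and
#' takes the top left singular vectors of the residual matrix as surrogate
#' variables. With `n_sv = "auto"` the number is chosen by a
#' permutation-based eigenvalue threshold (Buja-Eyuboglu style): a component
#' is kept while its singular value exceeds the `1 - alpha` quantile of
#' singular values obtained from column-permuted residuals.
#'
#' @param M Numeric matrix, samples x CpGs, of M-values.
#' @param phenotype Numeric or factor phenotype vector.
#' @param covariates Optional data frame / matrix of known covariates.
#' @param n_sv Number of surrogate variables, or `"auto"`.
#' @param n_perm Permutations for auto selection, default 20.
#' @param alpha Significance level for auto selection, default 0.05.
#' @return Matrix (samples x n_sv) of orthonormal surrogate variables;
#'   zero columns when none are found.
#' @export
estimate_surrogate_variables <- function(M, phenotype, covariates = NULL,
                                         n_sv = 0, n_perm = 20,
                                         alpha = 0.05) {
  df <- data.frame(phenotype = phenotype)
  if (!is.null(covariates) && NCOL(covariates) > 0)
    df <- cbind(df, as.data.frame(covariates))
  X <- stats::model.matrix(~., data = df)
  if (qr(X)$rank < ncol(X)) stop("known-covariate design is rank deficient")
  n <- nrow(M)
  H <- X %*% solve(crossprod(X), t(X))
  R <- M - H %*% M
  max_rank <- n - ncol(X)
  if (identical(n_sv, "auto")) {
    d <- svd(R, nu = 0, nv = 0)$d
    perm_top <- replicate(n_perm, {
      Rp <- apply(R, 2, sample)
      Rp <- Rp - (H %*% Rp)  # keep the permuted null in the residual space
      svd(Rp, nu = 0, nv = 0)$d[1]
    })
    thr <- stats::quantile(perm_top, 1 - alpha)
    n_sv <- sum(d[seq_len(max_rank)] > thr)
  }
  n_sv <- as.integer(n_sv)
  if (n_sv > max_rank) stop("n_sv exceeds residual rank (", max_rank, ")")
  if (n_sv == 0) return(matrix(numeric(0), n, 0))
  sv <- svd(R, nu = n_sv, nv = 0)
  out <- sv$u[, seq_len(n_sv), drop = FALSE]
  colnames(out) <- paste0("SV", seq_len(n_sv))
  out
}

#' Assemble the covariate set for an EWAS or association model
#'
#' Combines age, sex, admitted cell proportions, slide-associated PCs and
#' surrogate variables into one design data frame, recording which rule
#' admitted each column. Constant columns are dropped; perfectly collinear
#' pairs raise an error. The diagnosis column is never included.
#'
#' @param ds A [methylation_dataset()].
#' @param proportions Optional [estimate_cell_proportions()] output.
#' @param admitted Cell types to include (e.g. from
#'   [compare_cell_proportions()]).
#' @param pcs Optional output of [slide_associated_pcs()].
#' @param svs Optional surrogate-variable matrix.
#' @return List of class `"covariate_set"`: `design` (data frame, rows
#'   aligned with sample ids), `provenance` (column -> admitting rule).
#' @export
build_covariate_set <- function(ds, proportions = NULL,
                                admitted = character(0), pcs = NULL,
                                svs = NULL) {
  n <- nrow(ds$samples)
  design <- data.frame(row.names = seq_len(n))
  prov <- character(0)
  if ("age" %in% names(ds$samples) && !all(is.na(ds$samples$age))) {
    design$age <- ds$samples$age
    prov["age"] <- "always: age or predicted age"
  }
  if ("sex" %in% names(ds$samples)) {
    design$sex <- as.integer(ds$samples$sex == "M")
    prov["sex"] <- "always: sex"
  }
  for (ct in admitted) {
    design[[ct]] <- proportions[[ct]][match(ds$samples$id, proportions$id)]
    prov[ct] <- "cell proportion differing between groups (p < 0.05)"
  }
  if (!is.null(pcs) && NCOL(pcs$scores) > 0) {
    for (j in seq_len(ncol(pcs$scores))) {
      nm <- colnames(pcs$scores)[j]
      design[[nm]] <- pcs$scores[, j]
      prov[nm] <- "PC associated with slide (p < 0.05)"
    }
  }
  if (!is.null(svs) && NCOL(svs) > 0) {
    for (j in seq_len(ncol(svs))) {
      nm <- colnames(svs)[j] %||% paste0("SV", j)
      design[[nm]] <- svs[, j]
      prov[nm] <- "surrogate variable"
    }
  }
  keep <- vapply(design, function(x) stats::var(as.numeric(x)) > 0,
                 logical(1))
  design <- design[, keep, drop = FALSE]
  # guard joint collinearity with the intercept (e.g. a full set of cell
  # proportions sums to 1): drop later-admitted columns until full rank
  while (ncol(design) >= 1) {
    X <- cbind(1, as.matrix(as.data.frame(lapply(design, as.numeric))))
    qx <- qr(scale(X, center = FALSE,
                   scale = apply(abs(X), 2, max)))
    if (qx$rank == ncol(X)) break
    drop_col <- ncol(design)
    warning("dropping covariate '", names(design)[drop_col],
            "' (collinear with the remaining design)")
    design <- design[, -drop_col, drop = FALSE]
  }
  prov <- prov[names(design)]
  structure(list(design = design, provenance = prov,
                 ids = as.character(ds$samples$id)),
            class = "covariate_set")
}
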