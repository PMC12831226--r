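#' Mass-univariate EWAS of a phenotype on M-values
#'
#' Fits, for every CpG, the ordinary least-squares model
#' `M ~ phenotype + covariates` and reports the phenotype coefficient
#' ("effect", on the M scale), its standard error, t statistic and two-sided
#' p-value with `n - p` residual degrees of freedom. The design is shared
#' across CpGs, so the fit is a single QR decomposition applied to the whole
#' matrix. Samples missing the phenotype or any covariate are dropped
#' listwise; CpGs with zero variance (or missing values, which would break
#' the shared design) are reported as NA rows rather than dropped.
#'
#' @param M Numeric matrix, samples x CpGs, of M-values.
#' @param phenotype Binary (factor/character/0-1) or continuous phenotype;
#'   for factors the second level is coded 1. `"case"`/`"control"` is coded
#'   case = 1.
#' @param covariates Optional `covariate_set` (from [build_covariate_set()]),
#'   data frame or matrix of covariates.
#' @param probes Optional probe annotation to attach (`cpg`, `chrom`, `pos`);
#'   rows are matched by CpG id and the result is sorted by (chrom, pos).
#' @param model_id Free-text descriptor stored with the result.
#' @return Data frame of class `"ewas_result"`, one row per CpG:
#'   `cpg, chrom, pos, effect, se, t, p, n`, with attributes `phenotype` and
#'   `covariates` describing the model.
#' @export
run_ewas <- function(M, phenotype, covariates = NULL, probes = NULL,
                     model_id = "diagnosis") {
  y <- phenotype
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    y <- if (all(y %in% c("case", "control"))) as.integer(y == "case")
         else as.integer(factor(y)) - 1L
  }
  y <- as.numeric(y)
  if (length(unique(stats::na.omit(y))) < 2)
    stop("phenotype is constant")
  C <- NULL
  if (inherits(covariates, "covariate_set")) C <- covariates$design
  else if (!is.null(covariates)) C <- as.data.frame(covariates)
  X <- if (is.null(C) || ncol(C) == 0) cbind(`(Intercept)` = 1, phenotype = y)
       else cbind(`(Intercept)` = 1, phenotype = y,
                  as.matrix(as.data.frame(lapply(C, as.numeric))))
  use <- stats::complete.cases(X)
  X <- X[use, , drop = FALSE]
  Mu <- M[use, , drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 2) stop("too few samples for the design (need n > p + 1)")
  XtXinv <- chol2inv(qr.R(qrx))
  cjj <- XtXinv[2, 2]
  coefs <- qr.coef(qrx, Mu)                       # p x m
  res <- Mu - X %*% coefs
  sigma2 <- colSums(res^2) / df
  effect <- coefs[2, ]
  se <- sqrt(sigma2 * cjj)
  tval <- effect / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  bad_cpg <- matrixStats_colVars(Mu) <= 0 | apply(is.na(Mu), 2, any)
  effect[bad_cpg] <- NA_real_; se[bad_cpg] <- NA_real_
  tval[bad_cpg] <- NA_real_; pval[bad_cpg] <- NA_real_
  out <- data.frame(cpg = colnames(M), effect = effect, se = se, t = tval,
                    p = pval, n = n, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(probes)) {
    idx <- match(out$cpg, probes$cpg)
    out$chrom <- probes$chrom[idx]
    out$pos <- probes$pos[idx]
    out <- out[order(out$chrom, out$pos), ]
  } else {
    out$chrom <- NA_character_
    out$pos <- NA_integer_
  }
  out <- out[, c("cpg", "chrom", "pos", "effect", "se", "t", "p", "n")]
  rownames(out) <- NULL
  attr(out, "phenotype") <- model_id
  attr(out, "covariates") <- if (is.null(C)) character(0) else names(C)
  class(out) <- c("ewas_result", "data.frame")
  out
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Call genome-wide-significant positions
#'
#' Returns the rows of an EWAS result with `p < threshold` (strict), sorted
#' by p ascending, annotated with methylation direction (`"hyper"` for a
#' positive case effect, `"hypo"` for negative).
#'
#' @param res An `ewas_result`.
#' @param threshold Significance threshold, default `9.0e-8` (the strict
#'   array-wide level used for both 450K and EPIC).
#' @return Data frame of significant rows with an added `direction` column.
#' @export
call_genome_wide_significant <- function(res, threshold = 9.0e-8) {
  hit <- !is.na(res$p) & res$p < threshold
  out <- res[hit, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  out$direction <- ifelse(out$effect > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)` over non-NA p-values.
#'
#' @param p Vector of p-values.
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
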