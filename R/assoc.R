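#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an explicit IRLS loop (tolerance
#' 1e-8 on the coefficient change, at most `max_iter` iterations). Complete
#' or quasi-separation is detected (diverging coefficients or fitted
#' probabilities collapsing to 0/1) and reported through the `separated`
#' flag instead of returning spurious estimates as converged. The
#' intercept-only log-likelihood `ll0` is always included so pseudo-R2
#' measures can be formed.
#'
#' @param y Binary outcome vector (0/1, logical, or a two-level factor).
#' @param X Design matrix or data frame of predictors (intercept added
#'   automatically).
#' @param max_iter Maximum IRLS iterations, default 100.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @return List of class `"logistic_fit"`: `coefficients`, `se`, `z`, `p`,
#'   `ll1`, `ll0`, `n`, `converged`, `separated`.
#' @export
fit_logistic <- function(y, X = NULL, max_iter = 100, tol = 1e-8) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.character(y)) y <- as.integer(y == "case")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome contains a single class")
  Xm <- if (is.null(X) || NCOL(X) == 0) matrix(numeric(0), length(y), 0)
        else as.matrix(as.data.frame(X))
  Xm <- cbind(`(Intercept)` = 1, Xm)
  if (qr(Xm)$rank < ncol(Xm)) stop("design matrix is rank deficient")
  n <- length(y); p <- ncol(Xm)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE; separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xm %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    WX <- Xm * w
    fit <- tryCatch(solve(crossprod(Xm, WX), crossprod(WX, z)),
                    error = function(e) NULL)
    if (is.null(fit)) { separated <- TRUE; break }
    delta <- max(abs(fit - beta))
    beta <- as.numeric(fit)
    # scale-free divergence guard: |eta| ~ 30 means fitted probabilities
    # within 1e-13 of 0/1 -- only reachable when the data are separable
    if (max(abs(Xm %*% beta)) > 30) { separated <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.numeric(Xm %*% beta)
  mu <- stats::plogis(eta)
  if (!converged && !separated &&
      all(mu[y == 1] > 0.5) && all(mu[y == 0] < 0.5) &&
      max(abs(eta)) > 10)
    separated <- TRUE                # slow quasi-separation
  ll <- function(m) sum(y * log(m) + (1 - y) * log(1 - m))
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll1 <- ll(mu_c)
  pbar <- mean(y)
  ll0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  se <- z_ <- pv <- rep(NA_real_, p)
  if (!separated) {
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(Xm, Xm * w)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc)) {
      se <- sqrt(diag(vc))
      z_ <- beta / se
      pv <- 2 * stats::pnorm(abs(z_), lower.tail = FALSE)
    }
  }
  names(beta) <- names(se) <- names(z_) <- names(pv) <- colnames(Xm)
  structure(list(coefficients = beta, se = se, z = z_, p = pv,
                 ll1 = ll1, ll0 = ll0, n = n,
                 converged = converged, separated = separated),
            class = "logistic_fit")
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2_CS = 1 - exp((2/n) (ll0 - ll1))` rescaled to a unit maximum:
#' `R2_N = R2_CS / (1 - exp((2/n) ll0))`, with `ll0` the intercept-only
#' log-likelihood.
#'
#' @param fit A [fit_logistic()] result, or `NULL` when `ll0`, `ll1`, `n`
#'   are given directly.
#' @param ll0,ll1,n Override the fit's intercept-only log-likelihood, model
#'   log-likelihood and sample size.
#' @return Pseudo-R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit = NULL, ll0 = fit$ll0, ll1 = fit$ll1,
                          n = fit$n) {
  if (n <= 0) stop("n must be positive")
  if (ll0 == 0) stop("degenerate null model (ll0 = 0)")
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  denom <- 1 - exp((2 / n) * ll0)
  min(max(r2_cs / denom, 0), 1)
}

#' Rao score test for one column added to a logistic model
#'
#' Tests whether adding predictor `s` to a fitted logistic model improves it,
#' using only the null-model fit — so the test remains well defined under
#' complete or quasi-separation of the extended model, where the Wald
#' statistic degenerates.
#'
#' @param fit0 A [fit_logistic()] result for the null (reduced) model.
#' @param X0 The null-model predictor matrix/data frame used for `fit0`
#'   (without intercept; `NULL` for intercept-only).
#' @param y The binary outcome used for `fit0`.
#' @param s The candidate predictor column.
#' @return List: `z`, `p` (two-sided).
#' @export
score_test_logistic <- function(fit0, X0, y, s) {
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "case")
  Xm <- if (is.null(X0) || NCOL(X0) == 0) matrix(1, length(y), 1)
        else cbind(1, as.matrix(as.data.frame(X0)))
  eta <- as.numeric(Xm %*% fit0$coefficients)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  U <- sum(s * (y - mu))
  WX <- Xm * w
  A <- solve(crossprod(Xm, WX), crossprod(WX, s))
  V <- sum(s * w * s) - sum((w * s) * (Xm %*% A))
  if (V <= 0) return(list(z = 0, p = 1))
  z <- U / sqrt(V)
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Covariate-adjusted association of risk scores with diagnosis
#'
#' For every score threshold fits, on identical samples, a covariate-only
#' logistic model and a covariate-plus-score model, and reports the p-value
#' of the score term, both Nagelkerke pseudo-R2 values and their difference
#' (the incremental variance explained by the score). The headline `p` is
#' the Rao score test of the score term computed from the covariate-only
#' fit: unlike the Wald statistic it neither degenerates under complete
#' separation nor collapses toward 1 when the coefficient is large
#' (Hauck-Donner effect), both of which occur routinely when a score
#' strongly separates small cohorts. The Wald p is reported alongside as
#' `p_wald` (NA under separation, where it is undefined). Rows whose full
#' model separates keep `separated = TRUE`. The threshold with the largest
#' increment is flagged as `best`.
#'
#' @param diagnosis Binary outcome (case/control) per sample.
#' @param mrs An `mrs_profile` from [compute_mrs()] (or a samples x
#'   thresholds matrix).
#' @param covariates Optional `covariate_set`, data frame or matrix.
#' @return List of class `"association_result"`: `table` (one row per
#'   threshold: `threshold, n_sites, p, r2_covariates, r2_full, delta_r2,
#'   direction, separated, best`), `zscores` (z-standardized
#'   covariate-corrected scores, samples x thresholds).
#' @export
mrs_association <- function(diagnosis, mrs, covariates = NULL) {
  scores <- if (inherits(mrs, "mrs_profile")) mrs$scores else as.matrix(mrs)
  counts <- if (inherits(mrs, "mrs_profile")) mrs$site_counts
            else rep(NA_integer_, ncol(scores))
  C <- NULL
  if (inherits(covariates, "covariate_set")) C <- covariates$design
  else if (!is.null(covariates)) C <- as.data.frame(covariates)
  y <- diagnosis
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "case")
  keep <- !is.na(y)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]
  Cu <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
  fit0 <- tryCatch(fit_logistic(y, Cu), error = function(e) NULL)
  rows <- vector("list", ncol(scores))
  zsc <- matrix(NA_real_, sum(keep), ncol(scores),
                dimnames = list(NULL, colnames(scores)))
  null_ok <- !is.null(fit0) && !fit0$separated && fit0$converged
  for (j in seq_len(ncol(scores))) {
    s <- scores[keep, j]
    Xj <- if (is.null(Cu)) data.frame(mrs = s) else cbind(Cu, mrs = s)
    fit1 <- tryCatch(fit_logistic(y, Xj), error = function(e) NULL)
    sep <- !null_ok || is.null(fit1) || fit1$separated || !fit1$converged
    const_score <- stats::var(s) == 0
    p_wald <- p_sc <- r2_0 <- r2_1 <- NA_real_
    dirj <- NA_character_
    if (null_ok && !const_score) {
      st <- score_test_logistic(fit0, Cu, y, s)
      p_sc <- st$p
      dirj <- if (st$z > 0) "positive" else "negative"
      r2_0 <- nagelkerke_r2(fit0)
      if (!is.null(fit1)) r2_1 <- nagelkerke_r2(fit1)
      zsc[, j] <- tryCatch(standardize_scores(s, Cu),
                           error = function(e) rep(NA_real_, length(s)))
      if (!sep) {
        p_wald <- unname(fit1$p["mrs"])
        dirj <- if (unname(fit1$coefficients["mrs"]) > 0) "positive"
                else "negative"
      }
    } else if (null_ok && const_score) {
      r2_0 <- r2_1 <- nagelkerke_r2(fit0)
      p_wald <- 1; p_sc <- 1; sep <- FALSE
    }
    rows[[j]] <- data.frame(threshold = colnames(scores)[j],
                            n_sites = unname(counts[j]),
                            p = p_sc,
                            p_wald = p_wald, p_score = p_sc,
                            r2_covariates = r2_0, r2_full = r2_1,
                            delta_r2 = r2_1 - r2_0, direction = dirj,
                            separated = sep, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$best <- FALSE
  if (any(!is.na(tab$delta_r2)))
    tab$best[which.max(tab$delta_r2)] <- TRUE
  structure(list(table = tab, zscores = zsc, n = sum(keep)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> n =", x$n, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Z-standardize covariate-corrected scores
#'
#' Residualizes the score on the covariates by least squares (intercept
#' included) and divides the residuals by their sample standard deviation
#' (denominator n - 1). The output has mean 0 and SD 1 and is orthogonal to
#' every covariate column.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param covariates Optional data frame / matrix of covariates.
#' @return Numeric vector of z-scores.
#' @export
standardize_scores <- function(scores, covariates = NULL) {
  if (length(scores) < 3) stop("need at least 3 samples")
  X <- if (is.null(covariates) || NCOL(covariates) == 0)
    matrix(1, length(scores), 1)
  else cbind(1, as.matrix(as.data.frame(covariates)))
  res <- stats::lm.fit(X, scores)$residuals
  sdev <- stats::sd(res)
  if (!is.finite(sdev) || sdev < 1e-8 * max(stats::sd(scores), 1e-300))
    stop("zero residual variance: score is exactly linear in the covariates")
  as.numeric(res / sdev)
}

#' Pearson chi-squared test for a 2x2 table (no continuity correction)
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom.
#' No Yates correction is applied; this is the form that reproduces printed
#' epidemiological table statistics.
#'
#' @param a,b,c,d Cell counts, table rows `(a, b)` and `(c, d)`.
#' @return List: `statistic`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all table margins must be positive")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Two-sided test using the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction. `z` is signed so that larger
#' values in `group_b` give a positive z (the convention used when
#' reporting case-vs-control demographic contrasts). With every value
#' identical across both groups, `z = 0` and `p = 1`.
#'
#' @param group_a,group_b Numeric vectors.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List: `U` (number of (a, b) pairs with b > a, ties counted 1/2),
#'   `z`, `p`.
#' @export
mann_whitney <- function(group_a, group_b, correct = TRUE) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  rb <- sum(r[(na + 1):n])
  U <- rb - nb * (nb + 1) / 2                   # pairs with b > a (+ half-ties)
  mU <- na * nb / 2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  vU <- na * nb / 12 * ((n + 1) - tie_term)
  if (vU <= 0) return(list(U = U, z = 0, p = 1))
  d <- U - mU
  if (correct) d <- sign(d) * max(abs(d) - 0.5, 0)
  z <- d / sqrt(vU)
  list(U = U, z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
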