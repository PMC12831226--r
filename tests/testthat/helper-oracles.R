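# Independent oracles. These deliberately use different algorithms / stock R
# implementations from the code paths they check.

# Brute-force co-methylation pruning: O(m^2) pairwise edges with
# stats::cor(method = "spearman"), components by transitive closure over the
# full adjacency matrix, representative = smallest discovery p (tie: smaller
# position).
oracle_prune <- function(beta, ann, p_disc, window = 2000, rho = 0.3) {
  m <- ncol(beta)
  A <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (ann$chrom[i] == ann$chrom[j] &&
          abs(ann$pos[i] - ann$pos[j]) <= window) {
        r <- suppressWarnings(stats::cor(beta[, i], beta[, j],
                                         method = "spearman"))
        if (!is.na(r) && abs(r) >= rho - 1e-9) A[i, j] <- A[j, i] <- TRUE
      }
    }
  }
  diag(A) <- TRUE
  # transitive closure by boolean powering
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (i in seq_len(m)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(A[i, ] > 0)] <- cid
    }
  }
  retained <- vapply(split(seq_len(m), comp), function(idx) {
    pp <- p_disc[idx]; pp[is.na(pp)] <- Inf
    idx[order(pp, ann$pos[idx])][1]
  }, integer(1))
  sort(colnames(beta)[retained])
}

# Exact two-sided permutation p for the Mann-Whitney statistic.
oracle_mw_perm <- function(a, b) {
  na <- length(a); nb <- length(b)
  v <- c(a, b)
  obs <- abs(sum(rank(v)[(na + 1):(na + nb)]) - nb * (na + nb + 1) / 2)
  splits <- utils::combn(na + nb, nb)
  stat <- apply(splits, 2, function(idx)
    abs(sum(rank(v)[idx]) - nb * (na + nb + 1) / 2))
  mean(stat >= obs - 1e-12)
}
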