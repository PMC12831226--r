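# Small deterministic fixtures built in code.

# A minimal dataset with controllable matrices; defaults are clean.
make_fixture <- function(n_samples = 4, n_cpgs = 10, seed = 42,
                         chrom = rep("chr1", n_cpgs),
                         pos = seq_len(n_cpgs) * 1000L,
                         beta = NULL) {
  set.seed(seed)
  if (is.null(beta))
    beta <- matrix(runif(n_samples * n_cpgs, 0.2, 0.8), n_samples, n_cpgs)
  samples <- data.frame(
    id = paste0("s", seq_len(n_samples)),
    diagnosis = rep(c("case", "control"), length.out = n_samples),
    age = 30 + seq_len(n_samples),
    sex = rep(c("M", "F"), length.out = n_samples),
    slide = rep(c("sl1", "sl2"), length.out = n_samples),
    stringsAsFactors = FALSE)
  probes <- data.frame(cpg = sprintf("cg%05d", seq_len(n_cpgs)),
                       chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  dimnames(beta) <- list(samples$id, probes$cpg)
  detp <- matrix(0.001, n_samples, n_cpgs, dimnames = dimnames(beta))
  beads <- matrix(10L, n_samples, n_cpgs, dimnames = dimnames(beta))
  methylation_dataset(beta, samples, probes,
                      detection_p = detp, bead_count = beads)
}

# minimal EWAS-result-shaped table
make_weights <- function(cpg, effect, p, chrom = NA, pos = NA) {
  df <- data.frame(cpg = cpg, chrom = chrom, pos = pos, effect = effect,
                   se = abs(effect) / 2 + 0.1, t = 2, p = p,
                   n = 20, stringsAsFactors = FALSE)
  class(df) <- c("ewas_result", "data.frame")
  df
}
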