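#' The seven score-construction p-value thresholds
#'
#' Discovery p-value cutoffs used for thresholded score construction: strict
#' `<` for the six sub-1 thresholds and `<=` for the final threshold of 1
#' (all sites).
#' @export
PT_THRESHOLDS <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1)

#' Construct a set of GWAS loci with windows
#'
#' @param leads Data frame with columns `chrom`, `pos` (1-based lead
#'   positions) and optionally `name`.
#' @param window Half-width in bp; each locus spans
#'   `[pos - window, pos + window]` inclusive, clipped at 1.
#' @return Data frame of class `"loci_set"` with columns `chrom`, `pos`,
#'   `name`, `start`, `end`.
#' @export
loci_set <- function(leads, window = 100000) {
  leads <- as.data.frame(leads)
  stopifnot(all(c("chrom", "pos") %in% names(leads)))
  if (is.null(leads$name))
    leads$name <- if (nrow(leads)) paste0("locus", seq_len(nrow(leads)))
                  else character(0)
  leads$start <- pmax(1L, as.integer(leads$pos) - as.integer(window))
  leads$end <- as.integer(leads$pos) + as.integer(window)
  structure(leads[, c("chrom", "pos", "name", "start", "end")],
            class = c("loci_set", "data.frame"))
}

#' Intersect discovery and target CpG universes
#'
#' @param discovery An `ewas_result` (or anything with a `cpg` column).
#' @param target A [methylation_dataset()].
#' @return Character vector of shared CpG ids in target annotation order.
#' @export
intersect_sites <- function(discovery, target) {
  ids <- target$probes$cpg[target$probes$cpg %in% discovery$cpg]
  if (!length(ids)) stop("discovery and target CpG universes do not overlap")
  as.character(ids)
}

#' Prune correlated CpGs within a 2-kb window (co-methylation pruning)
#'
#' Builds a graph on the candidate sites with an edge between two CpGs iff
#' they lie on the same chromosome within `window` bp of each other and the
#' absolute Spearman correlation of their target beta columns is at least
#' `rho`. Within each connected component (transitive closure, so chains
#' merge even when the endpoints are further apart than the window) exactly
#' one CpG is retained: the one with the smallest discovery p-value, ties
#' broken by smaller position. `strict_pairwise = TRUE` instead treats each
#' site greedily against already-retained sites only (no chain merging).
#'
#' @param target A [methylation_dataset()] supplying beta values and
#'   positions.
#' @param sites Character vector of candidate CpG ids (must be annotated in
#'   the target).
#' @param discovery An `ewas_result` providing discovery p-values.
#' @param window Max pairwise distance in bp for an edge (default 2000,
#'   inclusive).
#' @param rho Spearman correlation threshold (default 0.3, inclusive).
#' @param strict_pairwise Disable transitive chain merging.
#' @return List of class `"independent_site_set"`: `retained` (CpG ids),
#'   `clusters` (named list: retained id -> pruned ids), `params`.
#' @export
comeback_prune <- function(target, sites, discovery, window = 2000,
                           rho = 0.3, strict_pairwise = FALSE) {
  if (nrow(target$beta) < 3) stop("need at least 3 target samples")
  ann <- target$probes[match(sites, target$probes$cpg), ]
  if (any(is.na(ann$pos)) || any(is.na(ann$cpg)))
    stop("some sites are missing from the target annotation")
  p_disc <- discovery$p[match(sites, discovery$cpg)]
  ord <- order(ann$chrom, ann$pos)
  sites_o <- sites[ord]; chrom_o <- as.character(ann$chrom[ord])
  pos_o <- ann$pos[ord]; p_o <- p_disc[ord]
  m <- length(sites_o)
  # rank-transform the candidate beta columns once
  Bc <- target$beta[, sites_o, drop = FALSE]
  Rk <- apply(Bc, 2, rank)
  Rk <- scale(Rk)                                # Spearman = Pearson on ranks
  nS <- nrow(Rk)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  # candidate pairs: same chromosome, positions within window (sorted scan)
  edges_i <- integer(0); edges_j <- integer(0)
  for (i in seq_len(m)) {
    k <- i + 1L
    while (k <= m && chrom_o[k] == chrom_o[i] &&
           pos_o[k] - pos_o[i] <= window) {
      edges_i <- c(edges_i, i); edges_j <- c(edges_j, k)
      k <- k + 1L
    }
  }
  if (length(edges_i)) {
    rho_hat <- colSums(Rk[, edges_i, drop = FALSE] *
                         Rk[, edges_j, drop = FALSE]) / (nS - 1)
    # inclusive threshold with an epsilon so exactly-at-boundary rational
    # Spearman values (ranks are integers) are not decided by rounding noise
    keep_edge <- !is.na(rho_hat) & abs(rho_hat) >= rho - 1e-9
    for (e in which(keep_edge)) unite(edges_i[e], edges_j[e])
  }
  if (strict_pairwise) {
    # greedy: order by discovery p, retain unless correlated-within-window
    # with an already retained site
    retained_idx <- logical(m)
    pr_order <- order(p_o, pos_o)
    live_edges <- if (length(edges_i)) which(keep_edge) else integer(0)
    nb <- vector("list", m)
    for (e in live_edges) {
      nb[[edges_i[e]]] <- c(nb[[edges_i[e]]], edges_j[e])
      nb[[edges_j[e]]] <- c(nb[[edges_j[e]]], edges_i[e])
    }
    assigned_to <- integer(m)
    for (i in pr_order) {
      conflict <- nb[[i]][retained_idx[nb[[i]]]]
      if (!length(conflict)) { retained_idx[i] <- TRUE; assigned_to[i] <- i }
      else assigned_to[i] <- conflict[1]
    }
    comp <- assigned_to
  } else {
    comp <- vapply(seq_len(m), find, integer(1))
  }
  clusters <- split(seq_len(m), comp)
  retained <- vapply(clusters, function(idx) {
    pp <- p_o[idx]
    pp[is.na(pp)] <- Inf
    best <- idx[order(pp, pos_o[idx])][1]
    best
  }, integer(1))
  cluster_map <- lapply(seq_along(clusters), function(ci) {
    pruned <- setdiff(clusters[[ci]], retained[ci])
    sites_o[pruned]
  })
  names(cluster_map) <- sites_o[retained]
  keep_ids <- sites_o[sort(retained)]
  structure(list(retained = keep_ids,
                 clusters = cluster_map,
                 params = list(window = window, rho = rho,
                               correlation = "spearman",
                               strict_pairwise = strict_pairwise)),
            class = "independent_site_set")
}

#' @export
print.independent_site_set <- function(x, ...) {
  cat("<independent_site_set>", length(x$retained), "retained,",
      sum(lengths(x$clusters)), "pruned (window",
      x$params$window, "bp, |rho| >=", x$params$rho, ")\n")
  invisible(x)
}

#' Compute methylation risk scores at the seven thresholds
#'
#' For each sample i and threshold `P_T`, the score is
#' `S_i = sum_{j : p_j < P_T} effect_j * m_ij` (with `p_j <= 1` at the final
#' threshold, i.e. all sites). `m_ij` is the target methylation of site j on
#' the chosen scale (M-values by default, matching the discovery effect
#' scale; beta behind `scale = "beta"`). Missing methylation values are
#' mean-imputed over samples, with the imputation count logged.
#'
#' @param target A [methylation_dataset()].
#' @param weights An `ewas_result` restricted (or restrictable) to the scored
#'   sites: supplies `effect` and discovery `p` per CpG.
#' @param sites CpG ids to score (e.g. `independent_site_set$retained`).
#' @param thresholds Ascending p-value cutoffs; last entry must be 1.
#' @param scale `"M"` (default) or `"beta"`.
#' @return List of class `"mrs_profile"`: `scores` (samples x thresholds
#'   matrix), `site_counts` (per threshold), `n_imputed`, `thresholds`,
#'   `samples`.
#' @export
compute_mrs <- function(target, weights, sites,
                        thresholds = PT_THRESHOLDS, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  stopifnot(!is.unsorted(thresholds), thresholds[length(thresholds)] == 1)
  idx <- match(sites, weights$cpg)
  if (any(is.na(idx)))
    stop("weights missing for ", sum(is.na(idx)), " scored sites")
  eff <- weights$effect[idx]
  p <- weights$p[idx]
  meth <- target$beta[, sites, drop = FALSE]
  if (scale == "M") meth <- beta_to_m(meth)
  n_imp <- sum(is.na(meth))
  if (n_imp > 0) {
    mu <- colMeans(meth, na.rm = TRUE)
    na_idx <- which(is.na(meth), arr.ind = TRUE)
    meth[na_idx] <- mu[na_idx[, 2]]
  }
  drop_na <- is.na(eff) | is.na(p)
  eff[drop_na] <- 0; p[drop_na] <- Inf
  scores <- sapply(thresholds, function(pt) {
    inc <- if (pt >= 1) p <= 1 else p < pt
    if (!any(inc)) return(rep(0, nrow(meth)))
    as.numeric(meth[, inc, drop = FALSE] %*% eff[inc])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  counts <- vapply(thresholds, function(pt)
    sum(if (pt >= 1) p <= 1 else p < pt), integer(1))
  if (counts[1] == 0)
    warning("no sites pass the smallest threshold; score is 0 there")
  colnames(scores) <- paste0("PT_", thresholds)
  rownames(scores) <- rownames(target$beta)
  structure(list(scores = scores,
                 site_counts = stats::setNames(counts,
                                               colnames(scores)),
                 n_imputed = n_imp,
                 thresholds = thresholds,
                 samples = as.character(target$samples$id),
                 scale = scale),
            class = "mrs_profile")
}

#' Subset CpG sites by GWAS-locus windows
#'
#' `mode = "include"` keeps sites whose position falls inside any locus
#' window (inclusive bounds, 1-based); `"exclude"` keeps the complement;
#' `"all"` returns the input. Include and exclude partition the input
#' exactly.
#'
#' @param probes Annotation data frame (`cpg`, `chrom`, `pos`) covering
#'   `sites`.
#' @param sites Character vector of CpG ids.
#' @param loci A [loci_set()].
#' @param mode `"all"`, `"include"` or `"exclude"`.
#' @return Character vector of CpG ids.
#' @export
subset_by_loci <- function(probes, sites, loci, mode = c("all", "include",
                                                         "exclude")) {
  mode <- match.arg(mode)
  if (mode == "all") return(sites)
  ann <- probes[match(sites, probes$cpg), ]
  if (any(is.na(ann$pos))) stop("sites missing from annotation")
  if (nrow(loci)) {
    norm <- function(ch) toupper(sub("^CHR", "", toupper(as.character(ch))))
    bad <- !norm(loci$chrom) %in% norm(ann$chrom)
    if (any(bad))
      stop("loci on chromosomes absent from the annotation: ",
           paste(unique(as.character(loci$chrom)[bad]), collapse = ", "))
  }
  inside <- rep(FALSE, length(sites))
  for (i in seq_len(nrow(loci))) {
    inside <- inside | (as.character(ann$chrom) ==
                          as.character(loci$chrom[i]) &
                          ann$pos >= loci$start[i] & ann$pos <= loci$end[i])
  }
  if (mode == "include") sites[inside] else sites[!inside]
}
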