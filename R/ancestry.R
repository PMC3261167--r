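#' LD pruning by sliding-window genotype correlation
#'
#' Walks each chromosome in windows of `window` SNPs advanced by `step`;
#' within a window, for every pair of retained SNPs with squared genotype
#' correlation strictly greater than `r2_max`, the later-positioned SNP is
#' dropped.
#'
#' @param study a [genotype_study()] with SNPs ordered by chromosome and
#'   position.
#' @param window window size in SNPs (default 50).
#' @param step window slide in SNPs (default 5).
#' @param r2_max squared-correlation threshold (default 0.30; pairs at
#'   exactly the threshold are both kept).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(study, window = 50, step = 5, r2_max = 0.30) {
  g <- study$genotypes
  removed <- logical(ncol(g))
  for (chr in unique(study$snp_meta$chrom)) {
    idx <- which(study$snp_meta$chrom == chr)
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (st in starts) {
      win <- idx[st:min(st + window - 1, length(idx))]
      win <- win[!removed[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        stats::cor(g[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(win) - 1)) {
        if (removed[win[a]]) next
        hits <- which(r2[a, ] > r2_max)
        hits <- hits[hits > a & !removed[win[hits]]]
        removed[win[hits]] <- TRUE
      }
    }
  }
  study$snp_meta$id[!removed]
}

#' Principal components of the genotype matrix
#'
#' Columns are mean-imputed at missing entries and standardised before the
#' decomposition; components are ordered by explained variance. Intended to
#' run on an LD-pruned, call-rate/MAF-filtered SNP set.
#'
#' @param study a [genotype_study()].
#' @param n_components number of components to return.
#' @return Subjects x components score matrix (attribute `"sdev"` carries
#'   the component standard deviations).
#' @export
compute_pcs <- function(study, n_components = 10) {
  g <- study$genotypes
  if (ncol(g) < n_components)
    stop("fewer SNPs than requested components")
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  sdv <- apply(g, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {  # no variable SNPs: all scores zero
    scores <- matrix(0, nrow(g), n_components)
    rownames(scores) <- study$subject_meta$id
    attr(scores, "sdev") <- rep(0, n_components)
    return(scores)
  }
  g <- scale(g[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  n_components <- min(n_components, ncol(g), nrow(g))
  pc <- stats::prcomp(g, center = FALSE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x
  rownames(scores) <- study$subject_meta$id
  attr(scores, "sdev") <- pc$sdev
  scores
}

#' Ancestry clustering of principal-component scores
#'
#' Runs k-means for every k in `k_range` with `n_restarts` random restarts
#' and scores each k by `mean silhouette width x restart stability`, where
#' stability is the mean pairwise adjusted Rand index between restart
#' assignments. The clustering at the score-maximising k is returned. The
#' score combines between-cluster separation, assignment accuracy and
#' run-to-run stability; it is a variant of (not a reconstruction of) the
#' published ancestry-clustering index.
#'
#' @param pc_scores subjects x components matrix from [compute_pcs()].
#' @param k_range inclusive range of cluster counts (default `c(2, 30)`).
#' @param n_restarts k-means restarts per k (default 10).
#' @param seed integer seed; results are deterministic given it.
#' @return A list of class `ancestry_clustering` with `assignments` (named
#'   integer vector), `k`, `pc_scores`, and `score_index` (per-k table).
#' @export
cluster_ancestry <- function(pc_scores, k_range = c(2, 30),
                             n_restarts = 10, seed = 1L) {
  n <- nrow(pc_scores)
  hi <- min(k_range[2], n - 1)
  if (hi < k_range[1] || k_range[1] < 2)
    stop("k_range infeasible for subject count")
  ks <- seq(k_range[1], hi)
  set.seed(seed)
  d <- stats::dist(pc_scores)
  rows <- lapply(ks, function(k) {
    fits <- lapply(seq_len(n_restarts), function(r)
      stats::kmeans(pc_scores, centers = k, nstart = 3, iter.max = 50))
    tw <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    best <- fits[[which.min(tw)]]
    pairs <- utils::combn(n_restarts, 2)
    stab <- mean(apply(pairs, 2, function(pr)
      mclust::adjustedRandIndex(fits[[pr[1]]]$cluster,
                                fits[[pr[2]]]$cluster)))
    sil <- mean(cluster::silhouette(best$cluster, d)[, "sil_width"])
    list(k = k, silhouette = sil, stability = stab,
         score = sil * stab, cluster = best$cluster)
  })
  score_index <- do.call(rbind, lapply(rows, function(r)
    data.frame(k = r$k, silhouette = r$silhouette,
               stability = r$stability, score = r$score)))
  best <- rows[[which.max(score_index$score)]]
  assignments <- best$cluster
  names(assignments) <- rownames(pc_scores)
  structure(list(assignments = assignments, k = best$k,
                 pc_scores = pc_scores, score_index = score_index),
            class = "ancestry_clustering")
}

round_half_down <- function(x) ceiling(x - 0.5)

#' Ratio-preserving control selection within ancestry clusters
#'
#' For every ancestry cluster containing at least one case, controls are
#' selected so the within-cluster case/control ratio is as close as
#' possible to `target_ratio`: the target control count is
#' `round(cases / target_ratio)` (ties toward fewer controls), any
#' always-kept controls count first, and the remainder is sampled without
#' replacement from the cluster's control pool. Clusters with no cases
#' contribute no controls.
#'
#' @param clustering an [cluster_ancestry()] result, or a named cluster
#'   assignment vector covering all ids involved.
#' @param case_ids,control_pool_ids subject ids of cases and of poolable
#'   controls.
#' @param fixed_control_ids controls always retained (counted toward the
#'   ratio before sampling); default none.
#' @param target_ratio desired case/control ratio per cluster.
#' @param seed integer seed for the sampling.
#' @return A list with `selected` (fixed + sampled control ids) and
#'   `per_cluster` (cases, fixed, sampled, achieved ratio per cluster).
#' @export
match_controls <- function(clustering, case_ids, control_pool_ids,
                           fixed_control_ids = character(0),
                           target_ratio = 0.88, seed = 1L) {
  assign <- if (inherits(clustering, "ancestry_clustering"))
    clustering$assignments else clustering
  ids <- c(case_ids, control_pool_ids, fixed_control_ids)
  if (!all(ids %in% names(assign)))
    stop("all ids must be present in the clustering")
  set.seed(seed)
  out <- lapply(sort(unique(assign)), function(cl) {
    members <- names(assign)[assign == cl]
    n_case <- sum(case_ids %in% members)
    fixed <- intersect(fixed_control_ids, members)
    pool <- intersect(control_pool_ids, members)
    if (n_case == 0)
      return(list(selected = character(0),
                  row = data.frame(cluster = cl, cases = 0,
                                   fixed = length(fixed), sampled = 0,
                                   controls = 0, ratio = NA_real_)))
    target <- round_half_down(n_case / target_ratio)
    n_extra <- max(0, target - length(fixed))
    if (n_extra > length(pool)) {
      warning(sprintf(
        "cluster %s: control pool exhausted (%d wanted, %d available)",
        cl, n_extra, length(pool)))
      n_extra <- length(pool)
    }
    sampled <- if (n_extra > 0) sample(pool, n_extra) else character(0)
    n_ctl <- length(fixed) + length(sampled)
    list(selected = c(fixed, sampled),
         row = data.frame(cluster = cl, cases = n_case,
                          fixed = length(fixed), sampled = length(sampled),
                          controls = n_ctl, ratio = n_case / n_ctl))
  })
  list(selected = unlist(lapply(out, `[[`, "selected")),
       per_cluster = do.call(rbind, lapply(out, `[[`, "row")))
}

#' Check for residual stratification in association p-values
#'
#' Fits, per SNP, an additive logistic regression of phenotype on genotype
#' dosage with and without the top principal components as covariates and
#' correlates the two sets of -log10 p-values. A high correlation
#' indicates that ancestry adjustment does not change the associations,
#' i.e. no residual confounding. SNPs with separated or non-converged fits
#' are flagged and excluded from the correlation.
#'
#' @param study a [genotype_study()].
#' @param assoc_snps SNP ids (or column indices) to test.
#' @param pc_scores principal-component scores from [compute_pcs()].
#' @param n_pcs number of leading components to adjust for (default 4).
#' @return A list with `p_unadjusted`, `p_adjusted`, `correlation` (Pearson
#'   correlation of the -log10 p-values), `crossing` (SNPs crossing the
#'   0.05 significance line between fits) and `flagged`.
#' @export
residual_stratification_check <- function(study, assoc_snps, pc_scores,
                                          n_pcs = 4) {
  if (!length(assoc_snps)) stop("no SNPs supplied")
  idx <- if (is.character(assoc_snps))
    match(assoc_snps, study$snp_meta$id) else assoc_snps
  y <- as.integer(study$subject_meta$phenotype == "EL")
  pcs <- pc_scores[, seq_len(n_pcs), drop = FALSE]
  fit_one <- function(j) {
    gj <- study$genotypes[, j]
    ok <- !is.na(gj)
    p0 <- tryCatch({
      f <- stats::glm(y[ok] ~ gj[ok], family = stats::binomial())
      stats::coef(summary(f))["gj[ok]", 4]
    }, warning = function(w) NA_real_, error = function(e) NA_real_)
    p1 <- tryCatch({
      f <- stats::glm(y[ok] ~ gj[ok] + pcs[ok, , drop = FALSE],
                      family = stats::binomial())
      stats::coef(summary(f))["gj[ok]", 4]
    }, warning = function(w) NA_real_, error = function(e) NA_real_)
    c(p0, p1)
  }
  ps <- vapply(idx, fit_one, numeric(2))
  p0 <- ps[1, ]; p1 <- ps[2, ]
  flagged <- is.na(p0) | is.na(p1)
  ok <- !flagged
  corr <- stats::cor(-log10(p0[ok]), -log10(p1[ok]))
  crossing <- which(ok & ((p0 < 0.05) != (p1 < 0.05)))
  list(p_unadjusted = p0, p_adjusted = p1, correlation = corr,
       crossing = study$snp_meta$id[idx][crossing],
       flagged = study$snp_meta$id[idx][flagged])
}
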