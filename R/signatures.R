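#' Cluster genetic risk profiles into genetic signatures
#'
#' Groups the rows of a subjects-by-K risk-profile array into clusters of
#' similar profiles while preserving the column (model size) ordering.
#' Two clusters merge when the Bayesian marginal likelihood of a single
#' shared polynomial curve (order selected up to `max_poly_order` by the
#' same marginal likelihood, conjugate normal-inverse-gamma prior on
#' coefficients and noise) exceeds the product of their separate marginal
#' likelihoods; merging is greedy best-gain-first until no merge improves
#' the score. A hierarchical pass over the cluster mean profiles then
#' checks whether similar clusters can be merged further under the same
#' criterion. Clusters smaller than `min_report_size` are pooled into a
#' "sporadic" residual. Reported clusters are labelled C1, C2, ... in
#' decreasing order of their average end-of-profile posterior and carry a
#' colour stratum from [stratum_label()].
#'
#' @param profiles subjects x K matrix from [risk_profiles()] (rownames are
#'   subject ids).
#' @param max_poly_order maximum polynomial order of the cluster curves
#'   (default 4); requires `K >= max_poly_order + 1`.
#' @param min_report_size smallest reported cluster (default 8).
#' @param seed integer seed (tie-breaks in merge order).
#' @param merge_threshold minimum log marginal-likelihood gain required to
#'   merge (default 0: merge only when the Bayesian score improves).
#' @param noise_floor residual standard deviation (on the probability
#'   scale) below which profile differences are treated as equivalent
#'   (default 0.02); implemented as a strong inverse-gamma prior on the
#'   curve noise so that saturated profiles do not split on meaningless
#'   micro-structure.
#' @param offset_var variance (relative to the residual variance) of the
#'   per-profile random intercept and slope around the cluster curve
#'   (default 4); absorbs subject-level differences in overall variant
#'   load and in early- versus late-ranked loading within a signature.
#' @return A `signature_clusters` object: list with `clusters` (data.frame:
#'   id, size, avg_posterior, stratum), `assignments` (per-subject cluster
#'   label, `"sporadic"` for pooled residual), `mean_profiles` (one row per
#'   reported cluster), `members` (list of subject ids per cluster).
#' @export
cluster_profiles <- function(profiles, max_poly_order = 4,
                             min_report_size = 8, seed = 1L,
                             merge_threshold = 0, offset_var = 4,
                             noise_floor = 0.02) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles); K <- ncol(profiles)
  if (K < max_poly_order + 1) stop("K < max_poly_order + 1")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("s", seq_len(n))
  set.seed(seed)
  eng <- poly_engine(K, max_poly_order, tau2 = offset_var,
                     noise_floor = noise_floor)

  # sufficient statistics per live cluster
  stats <- poly_stats_matrix(eng, profiles)
  stats$score <- as.numeric(poly_logml(eng, 1, stats$bty, stats$syy,
                                       stats$sz))
  members <- as.list(seq_len(n))
  live <- rep(TRUE, n)

  delta <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1))
    delta[i, (i + 1):n] <- poly_merge_delta(eng, stats, i, (i + 1):n)

  repeat {
    best <- which.max(delta)
    if (delta[best] <= merge_threshold) break
    i <- (best - 1) %% n + 1; j <- (best - 1) %/% n + 1
    stats$m[i] <- stats$m[i] + stats$m[j]
    stats$bty[, i] <- stats$bty[, i] + stats$bty[, j]
    stats$syy[i] <- stats$syy[i] + stats$syy[j]
    stats$sz[, i] <- stats$sz[, i] + stats$sz[, j]
    stats$score[i] <- poly_logml(eng, stats$m[i], stats$bty[, i],
                                 stats$syy[i], stats$sz[, i])
    members[[i]] <- c(members[[i]], members[[j]])
    live[j] <- FALSE
    delta[j, ] <- -Inf; delta[, j] <- -Inf
    others <- which(live)[which(live) != i]
    if (length(others)) {
      d <- poly_merge_delta(eng, stats, i, others)
      delta[i, ] <- -Inf; delta[, i] <- -Inf
      lo <- pmin(i, others); hi <- pmax(i, others)
      delta[cbind(lo, hi)] <- d
    } else break
  }

  # hierarchical post-pass: walk cluster pairs in order of mean-profile
  # proximity and re-check the merge criterion until no merge improves
  repeat {
    ids <- which(live)
    if (length(ids) < 2) break
    mean_prof <- t(vapply(ids, function(i)
      colMeans(profiles[members[[i]], , drop = FALSE]), numeric(K)))
    d <- as.matrix(stats::dist(mean_prof))
    diag(d) <- Inf
    ord <- order(d[upper.tri(d)])
    ut <- which(upper.tri(d), arr.ind = TRUE)
    merged_any <- FALSE
    for (pi in ord) {
      a <- ids[ut[pi, 1]]; b <- ids[ut[pi, 2]]
      if (poly_merge_delta(eng, stats, a, b) > merge_threshold) {
        stats$m[a] <- stats$m[a] + stats$m[b]
        stats$bty[, a] <- stats$bty[, a] + stats$bty[, b]
        stats$syy[a] <- stats$syy[a] + stats$syy[b]
        stats$sz[, a] <- stats$sz[, a] + stats$sz[, b]
        stats$score[a] <- poly_logml(eng, stats$m[a], stats$bty[, a],
                                     stats$syy[a], stats$sz[, a])
        members[[a]] <- c(members[[a]], members[[b]])
        live[b] <- FALSE
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }

  ids <- which(live)
  sizes <- stats$m[ids]
  final_post <- profiles[, K]
  avg_post <- vapply(ids, function(i)
    mean(final_post[members[[i]]]), numeric(1))
  reported <- sizes >= min_report_size
  ord <- order(avg_post[reported], decreasing = TRUE)
  rep_ids <- ids[reported][ord]

  assignments <- rep("sporadic", n)
  clusters <- NULL
  mean_profiles <- NULL
  mem_out <- list()
  for (ci in seq_along(rep_ids)) {
    lab <- paste0("C", ci)
    mem <- members[[rep_ids[ci]]]
    assignments[mem] <- lab
    clusters <- rbind(clusters, data.frame(
      id = lab, size = length(mem),
      avg_posterior = mean(final_post[mem]),
      stratum = stratum_label(mean(final_post[mem])),
      stringsAsFactors = FALSE))
    mean_profiles <- rbind(mean_profiles,
                           colMeans(profiles[mem, , drop = FALSE]))
    mem_out[[lab]] <- rownames(profiles)[mem]
  }
  if (!is.null(mean_profiles)) rownames(mean_profiles) <- clusters$id
  names(assignments) <- rownames(profiles)
  structure(list(clusters = clusters, assignments = assignments,
                 mean_profiles = mean_profiles, members = mem_out,
                 n_sporadic = sum(assignments == "sporadic")),
            class = "signature_clusters")
}

#' @export
print.signature_clusters <- function(x, ...) {
  cat(sprintf("signature_clusters: %d reported cluster(s), %d sporadic subject(s)\n",
              if (is.null(x$clusters)) 0 else nrow(x$clusters),
              x$n_sporadic))
  if (!is.null(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Colour stratum of a genetic signature
#'
#' Strata follow the predictive strength of the end-of-profile posterior:
#' Blue `> 0.95`, Red `[0.5, 0.95]`, Orange `(0.2, 0.5)`, Green `<= 0.2`.
#' The published inequalities are open on both sides and leave boundaries
#' undefined; here 0.95 and 0.5 fall to Red and 0.2 to Green.
#'
#' @param avg_posterior average posterior probability of exceptional
#'   longevity in `[0, 1]` (vectorised).
#' @return Character vector of stratum labels.
#' @export
stratum_label <- function(avg_posterior) {
  if (any(avg_posterior < 0 | avg_posterior > 1))
    stop("posterior probabilities must lie in [0, 1]")
  ifelse(avg_posterior > 0.95, "Blue",
         ifelse(avg_posterior >= 0.5, "Red",
                ifelse(avg_posterior > 0.2, "Orange", "Green")))
}

#' Log-rank comparison of survival between signature clusters
#'
#' Two-group log-rank test on age at death / last contact with censoring,
#' for each requested pair of clusters. No multiplicity adjustment is
#' applied by default; set `bonferroni = TRUE` to adjust over the pairs.
#'
#' @param clusters a [cluster_profiles()] result.
#' @param survival_records data.frame with `id`, `age_years`, `event_flag`
#'   (1 = death observed, 0 = censored).
#' @param pairs two-column matrix or list of cluster-id pairs to compare.
#' @param bonferroni adjust p-values over the pairs (default FALSE).
#' @return data.frame with `cluster1`, `cluster2`, `chisq`, `p_value`.
#' @export
compare_survival <- function(clusters, survival_records, pairs,
                             bonferroni = FALSE) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- rbind(pairs)
  out <- apply(pairs, 1, function(pr) {
    mem1 <- clusters$members[[pr[1]]]; mem2 <- clusters$members[[pr[2]]]
    if (length(mem1) < 2 || length(mem2) < 2)
      stop("each compared cluster needs at least 2 members")
    rec <- survival_records[survival_records$id %in% c(mem1, mem2), ]
    grp <- ifelse(rec$id %in% mem1, pr[1], pr[2])
    if (all(rec$event_flag == 0)) stop("all survival times censored")
    sd <- survival::survdiff(
      survival::Surv(rec$age_years, rec$event_flag) ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    data.frame(cluster1 = pr[1], cluster2 = pr[2], chisq = sd$chisq,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (bonferroni)
    out$p_value <- pmin(1, out$p_value * nrow(out))
  out
}

#' Association between genetic signatures and ancestry clusters
#'
#' Chi-square test of independence on the contingency table of signature
#' cluster by ancestry cluster over subjects carrying both labels.
#'
#' @param clusters a [cluster_profiles()] result (sporadic subjects are
#'   excluded).
#' @param ancestry named cluster-assignment vector (e.g. from
#'   [cluster_ancestry()]).
#' @return list with `table`, `chisq`, `p_value`.
#' @export
signature_ethnicity_association <- function(clusters, ancestry) {
  sig <- clusters$assignments[clusters$assignments != "sporadic"]
  common <- intersect(names(sig), names(ancestry))
  tab <- table(signature = sig[common], ancestry = ancestry[common])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate partition: need at least 2 levels on both sides")
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(table = tab, chisq = unname(ct$statistic),
       p_value = unname(ct$p.value))
}

#' Stratified summary of genetic signatures across cohorts
#'
#' Tabulates the fraction of subjects per colour stratum (by their
#' end-of-profile posterior probability of exceptional longevity), for the
#' clustered case profiles and, optionally, a control profile set.
#'
#' @param clusters a [cluster_profiles()] result for the case cohort.
#' @param case_profiles the profile matrix that was clustered.
#' @param control_profiles optional control profile matrix.
#' @return data.frame of stratum fractions per cohort.
#' @export
signature_summary <- function(clusters, case_profiles,
                              control_profiles = NULL) {
  strata <- c("Blue", "Red", "Orange", "Green")
  frac <- function(prof) {
    lab <- stratum_label(prof[, ncol(prof)])
    as.numeric(table(factor(lab, levels = strata)) / nrow(prof))
  }
  out <- data.frame(cohort = "cases", stratum = strata,
                    fraction = frac(case_profiles),
                    stringsAsFactors = FALSE)
  if (!is.null(control_profiles) && nrow(control_profiles) > 0)
    out <- rbind(out, data.frame(cohort = "controls", stratum = strata,
                                 fraction = frac(control_profiles),
                                 stringsAsFactors = FALSE))
  out
}
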