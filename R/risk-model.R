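#' @name risk-model
#' @title Nested naive-Bayes genetic risk models
#'
#' @description
#' The genetic risk of a subject is scored by a family of nested naive-Bayes
#' classifiers. SNPs are ranked by decreasing maximum Bayes factor and the
#' k-th model uses the top k SNPs (Sigma_k, k = 1..K). Given a subject's
#' genotypes g_1..g_k the posterior probability of exceptional longevity is
#' \deqn{p(EL | \Sigma_k) = \frac{p(EL) \prod_i \hat p(g_i | EL)}
#'   {p(EL) \prod_i \hat p(g_i|EL) + p(AL) \prod_i \hat p(g_i|AL)}}
#' with conditional genotype probabilities estimated by posterior means
#' under a Dirichlet(2, ..., 2) prior and prior p(EL) = 0.5 (which makes
#' the MAP classification independent of the prior). Products are computed
#' in log space; missing genotypes contribute no factor. The vector
#' (p(EL|Sigma_1), ..., p(EL|Sigma_K)) is the subject's genetic risk
#' profile and its arithmetic mean is the ensemble score.
NULL

# category index of a genotype code under a prediction recoding;
# allelic SNPs are predicted from the full 3-category genotype table
# (a subject contributes one genotype, not two independent alleles)
genotype_category <- function(g, model) {
  switch(model,
         genotypic = ,
         allelic = 3L - g,              # 2,1,0 -> 1(MM),2(Mm),3(mm)
         dominant = ifelse(g >= 1L, 1L, 2L),
         recessive = ifelse(g == 2L, 1L, 2L))
}

n_categories <- function(model)
  if (model %in% c("genotypic", "allelic")) 3L else 2L

#' Rank SNPs for risk modelling
#'
#' Orders the association-scan results by decreasing log10 MBF and keeps
#' the top `top_k` candidates (the default pool of 500 corresponds to a
#' posterior probability of association of roughly 0.95 and is pruned to
#' ~400 by [prune_correlated()] before model fitting).
#'
#' @param assoc data.frame from [assoc_scan()].
#' @param top_k pool size (default 500).
#' @return data.frame with columns `id`, `model` (best single-SNP model),
#'   `log10_mbf`, in rank order.
#' @export
rank_snps <- function(assoc, top_k = 500) {
  ord <- order(assoc$log10_mbf, decreasing = TRUE)
  head(data.frame(id = assoc$id[ord], model = assoc$best_model[ord],
                  log10_mbf = assoc$log10_mbf[ord],
                  stringsAsFactors = FALSE), top_k)
}

#' Prune ranked SNPs that are conditionally independent of the phenotype
#'
#' Rank-ordered conditional-independence screen standing in for a full
#' Bayesian-network search over SNP dependencies. For each candidate in
#' rank order, mutual dependence on every retained higher-ranked SNP is
#' scored by the Dirichlet-multinomial Bayes factor on their genotype
#' cross-table; when the dependence BF exceeds `bf_threshold_pair`
#' (two-way; `bf_threshold_multi` when testing joint dependence on the two
#' most significant retained SNPs), the candidate's phenotype-association
#' BF is recomputed within the genotype strata of the dependent SNP(s)
#' (strata smaller than `min_stratum` are skipped; stratum log10 BFs add),
#' and the candidate is dropped if the independence hypothesis wins
#' (conditional BF below 1). A SNP in perfect LD with a retained SNP
#' carries no conditional signal and is always removed; SNPs independent
#' of all retained SNPs are never tested and survive.
#'
#' @param ranked data.frame from [rank_snps()].
#' @param study the training [genotype_study()].
#' @param bf_threshold_pair BF-scale threshold for declaring two-way
#'   SNP-SNP dependence (default 100).
#' @param bf_threshold_multi BF-scale threshold for joint (multi-SNP)
#'   dependence (default 10).
#' @param min_stratum smallest stratum used for conditioning (default 20).
#' @param check_joint also test joint dependence on the two most
#'   significant retained SNPs (default FALSE: on sparse joint tables the
#'   uniform-prior dependence BF over-detects dependence, so the joint
#'   screen is opt-in).
#' @param alpha Dirichlet hyper-parameter (default 2).
#' @return The surviving subset of `ranked`, order preserved.
#' @export
prune_correlated <- function(ranked, study, bf_threshold_pair = 100,
                             bf_threshold_multi = 10, min_stratum = 20,
                             check_joint = FALSE, alpha = 2) {
  el <- study$subject_meta$phenotype == "EL"
  gmat <- study$genotypes[, match(ranked$id, study$snp_meta$id),
                          drop = FALSE]
  dep_bf <- function(a, b) {
    # posterior odds of dependence between two genotype variables via the
    # BIC approximation: log10 odds = (chi2 - df log N) / (2 log 10).
    # (The uniform-prior Dirichlet-multinomial BF is kept for phenotype
    # association but over-detects dependence on skewed genotype margins,
    # so the SNP-SNP screen uses the calibrated approximation.)
    tab <- table(factor(a, levels = 0:2), as.factor(b))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) return(-Inf)
    n <- sum(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / n
    chi2 <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    (chi2 - df * log(n)) / (2 * log(10))
  }
  cond_assoc_bf <- function(cand, strata) {
    # stratum contributions use only candidate categories observed in the
    # stratum; a stratum where the candidate is constant is uninformative
    tot <- 0; informative <- 0L; sized <- 0L
    for (sv in unique(strata[!is.na(strata)])) {
      rows <- which(strata == sv)
      if (length(rows) < min_stratum) next
      sized <- sized + 1L
      cs <- cand[rows]
      tab <- rbind(table(factor(cs[el[rows]], levels = 0:2)),
                   table(factor(cs[!el[rows]], levels = 0:2)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2) next
      tot <- tot + log10_bayes_factor(tab, alpha)
      informative <- informative + 1L
    }
    list(bf = tot, informative = informative, sized = sized)
  }
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    cand <- gmat[, i]
    kept <- which(keep)
    ok <- TRUE
    for (r in kept) {
      if (dep_bf(cand, gmat[, r]) > log10(bf_threshold_pair)) {
        cb <- cond_assoc_bf(cand, gmat[, r])
        # collinear candidate (sizeable strata but never any variation)
        # carries no conditional signal; all-small strata skip the check
        if ((cb$sized > 0L && cb$informative == 0L) ||
            (cb$informative > 0L && cb$bf < 0)) { ok <- FALSE; break }
      }
    }
    if (ok && check_joint && length(kept) >= 2) {
      joint <- interaction(gmat[, kept[1]], gmat[, kept[2]], drop = TRUE)
      if (dep_bf(cand, joint) > log10(bf_threshold_multi)) {
        cb <- cond_assoc_bf(cand, joint)
        if ((cb$sized > 0L && cb$informative == 0L) ||
            (cb$informative > 0L && cb$bf < 0)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  ranked[keep, , drop = FALSE]
}

#' Fit the nested naive-Bayes model set
#'
#' Estimates, for every ranked SNP, the conditional genotype-category
#' probabilities in cases and controls by posterior means under a
#' Dirichlet prior ([estimate_conditional_probs()]), using each SNP's best
#' single-SNP model recoding for prediction.
#'
#' @param study training [genotype_study()] containing both phenotypes.
#' @param ranked data.frame with columns `id` and `model`, in rank order
#'   (from [rank_snps()] / [prune_correlated()]).
#' @param alpha Dirichlet hyper-parameter (default 2).
#' @param prior prior probability p(EL) (default 0.5).
#' @return A `nested_model_set`: list with `snps` (the ranking), `p_el` and
#'   `p_al` (K x 3 matrices of conditional category probabilities, unused
#'   categories NA), `prior`, `K`.
#' @export
fit_nested <- function(study, ranked, alpha = 2, prior = 0.5) {
  stopifnot(prior > 0, prior < 1,
            all(c("EL", "AL") %in% study$subject_meta$phenotype))
  idx <- match(ranked$id, study$snp_meta$id)
  if (anyNA(idx)) stop("ranked SNPs absent from the training study")
  el <- study$subject_meta$phenotype == "EL"
  K <- nrow(ranked)
  p_el <- matrix(NA_real_, K, 3)
  p_al <- matrix(NA_real_, K, 3)
  for (k in seq_len(K)) {
    m <- ranked$model[k]
    nc <- n_categories(m)
    cat_k <- genotype_category(study$genotypes[, idx[k]], m)
    tab <- rbind(table(factor(cat_k[el], levels = seq_len(nc))),
                 table(factor(cat_k[!el], levels = seq_len(nc))))
    pr <- estimate_conditional_probs(tab, alpha)
    p_el[k, seq_len(nc)] <- pr[1, ]
    p_al[k, seq_len(nc)] <- pr[2, ]
  }
  structure(list(snps = ranked, p_el = p_el, p_al = p_al,
                 prior = prior, K = K),
            class = "nested_model_set")
}

#' @export
print.nested_model_set <- function(x, ...) {
  cat(sprintf("nested_model_set: K = %d SNPs, prior p(EL) = %g\n",
              x$K, x$prior))
  invisible(x)
}

# per-subject log-likelihood-ratio contributions, subjects x K;
# missing genotypes contribute 0 (no factor)
llr_matrix <- function(study, model_set) {
  idx <- match(model_set$snps$id, study$snp_meta$id)
  if (anyNA(idx)) stop("model SNPs absent from the study")
  g <- study$genotypes[, idx, drop = FALSE]
  K <- model_set$K
  llr <- matrix(0, nrow(g), K)
  for (k in seq_len(K)) {
    cat_k <- genotype_category(g[, k], model_set$snps$model[k])
    v <- log(model_set$p_el[k, ]) - log(model_set$p_al[k, ])
    lk <- v[cat_k]
    lk[is.na(lk)] <- 0
    llr[, k] <- lk
  }
  llr
}

#' Posterior probability of exceptional longevity under nested SNP sets
#'
#' Computes the genetic risk profile of every subject: the posterior
#' p(EL | Sigma_k) for k = 1..K, evaluated in log space (the posterior under
#' Sigma_k uses the cumulative log-likelihood ratio of the top k SNPs).
#'
#' @param study a [genotype_study()] of subjects to score.
#' @param model_set a fitted [fit_nested()] model set.
#' @return Subjects x K matrix of posterior probabilities in `[0, 1]`.
#' @export
risk_profiles <- function(study, model_set) {
  llr <- llr_matrix(study, model_set)
  cum <- t(apply(llr, 1, cumsum))
  if (model_set$K == 1) cum <- matrix(llr, ncol = 1)
  post <- stats::plogis(stats::qlogis(model_set$prior) + cum)
  rownames(post) <- study$subject_meta$id
  colnames(post) <- paste0("k", seq_len(model_set$K))
  post
}

#' Single-subject posterior for one nested SNP set
#'
#' @param genotypes named genotype vector (names = SNP ids, codes 0/1/2/NA).
#' @param model_set a [fit_nested()] model set.
#' @param k size of the nested set Sigma_k (default K, the full model).
#' @return The posterior probability p(EL | Sigma_k).
#' @export
posterior_el <- function(genotypes, model_set, k = model_set$K) {
  stopifnot(k >= 1, k <= model_set$K)
  llr <- 0
  for (i in seq_len(k)) {
    g <- genotypes[[model_set$snps$id[i]]]
    if (is.null(g) || is.na(g)) next
    cat_i <- genotype_category(as.integer(g), model_set$snps$model[i])
    llr <- llr + log(model_set$p_el[i, cat_i]) -
      log(model_set$p_al[i, cat_i])
  }
  stats::plogis(stats::qlogis(model_set$prior) + llr)
}

#' Ensemble score and classification from risk profiles
#'
#' The ensemble posterior of a subject is the arithmetic mean of the
#' profile entries; the subject is classified EL when the score is at
#' least 0.5 (a tie classifies EL, matching the `>=` in the sensitivity
#' definition).
#'
#' @param profiles subjects x K matrix from [risk_profiles()].
#' @return data.frame with `id`, `ensemble`, `classification`.
#' @export
ensemble_posterior <- function(profiles) {
  score <- rowMeans(profiles)
  data.frame(id = rownames(profiles), ensemble = score,
             classification = ifelse(score >= 0.5, "EL", "AL"),
             stringsAsFactors = FALSE)
}

#' Sensitivity, specificity, AUC of a score
#'
#' Sensitivity is the proportion of EL subjects with score at least 0.5;
#' specificity the proportion of AL subjects with score below 0.5. The AUC
#' is the probability that a random case outscores a random control (ties
#' counted half), equal to the trapezoidal area under the ROC curve over
#' all score thresholds. With only one class present the undefined rates
#' are `NA`.
#'
#' @param scores numeric vector of predictive scores in `[0, 1]`.
#' @param labels vector of `"EL"` / `"AL"` true labels.
#' @param age optional ages for stratified sensitivity.
#' @param age_breaks optional breaks defining the age strata.
#' @return An `eval_report` list: `sensitivity`, `specificity`, `accuracy`,
#'   `auc`, `confusion` (TP, FN, TN, FP), optionally `by_age`.
#' @export
evaluate_scores <- function(scores, labels, age = NULL, age_breaks = NULL) {
  el <- labels == "EL"
  tp <- sum(scores >= 0.5 & el); fn <- sum(scores < 0.5 & el)
  tn <- sum(scores < 0.5 & !el); fp <- sum(scores >= 0.5 & !el)
  sens <- if (any(el)) tp / (tp + fn) else NA_real_
  spec <- if (any(!el)) tn / (tn + fp) else NA_real_
  auc <- if (any(el) && any(!el)) {
    r <- rank(scores)
    (sum(r[el]) - sum(el) * (sum(el) + 1) / 2) / (sum(el) * sum(!el))
  } else NA_real_
  rep <- list(sensitivity = sens, specificity = spec,
              accuracy = (tp + tn) / length(scores), auc = auc,
              confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
  if (!is.null(age) && !is.null(age_breaks)) {
    strata <- cut(age[el], age_breaks, include.lowest = TRUE)
    rep$by_age <- tapply(scores[el] >= 0.5, strata, mean)
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Per-k sensitivity and specificity traces
#'
#' @param profiles subjects x K matrix from [risk_profiles()].
#' @param labels `"EL"` / `"AL"` labels.
#' @return data.frame with `k`, `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_traces <- function(profiles, labels) {
  el <- labels == "EL"
  sens <- colMeans(profiles[el, , drop = FALSE] >= 0.5)
  spec <- colMeans(profiles[!el, , drop = FALSE] < 0.5)
  data.frame(k = seq_len(ncol(profiles)), sensitivity = sens,
             specificity = spec,
             accuracy = (sens * sum(el) + spec * sum(!el)) / length(el))
}

#' Select the working model size K*
#'
#' Among model sizes where accuracy exceeds `acc_min`, the
#' sensitivity-specificity gap is below `tol`, and the sensitivity trace is
#' flat over the next `plateau_window` sizes (range below `tol`), returns
#' the k minimising the gap (ties to the smallest k). If no size
#' qualifies, returns the overall gap minimiser with a warning.
#'
#' @param traces data.frame from [sens_spec_traces()].
#' @param plateau_window forward window (in SNPs) over which the
#'   sensitivity must be flat (default 5).
#' @param tol gap/flatness tolerance (default 0.02).
#' @param acc_min minimum accuracy (default 0.85).
#' @return The selected k (integer), with attribute `"qualified"`.
#' @export
select_k <- function(traces, plateau_window = 5, tol = 0.02,
                     acc_min = 0.85) {
  K <- nrow(traces)
  gap <- abs(traces$sensitivity - traces$specificity)
  plateau <- vapply(seq_len(K), function(k) {
    win <- traces$sensitivity[k:min(k + plateau_window, K)]
    diff(range(win)) < tol
  }, logical(1))
  ok <- traces$accuracy > acc_min & gap < tol & plateau
  if (any(ok)) {
    cand <- which(ok)
    kstar <- cand[which.min(gap[cand])]
    structure(as.integer(kstar), qualified = TRUE)
  } else {
    warning("no model size meets the accuracy/gap criteria; ",
            "returning the gap minimiser")
    structure(as.integer(which.min(gap)), qualified = FALSE)
  }
}

#' Resampling validation of the nested models
#'
#' Repeatedly splits the study into non-overlapping training and test
#' fractions (stratified by phenotype), re-estimates the conditional
#' probability tables on the training split (SNP order and model tags are
#' kept fixed), evaluates per-k sensitivity and specificity on the test
#' split, and averages the traces over replicates. The per-replicate
#' qualifying model size ([select_k()]) is summarised by its mean.
#'
#' @param study the full [genotype_study()].
#' @param ranked data.frame of ranked (pruned) SNPs with `id`, `model`.
#' @param n_reps number of random splits (default 1000).
#' @param train_frac training fraction (default 2/3).
#' @param seed integer seed.
#' @param ... passed to [select_k()].
#' @return A list with `mean_traces` (data.frame), `k_values`
#'   (per-replicate K*), `mean_k`.
#' @export
resample_validate <- function(study, ranked, n_reps = 1000,
                              train_frac = 2 / 3, seed = 1L, ...) {
  set.seed(seed)
  el_idx <- which(study$subject_meta$phenotype == "EL")
  al_idx <- which(study$subject_meta$phenotype == "AL")
  K <- nrow(ranked)
  acc_sens <- acc_spec <- numeric(K)
  k_values <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    tr <- c(sample(el_idx, round(train_frac * length(el_idx))),
            sample(al_idx, round(train_frac * length(al_idx))))
    te <- setdiff(seq_len(nrow(study$genotypes)), tr)
    ms <- fit_nested(subset_study(study, subjects = tr), ranked)
    prof <- risk_profiles(subset_study(study, subjects = te), ms)
    tr_traces <- sens_spec_traces(
      prof, study$subject_meta$phenotype[te])
    acc_sens <- acc_sens + tr_traces$sensitivity
    acc_spec <- acc_spec + tr_traces$specificity
    k_values[r] <- suppressWarnings(select_k(tr_traces, ...))
  }
  n_el <- length(el_idx); n_al <- length(al_idx)
  mean_traces <- data.frame(
    k = seq_len(K), sensitivity = acc_sens / n_reps,
    specificity = acc_spec / n_reps)
  mean_traces$accuracy <- (mean_traces$sensitivity * n_el +
                             mean_traces$specificity * n_al) / (n_el + n_al)
  list(mean_traces = mean_traces, k_values = k_values,
       mean_k = mean(k_values))
}

#' Negative-control model orderings
#'
#' Compares the MBF-ordered baseline ensemble with a control built either
#' by randomly permuting the order of its SNPs (`shuffle_top`) or by
#' selecting the same number of SNPs at random from the top `m` of the
#' ranked pool (`random_from_top_m`).
#'
#' @param study evaluation [genotype_study()].
#' @param model_set fitted baseline [fit_nested()] set.
#' @param mode `"shuffle_top"` or `"random_from_top_m"`.
#' @param ranked_pool full ranked pool (required for
#'   `"random_from_top_m"`).
#' @param m pool depth for random selection (default 1700).
#' @param train_study study used to refit control tables (defaults to
#'   `study`).
#' @param seed integer seed.
#' @return list with `baseline` and `control` [evaluate_scores()] reports.
#' @export
order_controls <- function(study, model_set,
                           mode = c("shuffle_top", "random_from_top_m"),
                           ranked_pool = NULL, m = 1700,
                           train_study = study, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  labels <- study$subject_meta$phenotype
  base_scores <- ensemble_posterior(risk_profiles(study, model_set))$ensemble
  control_set <- if (mode == "shuffle_top") {
    perm <- sample(model_set$K)
    fit_nested(train_study, model_set$snps[perm, , drop = FALSE],
               prior = model_set$prior)
  } else {
    if (is.null(ranked_pool)) stop("ranked_pool required for random mode")
    m <- min(m, nrow(ranked_pool))
    pick <- sort(sample(m, model_set$K))
    fit_nested(train_study, ranked_pool[pick, , drop = FALSE],
               prior = model_set$prior)
  }
  ctrl_scores <- ensemble_posterior(
    risk_profiles(study, control_set))$ensemble
  list(baseline = evaluate_scores(base_scores, labels),
       control = evaluate_scores(ctrl_scores, labels),
       mode = mode)
}
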