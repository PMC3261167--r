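#' Pearson chi-square test and odds ratios for a phenotype-by-genotype table
#'
#' Classical counterpart of the Bayes-factor test: the Pearson chi-square
#' statistic of independence with `K - 1` degrees of freedom (no continuity
#' correction), and odds ratios for exceptional longevity. For two-column
#' recodings the single OR is `(n_11 * n_02) / (n_12 * n_01)`; for the
#' genotypic model two ORs are reported for the Mm and mm columns relative to
#' the MM (M-homozygote) reference column. An OR with a zero cell in its
#' cross-product is reported as `NA`.
#'
#' @param tab 2 x K count matrix (rows cases, controls).
#' @return A list with `chi2`, `df`, `p_value`, `odds_ratio` (length K - 1).
#' @examples
#' chi2_and_or(rbind(c(120, 681), c(238, 676)))  # OR ~ 0.50, p ~ 1e-8
#' @export
chi2_and_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) >= 2)
  if (any(tab < 0)) stop("negative counts")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1
  ors <- if (ncol(tab) == 2) {
    # odds of EL in category-1 carriers relative to category 2
    num <- tab[1, 1] * tab[2, 2]; den <- tab[1, 2] * tab[2, 1]
    if (num == 0 || den == 0) NA_real_ else num / den
  } else {
    # genotypic: odds of EL per genotype relative to the MM reference column
    vapply(2:ncol(tab), function(k) {
      num <- tab[1, k] * tab[2, 1]
      den <- tab[2, k] * tab[1, 1]
      if (num == 0 || den == 0) NA_real_ else num / den
    }, numeric(1))
  }
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       odds_ratio = ors)
}

# Vectorised Pearson chi-square across SNPs (2 x K tables per row of the
# S x K case/control count matrices). Monomorphic tables give statistic 0.
chi2_vec <- function(cases, controls) {
  n1 <- rowSums(cases); n0 <- rowSums(controls); n <- n1 + n0
  chi2 <- numeric(nrow(cases))
  for (k in seq_len(ncol(cases))) {
    ck <- cases[, k] + controls[, k]
    e1 <- n1 * ck / n
    e0 <- n0 * ck / n
    ok <- ck > 0
    chi2[ok] <- chi2[ok] + (cases[ok, k] - e1[ok])^2 / e1[ok] +
      (controls[ok, k] - e0[ok])^2 / e0[ok]
  }
  chi2
}

#' Single-SNP association scan over four genetic models
#'
#' Computes, for every SNP in the study, the Dirichlet-multinomial log10
#' Bayes factor under the genotypic, allelic, dominant and recessive models,
#' the maximum (MBF) and winning model, the Pearson chi-square p-value per
#' model, the odds ratio of the winning two-column recoding, and the
#' posterior-mean genotype probabilities in cases and controls.
#'
#' @param study a [genotype_study()].
#' @param alpha Dirichlet hyper-parameter per cell (default 2).
#' @param or compute the per-SNP odds ratio of the winning model (default
#'   TRUE; the only non-vectorised column, worth skipping on very large
#'   null scans).
#' @return A data.frame with one row per SNP, ordered as in the study,
#'   containing columns `id`, `bf_genotypic`, `bf_allelic`, `bf_dominant`,
#'   `bf_recessive`, `log10_mbf`, `best_model`, `chi2_*`, `p_*` per model,
#'   `or_best`, and `pEL_MM/Mm/mm`, `pAL_MM/Mm/mm`.
#' @export
assoc_scan <- function(study, alpha = 2, or = TRUE) {
  cc <- genotype_counts(study)
  mb <- mbf_vec(cc$cases, cc$controls, alpha)
  res <- data.frame(id = study$snp_meta$id, stringsAsFactors = FALSE)
  for (m in .GENETIC_MODELS) {
    ca <- recode_counts(cc$cases, m); co <- recode_counts(cc$controls, m)
    res[[paste0("bf_", m)]] <- mb$log10_bf[, m]
    chi2 <- chi2_vec(ca, co)
    res[[paste0("chi2_", m)]] <- chi2
    res[[paste0("p_", m)]] <- stats::pchisq(chi2, ncol(ca) - 1,
                                            lower.tail = FALSE)
  }
  res$log10_mbf <- mb$log10_mbf
  res$best_model <- mb$best_model
  res$or_best <- if (!or) NA_real_ else vapply(seq_len(nrow(res)), function(i) {
    m <- if (res$best_model[i] == "genotypic") "dominant" else res$best_model[i]
    tab <- rbind(recode_counts(cc$cases[i, , drop = FALSE], m),
                 recode_counts(cc$controls[i, , drop = FALSE], m))
    chi2_and_or(tab)$odds_ratio[1]
  }, numeric(1))
  pEL <- estimate_conditional_probs(cc$cases, alpha)
  pAL <- estimate_conditional_probs(cc$controls, alpha)
  colnames(pEL) <- paste0("pEL_", c("MM", "Mm", "mm"))
  colnames(pAL) <- paste0("pAL_", c("MM", "Mm", "mm"))
  cbind(res, pEL, pAL)
}

#' Genomic control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, df)`; for 1 df the null median is
#' 0.4549. Values near 1 indicate no stratification inflation.
#'
#' @param chi2 vector of association chi-square statistics.
#' @param df degrees of freedom of the statistics (default 1).
#' @return The inflation factor, a single number.
#' @export
genomic_control_lambda <- function(chi2, df = 1) {
  stopifnot(length(chi2) >= 1)
  stats::median(chi2) / stats::qchisq(0.5, df)
}

#' Type-I-error calibration of the MBF decision rule
#'
#' Simulates null case-control datasets (no association: one genotype
#' distribution shared by cases and controls) and estimates the false-positive
#' rate of the rule that calls a SNP significant when the maximum Bayes factor
#' over the four genetic models exceeds a threshold. Replicates are
#' allocated evenly across the `maf_grid` frequencies (a stratified
#' design), genotypes are multinomial under Hardy-Weinberg equilibrium,
#' and the four closed-form Bayes factors are computed with
#' hyper-parameter `alpha`. The uncertainty interval is from the conjugate
#' Beta(1, 1) posterior of the error probability.
#'
#' @param n_cases,n_controls group sizes per replicate (defaults 800 / 950).
#' @param maf_grid allele-frequency grid sampled uniformly per replicate
#'   (default 0.05, 0.10, ..., 0.50).
#' @param thresholds MBF thresholds on the Bayes-factor (not log) scale.
#' @param reps number of null replicates (default 100000).
#' @param alpha Dirichlet hyper-parameter per cell (default 2).
#' @param cred_level credible level of the reported interval.
#' @return A data.frame with one row per threshold: `threshold`, `errors`,
#'   `reps`, `rate_per_100k` and the credible interval bounds (same scale).
#' @export
simulate_mbf_error_rate <- function(n_cases = 800, n_controls = 950,
                                    maf_grid = seq(0.05, 0.5, by = 0.05),
                                    thresholds = c(100, 1400),
                                    reps = 100000, alpha = 2,
                                    cred_level = 0.95) {
  if (reps < 1) stop("reps must be >= 1")
  p <- rep_len(rep(maf_grid, each = ceiling(reps / length(maf_grid))),
               reps)
  hwe <- cbind(p^2, 2 * p * (1 - p), (1 - p)^2)
  draw_counts <- function(n) {
    n_mm <- stats::rbinom(reps, n, hwe[, 1])
    n_mh <- stats::rbinom(reps, n - n_mm, hwe[, 2] / (1 - hwe[, 1]))
    cbind(n_mm, n_mh, n - n_mm - n_mh)
  }
  mbf <- mbf_vec(draw_counts(n_cases), draw_counts(n_controls),
                 alpha)$log10_mbf
  lo <- (1 - cred_level) / 2
  out <- lapply(thresholds, function(thr) {
    x <- sum(mbf > log10(thr))
    data.frame(threshold = thr, errors = x, reps = reps,
               rate_per_100k = 1e5 * x / reps,
               lower = 1e5 * stats::qbeta(lo, x + 1, reps - x + 1),
               upper = 1e5 * stats::qbeta(1 - lo, x + 1, reps - x + 1))
  })
  do.call(rbind, out)
}

#' Test whether a SNP association is explained away by sex
#'
#' Conditions the phenotype-SNP association on sex: within each sex stratum
#' the Dirichlet-multinomial machinery scores the dependence model (genotype
#' distribution differs between cases and controls) against the independence
#' model (one shared distribution), and the stratum log10 Bayes factors add.
#' A negative conditional log10 BF means the independence model wins, i.e.
#' the marginal association is attributable to sex imbalance.
#'
#' @param tabs_by_sex named list of 2 x K count matrices, one per sex stratum
#'   (rows cases, controls).
#' @param alpha Dirichlet hyper-parameter per cell (default 2).
#' @return A list with `log10_bf_conditional`, per-stratum `log10_bf`, and
#'   `explained_away` (TRUE when independence wins).
#' @export
gender_conditioned_test <- function(tabs_by_sex, alpha = 2) {
  stopifnot(is.list(tabs_by_sex), length(tabs_by_sex) >= 2)
  keep <- vapply(tabs_by_sex, function(tab) sum(tab) > 0, logical(1))
  if (!all(keep)) {
    warning(sprintf("skipping %d empty sex stratum(s)", sum(!keep)))
    tabs_by_sex <- tabs_by_sex[keep]
  }
  bf <- vapply(tabs_by_sex, log10_bayes_factor, numeric(1), alpha = alpha)
  total <- sum(bf)
  list(log10_bf_conditional = total, log10_bf = bf,
       explained_away = total < 0)
}

#' Per-subject burden of known disease risk alleles
#'
#' For every subject and risk-allele category, the fraction of risk alleles
#' carried among those typed: `sum(risk-allele dosage) / (2 * number of typed
#' SNPs in the category)`. Case/control burdens are compared per category
#' with a two-sample t-test.
#'
#' @param study a [genotype_study()].
#' @param risk_allele_table data.frame with columns `snp_id`, `risk_allele`
#'   (an allele letter matching `allele_M` or `allele_m` of the SNP) and
#'   `category`.
#' @return A list with `rates` (subjects x categories data.frame of burden
#'   rates), `tests` (per-category means and t-test p-value), and
#'   `n_skipped` (risk SNPs absent from the study).
#' @export
risk_allele_burden <- function(study, risk_allele_table) {
  stopifnot(all(c("snp_id", "risk_allele", "category") %in%
                  names(risk_allele_table)))
  idx <- match(risk_allele_table$snp_id, study$snp_meta$id)
  n_skipped <- sum(is.na(idx))
  tabu <- risk_allele_table[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no risk-allele SNPs present in the study")
  g <- study$genotypes[, idx, drop = FALSE]
  is_M <- tabu$risk_allele == study$snp_meta$allele_M[idx]
  is_m <- tabu$risk_allele == study$snp_meta$allele_m[idx]
  if (any(!is_M & !is_m)) stop("risk allele not among the SNP's alleles")
  dose <- g
  dose[, !is_M] <- 2L - dose[, !is_M, drop = FALSE]
  cats <- sort(unique(tabu$category))
  rates <- sapply(cats, function(cc) {
    cols <- which(tabu$category == cc)
    typed <- rowSums(!is.na(dose[, cols, drop = FALSE]))
    rowSums(dose[, cols, drop = FALSE], na.rm = TRUE) / (2 * typed)
  })
  rates <- as.data.frame(rates)
  names(rates) <- cats
  el <- study$subject_meta$phenotype == "EL"
  tests <- do.call(rbind, lapply(cats, function(cc) {
    tt <- stats::t.test(rates[[cc]][el], rates[[cc]][!el])
    data.frame(category = cc, mean_EL = mean(rates[[cc]][el], na.rm = TRUE),
               mean_AL = mean(rates[[cc]][!el], na.rm = TRUE),
               p_value = tt$p.value)
  }))
  list(rates = rates, tests = tests, n_skipped = n_skipped)
}
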