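#' @name bayes-factor
#' @title Dirichlet-multinomial Bayes factors for case-control SNP association
#'
#' @description
#' The association evidence for a SNP is measured by the Bayes factor (BF)
#' comparing two hypotheses about a 2 x K contingency table of genotype (or
#' allele) counts in cases and controls:
#'
#' * H1 (association): the case row and the control row follow independent
#'   multinomial distributions whose parameter vectors have independent
#'   Dirichlet priors with hyper-parameters `alpha_jk`;
#' * H0 (no association): both rows share one multinomial parameter vector
#'   with a Dirichlet prior whose hyper-parameters are the column sums
#'   `alpha_.k = sum_j alpha_jk`.
#'
#' Both marginal likelihoods are available in closed form:
#' \deqn{p(data | H1) = \prod_j \frac{\Gamma(\alpha_{j.})}{\Gamma(\alpha_{j.}+n_{j.})}
#'       \prod_k \frac{\Gamma(\alpha_{jk}+n_{jk})}{\Gamma(\alpha_{jk})}}
#' \deqn{p(data | H0) = \frac{\Gamma(\alpha)}{\Gamma(\alpha+N)}
#'       \prod_k \frac{\Gamma(\alpha_{.k}+n_{.k})}{\Gamma(\alpha_{.k})}}
#' and the BF is their ratio, computed throughout in log-gamma space. With
#' equal prior probabilities on H0 and H1 the BF equals the posterior odds of
#' association. The default hyper-parameter is `alpha_jk = 2` in every cell.
#'
#' Four genetic models are scored by recoding the 2 x 3 genotype counts
#' (columns MM, Mm, mm, where M is the lexicographically first allele):
#' genotypic (3 columns as is), allelic (allele counts `2*MM + Mm` vs
#' `Mm + 2*mm`, total 2N), dominant (`MM + Mm` vs `mm`) and recessive
#' (`MM` vs `Mm + mm`). The maximum BF over the four models (MBF) is the
#' per-SNP significance measure.
NULL

.GENETIC_MODELS <- c("genotypic", "allelic", "dominant", "recessive")

#' Recode genotype counts under a genetic model
#'
#' @param counts3 numeric matrix with 3 columns (counts of genotypes MM, Mm,
#'   mm, i.e. 2, 1, 0 copies of allele M); one row per group (typically 2:
#'   cases then controls) or per SNP.
#' @param model one of `"genotypic"`, `"allelic"`, `"dominant"`, `"recessive"`.
#' @return A count matrix with 3 columns (genotypic) or 2 columns (others).
#' @examples
#' x <- rbind(cases = c(10, 20, 30), controls = c(5, 25, 30))
#' recode_counts(x, "allelic")   # (40, 80) in the cases row
#' recode_counts(x, "dominant")  # (30, 30)
#' recode_counts(x, "recessive") # (10, 50)
#' @export
recode_counts <- function(counts3, model = .GENETIC_MODELS) {
  model <- match.arg(model)
  counts3 <- rbind(counts3)
  stopifnot(ncol(counts3) == 3)
  if (any(counts3 < 0)) stop("negative counts")
  out <- switch(model,
    genotypic = counts3,
    allelic   = cbind(2 * counts3[, 1] + counts3[, 2],
                      counts3[, 2] + 2 * counts3[, 3]),
    dominant  = cbind(counts3[, 1] + counts3[, 2], counts3[, 3]),
    recessive = cbind(counts3[, 1], counts3[, 2] + counts3[, 3]))
  rownames(out) <- rownames(counts3)
  out
}

#' Log10 Bayes factor for a 2 x K contingency table
#'
#' Closed-form Dirichlet-multinomial Bayes factor for association between the
#' row variable (phenotype) and the column variable (genotype category). See
#' [bayes-factor] for the model. An all-zero table gives log10 BF = 0.
#'
#' @param tab numeric matrix of non-negative counts, rows = phenotype groups
#'   (cases, controls), columns = genotype categories.
#' @param alpha Dirichlet hyper-parameters: a scalar (used in every cell,
#'   default 2) or a matrix shaped like `tab`.
#' @return log10 of the Bayes factor `p(data|H1) / p(data|H0)`.
#' @examples
#' log10_bayes_factor(rbind(c(1, 0), c(0, 1)))  # log10(1.125)
#' @export
log10_bayes_factor <- function(tab, alpha = 2) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  if (length(alpha) == 1) alpha <- matrix(alpha, nrow(tab), ncol(tab))
  if (any(alpha <= 0)) stop("Dirichlet hyper-parameters must be positive")
  stopifnot(all(dim(alpha) == dim(tab)))
  a_row <- rowSums(alpha); n_row <- rowSums(tab)
  a_col <- colSums(alpha); n_col <- colSums(tab)
  a <- sum(alpha); n <- sum(tab)
  logp1 <- sum(lgamma(a_row) - lgamma(a_row + n_row)) +
    sum(lgamma(alpha + tab) - lgamma(alpha))
  logp0 <- lgamma(a) - lgamma(a + n) +
    sum(lgamma(a_col + n_col) - lgamma(a_col))
  (logp1 - logp0) / log(10)
}

# Vectorised log10 BF across SNPs for one model: `cases` and `controls` are
# S x K count matrices (same K), scalar alpha per cell. Row j margins are
# per-SNP totals. Identical algebra to log10_bayes_factor().
log10_bf_vec <- function(cases, controls, alpha = 2) {
  k <- ncol(cases)
  n1 <- rowSums(cases); n0 <- rowSums(controls); n <- n1 + n0
  a_row <- k * alpha; a <- 2 * k * alpha; a_col <- 2 * alpha
  logp1 <- (lgamma(a_row) - lgamma(a_row + n1)) +
    (lgamma(a_row) - lgamma(a_row + n0)) +
    rowSums(lgamma(alpha + cases)) + rowSums(lgamma(alpha + controls)) -
    2 * k * lgamma(alpha)
  logp0 <- lgamma(a) - lgamma(a + n) +
    rowSums(lgamma(a_col + cases + controls)) - k * lgamma(a_col)
  (logp1 - logp0) / log(10)
}

#' Maximum Bayes factor (MBF) over the four genetic models
#'
#' Evaluates the Dirichlet-multinomial log10 Bayes factor under the
#' genotypic, allelic, dominant and recessive recodings of a SNP's 2 x 3
#' genotype counts and returns the maximum together with the winning model.
#'
#' @param counts3 2 x 3 matrix of genotype counts (rows cases, controls;
#'   columns MM, Mm, mm).
#' @inheritParams log10_bayes_factor
#' @return A list with `log10_mbf`, `best_model`, and `log10_bf` (named
#'   vector over the four models).
#' @export
max_bayes_factor <- function(counts3, alpha = 2) {
  stopifnot(nrow(counts3) == 2, ncol(counts3) == 3)
  bfs <- vapply(.GENETIC_MODELS, function(m)
    log10_bayes_factor(recode_counts(counts3, m), alpha), numeric(1))
  list(log10_mbf = max(bfs),
       best_model = .GENETIC_MODELS[which.max(bfs)],
       log10_bf = bfs)
}

# Vectorised MBF across SNPs: cases/controls are S x 3 genotype count
# matrices. Returns a list of per-model log10 BF matrix, mbf and best model.
mbf_vec <- function(cases, controls, alpha = 2) {
  bf <- sapply(.GENETIC_MODELS, function(m)
    log10_bf_vec(recode_counts(cases, m), recode_counts(controls, m), alpha))
  bf <- matrix(bf, ncol = 4, dimnames = list(NULL, .GENETIC_MODELS))
  best <- max.col(bf, ties.method = "first")
  list(log10_bf = bf,
       log10_mbf = bf[cbind(seq_len(nrow(bf)), best)],
       best_model = .GENETIC_MODELS[best])
}

#' Posterior-mean conditional genotype probabilities
#'
#' Conjugate Bayesian estimates of the genotype-category distribution within
#' each phenotype row: `p_hat(g_k | row j) = (n_jk + alpha_jk) /
#' (n_j. + alpha_j.)`. Rows always sum to one and no category gets
#' probability zero.
#'
#' @inheritParams log10_bayes_factor
#' @return A matrix shaped like `tab` with rows summing to 1.
#' @examples
#' estimate_conditional_probs(rbind(EL = c(120, 681), AL = c(238, 676)))
#' @export
estimate_conditional_probs <- function(tab, alpha = 2) {
  tab <- as.matrix(tab)
  if (length(alpha) == 1) alpha <- matrix(alpha, nrow(tab), ncol(tab))
  (tab + alpha) / rowSums(tab + alpha)
}
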