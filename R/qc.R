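#' Quality-control thresholds
#'
#' Default values follow a stringent array-GWAS cleaning protocol: samples
#' with call rate below 96.5% are excluded but rescued if their recomputed
#' call rate is at least 93%; SNPs must have call rate above 98% in every
#' batch-by-phenotype stratum and overall, a Hardy-Weinberg chi-square
#' statistic in controls below 50, a maximum between-batch minor-allele
#' frequency difference below 0.2, and a heterozygosity-excess score within
#' [-0.3, 0.3].
#'
#' @param sample_cr_primary,sample_cr_rescue sample call-rate thresholds.
#' @param snp_cr per-stratum SNP call-rate threshold.
#' @param hwe_chi2_max upper bound on the control HWE chi-square (1 df).
#' @param maf_diff_max upper bound on between-batch MAF differences.
#' @param het_excess_range allowed interval for the heterozygosity-excess
#'   score `F = 1 - observed het / expected het under HWE`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(sample_cr_primary = 0.965,
                          sample_cr_rescue = 0.93,
                          snp_cr = 0.98, hwe_chi2_max = 50,
                          maf_diff_max = 0.2,
                          het_excess_range = c(-0.3, 0.3)) {
  stopifnot(sample_cr_primary >= 0, sample_cr_primary <= 1,
            sample_cr_rescue >= 0, sample_cr_rescue <= 1,
            snp_cr >= 0, snp_cr <= 1, hwe_chi2_max > 0,
            maf_diff_max >= 0, maf_diff_max <= 1,
            length(het_excess_range) == 2)
  structure(list(sample_cr_primary = sample_cr_primary,
                 sample_cr_rescue = sample_cr_rescue,
                 snp_cr = snp_cr, hwe_chi2_max = hwe_chi2_max,
                 maf_diff_max = maf_diff_max,
                 het_excess_range = het_excess_range),
            class = "qc_thresholds")
}

#' Sample-level quality control
#'
#' Two-pass call-rate rule: samples with call rate below
#' `sample_cr_primary` are excluded in pass 1; excluded samples with call
#' rate at or above `sample_cr_rescue` are re-admitted in pass 2. (In the
#' array-intensity original, pass 2 follows a re-clustering of genotype
#' calls; from hard genotype calls the call rate is unchanged, so the rule
#' reduces to a final threshold at the rescue level — a documented
#' simplification.)
#'
#' @param study a [genotype_study()].
#' @param thresholds a [qc_thresholds()].
#' @return A list with `study` (retained samples) and `report` (per-sample
#'   call rate and decision).
#' @export
apply_sample_qc <- function(study, thresholds = qc_thresholds()) {
  stopifnot(nrow(study$genotypes) > 0)
  cr <- rowMeans(!is.na(study$genotypes))
  pass1 <- cr >= thresholds$sample_cr_primary
  rescued <- !pass1 & cr >= thresholds$sample_cr_rescue
  keep <- pass1 | rescued
  report <- data.frame(id = study$subject_meta$id, call_rate = cr,
                       pass1 = pass1, rescued = rescued,
                       decision = ifelse(keep, "retained", "excluded"),
                       stringsAsFactors = FALSE)
  list(study = subset_study(study, subjects = which(keep)), report = report)
}

# HWE chi-square (1 df) from a SNPs x 3 count matrix (MM, Mm, mm)
hwe_chi2 <- function(counts3) {
  n <- rowSums(counts3)
  p <- (2 * counts3[, 1] + counts3[, 2]) / (2 * n)
  e <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  chi2 <- rowSums((counts3 - e)^2 / e)
  chi2[p == 0 | p == 1] <- NA_real_  # monomorphic: test undefined
  chi2
}

#' SNP-level quality control
#'
#' Keeps a SNP iff all of: call rate above `snp_cr` overall and within
#' every batch-by-phenotype stratum; Hardy-Weinberg chi-square in controls
#' below `hwe_chi2_max` (monomorphic SNPs are flagged and the test is
#' skipped); the maximum pairwise between-batch minor-allele-frequency
#' difference below `maf_diff_max`; and the heterozygosity-excess score
#' `F = 1 - observed/expected heterozygosity` within `het_excess_range`.
#'
#' @inheritParams apply_sample_qc
#' @return A list with `study` (retained SNPs) and `report` (per-rule
#'   failure counts plus a per-SNP decision table).
#' @export
apply_snp_qc <- function(study, thresholds = qc_thresholds()) {
  g <- study$genotypes
  sm <- study$subject_meta
  stopifnot(!is.null(sm$batch))
  obs <- !is.na(g)

  cr_ok <- colMeans(obs) > thresholds$snp_cr
  for (b in unique(sm$batch)) for (ph in c("EL", "AL")) {
    rows <- sm$batch == b & sm$phenotype == ph
    if (any(rows))
      cr_ok <- cr_ok &
        colMeans(obs[rows, , drop = FALSE]) > thresholds$snp_cr
  }

  ctrl <- sm$phenotype == "AL"
  cc <- cbind(colSums(g[ctrl, , drop = FALSE] == 2L, na.rm = TRUE),
              colSums(g[ctrl, , drop = FALSE] == 1L, na.rm = TRUE),
              colSums(g[ctrl, , drop = FALSE] == 0L, na.rm = TRUE))
  hwe <- hwe_chi2(cc)
  monomorphic <- is.na(hwe)
  hwe_ok <- monomorphic | hwe < thresholds$hwe_chi2_max

  batches <- sort(unique(sm$batch))
  maf_by_batch <- sapply(batches, function(b) {
    rows <- sm$batch == b
    f <- colMeans(g[rows, , drop = FALSE], na.rm = TRUE) / 2
    pmin(f, 1 - f)
  })
  maf_by_batch <- matrix(maf_by_batch, ncol = length(batches))
  maf_diff <- apply(maf_by_batch, 1, max) - apply(maf_by_batch, 1, min)
  maf_ok <- maf_diff < thresholds$maf_diff_max

  p <- colMeans(g, na.rm = TRUE) / 2
  het_obs <- colMeans(g == 1L, na.rm = TRUE)
  het_exp <- 2 * p * (1 - p)
  fhat <- ifelse(het_exp > 0, 1 - het_obs / het_exp, 0)
  het_ok <- fhat >= thresholds$het_excess_range[1] &
    fhat <= thresholds$het_excess_range[2]

  keep <- cr_ok & hwe_ok & maf_ok & het_ok
  report <- list(
    n_input = ncol(g), n_retained = sum(keep),
    failures = c(call_rate = sum(!cr_ok), hwe = sum(!hwe_ok),
                 maf_diff = sum(!maf_ok), het_excess = sum(!het_ok)),
    n_monomorphic = sum(monomorphic),
    per_snp = data.frame(id = study$snp_meta$id, cr_ok = cr_ok,
                         hwe_chi2 = hwe, maf_diff = maf_diff,
                         het_excess = fhat, monomorphic = monomorphic,
                         retained = keep, stringsAsFactors = FALSE))
  list(study = subset_study(study, snps = which(keep)), report = report)
}

#' Detect duplicate or highly related samples by identity-by-state
#'
#' Computes the genome-wide mean identity-by-state proportion
#' `IBS = 1 - |g_i - g_j| / 2` over SNPs typed in both subjects (a
#' method-of-moments stand-in for a full identity-by-descent analysis) and
#' flags pairs above the threshold. Duplicate samples give IBS = 1.
#'
#' @param study a [genotype_study()] with at least 2 subjects.
#' @param ibs_threshold flagging threshold (default 0.9, duplicates).
#' @return data.frame of flagged pairs (`id1`, `id2`, `ibs`, `n_shared`).
#' @export
detect_duplicates <- function(study, ibs_threshold = 0.9) {
  g <- study$genotypes
  stopifnot(nrow(g) >= 2)
  m <- !is.na(g)
  x <- g; x[!m] <- 0L
  storage.mode(x) <- "double"; storage.mode(m) <- "double"
  a <- tcrossprod(x, m)            # sum of g_i over both-observed SNPs
  i1 <- (x >= 1) * m; i2 <- (x == 2) * m
  smin <- tcrossprod(i1) + tcrossprod(i2)
  d <- a + t(a) - 2 * smin         # sum |g_i - g_j|
  n_obs <- tcrossprod(m)
  ibs <- 1 - d / (2 * n_obs)
  idx <- which(upper.tri(ibs) & ibs > ibs_threshold, arr.ind = TRUE)
  data.frame(id1 = study$subject_meta$id[idx[, 1]],
             id2 = study$subject_meta$id[idx[, 2]],
             ibs = ibs[idx], n_shared = n_obs[idx],
             stringsAsFactors = FALSE)
}
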