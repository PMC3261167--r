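#' Genotype study container
#'
#' A `genotype_study` bundles a subjects-by-SNPs genotype matrix with SNP and
#' subject metadata. Genotypes are coded 0/1/2 as the count of allele M, the
#' lexicographically first of the two alleles (the convention produced by
#' Illumina TOP-strand calling, where alleles are typically A/G or A/C and the
#' reported allele order is alphabetical). Missing genotypes are `NA`.
#'
#' @param genotypes integer matrix, subjects in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are subject ids, column names SNP ids.
#' @param snp_meta data.frame with one row per SNP: columns `id`, `chrom`,
#'   `pos`, `allele_M`, `allele_m` (and optionally others, e.g. `is_lav`).
#' @param subject_meta data.frame with one row per subject: columns `id`,
#'   `phenotype` (`"EL"` for cases, `"AL"` for controls), and optionally
#'   `age_years`, `sex`, `batch`, `subpop`, `latent_group`, `event_flag`.
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(genotypes, snp_meta, subject_meta) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(genotypes) == nrow(subject_meta),
            ncol(genotypes) == nrow(snp_meta))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(subject_meta$id)) stop("duplicate subject ids")
  if (anyDuplicated(snp_meta$id)) stop("duplicate SNP ids")
  if (!all(subject_meta$phenotype %in% c("EL", "AL")))
    stop("phenotype labels must be 'EL' or 'AL'")
  rownames(genotypes) <- subject_meta$id
  colnames(genotypes) <- snp_meta$id
  structure(list(genotypes = genotypes,
                 snp_meta = as.data.frame(snp_meta),
                 subject_meta = as.data.frame(subject_meta)),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  n_el <- sum(x$subject_meta$phenotype == "EL")
  n_al <- sum(x$subject_meta$phenotype == "AL")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf(
    "genotype_study: %d subjects (%d EL / %d AL) x %d SNPs, %.2f%% missing\n",
    nrow(x$genotypes), n_el, n_al, ncol(x$genotypes), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_study <- function(x) dim(x$genotypes)

#' Subset a genotype study
#'
#' @param x a `genotype_study`.
#' @param subjects,snps index vectors (logical, integer, or character ids).
#' @return A new `genotype_study` restricted to the selected rows/columns.
#' @export
subset_study <- function(x, subjects = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_study"))
  si <- if (is.null(subjects)) seq_len(nrow(x$genotypes)) else subjects
  vi <- if (is.null(snps)) seq_len(ncol(x$genotypes)) else snps
  if (is.character(si)) si <- match(si, x$subject_meta$id)
  if (is.character(vi)) vi <- match(vi, x$snp_meta$id)
  genotype_study(x$genotypes[si, vi, drop = FALSE],
                 x$snp_meta[vi, , drop = FALSE],
                 x$subject_meta[si, , drop = FALSE])
}

# case/control genotype count matrices (SNPs x 3 columns: MM, Mm, mm),
# i.e. counts of subjects with 2, 1, 0 copies of allele M
genotype_counts <- function(study) {
  g <- study$genotypes
  el <- study$subject_meta$phenotype == "EL"
  count3 <- function(m) {
    cbind(`2` = colSums(m == 2L, na.rm = TRUE),
          `1` = colSums(m == 1L, na.rm = TRUE),
          `0` = colSums(m == 0L, na.rm = TRUE))
  }
  list(cases = count3(g[el, , drop = FALSE]),
       controls = count3(g[!el, , drop = FALSE]))
}
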