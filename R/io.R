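#' File bundle describing an on-disk genotype study
#'
#' @param prefix path prefix; dialect-specific suffixes are appended
#'   (`internal_tsv`: `.genotypes.tsv`, `.snps.tsv`, `.subjects.tsv`;
#'   `vcf`: `.vcf` plus `.subjects.tsv`; `plink_text`: `.ped`/`.map` plus
#'   `.subjects.tsv`).
#' @param dialect one of `"internal_tsv"`, `"vcf"`, `"plink_text"`.
#' @return A `study_bundle` list of file paths and the dialect tag.
#' @export
study_bundle <- function(prefix,
                         dialect = c("internal_tsv", "vcf", "plink_text")) {
  dialect <- match.arg(dialect)
  paths <- switch(dialect,
    internal_tsv = list(genotypes = paste0(prefix, ".genotypes.tsv"),
                        snps = paste0(prefix, ".snps.tsv"),
                        subjects = paste0(prefix, ".subjects.tsv")),
    vcf = list(vcf = paste0(prefix, ".vcf"),
               subjects = paste0(prefix, ".subjects.tsv")),
    plink_text = list(ped = paste0(prefix, ".ped"),
                      map = paste0(prefix, ".map"),
                      subjects = paste0(prefix, ".subjects.tsv")))
  structure(c(paths, list(dialect = dialect)), class = "study_bundle")
}

#' Write a genotype study to disk
#'
#' The `internal_tsv` dialect (a genotype matrix TSV with subjects as rows
#' plus SNP and subject metadata TSVs) is lossless. The `vcf` dialect writes
#' a minimal VCF 4.2 sites+GT file (REF = allele M, ALT = allele m, missing
#' genotypes as `./.`) plus a subject table sidecar. The `plink_text`
#' dialect writes whitespace-delimited .ped/.map files (missing genotypes as
#' `0 0`, phenotype column 2 = case, 1 = control) plus the sidecar.
#'
#' @param study a [genotype_study()].
#' @param bundle a [study_bundle()].
#' @return The bundle, invisibly.
#' @export
write_study <- function(study, bundle) {
  stopifnot(inherits(study, "genotype_study"),
            inherits(bundle, "study_bundle"))
  utils::write.table(study$subject_meta, bundle$subjects, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  switch(bundle$dialect,
         internal_tsv = write_internal(study, bundle),
         vcf = write_vcf_gt(study, bundle$vcf),
         plink_text = write_plink(study, bundle))
  invisible(bundle)
}

write_internal <- function(study, bundle) {
  g <- as.data.frame(study$genotypes)
  g <- cbind(subject_id = study$subject_meta$id, g)
  utils::write.table(g, bundle$genotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$snp_meta, bundle$snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# minimal VCF 4.2 writer: fixed columns + GT-only FORMAT. Written by hand
# because the file is trivial and must stay plain text.
write_vcf_gt <- function(study, path) {
  gt_code <- c(`2` = "0/0", `1` = "0/1", `0` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=longsig",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       study$subject_meta$id), collapse = "\t")), con)
  g <- t(study$genotypes)  # SNPs x subjects
  for (i in seq_len(nrow(g))) {
    gt <- gt_code[as.character(g[i, ])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(study$snp_meta$chrom[i], study$snp_meta$pos[i],
                       study$snp_meta$id[i], study$snp_meta$allele_M[i],
                       study$snp_meta$allele_m[i], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
}

write_plink <- function(study, bundle) {
  utils::write.table(
    data.frame(chrom = study$snp_meta$chrom, id = study$snp_meta$id,
               cm = 0, pos = study$snp_meta$pos),
    bundle$map, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  sm <- study$subject_meta
  sex <- if ("sex" %in% names(sm)) ifelse(sm$sex == "M", 1L, 2L) else 0L
  g <- study$genotypes
  a_M <- study$snp_meta$allele_M; a_m <- study$snp_meta$allele_m
  lines <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, a_M, a_m))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, a_M, a_m))
    paste(c(sm$id[i], sm$id[i], 0, 0, sex[i],
            ifelse(sm$phenotype[i] == "EL", 2L, 1L),
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, bundle$ped)
}

#' Read a genotype study from disk
#'
#' Genotypes are mapped to counts of the lexicographically first allele M;
#' VCF `./.` and PLINK `0 0` become missing. Non-biallelic VCF records are
#' skipped with a warning.
#'
#' @param bundle a [study_bundle()] whose files exist.
#' @return A [genotype_study()].
#' @export
read_study <- function(bundle) {
  stopifnot(inherits(bundle, "study_bundle"))
  subject_meta <- utils::read.table(bundle$subjects, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
  switch(bundle$dialect,
         internal_tsv = read_internal(bundle, subject_meta),
         vcf = read_vcf_gt(bundle$vcf, subject_meta),
         plink_text = read_plink(bundle, subject_meta))
}

read_internal <- function(bundle, subject_meta) {
  g <- utils::read.table(bundle$genotypes, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  snp_meta <- utils::read.table(bundle$snps, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ids <- g$subject_id
  g <- as.matrix(g[, -1, drop = FALSE])
  if (!identical(as.character(ids), as.character(subject_meta$id)))
    stop("subject order mismatch between genotype and subject tables")
  genotype_study(g, snp_meta, subject_meta)
}

read_vcf_gt <- function(path, subject_meta) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- rbind(fixm)
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1
  if (any(!biallelic))
    warning(sprintf("skipping %d non-biallelic record(s)", sum(!biallelic)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  alt_count <- matrix(0L, nrow(gt), ncol(gt))
  alt_count[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  alt_count[gt %in% c("1/1", "1|1")] <- 2L
  alt_count[is.na(gt) | gt %in% c("./.", ".|.", ".")] <- NA_integer_
  # M = lexicographically first of the two alleles
  m_is_ref <- fix$REF < fix$ALT
  code <- alt_count
  code[m_is_ref, ] <- 2L - alt_count[m_is_ref, , drop = FALSE]
  snp_meta <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         allele_M = ifelse(m_is_ref, fix$REF, fix$ALT),
                         allele_m = ifelse(m_is_ref, fix$ALT, fix$REF),
                         stringsAsFactors = FALSE)
  g <- t(code)
  sm <- subject_meta[match(colnames(gt), subject_meta$id), , drop = FALSE]
  genotype_study(g, snp_meta, sm)
}

read_plink <- function(bundle, subject_meta) {
  map <- utils::read.table(bundle$map, header = FALSE,
                           stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(bundle$ped, header = FALSE,
                           colClasses = "character")
  s <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * s)
  alle <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- alle[, seq(1, 2 * s, by = 2), drop = FALSE]
  a2 <- alle[, seq(2, 2 * s, by = 2), drop = FALSE]
  g <- matrix(NA_integer_, nrow(ped), s)
  for (j in seq_len(s)) {
    obs <- sort(unique(c(a1[, j], a2[, j])))
    obs <- setdiff(obs, "0")
    if (length(obs) > 2) stop(sprintf("SNP %s is not biallelic", map$id[j]))
    m_allele <- if (length(obs)) min(obs) else NA_character_
    ok <- a1[, j] != "0" & a2[, j] != "0"
    g[ok, j] <- (a1[ok, j] == m_allele) + (a2[ok, j] == m_allele)
  }
  m_all <- vapply(seq_len(s), function(j) {
    obs <- setdiff(sort(unique(c(a1[, j], a2[, j]))), "0")
    c(if (length(obs)) obs[1] else "N",
      if (length(obs) > 1) obs[2] else "N")
  }, character(2))
  snp_meta <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                         allele_M = m_all[1, ], allele_m = m_all[2, ],
                         stringsAsFactors = FALSE)
  sm <- subject_meta[match(ped[[2]], subject_meta$id), , drop = FALSE]
  genotype_study(g, snp_meta, sm)
}
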