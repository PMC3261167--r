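#' Configuration for a synthetic case-control longevity study
#'
#' Defines the generative conditions of a synthetic genome-wide case-control
#' study of exceptional longevity (EL cases vs AL controls). Defaults emulate
#' the discovery design of a centenarian GWAS: 801 cases and 914 matched
#' controls, biallelic SNPs coded on the lexicographically first allele,
#' latent ancestry subpopulations under the Balding-Nichols model, planted
#' longevity-associated variants (LAVs) specified by their conditional
#' genotype/carrier frequencies given phenotype, genotyping batches,
#' missing-at-random genotypes, case ages Normal(104, 3) truncated at 95 and
#' control ages Normal(75, 7).
#'
#' @param n_cases,n_controls group sizes (defaults 801 / 914).
#' @param n_snps number of biallelic SNPs (default 250000; scale down for
#'   interactive work).
#' @param n_lavs number of planted longevity-associated variants.
#' @param lav_models character vector recycled over LAVs; each element one of
#'   `"genotypic"`, `"allelic"`, `"dominant"`, `"recessive"`.
#' @param lav_effect `NULL` to auto-generate effects (control frequency
#'   uniform on 0.10-0.40, case frequency shifted by `lav_gap` in a random
#'   direction, emulating the 0.15-vs-0.26 carrier-prevalence gap of a
#'   strong longevity variant), or a list with one element per LAV:
#'   `list(model =, case =, control =)` where `case`/`control` are length-3
#'   genotype distributions (MM, Mm, mm) for the genotypic model and scalar
#'   allele / carrier / M-homozygote frequencies for the allelic / dominant /
#'   recessive models.
#' @param lav_gap absolute case-control frequency gap used when auto
#'   generating effects (default 0.11).
#' @param maf_range interval in (0, 0.5] for ancestral allele frequencies of
#'   non-LAV SNPs.
#' @param n_subpops number of latent ancestry subpopulations.
#' @param fst Balding-Nichols divergence parameter in `[0, 0.5)`.
#' @param subpop_case_bias `NULL` for identical subpopulation mixtures in
#'   cases and controls, or a vector of case-specific subpopulation weights
#'   (used to plant stratification confounding).
#' @param missing_rate probability that any genotype call is missing
#'   (missing completely at random).
#' @param n_batches number of genotyping batches.
#' @param n_signature_groups number of latent case subgroups with distinct
#'   LAV subsets (1 = homogeneous cases).
#' @param group_lav_overlap fraction of LAVs shared by all signature groups.
#' @param survival_params data.frame with columns `mean` and `sd` (years),
#'   one row per signature group, for case age-at-death distributions;
#'   recycled if a single row. Default mean 104, sd 3.
#' @param case_age_min lower truncation of case ages (default 95).
#' @param control_age mean and sd of control ages (default 75, 7).
#' @param seed integer seed; the study is fully reproducible from it.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_cases = 801, n_controls = 914, n_snps = 250000,
                         n_lavs = 100,
                         lav_models = c("genotypic", "allelic", "dominant",
                                        "recessive"),
                         lav_effect = NULL, lav_gap = 0.11,
                         maf_range = c(0.05, 0.5),
                         n_subpops = 1, fst = 0, subpop_case_bias = NULL,
                         missing_rate = 0.01, n_batches = 2,
                         n_signature_groups = 1, group_lav_overlap = 0,
                         survival_params = data.frame(mean = 104, sd = 3),
                         case_age_min = 95,
                         control_age = c(mean = 75, sd = 7),
                         seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_snps = as.integer(n_snps), n_lavs = as.integer(n_lavs),
              lav_models = lav_models, lav_effect = lav_effect,
              lav_gap = lav_gap, maf_range = maf_range,
              n_subpops = as.integer(n_subpops), fst = fst,
              subpop_case_bias = subpop_case_bias,
              missing_rate = missing_rate, n_batches = as.integer(n_batches),
              n_signature_groups = as.integer(n_signature_groups),
              group_lav_overlap = group_lav_overlap,
              survival_params = survival_params,
              case_age_min = case_age_min, control_age = control_age,
              seed = as.integer(seed))
  class(cfg) <- "study_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_cases > 0, n_controls > 0, n_snps > 0,
              n_lavs >= 0, n_lavs <= n_snps,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2],
              n_subpops >= 1, fst >= 0, fst < 0.5,
              missing_rate >= 0, missing_rate <= 1,
              n_batches >= 1, n_signature_groups >= 1,
              group_lav_overlap >= 0, group_lav_overlap <= 1,
              all(survival_params$sd > 0))
    stopifnot(all(lav_models %in% .GENETIC_MODELS))
  })
  if (!is.null(cfg$lav_effect)) {
    if (length(cfg$lav_effect) != cfg$n_lavs)
      stop("lav_effect must have one element per LAV")
    for (ef in cfg$lav_effect) validate_lav_effect(ef)
  }
  invisible(cfg)
}

validate_lav_effect <- function(ef) {
  stopifnot(is.list(ef), ef$model %in% .GENETIC_MODELS)
  for (v in list(ef$case, ef$control)) {
    if (ef$model == "genotypic") {
      if (length(v) != 3 || any(v < 0) || abs(sum(v) - 1) > 1e-8)
        stop("genotypic LAV effect must be a length-3 distribution")
    } else {
      if (length(v) != 1 || v < 0 || v > 1)
        stop("scalar LAV frequency outside [0, 1]")
    }
  }
  invisible(ef)
}

# allele frequency of M implied by a LAV effect spec, for genotype sampling:
# dominant f = carrier prevalence 1-(1-q)^2; recessive f = q^2; allelic f = q
lav_allele_freq <- function(model, f) {
  switch(model,
         allelic = f,
         dominant = 1 - sqrt(1 - f),
         recessive = sqrt(f),
         stop("no scalar frequency for the genotypic model"))
}

draw_lav_genotypes <- function(n, model, f) {
  if (model == "genotypic") {
    # f is a distribution over (MM, Mm, mm) = M-counts (2, 1, 0)
    sample(c(2L, 1L, 0L), n, replace = TRUE, prob = f)
  } else {
    stats::rbinom(n, 2L, lav_allele_freq(model, f))
  }
}

auto_lav_effects <- function(cfg) {
  models <- rep_len(cfg$lav_models, cfg$n_lavs)
  lapply(seq_len(cfg$n_lavs), function(i) {
    f0 <- stats::runif(1, 0.10, 0.40)
    f1 <- f0 + sample(c(-1, 1), 1) * cfg$lav_gap
    f1 <- min(max(f1, 0.01), 0.99)
    if (models[i] == "genotypic") {
      g0 <- c(f0^2, 2 * f0 * (1 - f0), (1 - f0)^2)
      g1 <- c(f1^2, 2 * f1 * (1 - f1), (1 - f1)^2)
      list(model = "genotypic", case = g1, control = g0)
    } else {
      list(model = models[i], case = f1, control = f0)
    }
  })
}

# truncated-normal ages via inverse-cdf sampling
rage <- function(n, mean, sd, lower = -Inf) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic case-control genotype study
#'
#' Draws a [genotype_study()] under the conditions of a [study_config()].
#' Non-LAV SNPs share one (subpopulation-perturbed) allele frequency between
#' cases and controls and follow Hardy-Weinberg equilibrium within
#' subpopulation; planted LAVs are drawn from their stated case/control
#' conditional distributions; genotypes go missing completely at random at
#' `missing_rate`; ages come from the configured distributions. The study is
#' bit-reproducible from `config$seed`.
#'
#' Latent signature-group labels are assigned here but all case groups share
#' the same LAV distributions until [plant_signature_groups()] is applied.
#'
#' @param config a [study_config()].
#' @return A [genotype_study()]; `snp_meta$is_lav` flags planted variants and
#'   `attr(, "lav_info")` records their models and true conditional
#'   frequencies.
#' @export
generate_study <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n_ca <- config$n_cases; n_co <- config$n_controls
  n <- n_ca + n_co; s <- config$n_snps

  # SNP map: 22 chromosomes, strictly increasing positions within chromosome
  chrom <- sort(rep_len(seq_len(22), s))
  pos <- unlist(lapply(split(seq_len(s), chrom), function(ix)
    sort(sample.int(2.4e8, length(ix)))), use.names = FALSE)
  pair <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), 4, 2, byrow = TRUE)
  al <- pair[sample.int(4, s, replace = TRUE), , drop = FALSE]
  snp_meta <- data.frame(id = sprintf("snp%06d", seq_len(s)),
                         chrom = chrom, pos = pos,
                         allele_M = al[, 1], allele_m = al[, 2],
                         is_lav = FALSE, stringsAsFactors = FALSE)

  pheno <- rep(c("EL", "AL"), c(n_ca, n_co))
  if (is.null(config$subpop_case_bias)) {
    subpop <- sample.int(config$n_subpops, n, replace = TRUE)
  } else {
    w <- rep_len(config$subpop_case_bias, config$n_subpops)
    subpop <- c(sample.int(config$n_subpops, n_ca, replace = TRUE, prob = w),
                sample.int(config$n_subpops, n_co, replace = TRUE))
  }

  # ancestral frequencies and Balding-Nichols subpopulation perturbation
  p0 <- stats::runif(s, config$maf_range[1], config$maf_range[2])
  freq <- matrix(p0, nrow = config$n_subpops, ncol = s, byrow = TRUE)
  if (config$fst > 0 && config$n_subpops > 1) {
    shape <- (1 - config$fst) / config$fst
    for (k in seq_len(config$n_subpops))
      freq[k, ] <- stats::rbeta(s, p0 * shape, (1 - p0) * shape)
  }

  g <- matrix(0L, n, s)
  for (k in seq_len(config$n_subpops)) {
    rows <- which(subpop == k)
    if (!length(rows)) next
    g[rows, ] <- stats::rbinom(length(rows) * s, 2L,
                               rep(freq[k, ], each = length(rows)))
  }

  # plant LAVs: overwrite genotypes with phenotype-conditional draws
  lav_info <- NULL
  if (config$n_lavs > 0) {
    effects <- if (is.null(config$lav_effect)) auto_lav_effects(config)
               else config$lav_effect
    lav_idx <- sort(sample.int(s, config$n_lavs))
    snp_meta$is_lav[lav_idx] <- TRUE
    for (i in seq_len(config$n_lavs)) {
      ef <- effects[[i]]
      j <- lav_idx[i]
      g[pheno == "EL", j] <- draw_lav_genotypes(n_ca, ef$model, ef$case)
      g[pheno == "AL", j] <- draw_lav_genotypes(n_co, ef$model, ef$control)
    }
    lav_info <- list(index = lav_idx, effects = effects)
  }

  if (config$missing_rate > 0)
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_

  surv <- config$survival_params
  surv <- surv[rep_len(seq_len(nrow(surv)), config$n_signature_groups), ,
               drop = FALSE]
  latent_group <- ifelse(pheno == "EL",
                         sample.int(config$n_signature_groups, n,
                                    replace = TRUE), 0L)
  age <- numeric(n)
  for (grp in seq_len(config$n_signature_groups)) {
    rows <- which(latent_group == grp)
    age[rows] <- rage(length(rows), surv$mean[grp], surv$sd[grp],
                      config$case_age_min)
  }
  ctrl <- which(pheno == "AL")
  age[ctrl] <- stats::rnorm(length(ctrl), config$control_age[["mean"]],
                            config$control_age[["sd"]])

  subject_meta <- data.frame(
    id = sprintf("subj%05d", seq_len(n)), phenotype = pheno,
    age_years = age, sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample.int(config$n_batches, n, replace = TRUE),
    subpop = subpop, latent_group = latent_group,
    event_flag = 1L, stringsAsFactors = FALSE)

  study <- genotype_study(g, snp_meta, subject_meta)
  attr(study, "lav_info") <- lav_info
  study
}

#' Plant latent signature groups into a generated study
#'
#' Partitions the cases of a study into `n_signature_groups` latent groups
#' and makes each group enriched only for its own subset of the planted
#' LAVs: at LAVs outside a group's subset, that group's cases are redrawn
#' from the control conditional distribution. A fraction
#' `group_lav_overlap` of the LAVs is shared by all groups; the remainder is
#' split disjointly. Case ages are redrawn from the group-specific
#' `survival_params` rows. With one group the study is returned with
#' genotypes and ages redrawn from the same distributions as
#' [generate_study()].
#'
#' @param study a study from [generate_study()] (must carry `lav_info`).
#' @param config the [study_config()] used to generate it.
#' @return The modified [genotype_study()]; `attr(, "group_lavs")` lists each
#'   group's LAV indices.
#' @export
plant_signature_groups <- function(study, config) {
  lav <- attr(study, "lav_info")
  if (is.null(lav)) stop("study has no planted LAVs")
  n_grp <- config$n_signature_groups
  cases <- which(study$subject_meta$phenotype == "EL")
  if (n_grp > length(cases)) stop("more signature groups than cases")
  set.seed(config$seed + 1L)

  grp <- rep_len(seq_len(n_grp), length(cases))
  grp <- sample(grp)
  study$subject_meta$latent_group[cases] <- grp

  n_lav <- length(lav$index)
  n_shared <- round(config$group_lav_overlap * n_lav)
  shared <- seq_len(n_shared)
  unshared <- setdiff(seq_len(n_lav), shared)
  own <- if (length(unshared))
    split(unshared, rep_len(seq_len(n_grp), length(unshared)))
  else rep(list(integer(0)), n_grp)
  group_lavs <- lapply(seq_len(n_grp), function(gidx)
    lav$index[sort(c(shared, own[[min(gidx, length(own))]]))])

  if (n_grp > 1) {
    for (gidx in seq_len(n_grp)) {
      rows <- cases[grp == gidx]
      foreign <- setdiff(seq_len(n_lav),
                         match(group_lavs[[gidx]], lav$index))
      for (i in foreign) {
        ef <- lav$effects[[i]]
        miss <- is.na(study$genotypes[rows, lav$index[i]])
        gnew <- draw_lav_genotypes(length(rows), ef$model, ef$control)
        gnew[miss] <- NA_integer_
        study$genotypes[rows, lav$index[i]] <- gnew
      }
    }
  }

  surv <- config$survival_params
  surv <- surv[rep_len(seq_len(nrow(surv)), n_grp), , drop = FALSE]
  for (gidx in seq_len(n_grp)) {
    rows <- cases[grp == gidx]
    study$subject_meta$age_years[rows] <-
      rage(length(rows), surv$mean[gidx], surv$sd[gidx], config$case_age_min)
  }
  attr(study, "group_lavs") <- group_lavs
  study
}

#' Read a study configuration from a flat YAML file
#'
#' Keys mirror the arguments of [study_config()]; `survival_params` may be
#' given as parallel lists `survival_mean` and `survival_sd`.
#'
#' @param path path to a YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$survival_mean)) {
    y$survival_params <- data.frame(mean = unlist(y$survival_mean),
                                    sd = unlist(y$survival_sd))
    y$survival_mean <- NULL; y$survival_sd <- NULL
  }
  if (!is.null(y$control_age)) y$control_age <- unlist(y$control_age)
  do.call(study_config, y)
}
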