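#' Run the discovery pipeline end to end
#'
#' Executes the full analysis flow on a study: sample and SNP quality
#' control, LD pruning, principal-component ancestry clustering,
#' ratio-preserving control matching, the four-model Bayes-factor
#' association scan with genomic control, ranking/pruning of candidate
#' SNPs, fitting of the nested naive-Bayes model set, selection of the
#' working model size K*, per-subject risk profiles and the ensemble
#' evaluation, and clustering of case profiles into genetic signatures
#' with survival and ancestry cross-checks.
#'
#' @param config a [study_config()] (a synthetic study is generated from
#'   it), or an existing [genotype_study()].
#' @param qc a [qc_thresholds()].
#' @param n_pcs number of principal components for ancestry clustering.
#' @param k_range,k_restarts ancestry clustering controls (see
#'   [cluster_ancestry()]).
#' @param match should ratio-preserving control matching be applied
#'   (default TRUE)?
#' @param top_k candidate pool size for risk modelling (default 500).
#' @param prune run [prune_correlated()] on the pool (default TRUE).
#' @param select_args list of arguments for [select_k()].
#' @param signature_args list of arguments for [cluster_profiles()].
#' @param seed global seed for the stochastic stages.
#' @param out_dir optional directory; if given, artifact tables and a
#'   run manifest are written as TSVs.
#' @return A list of artifacts: `study` (post-QC, matched), `qc_reports`,
#'   `clustering`, `matching`, `assoc`, `lambda`, `ranked`, `model_set`
#'   (truncated at K*), `k_star`, `traces`, `profiles`, `ensemble`,
#'   `evaluation`, `signatures`, `survival_tests`, `ethnicity_test`.
#' @export
run_discovery <- function(config, qc = qc_thresholds(), n_pcs = 4,
                          k_range = c(2, 10), k_restarts = 5,
                          match = TRUE, top_k = 500, prune = TRUE,
                          select_args = list(), signature_args = list(),
                          seed = 1L, out_dir = NULL) {
  study <- if (inherits(config, "study_config")) {
    st <- generate_study(config)
    if (config$n_signature_groups > 1)
      st <- plant_signature_groups(st, config)
    st
  } else config
  if (!inherits(study, "genotype_study")) stop("invalid input")

  sq <- apply_sample_qc(study, qc)
  vq <- apply_snp_qc(sq$study, qc)
  study <- vq$study

  pruned_ids <- ld_prune(study)
  pcs <- compute_pcs(subset_study(study, snps = pruned_ids),
                     n_components = max(n_pcs, 2))
  clustering <- cluster_ancestry(pcs, k_range = k_range,
                                 n_restarts = k_restarts, seed = seed)

  matching <- NULL
  if (match) {
    sm <- study$subject_meta
    case_ids <- sm$id[sm$phenotype == "EL"]
    pool_ids <- sm$id[sm$phenotype == "AL"]
    matching <- match_controls(clustering, case_ids, pool_ids,
                               target_ratio = length(case_ids) /
                                 length(pool_ids),
                               seed = seed)
    study <- subset_study(study,
                          subjects = c(case_ids, matching$selected))
  }

  assoc <- assoc_scan(study)
  lambda <- genomic_control_lambda(assoc$chi2_allelic)

  ranked <- rank_snps(assoc, top_k = top_k)
  if (prune) ranked <- prune_correlated(ranked, study)
  model_full <- fit_nested(study, ranked)
  prof_full <- risk_profiles(study, model_full)
  labels <- study$subject_meta$phenotype
  traces <- sens_spec_traces(prof_full, labels)
  k_star <- suppressWarnings(do.call(select_k, c(list(traces),
                                                 select_args)))
  model_set <- truncate_model_set(model_full, k_star)
  profiles <- prof_full[, seq_len(k_star), drop = FALSE]
  ens <- ensemble_posterior(profiles)
  evaluation <- evaluate_scores(ens$ensemble, labels)

  case_prof <- profiles[labels == "EL", , drop = FALSE]
  if (is.null(signature_args$max_poly_order))
    signature_args$max_poly_order <- max(0, min(4, k_star - 1))
  signatures <- do.call(cluster_profiles,
                        c(list(case_prof), signature_args,
                          list(seed = seed)))
  surv <- study$subject_meta[, c("id", "age_years", "event_flag")]
  names(surv) <- c("id", "age_years", "event_flag")
  survival_tests <- NULL
  if (!is.null(signatures$clusters) && nrow(signatures$clusters) >= 2) {
    top <- signatures$clusters$id[1]
    bottom <- signatures$clusters$id[nrow(signatures$clusters)]
    survival_tests <- compare_survival(signatures, surv,
                                       rbind(c(top, bottom)))
  }
  ethnicity_test <- tryCatch(
    signature_ethnicity_association(signatures, clustering$assignments),
    error = function(e) NULL)

  artifacts <- list(study = study, qc_reports = list(sample = sq$report,
                                                     snp = vq$report),
                    clustering = clustering, matching = matching,
                    assoc = assoc, lambda = lambda, ranked = ranked,
                    model_set = model_set, k_star = k_star,
                    traces = traces, profiles = profiles, ensemble = ens,
                    evaluation = evaluation, signatures = signatures,
                    survival_tests = survival_tests,
                    ethnicity_test = ethnicity_test)
  if (!is.null(out_dir)) write_artifacts(artifacts, out_dir, seed)
  artifacts
}

truncate_model_set <- function(model_set, k) {
  stopifnot(k >= 1, k <= model_set$K)
  structure(list(snps = model_set$snps[seq_len(k), , drop = FALSE],
                 p_el = model_set$p_el[seq_len(k), , drop = FALSE],
                 p_al = model_set$p_al[seq_len(k), , drop = FALSE],
                 prior = model_set$prior, K = as.integer(k)),
            class = "nested_model_set")
}

write_artifacts <- function(art, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) utils::write.table(
    x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  wt(art$assoc, "association")
  wt(art$traces, "traces")
  wt(data.frame(id = art$ensemble$id, ensemble = art$ensemble$ensemble,
                classification = art$ensemble$classification),
     "ensemble")
  wt(cbind(id = rownames(art$profiles), as.data.frame(art$profiles)),
     "profiles")
  if (!is.null(art$signatures$clusters)) wt(art$signatures$clusters,
                                            "signature_clusters")
  wt(data.frame(id = names(art$signatures$assignments),
                cluster = art$signatures$assignments), "assignments")
  manifest <- c(sprintf("package_version\t%s",
                        as.character(utils::packageVersion("longsig"))),
               sprintf("seed\t%d", seed),
               sprintf("k_star\t%d", art$k_star),
               sprintf("lambda\t%.6f", art$lambda),
               sprintf("n_subjects\t%d", nrow(art$study$genotypes)),
               sprintf("n_snps\t%d", ncol(art$study$genotypes)))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' Evaluate a fitted model set on an independent study
#'
#' Applies the trained ensemble to a replication cohort without refitting:
#' SNPs absent from the replication study are dropped from the nested sets
#' (with a message), posteriors are computed over the intersection, and
#' sensitivity/specificity/AUC are reported, optionally within age strata
#' of the cases.
#'
#' @param model_set fitted [fit_nested()] model set.
#' @param study replication [genotype_study()].
#' @param age_breaks optional age-stratum breaks for case sensitivity.
#' @return list with `report` ([evaluate_scores()]), `profiles`,
#'   `n_snps_used`, `dropped_snps`.
#' @export
run_replication <- function(model_set, study, age_breaks = NULL) {
  present <- model_set$snps$id %in% study$snp_meta$id
  if (!any(present)) stop("no model SNPs present in the replication study")
  if (any(!present))
    message(sprintf("dropping %d model SNP(s) absent from replication set",
                    sum(!present)))
  ms <- structure(list(snps = model_set$snps[present, , drop = FALSE],
                       p_el = model_set$p_el[present, , drop = FALSE],
                       p_al = model_set$p_al[present, , drop = FALSE],
                       prior = model_set$prior, K = sum(present)),
                  class = "nested_model_set")
  profiles <- risk_profiles(study, ms)
  ens <- ensemble_posterior(profiles)
  labels <- study$subject_meta$phenotype
  report <- evaluate_scores(ens$ensemble, labels,
                            age = study$subject_meta$age_years,
                            age_breaks = age_breaks)
  list(report = report, profiles = profiles, n_snps_used = ms$K,
       dropped_snps = model_set$snps$id[!present])
}
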