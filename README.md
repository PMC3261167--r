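# longsig

Bayesian case-control analysis of exceptional longevity: closed-form
Bayes-factor association testing over four genetic models, ancestry-matched
control selection, an ensemble of nested naive-Bayes genetic risk models,
and clustering of per-subject risk profiles into "genetic signatures"
correlated with survival.

## The problem and who this is for

Genome-wide case-control studies of extreme human longevity compare
centenarians (EL, exceptional longevity) with average-longevity controls
(AL). Effect sizes are modest, the phenotype is rare, controls usually come
from external repositories (so population stratification must be removed by
genetic matching), and the interesting biology lives in the *joint* effect
of hundreds of variants rather than in single hits. `longsig` provides the
full chain for this design, aimed at statistical geneticists who want a
reproducible, testable implementation of the Bayesian methodology — and a
synthetic-data generator that emulates the design's statistical structure,
since the original cohorts are not publicly distributable.

## The statistics at the core

For each SNP, a 2 x 3 table of genotype counts n_jk is scored by the
Dirichlet-multinomial Bayes factor

    BF = p(data | H1) / p(data | H0)

where under H1 the case and control rows are independent multinomials with
independent Dirichlet(alpha_jk) priors (alpha_jk = 2 by default), and under
H0 both rows share one multinomial with a Dirichlet prior given by the
column margins alpha_.k = sum_j alpha_jk. Both marginal likelihoods are
closed-form gamma-function ratios, evaluated in log space. Each SNP is
tested under genotypic, allelic, dominant and recessive recodings, and
ranked by the maximum Bayes factor (MBF); the false-positive rate of
"MBF > threshold" is calibrated by null simulation.

The risk model is an ensemble of nested naive-Bayes classifiers: with SNPs
ordered by MBF (after conditional-independence pruning), the k-th model
computes

    p(EL | Sigma_k) = p(EL) prod_i p(g_i|EL) /
                      [ p(EL) prod_i p(g_i|EL) + p(AL) prod_i p(g_i|AL) ]

with prior p(EL) = 0.5 and posterior-mean conditional genotype
probabilities. The vector over k = 1..K is a subject's genetic risk
profile; its mean is the ensemble score. Profiles of cases are clustered by
a conjugate Bayesian polynomial-curve model (order <= 4, per-profile random
intercept/slope) into genetic signatures, whose survival distributions are
compared by log-rank tests.

## Worked example

Simulate a small study with planted longevity-associated variants and two
ancestry subpopulations, then run the whole discovery pipeline:

```r
library(longsig)

cfg <- study_config(n_cases = 200, n_controls = 220, n_snps = 2000,
                    n_lavs = 30, lav_gap = 0.2, missing_rate = 0.005,
                    n_subpops = 2, fst = 0.02, seed = 42)
art <- run_discovery(cfg, top_k = 80, k_range = c(2, 4), seed = 42)

art$study
#> genotype_study: 416 subjects (200 EL / 216 AL) x 1606 SNPs, 0.41% missing
round(art$lambda, 3)
#> [1] 1.048
head(rank_snps(art$assoc, 3))
#>         id   model log10_mbf
#>  snp001547 allelic  22.32312
#>  snp000445 allelic  20.27163
#>  snp001977 allelic  16.94618
art$k_star
#> [1] 23
art$evaluation
#> sensitivity 0.955  specificity 0.912  AUC 0.986
art$signatures
#> signature_clusters: 4 reported cluster(s), 29 sporadic subject(s)
#>   id size avg_posterior stratum
#> 1 C1  109     0.9872367    Blue
#> 2 C2   43     0.9475422     Red
#> 3 C3    8     0.9440525     Red
#> 4 C4   11     0.9217418     Red
```

Reading the output: QC removed SNPs failing the call-rate/HWE/batch rules
(2000 -> 1606); the genomic-control factor 1.05 says the matched set is
essentially free of stratification inflation; the top-ranked SNPs are
planted variants with overwhelming evidence (log10 MBF > 16, i.e. posterior
odds above 10^16); the model-size rule settled on an ensemble of K* = 23
SNPs whose ensemble score separates cases from controls with 95%/91%
sensitivity/specificity on the discovery set; and the case profiles group
into four signatures of decreasing predictive strength (colour strata as
in the published convention: Blue > 0.95, Red 0.5-0.95, Orange 0.2-0.5,
Green <= 0.2), with 29 subjects in rare "sporadic" profiles.

Individual stages are exported and composable: `generate_study`,
`apply_sample_qc` / `apply_snp_qc`, `ld_prune`, `compute_pcs`,
`cluster_ancestry`, `match_controls`, `assoc_scan`,
`simulate_mbf_error_rate`, `rank_snps`, `prune_correlated`, `fit_nested`,
`risk_profiles`, `ensemble_posterior`, `evaluate_scores`, `select_k`,
`resample_validate`, `order_controls`, `cluster_profiles`,
`compare_survival`, `run_replication`, and `read_study` / `write_study`
for VCF, PLINK text, and the internal TSV dialect.

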