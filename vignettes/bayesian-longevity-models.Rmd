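---
title: "Bayesian genetic risk models and signatures of exceptional longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian genetic risk models and signatures of exceptional longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsig)
```

`longsig` implements a complete case-control analysis chain for genetic
studies of exceptional longevity (EL cases, typically centenarians, versus
AL average-longevity controls): quality control, ancestry-matched control
selection, single-SNP Bayesian association testing over four genetic
models, an ensemble of nested naive-Bayes genetic risk models, and
model-based clustering of per-subject risk profiles into "genetic
signatures". Because the cohorts such analyses are built on are not
publicly distributable, the package ships a synthetic-data generator that
emulates their statistical structure; every stage is exercised and tested
against it.

## The single-SNP association model

For one biallelic SNP the data are a 2 x 3 contingency table of genotype
counts $n_{jk}$ (rows: cases $Y=1$, controls $Y=0$; columns: genotypes MM,
Mm, mm, where M is the lexicographically first allele, the TOP-strand
convention of Illumina calling). Under the association hypothesis H1 the
two rows are independent multinomials whose probability vectors carry
independent Dirichlet priors with hyper-parameters $\alpha_{jk}$; under the
no-association hypothesis H0 both rows share one multinomial with a
Dirichlet prior whose hyper-parameters are the column margins
$\alpha_{\cdot k} = \sum_j \alpha_{jk}$. Both marginal likelihoods are
closed-form ratios of gamma functions:

$$p(\mathrm{data}\mid H_1) = \prod_j
  \frac{\Gamma(\alpha_{j\cdot})}{\Gamma(\alpha_{j\cdot}+n_{j\cdot})}
  \prod_k \frac{\Gamma(\alpha_{jk}+n_{jk})}{\Gamma(\alpha_{jk})},
\qquad
p(\mathrm{data}\mid H_0) = \frac{\Gamma(\alpha)}{\Gamma(\alpha+N)}
  \prod_k \frac{\Gamma(\alpha_{\cdot k}+n_{\cdot k})}
               {\Gamma(\alpha_{\cdot k})}.$$

The Bayes factor BF is their ratio; with equal prior probability on the
two hypotheses it equals the posterior odds of association. Everything is
computed in log-gamma space (`lgamma`), so tables with totals up to $10^7$
pose no overflow risk. The default hyper-parameter is $\alpha_{jk} = 2$ in
every cell, hence $\alpha_{\cdot k} = 4$ for the pooled H0 prior. The
closed form is verified in the test suite against a Monte-Carlo
prior-integration oracle (averaging the multinomial likelihood over
Dirichlet draws) and against the hand-computable 2 x 2 table
$[[1,0],[0,1]]$, whose BF is exactly $1.125$.

Four genetic models recode the genotype counts before the BF is applied:
*genotypic* (three columns as counted), *allelic* (allele counts
$2n_{j1}+n_{j2}$ vs $n_{j2}+2n_{j3}$, total $2N$ alleles — an
approximation that treats the two alleles of a subject as independent,
exact only under Hardy-Weinberg equilibrium), *dominant* (MM/Mm vs mm) and
*recessive* (MM vs Mm/mm). The per-SNP significance measure is the
maximum Bayes factor over the four models (MBF); the winning model also
fixes the recoding under which the SNP later enters the risk model.
Frequentist companions (Pearson chi-square without continuity correction,
df = columns − 1, and odds ratios; reference category for the genotypic OR
is the M-homozygote column) and the genomic-control factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ are computed alongside.

### Calibrating the MBF decision rule

Scanning four models inflates type-I error, so the decision rule
"call a SNP significant when MBF exceeds a threshold" is calibrated by
simulation (`simulate_mbf_error_rate`): null datasets of 800 cases and
950 controls, allele frequencies allocated evenly over the grid
0.05, 0.10, ..., 0.50, genotypes multinomial under HWE identically in both
groups, and the fraction of replicates whose MBF crosses the threshold
reported per 100,000 tests with a conjugate Beta interval. The whole
computation is closed-form per replicate and vectorised, so millions of
replicates run in seconds. `scripts/acceptance.R` recomputes these rates
from scratch at two conventional thresholds (MBF > 100, i.e.
$\log_{10}\mathrm{MBF} > 2$, and MBF > 1400).

### Sex conditioning

For candidate SNPs, `gender_conditioned_test` checks whether an apparent
association survives conditioning on sex: within each sex stratum the same
Dirichlet-multinomial machinery scores dependence of genotype on phenotype,
stratum log-BFs add, and a negative conditional log-BF flags the
association as explained away by sex imbalance.

## Quality control

`apply_sample_qc` implements a two-pass call-rate rule: exclude samples
with call rate below 96.5%, then re-admit those at or above 93%. (In the
array-intensity original the second pass follows a re-clustering of
genotype calls; from hard genotype calls the call rate cannot change, so
the rule reduces to a final 93% threshold — a documented simplification.)
`apply_snp_qc` keeps a SNP only if its call rate exceeds 98% overall and
within every batch-by-phenotype stratum, its Hardy-Weinberg chi-square in
controls is below 50 (monomorphic SNPs skip the test and are flagged), its
largest between-batch minor-allele-frequency difference is below 0.2, and
its heterozygosity-excess score lies in $[-0.3, 0.3]$. The published
excess-heterozygosity score is an intensity-based metric that cannot be
reconstructed from genotypes; we use the closest genotype-only analogue,
$\hat F = 1 - \mathrm{het}_{\mathrm{obs}}/\mathrm{het}_{\mathrm{exp}}$.
The intensity-based cluster-separation rule is likewise out of reach from
genotypes and is intentionally absent. Note that with strata of only a few
dozen subjects the strict per-stratum call-rate rule is severe — a single
missing call in a 46-subject stratum already breaks 98% — which is visible
in synthetic runs with small cohorts. Relatedness screening
(`detect_duplicates`) uses genome-wide identity-by-state proportions
computed by matrix algebra, a method-of-moments stand-in for a full IBD
analysis; duplicates surface at IBS = 1.

## Ancestry matching

Stratification control follows the matching strategy: LD-prune SNPs in
sliding windows of 50 SNPs advanced by 5, dropping the later SNP of any
pair with $r^2 > 0.30$; compute principal components of the standardized,
mean-imputed genotype matrix; cluster subjects with k-means over
k = 2..30; and select controls cluster by cluster so the case/control
ratio matches a target. The published clustering score index is described
only qualitatively (assignment accuracy, restart stability, between-cluster
separation), so we define it as *mean silhouette width x mean pairwise
adjusted Rand index across restarts* — a variant, not a reconstruction. On
unstructured data this index is flat in k and low everywhere; it is
informative for choosing k only when structure exists. The per-cluster
control count is $\mathrm{round}(\mathrm{cases}/\mathrm{ratio})$ with ties
rounded toward fewer controls; clusters without cases contribute no
controls; always-kept controls count toward the target before sampling.
`residual_stratification_check` refits each candidate SNP by additive
logistic regression with and without leading principal components and
correlates the two $-\log_{10} p$ vectors. The principal components must
come from a genome-wide panel in which truly associated SNPs are a small
fraction; if the PC panel is dominated by signal SNPs the components absorb
the phenotype contrast and the check is meaningless.

## Nested naive-Bayes risk models

SNPs are ranked by decreasing MBF; the top 500 form the candidate pool.
`prune_correlated` then removes candidates that are conditionally
independent of the phenotype given a more significant SNP: mutual
dependence between SNP pairs is screened with a BIC-approximated posterior
odds (the uniform-prior Dirichlet-multinomial BF systematically
over-detects dependence on skewed genotype margins, so it is not used for
this purpose), at posterior odds 100 for two-way dependence; where
dependence is declared, the candidate's association BF is recomputed
within the genotype strata of the retained SNP (strata under 20 subjects
are skipped) and the candidate is dropped when independence wins. A
candidate fully determined by a retained SNP (perfect LD) is always
dropped. Joint conditioning on two retained SNPs (threshold 10) is
available but off by default, because the sparse 3 x 9 joint tables make
even the BIC screen unreliable at desk-scale sample sizes.

The k-th nested classifier $\Sigma_k$ uses the top k surviving SNPs. Each
SNP contributes its conditional genotype-category probabilities
$\hat p(g \mid EL)$ and $\hat p(g \mid AL)$, estimated as posterior means
$(n_{jk}+\alpha_{jk})/(n_{j\cdot}+\alpha_{j\cdot})$ with $\alpha = 2$
(so no category ever has probability zero), under the SNP's winning
single-SNP recoding. When the allelic model wins, prediction still uses
the three-category genotype table: a subject contributes one genotype, not
two independent alleles. The posterior for a subject is

$$p(EL \mid \Sigma_k) = \frac{p(EL)\prod_i \hat p(g_i \mid EL)}
 {p(EL)\prod_i \hat p(g_i\mid EL) + p(AL)\prod_i \hat p(g_i \mid AL)},$$

with prior $p(EL) = 0.5$, evaluated in log space; missing genotypes
contribute no factor (missing-at-random). At prior one half the MAP
classification reduces to comparing the two likelihood products, so it is
prior-free; ties at posterior exactly 0.5 classify EL, matching the
$\geq$ in the sensitivity definition. The vector
$(p(EL\mid\Sigma_1), \ldots, p(EL\mid\Sigma_K))$ is the subject's genetic
risk profile; it moves up at step $k{+}1$ exactly when the subject's
genotype at the $(k{+}1)$-th SNP is more frequent in cases than controls —
an identity that holds independently of the preceding SNPs and is enforced
as an exact property test. The ensemble score is the arithmetic mean of
the profile and is the subject-level predictor.

The working model size K* is chosen from the sensitivity/specificity
traces: among sizes with accuracy above 0.85, sensitivity-specificity gap
below 0.02, and a flat sensitivity plateau over the next five sizes, the
gap minimiser wins (ties to the smallest k); if nothing qualifies the gap
minimiser is returned with a warning. `resample_validate` repeats
train/test splitting (default 2/3 vs 1/3, stratified, 1000 replicates at
full scale) re-estimating only the conditional tables — the SNP order and
model tags stay fixed, as in the original design. Negative controls
(`order_controls`) either permute the order of the chosen SNPs or replace
them by a random draw from the top 1700 candidates; on planted-signal data
the MBF-ordered ensemble beats both.

## Genetic signatures

Risk profiles of the cases form an N x K array; `cluster_profiles` groups
its rows while preserving the column order, in the spirit of Bayesian
model-based curve clustering. A cluster is modelled as noisy observations
of one shared polynomial curve in $x = (k-1)/(K-1) \in [0,1]$, order
selected up to 4 by the marginal likelihood itself, with conjugate
normal-inverse-gamma priors; two clusters merge when the marginal
likelihood of the shared curve beats the product of the separate ones,
greedy best-gain first, followed by a hierarchical pass over cluster mean
profiles that re-checks the same criterion. This scoring is a faithful
variant of, not a reconstruction of, the published clustering program,
whose exact score lives in its own references. Two model components were
found necessary during development and are documented here:

* **Per-profile random intercept and slope.** Subjects sharing a signature
  shape differ in their overall variant load and in early- versus
  late-ranked loading; under an iid-noise curve model any two subsets with
  slightly different level or tilt refuse to merge and clusters splinter.
  Each profile therefore gets a random offset and tilt
  $u_i \sim N(0, \sigma^2\,\tau^2 I_2)$ with $\tau^2 = 4$
  (`offset_var`). Conjugacy survives via the Woodbury identity and one
  extra additive 2 x 2 sufficient statistic.
* **A noise floor.** Saturated profiles (posterior pinned at 0 or 1)
  collapse the residual variance, after which the marginal likelihood
  resolves scientifically meaningless micro-differences between saturated
  profiles. Profiles are therefore treated as known only to a granularity
  of `noise_floor = 0.02` on the probability scale (the jitter variance is
  added to each profile's second moment). Floors of 0.03 and 0.05 behave
  almost identically; 0.02 is kept.

Clusters smaller than 8 members are pooled into a "sporadic" residual.
Reported clusters are labelled C1, C2, ... by decreasing mean
end-of-profile posterior $p(EL \mid \Sigma_K)$ — the quantity the colour
strata are defined on: Blue above 0.95, Red in $[0.5, 0.95]$, Orange in
$(0.2, 0.5)$, Green at or below 0.2. The published inequalities are open
on both sides and leave the boundaries undefined; here 0.95 and 0.5 fall
to Red and 0.2 to Green. Survival differences between clusters use the
standard two-group log-rank test (`survival::survdiff`) with no
multiplicity adjustment by default (matching the original reporting; a
Bonferroni switch exists). Association between signature clusters and
ancestry clusters is a plain chi-square on their cross-table.

On profiles built from unselected null SNPs the clustering produces many
small clusters and a large sporadic pool, while structured profiles
concentrate in a few large clusters — the qualitative signature of real
versus random profile structure.

## The synthetic-data generator

`study_config`/`generate_study` emulate the discovery design: 801 cases
and 914 controls by default; case ages Normal(104, 3) truncated at 95 and
control ages Normal(75, 7) (the printed cohort moments); biallelic SNPs
with lexicographic allele coding; latent ancestry subpopulations under the
Balding-Nichols model (subpopulation frequencies Beta-distributed around
an ancestral frequency with divergence `fst` — structure is described only
phenomenologically in the source study, and Balding-Nichols is the
standard one-parameter construction); genotyping batches; and genotypes
missing completely at random. Longevity-associated variants (LAVs) are
planted by specifying the conditional genotype or carrier distributions
given phenotype directly — the exact quantities the classifier estimates,
which makes parameter recovery testable; odds ratios are derived, not
specified. The real effect-size distribution is unknown; the default
auto-generated effects use a control frequency uniform on 0.10-0.40 and a
case-control gap of 0.11 in a random direction, echoing the 0.15-versus-
0.26 carrier-prevalence gap of the strongest published longevity variant.
`plant_signature_groups` partitions cases into latent groups, each
enriched only for its own LAV subset (with a configurable shared
fraction), and draws group-specific survival. One caveat discovered during
development: when all groups' variants have equal effect sizes their LAV
sets interleave in MBF rank and the groups' cumulative risk profiles
become exchangeable random walks — the group labels are then not
recoverable from profile shapes by any method. Identifiable signature
structure requires the groups' variant sets to occupy distinguishable rank
bands (e.g. different effect strengths), which is how the recovery tests
configure it.

What the generator does *not* emulate: linkage-disequilibrium haplotype
structure (only explicit duplicated/correlated columns, used to test LD
pruning), X-chromosome dosage, genotype-calling intensity artefacts,
family structure, and real GWAS allele-frequency spectra. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not performance on real arrays.

## Problem sizes and numerical choices

The test suite runs synthetic studies of a few hundred subjects and a few
hundred to a few thousand SNPs, with 10^6 replicates for the calibration
simulation and 10^5-SNP scans for the genomic-control checks; these sizes
give Monte-Carlo errors comfortably below the tolerances asserted while
keeping the default suite under a minute of compute. The acceptance script
uses 8 x 10^6 calibration replicates in batches. Other numerical choices:
Bayes factors and posteriors are computed exclusively in log space;
all-zero contingency tables return log BF 0; monomorphic SNPs skip the
HWE test; pairwise-complete correlations drive LD pruning; principal
components use per-SNP mean imputation; k-means runs three internal starts
per restart; and every stochastic stage takes an explicit seed, making the
pipeline bit-reproducible end to end.

## Limitations

The allelic-model BF treats alleles as independent observations and is
approximate away from HWE. The pruning step is a rank-ordered screen, not
a full Bayesian-network structure search. The ancestry score index and
the profile-clustering score are declared variants of published but
unreproducible procedures. The sex-consistency sample check and
intensity-based SNP filters require raw array data and are absent. At
desk-scale sample sizes the strict per-stratum call-rate rule is
aggressive, and conditional-independence pruning has limited power in
small strata.
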