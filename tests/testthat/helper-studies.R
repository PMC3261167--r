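# Shared fixture builders: all synthetic, constructed in code at test time.

# tiny deterministic study assembled by hand
tiny_study <- function() {
  g <- rbind(c(2L, 1L, 0L, 1L),
             c(1L, 1L, 2L, 0L),
             c(0L, 2L, 1L, 1L),
             c(2L, 0L, 0L, 2L))
  snp_meta <- data.frame(id = paste0("rs", 1:4), chrom = c(1, 1, 2, 2),
                         pos = c(100, 200, 50, 80),
                         allele_M = c("A", "A", "C", "A"),
                         allele_m = c("G", "C", "T", "T"),
                         stringsAsFactors = FALSE)
  subject_meta <- data.frame(id = paste0("s", 1:4),
                             phenotype = c("EL", "EL", "AL", "AL"),
                             age_years = c(104, 101, 76, 73),
                             sex = c("F", "M", "F", "M"),
                             batch = c(1L, 1L, 2L, 2L),
                             stringsAsFactors = FALSE)
  genotype_study(g, snp_meta, subject_meta)
}

# moderate planted-signal study for risk-model tests
planted_study <- function(seed = 11, n_cases = 150, n_controls = 150,
                          n_snps = 300, n_lavs = 30, gap = 0.11,
                          missing_rate = 0.01, ...) {
  generate_study(study_config(n_cases = n_cases, n_controls = n_controls,
                              n_snps = n_snps, n_lavs = n_lavs,
                              lav_gap = gap, missing_rate = missing_rate,
                              seed = seed, ...))
}

null_study <- function(seed = 21, n_cases = 150, n_controls = 150,
                       n_snps = 400, ...) {
  generate_study(study_config(n_cases = n_cases, n_controls = n_controls,
                              n_snps = n_snps, n_lavs = 0,
                              missing_rate = 0, seed = seed, ...))
}

# hand-built nested model set (bypasses fitting; used for closed-form
# posterior checks). likelihoods: list of c(pEL, pAL) pairs for the
# category-1 ("carrier") cell of a dominant recoding.
toy_model_set <- function(likelihood_pairs, prior = 0.5) {
  K <- length(likelihood_pairs)
  p_el <- matrix(NA_real_, K, 3)
  p_al <- matrix(NA_real_, K, 3)
  for (k in seq_len(K)) {
    p_el[k, 1:2] <- c(likelihood_pairs[[k]][1],
                      1 - likelihood_pairs[[k]][1])
    p_al[k, 1:2] <- c(likelihood_pairs[[k]][2],
                      1 - likelihood_pairs[[k]][2])
  }
  structure(list(snps = data.frame(id = paste0("rs", seq_len(K)),
                                   model = "dominant",
                                   log10_mbf = NA_real_,
                                   stringsAsFactors = FALSE),
                 p_el = p_el, p_al = p_al, prior = prior, K = K),
            class = "nested_model_set")
}

# study whose genotypes put every subject in the carrier category of all
# SNPs of a toy model set
carrier_study <- function(model_set, n = 1) {
  K <- model_set$K
  g <- matrix(2L, n, K)
  snp_meta <- data.frame(id = model_set$snps$id,
                         chrom = 1, pos = seq_len(K),
                         allele_M = "A", allele_m = "G",
                         stringsAsFactors = FALSE)
  subject_meta <- data.frame(id = paste0("s", seq_len(n)),
                             phenotype = rep("EL", n),
                             stringsAsFactors = FALSE)
  genotype_study(g, snp_meta, subject_meta)
}

# Monte-Carlo oracle for the Dirichlet-multinomial Bayes factor: average
# multinomial likelihood over prior draws (independent of the closed form)
mc_log10_bf <- function(tab, alpha = 2, n_draws = 20000) {
  k <- ncol(tab)
  rdir <- function(n, a) {
    x <- matrix(stats::rgamma(n * k, shape = a), n, k)
    x / rowSums(x)
  }
  lik_row <- function(theta, counts)
    exp(colSums(t(log(theta)) * counts))
  t1 <- rdir(n_draws, alpha); t2 <- rdir(n_draws, alpha)
  h1 <- lik_row(t1, tab[1, ]) * lik_row(t2, tab[2, ])
  t0 <- rdir(n_draws, 2 * alpha)
  h0 <- lik_row(t0, colSums(tab))
  est <- log10(mean(h1)) - log10(mean(h0))
  se <- sqrt(stats::var(h1) / n_draws) / (mean(h1) * log(10)) +
    sqrt(stats::var(h0) / n_draws) / (mean(h0) * log(10))
  list(log10_bf = est, se = se)
}
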