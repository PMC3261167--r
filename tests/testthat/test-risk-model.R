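test_that("posterior arithmetic matches hand computation", {
  # two SNPs with likelihood pairs (0.8, 0.2) and (0.6, 0.4), prior 0.5:
  # p(EL) = 0.48 / 0.56 = 6/7
  ms <- toy_model_set(list(c(0.8, 0.2), c(0.6, 0.4)))
  st <- carrier_study(ms)
  prof <- risk_profiles(st, ms)
  expect_equal(prof[1, 2], 6 / 7, tolerance = 1e-12)
  expect_equal(posterior_el(stats::setNames(c(2L, 2L), ms$snps$id), ms),
               6 / 7, tolerance = 1e-12)
  # uninformative SNPs leave the posterior at the prior
  ms0 <- toy_model_set(list(c(0.3, 0.3), c(0.7, 0.7)))
  expect_equal(unname(risk_profiles(carrier_study(ms0), ms0)[1, ]),
               c(0.5, 0.5))
  # missing genotype contributes no factor
  expect_equal(posterior_el(stats::setNames(c(2L, NA), ms$snps$id), ms),
               posterior_el(stats::setNames(2L, ms$snps$id[1]),
                            longsig:::truncate_model_set(ms, 1)))
})

test_that("log-space evaluation equals the direct product form", {
  set.seed(901)
  for (rep in 1:20) {
    K <- sample(10:50, 1)
    pe <- stats::runif(K, 0.05, 0.95)
    pa <- stats::runif(K, 0.05, 0.95)
    ms <- toy_model_set(Map(c, pe, pa))
    prof <- risk_profiles(carrier_study(ms), ms)
    direct <- 0.5 * cumprod(pe) /
      (0.5 * cumprod(pe) + 0.5 * cumprod(pa))
    expect_equal(unname(prof[1, ]), direct, tolerance = 1e-12)
  }
})

test_that("profile monotonicity holds exactly: step up iff the genotype is more common in cases", {
  set.seed(902)
  n_checks <- 0
  for (rep in 1:100) {
    K <- 10
    pe <- stats::runif(K, 0.05, 0.95)
    pa <- stats::runif(K, 0.05, 0.95)
    ms <- toy_model_set(Map(c, pe, pa))
    g <- stats::setNames(sample(c(0L, 2L), K, replace = TRUE),
                         ms$snps$id)
    st <- carrier_study(ms)
    st$genotypes[1, ] <- g
    prof <- risk_profiles(st, ms)[1, ]
    for (k in 2:K) {
      cat_k <- if (g[k] == 2L) 1L else 2L
      up <- ms$p_el[k, cat_k] > ms$p_al[k, cat_k]
      expect_identical(unname(prof[k] > prof[k - 1]), unname(up))
      n_checks <- n_checks + 1
    }
  }
  expect_gte(n_checks, 900)
})

test_that("with prior 0.5 the classification is prior-free likelihood comparison", {
  set.seed(903)
  for (rep in 1:50) {
    K <- 8
    pe <- stats::runif(K, 0.1, 0.9); pa <- stats::runif(K, 0.1, 0.9)
    ms <- toy_model_set(Map(c, pe, pa))
    st <- carrier_study(ms)
    post <- risk_profiles(st, ms)[1, K]
    expect_identical(post >= 0.5, prod(pe) >= prod(pa))
  }
})

test_that("fitting recovers planted conditional tables within binomial error", {
  eff <- list(list(model = "dominant", case = 0.15, control = 0.26),
              list(model = "recessive", case = 0.35, control = 0.25),
              list(model = "genotypic", case = c(0.2, 0.5, 0.3),
                   control = c(0.1, 0.4, 0.5)))
  cfg <- study_config(n_cases = 800, n_controls = 900, n_snps = 12,
                      n_lavs = 3, lav_effect = eff, missing_rate = 0,
                      seed = 904)
  st <- generate_study(cfg)
  lav <- attr(st, "lav_info")
  ranked <- data.frame(id = st$snp_meta$id[lav$index],
                       model = c("dominant", "recessive", "genotypic"),
                       stringsAsFactors = FALSE)
  ms <- fit_nested(st, ranked)
  # 4-standard-deviation binomial bounds at these sample sizes
  bound <- function(p, n) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(ms$p_el[1, 1] - 0.15), bound(0.15, 800))
  expect_lt(abs(ms$p_al[1, 1] - 0.26), bound(0.26, 900))
  expect_lt(abs(ms$p_el[2, 1] - 0.35), bound(0.35, 800))
  truth_el <- c(0.2, 0.5, 0.3); truth_al <- c(0.1, 0.4, 0.5)
  expect_true(all(abs(ms$p_el[3, ] - truth_el) < bound(truth_el, 800)))
  expect_true(all(abs(ms$p_al[3, ] - truth_al) < bound(truth_al, 900)))
  expect_lt(mean(abs(ms$p_el[3, ] - truth_el)), 0.03)
  # smoothing: no estimated probability is ever zero
  expect_true(all(ms$p_el[!is.na(ms$p_el)] > 0))
})

test_that("zero-count categories get the smoothed prior estimate", {
  g <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1)
  st <- genotype_study(
    g, data.frame(id = "v1", chrom = 1, pos = 1, allele_M = "A",
                  allele_m = "G"),
    data.frame(id = paste0("s", 1:20),
               phenotype = rep(c("EL", "AL"), each = 10)))
  ms <- fit_nested(st, data.frame(id = "v1", model = "dominant"))
  # cases: 10 carriers, 0 non-carriers -> (0 + 2) / (10 + 4)
  expect_equal(ms$p_el[1, 2], 2 / 14)
  expect_equal(ms$p_el[1, 1], 12 / 14)
})

test_that("ensemble score is the profile mean and ties classify EL", {
  prof <- rbind(a = c(0.2, 0.4, 0.9), b = c(0.7, 0.7, 0.7),
                c = c(0.5, 0.5, 0.5))
  ens <- ensemble_posterior(prof)
  expect_equal(ens$ensemble, c(0.5, 0.7, 0.5))
  expect_equal(ens$classification, c("EL", "EL", "EL"))
  expect_equal(ensemble_posterior(rbind(d = c(0.1, 0.2)))$classification,
               "AL")
})

test_that("evaluation report computes the standard rates", {
  scores <- c(rep(0.9, 89), rep(0.1, 11), rep(0.2, 89), rep(0.8, 11))
  labels <- rep(c("EL", "AL"), each = 100)
  r <- evaluate_scores(scores, labels)
  expect_equal(r$sensitivity, 0.89)
  expect_equal(r$specificity, 0.89)
  expect_equal(unname(r$confusion), c(89, 11, 89, 11))
  # perfect separation
  rp <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2), c("EL", "EL", "AL", "AL"))
  expect_equal(c(rp$sensitivity, rp$specificity, rp$auc), c(1, 1, 1))
  # label-independent scores give AUC ~ 0.5
  set.seed(905)
  rn <- evaluate_scores(stats::runif(4000), rep(c("EL", "AL"), 2000))
  expect_lt(abs(rn$auc - 0.5), 0.03)
  # single-class input: undefined rate is NA
  r1 <- evaluate_scores(c(0.9, 0.2), c("EL", "EL"))
  expect_true(is.na(r1$specificity))
  expect_equal(r1$sensitivity, 0.5)
})

test_that("model-size selection follows the gap/accuracy/plateau rule", {
  K <- 30
  sens <- c(seq(0.5, 0.9, length.out = 10), rep(0.9, 20))
  spec <- c(seq(0.99, 0.91, length.out = 10), rep(0.9, 20))
  tr <- data.frame(k = 1:K, sensitivity = sens, specificity = spec,
                   accuracy = (sens + spec) / 2)
  k <- select_k(tr, tol = 0.02, acc_min = 0.85)
  expect_true(attr(k, "qualified"))
  # k = 11 is the smallest qualifying size with zero sens/spec gap
  expect_equal(as.integer(k), 11)
  # traces never within tolerance: warned fallback to the gap minimiser
  tr2 <- tr; tr2$specificity <- tr2$sensitivity + 0.1
  expect_warning(k2 <- select_k(tr2), "gap minimiser")
  expect_false(attr(k2, "qualified"))
})

test_that("pruning removes duplicates, keeps independent signals, returns a subsequence", {
  eff <- rep(list(list(model = "dominant", case = 0.35, control = 0.15)), 2)
  cfg <- study_config(n_cases = 300, n_controls = 300, n_snps = 40,
                      n_lavs = 2, lav_effect = eff, missing_rate = 0,
                      seed = 906)
  st <- generate_study(cfg)
  a <- assoc_scan(st)
  rk <- rank_snps(a, 20)
  pruned <- prune_correlated(rk, st)
  # structural: pruned list is a subsequence of the input
  expect_true(all(pruned$id %in% rk$id))
  expect_equal(pruned$id, rk$id[rk$id %in% pruned$id])
  # the two independently planted LAVs both survive
  lav_ids <- st$snp_meta$id[attr(st, "lav_info")$index]
  expect_true(all(lav_ids %in% pruned$id))

  # an exact duplicate of the top SNP carries no conditional signal
  g <- st$genotypes
  top_j <- match(rk$id[1], st$snp_meta$id)
  dup_j <- match(rk$id[2], st$snp_meta$id)
  g[, dup_j] <- g[, top_j]
  st2 <- genotype_study(g, st$snp_meta, st$subject_meta)
  rk2 <- rank_snps(assoc_scan(st2), 20)
  pruned2 <- prune_correlated(rk2, st2)
  expect_equal(nrow(pruned2), nrow(rk2) - 1)
  dup_pair <- c(st$snp_meta$id[top_j], st$snp_meta$id[dup_j])
  expect_equal(sum(dup_pair %in% pruned2$id), 1)
})

test_that("resampling validation is degenerate-stable and null-calibrated", {
  # perfectly separable deterministic study: no variance across splits
  g <- matrix(c(rep(2L, 30), rep(0L, 30)), ncol = 1)
  g <- cbind(g, g)
  st <- genotype_study(
    g, data.frame(id = c("v1", "v2"), chrom = 1, pos = 1:2,
                  allele_M = "A", allele_m = "G"),
    data.frame(id = paste0("s", 1:60),
               phenotype = rep(c("EL", "AL"), each = 30)))
  rk <- data.frame(id = c("v1", "v2"), model = "dominant")
  rv <- resample_validate(st, rk, n_reps = 10, seed = 907)
  expect_equal(rv$mean_traces$sensitivity, c(1, 1))
  expect_equal(rv$mean_traces$specificity, c(1, 1))

  # null study with an arbitrary (unselected) SNP list: both rates hover
  # at one half. (Ranking by MBF on the full study before splitting
  # leaks selection into the test halves, so the SNPs are fixed a priori.)
  stn <- null_study(seed = 908, n_cases = 80, n_controls = 80,
                    n_snps = 100)
  rkn <- data.frame(id = stn$snp_meta$id[1:15], model = "genotypic",
                    stringsAsFactors = FALSE)
  rvn <- resample_validate(stn, rkn, n_reps = 20, seed = 909)
  expect_lt(abs(mean(rvn$mean_traces$sensitivity) - 0.5), 0.12)
  expect_lt(abs(mean(rvn$mean_traces$specificity) - 0.5), 0.12)
})

test_that("degenerate negative-control mode reduces to the baseline", {
  # K = 1: any permutation of the SNP order is the identity
  st <- planted_study(seed = 910, n_cases = 60, n_controls = 60,
                      n_snps = 50, n_lavs = 5)
  rk <- rank_snps(assoc_scan(st), 1)
  ms <- fit_nested(st, rk)
  oc <- order_controls(st, ms, "shuffle_top", seed = 911)
  expect_equal(oc$baseline$sensitivity, oc$control$sensitivity)
  expect_equal(oc$baseline$specificity, oc$control$specificity)
  expect_error(order_controls(st, ms, "random_from_top_m"), "ranked_pool")
})

test_that("replication evaluation without refitting is consistent", {
  st <- planted_study(seed = 912, n_cases = 100, n_controls = 100,
                      n_snps = 150, n_lavs = 20)
  rk <- rank_snps(assoc_scan(st), 30)
  ms <- fit_nested(st, rk)
  prof <- risk_profiles(st, ms)
  base <- evaluate_scores(ensemble_posterior(prof)$ensemble,
                          st$subject_meta$phenotype)
  rep1 <- run_replication(ms, st)
  expect_equal(rep1$report$sensitivity, base$sensitivity)
  expect_equal(rep1$report$auc, base$auc)
  # missing SNPs are dropped with a message
  st2 <- subset_study(st, snps = which(!st$snp_meta$id %in% rk$id[1:5]))
  expect_message(rep2 <- run_replication(ms, st2), "dropping 5")
  expect_equal(rep2$n_snps_used, 25)
  expect_error(run_replication(ms, subset_study(st2, snps = 1:3)),
               "no model SNPs")
})
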