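test_that("LD pruning drops one of a perfectly correlated pair and spares the rest", {
  st <- null_study(seed = 71, n_cases = 250, n_controls = 250,
                   n_snps = 100)
  g <- st$genotypes
  g[, 10] <- g[, 9]  # duplicated SNP column, r^2 = 1, same window
  st2 <- genotype_study(g, st$snp_meta, st$subject_meta)
  kept <- ld_prune(st2)
  expect_true(xor(st$snp_meta$id[9] %in% kept,
                  st$snp_meta$id[10] %in% kept))
  # independent SNPs at n = 500: nothing else pruned
  expect_equal(length(kept), 99)
  kept0 <- ld_prune(st)
  expect_equal(length(kept0), 100)
})

test_that("pairs at r^2 just below the threshold are both kept", {
  set.seed(72)
  n <- 400
  g1 <- stats::rbinom(n, 2, 0.5)
  g2 <- g1
  flip <- sample(n, 190)  # degrade correlation to just under 0.30
  g2[flip] <- stats::rbinom(190, 2, 0.5)
  r2 <- stats::cor(g1, g2)^2
  expect_lt(r2, 0.30); expect_gt(r2, 0.20)
  st <- genotype_study(
    cbind(g1, g2),
    data.frame(id = c("a", "b"), chrom = 1, pos = 1:2,
               allele_M = "A", allele_m = "G"),
    data.frame(id = paste0("s", 1:n),
               phenotype = rep(c("EL", "AL"), n / 2)))
  expect_setequal(ld_prune(st), c("a", "b"))
})

test_that("principal components capture planted population structure", {
  st <- generate_study(study_config(n_cases = 200, n_controls = 200,
                                    n_snps = 3000, n_lavs = 0,
                                    n_subpops = 2, fst = 0.1,
                                    missing_rate = 0.01, seed = 73))
  pcs <- compute_pcs(st, 4)
  km <- stats::kmeans(pcs[, 1], 2, nstart = 5)
  agree <- mean(km$cluster == st$subject_meta$subpop)
  expect_gt(max(agree, 1 - agree), 0.95)
  # identical subjects give all-zero scores
  g <- matrix(1L, 10, 20)
  st0 <- genotype_study(
    g, data.frame(id = paste0("v", 1:20), chrom = 1, pos = 1:20,
                  allele_M = "A", allele_m = "G"),
    data.frame(id = paste0("s", 1:10),
               phenotype = rep(c("EL", "AL"), 5)))
  expect_error(compute_pcs(st0, 25), "fewer SNPs")
  expect_equal(max(abs(compute_pcs(st0, 2))), 0)
})

test_that("a structure-free study has no dominant principal axis", {
  st <- null_study(seed = 74, n_cases = 150, n_controls = 150,
                   n_snps = 1500)
  pcs <- compute_pcs(st, 10)
  sdev <- attr(pcs, "sdev")
  # leading eigenvalue close to the bulk (no separation), in contrast to
  # the structured case where PC1 dwarfs PC2
  expect_lt(sdev[1] / sdev[2], 1.1)
})

test_that("ancestry clustering recovers separated groups and scores degeneracy", {
  set.seed(75)
  blobs <- rbind(matrix(stats::rnorm(120, 0), 60, 2),
                 matrix(stats::rnorm(120, 6), 60, 2),
                 cbind(stats::rnorm(60, 12), stats::rnorm(60, 0)))
  rownames(blobs) <- paste0("s", 1:180)
  cl <- cluster_ancestry(blobs, k_range = c(2, 6), n_restarts = 5,
                         seed = 75)
  expect_equal(cl$k, 3)
  truth <- rep(1:3, each = 60)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1)

  # a single blob: every k scores poorly and far below separated blobs,
  # with no strongly preferred cluster count
  one <- matrix(stats::rnorm(300), 150, 2)
  rownames(one) <- paste0("s", 1:150)
  cl1 <- cluster_ancestry(one, k_range = c(2, 5), n_restarts = 10,
                          seed = 76)
  expect_lt(max(cl1$score_index$score), 0.5)
  expect_lt(max(cl1$score_index$score),
            min(0.7, max(cl$score_index$score)))
  expect_error(cluster_ancestry(blobs[1:2, ], k_range = c(5, 10)),
               "infeasible")
})

test_that("control matching reproduces the ratio-preserving arithmetic", {
  # cluster A: 21 cases + 20 fixed controls at target 0.88 -> sample 4
  # more (21/24 = 0.875); cluster B: 31 cases + 16 fixed -> sample 19
  # (31/35 = 0.886); cluster C: no cases -> no controls
  assign <- c(rep("A", 21 + 20 + 50), rep("B", 31 + 16 + 50),
              rep("C", 30))
  ids <- paste0("s", seq_along(assign))
  names(assign) <- ids
  a_ids <- ids[assign == "A"]; b_ids <- ids[assign == "B"]
  c_ids <- ids[assign == "C"]
  cases <- c(a_ids[1:21], b_ids[1:31])
  fixed <- c(a_ids[22:41], b_ids[32:47])
  pool <- c(a_ids[42:91], b_ids[48:97], c_ids)
  m <- match_controls(assign, cases, pool, fixed_control_ids = fixed,
                      target_ratio = 0.88, seed = 77)
  pc <- m$per_cluster
  expect_equal(pc$sampled[pc$cluster == "A"], 4)
  expect_equal(pc$controls[pc$cluster == "A"], 24)
  expect_equal(pc$ratio[pc$cluster == "A"], 21 / 24)
  expect_equal(pc$sampled[pc$cluster == "B"], 19)
  expect_equal(pc$ratio[pc$cluster == "B"], 31 / 35)
  expect_equal(pc$controls[pc$cluster == "C"], 0)
  expect_false(any(m$selected %in% c_ids))

  # exhausted pool: best achievable ratio with a warning
  w <- testthat::capture_warnings(
    m2 <- match_controls(assign, cases, pool[1:5],
                         fixed_control_ids = NULL,
                         target_ratio = 0.88, seed = 78))
  expect_true(any(grepl("exhausted", w)))
  expect_lte(m2$per_cluster$controls[1], 5)
})

test_that("ancestry matching restores a null genomic control factor", {
  # stratification confounding: subpopulations at fst 0.08 with cases
  # drawn overwhelmingly from subpopulation 1
  cfg <- study_config(n_cases = 150, n_controls = 300, n_snps = 1200,
                      n_lavs = 0, n_subpops = 2, fst = 0.08,
                      subpop_case_bias = c(0.9, 0.1),
                      missing_rate = 0, seed = 79)
  st <- generate_study(cfg)
  lam_before <- genomic_control_lambda(assoc_scan(st)$chi2_allelic)
  expect_gt(lam_before, 1.2)

  pcs <- compute_pcs(st, 4)
  cl <- cluster_ancestry(pcs, k_range = c(2, 4), n_restarts = 5,
                         seed = 79)
  sm <- st$subject_meta
  cases <- sm$id[sm$phenotype == "EL"]
  pool <- sm$id[sm$phenotype == "AL"]
  m <- suppressWarnings(
    match_controls(cl, cases, pool, target_ratio = 0.9, seed = 79))
  matched <- subset_study(st, subjects = c(cases, m$selected))
  lam_after <- genomic_control_lambda(assoc_scan(matched)$chi2_allelic)
  expect_lt(lam_after, lam_before)
  expect_lt(abs(lam_after - 1), 0.12)
})

test_that("principal-component adjustment flags only confounded designs", {
  # PCs from a genome-wide-like panel where signal SNPs are a small
  # fraction; associations of the top-ranked SNPs barely move under
  # adjustment when no structure is planted
  st <- generate_study(study_config(n_cases = 150, n_controls = 150,
                                    n_snps = 2000, n_lavs = 30,
                                    missing_rate = 0, seed = 80))
  pcs <- compute_pcs(st, 4)
  top <- rank_snps(assoc_scan(st), 60)$id
  r <- residual_stratification_check(st, top, pcs)
  expect_gt(r$correlation, 0.9)

  # strong unmatched structure linked to phenotype: correlation collapses
  cfg <- study_config(n_cases = 150, n_controls = 150, n_snps = 2000,
                      n_lavs = 30, n_subpops = 2, fst = 0.15,
                      subpop_case_bias = c(0.9, 0.1),
                      missing_rate = 0, seed = 81)
  stc <- generate_study(cfg)
  pcs2 <- compute_pcs(stc, 4)
  top2 <- rank_snps(assoc_scan(stc), 60)$id
  r2 <- residual_stratification_check(stc, top2, pcs2)
  expect_lt(r2$correlation, 0.5)
  expect_lt(r2$correlation, r$correlation)
  expect_error(residual_stratification_check(st, character(0), pcs),
               "no SNPs")
})
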