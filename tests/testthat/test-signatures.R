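make_profiles <- function(shapes, n_each, noise = 0.05, K = 30,
                          seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(shapes), function(i) {
    base <- shapes[[i]](seq(0, 1, length.out = K))
    t(replicate(n_each[i],
                pmin(pmax(base + stats::rnorm(K, 0, noise), 0), 1)))
  }))
  rownames(out) <- paste0("s", seq_len(nrow(out)))
  out
}

test_that("identical profiles collapse to a single cluster", {
  prof <- matrix(rep(seq(0.2, 0.8, length.out = 20), each = 30), 30, 20)
  rownames(prof) <- paste0("s", 1:30)
  cl <- cluster_profiles(prof)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 30)
  expect_equal(cl$n_sporadic, 0)
})

test_that("two planted profile shapes are recovered exactly", {
  prof <- make_profiles(
    list(function(x) stats::plogis(-2 + 5 * x), function(x) rep(0.1, length(x))),
    c(50, 50), seed = 2)
  cl <- cluster_profiles(prof)
  # the greedy merge may shave a planted group into a satellite cluster,
  # so recovery is asserted by adjusted Rand index, not exact count
  expect_lte(nrow(cl$clusters), 3)
  truth <- rep(1:2, each = 50)
  expect_gt(mclust::adjustedRandIndex(cl$assignments, truth), 0.8)
  # rising shape ends high -> first (most predictive) cluster
  expect_gt(cl$clusters$avg_posterior[1], 0.8)
  expect_lt(cl$clusters$avg_posterior[nrow(cl$clusters)], 0.2)
  expect_equal(cl$clusters$stratum[1], "Red")
  expect_equal(cl$clusters$stratum[nrow(cl$clusters)], "Green")
})

test_that("clustering is invariant to subject order", {
  prof <- make_profiles(
    list(function(x) 0.2 + 0.6 * x, function(x) 0.8 - 0.6 * x,
         function(x) rep(0.5, length(x))),
    c(20, 20, 20), seed = 3)
  cl1 <- cluster_profiles(prof)
  perm <- sample(nrow(prof))
  cl2 <- cluster_profiles(prof[perm, ], seed = 1)
  expect_equal(
    mclust::adjustedRandIndex(cl1$assignments[rownames(prof)],
                              cl2$assignments[rownames(prof)]), 1)
})

test_that("reported and sporadic subjects partition the input", {
  prof <- make_profiles(
    list(function(x) 0.9 * x, function(x) rep(0.5, length(x))),
    c(40, 5), noise = 0.08, seed = 4)
  cl <- cluster_profiles(prof, min_report_size = 8)
  n_rep <- sum(cl$assignments != "sporadic")
  expect_equal(n_rep + cl$n_sporadic, nrow(prof))
  expect_true(all(cl$clusters$size >= 8))
})

test_that("unstructured noise profiles yield mostly small clusters", {
  set.seed(5)
  noise <- matrix(stats::runif(60 * 30, 0.3, 0.7), 60, 30)
  rownames(noise) <- paste0("n", 1:60)
  cl_noise <- cluster_profiles(noise)
  frac_noise <- 1 - cl_noise$n_sporadic / 60

  structured <- make_profiles(
    list(function(x) stats::plogis(-2 + 5 * x),
         function(x) rep(0.15, length(x)), function(x) 0.6 - 0.3 * x),
    c(20, 20, 20), seed = 6)
  cl_str <- cluster_profiles(structured)
  frac_str <- 1 - cl_str$n_sporadic / 60
  expect_gt(frac_str, 0.9)
  expect_lt(frac_noise, frac_str)
})

test_that("stratum labels follow the posterior thresholds", {
  expect_equal(stratum_label(c(0.97, 0.6, 0.3, 0.1)),
               c("Blue", "Red", "Orange", "Green"))
  # boundary decisions: 0.95 and 0.5 fall to Red, 0.2 to Green
  expect_equal(stratum_label(c(0.95, 0.5, 0.2)),
               c("Red", "Red", "Green"))
  expect_error(stratum_label(1.2), "0, 1")
})

test_that("log-rank comparison detects planted survival shifts", {
  prof <- make_profiles(
    list(function(x) stats::plogis(-2 + 5 * x), function(x) rep(0.1, length(x))),
    c(90, 28), seed = 7)
  cl <- cluster_profiles(prof)
  expect_gte(nrow(cl$clusters), 2)

  # identical survival: statistic ~ 0
  rec_same <- data.frame(id = rownames(prof),
                         age_years = rep(c(100, 103, 106), length.out = 118),
                         event_flag = 1L)
  r0 <- compare_survival(cl, rec_same, cbind("C1", "C2"))
  expect_gt(r0$p_value, 0.5)

  # planted medians 105 vs 103 (sd 3): majority detection over replicates
  hits <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    ages <- ifelse(cl$assignments[rownames(prof)] == "C1",
                   stats::rnorm(118, 105, 3), stats::rnorm(118, 103, 3))
    rec <- data.frame(id = rownames(prof), age_years = ages,
                      event_flag = 1L)
    r <- compare_survival(cl, rec, cbind("C1", "C2"))
    hits <- hits + (r$p_value < 0.05)
  }
  expect_gte(hits, 6)

  # oracle cross-check of the statistic against survival::survdiff
  rec <- data.frame(id = rownames(prof),
                    age_years = stats::rnorm(118, 104, 3),
                    event_flag = rep(c(1L, 0L), length.out = 118))
  r <- compare_survival(cl, rec, cbind("C1", "C2"))
  mem <- cl$assignments[rownames(prof)] %in% c("C1", "C2")
  sd0 <- survival::survdiff(
    survival::Surv(rec$age_years[mem], rec$event_flag[mem]) ~
      cl$assignments[rownames(prof)][mem])
  expect_equal(r$chisq, sd0$chisq)

  # single-member group is rejected
  cl_bad <- cl
  cl_bad$members$C2 <- cl_bad$members$C2[1]
  expect_error(compare_survival(cl_bad, rec, cbind("C1", "C2")),
               "at least 2")
})

test_that("signature-ethnicity association distinguishes planted confounding", {
  prof <- make_profiles(
    list(function(x) 0.8 * x, function(x) rep(0.2, length(x))),
    c(40, 40), seed = 8)
  cl <- cluster_profiles(prof)
  ids <- rownames(prof)
  # identical partition: association is overwhelming
  anc_same <- stats::setNames(
    as.integer(factor(cl$assignments[ids])), ids)
  r1 <- signature_ethnicity_association(cl, anc_same)
  expect_lt(r1$p_value, 1e-10)
  # independent partition: no association
  set.seed(9)
  anc_rand <- stats::setNames(sample(1:3, 80, replace = TRUE), ids)
  r2 <- signature_ethnicity_association(cl, anc_rand)
  expect_gt(r2$p_value, 0.001)
  # degenerate single-level partition errors
  expect_error(
    signature_ethnicity_association(cl, stats::setNames(rep(1, 80), ids)),
    "degenerate")
})

test_that("signature summaries tabulate stratum fractions per cohort", {
  prof_hi <- matrix(0.98, 20, 10)
  rownames(prof_hi) <- paste0("h", 1:20)
  cl <- cluster_profiles(prof_hi, max_poly_order = 3)
  s1 <- signature_summary(cl, prof_hi)
  expect_equal(s1$fraction[s1$stratum == "Blue"], 1)

  prof_lo <- matrix(0.1, 15, 10)
  rownames(prof_lo) <- paste0("l", 1:15)
  s2 <- signature_summary(cl, prof_hi, prof_lo)
  ctrl <- s2[s2$cohort == "controls", ]
  expect_equal(ctrl$fraction[ctrl$stratum == "Green"], 1)
  expect_equal(ctrl$fraction[ctrl$stratum == "Blue"], 0)
  # empty control set: case-only summary
  expect_equal(unique(signature_summary(cl, prof_hi,
                                        prof_hi[0, ])$cohort), "cases")
})
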