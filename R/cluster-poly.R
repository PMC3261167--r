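# Conjugate Bayesian polynomial regression marginal likelihoods used as the
# merge score for clustering genetic risk profiles.
#
# Each cluster of profiles (rows of an N x K array, columns ordered by model
# size k) is modelled as noisy observations of one shared polynomial curve
# in x = (k-1)/(K-1), rescaled to [0,1], with order selected up to
# `max_order` by the marginal likelihood itself:
#
#   y_i = X beta + Z u_i + e_i,   u_i ~ N(0, sigma^2 T),
#                                 e_i ~ N(0, sigma^2 I)
#
# where Z = [1, x] gives every profile a random vertical offset and tilt
# around the cluster curve (T = tau2 * I2). Subjects sharing a signature
# shape differ in how many of its variants they carry overall and in how
# the early- versus late-ranked variants are loaded; without the random
# intercept/slope any two subsets with slightly different level or tilt
# refuse to merge and clusters splinter. The prior on the curve is
# normal-inverse-gamma: beta ~ N(m0, sigma^2 g I), sigma^2 ~ IG(a0, b0),
# with m0 = (0.5, 0, ...) (prior curve at the uninformative posterior) and
# g = 4 (weak), a0 = 2, b0 = 0.02 (prior residual sd ~ 0.14), tau2 = 4
# (offset/tilt sd twice the residual sd). Profiles are treated as known
# only to a granularity `noise_floor` (default sd 0.02 on the probability
# scale): the corresponding jitter variance is added to each profile's
# second moment. Risk profiles saturate near 0 or 1, where the residual
# variance collapses and the marginal likelihood would otherwise resolve
# scientifically meaningless micro-differences between saturated
# profiles.
#
# All profiles share the abscissae, so by the Woodbury identity a cluster
# is summarised by additive sufficient statistics: member count m, B'ysum,
# sum y^2, and S = sum_i (Z'y_i)(Z'y_i)' (a symmetric 2x2). Merge scores
# then cost one small triangular solve per polynomial order.

poly_engine <- function(K, max_order = 4, g = 4, a0 = 2, b0 = 0.02,
                        noise_floor = 0.02, tau2 = 4) {
  if (K < max_order + 1)
    stop("profiles must have length at least max_poly_order + 1")
  x <- (seq_len(K) - 1) / max(1, K - 1)
  basis <- outer(x, 0:max_order, `^`)
  Z <- basis[, 1:2, drop = FALSE]
  W <- solve(diag(1 / tau2, 2) + crossprod(Z))
  # per-profile log-determinant of (I + Z T Z')
  logdet_prof <- determinant(diag(1 / tau2, 2) + crossprod(Z),
                             logarithm = TRUE)$modulus[1] + 2 * log(tau2)
  pre <- lapply(0:max_order, function(d) {
    P <- d + 1
    B <- basis[, seq_len(P), drop = FALSE]
    XtZ <- crossprod(B, Z)                       # P x 2
    v0inv <- diag(1 / g, P)
    m0 <- c(0.5, rep(0, P - 1))
    list(P = P, A = crossprod(B) - XtZ %*% W %*% t(XtZ),
         proj = XtZ %*% W,                       # P x 2
         v0inv = v0inv, c0 = drop(v0inv %*% m0),
         q0 = drop(crossprod(m0, v0inv %*% m0)),
         logdet_v0 = P * log(g))
  })
  env <- new.env(parent = emptyenv())  # Cholesky cache keyed by (order, m)
  list(K = K, basis = basis, pre = pre, a0 = a0, b0 = b0, W = W,
       jitter = K * noise_floor^2, logdet_prof = logdet_prof, cache = env)
}

# cluster sufficient statistics from a profile matrix (rows = members);
# S is stored as the 3-vector (S11, S12, S22)
poly_stats_matrix <- function(eng, profiles) {
  zt <- profiles %*% eng$basis[, 1:2]            # n x 2, rows z_i'
  list(m = rep(1L, nrow(profiles)),
       bty = crossprod(eng$basis, t(profiles)),  # (order+1) x n
       syy = rowSums(profiles^2) + eng$jitter,
       sz = rbind(zt[, 1]^2, zt[, 1] * zt[, 2], zt[, 2]^2))
}

chol_for <- function(eng, d_i, m) {
  key <- paste0(d_i, ".", m)
  got <- eng$cache[[key]]
  if (!is.null(got)) return(got)
  pe <- eng$pre[[d_i]]
  r <- chol(pe$v0inv + m * pe$A)
  out <- list(r = r, logdet_vn = -2 * sum(log(diag(r))))
  assign(key, out, envir = eng$cache)
  out
}

# log marginal likelihood of clusters sharing one member count m; bty may
# have one column per cluster, sz the matching 3-row statistic
poly_logml <- function(eng, m, bty, syy, sz) {
  bty <- cbind(bty); sz <- cbind(sz)
  n <- m * eng$K
  an <- eng$a0 + n / 2
  w <- eng$W
  tr_wsz <- w[1, 1] * sz[1, ] + 2 * w[1, 2] * sz[2, ] + w[2, 2] * sz[3, ]
  best <- rep(-Inf, ncol(bty))
  for (d_i in seq_along(eng$pre)) {
    pe <- eng$pre[[d_i]]
    ch <- chol_for(eng, d_i, m)
    u <- pe$c0 + bty[seq_len(pe$P), , drop = FALSE] -
      pe$proj %*% bty[1:2, , drop = FALSE]
    z <- backsolve(ch$r, u, transpose = TRUE)
    quad <- colSums(z^2)
    bn <- eng$b0 + 0.5 * (syy - tr_wsz + pe$q0 - quad)
    lm <- -n / 2 * log(2 * pi) - m / 2 * eng$logdet_prof +
      0.5 * (ch$logdet_vn - pe$logdet_v0) +
      eng$a0 * log(eng$b0) - an * log(bn) + lgamma(an) - lgamma(eng$a0)
    best <- pmax(best, lm)
  }
  best
}

# merge gains of cluster i against clusters js (vectorised; groups js by
# member count so each group shares one Cholesky factor)
poly_merge_delta <- function(eng, stats, i, js) {
  delta <- numeric(length(js))
  m_i <- stats$m[i]
  for (mj in unique(stats$m[js])) {
    sel <- which(stats$m[js] == mj)
    jj <- js[sel]
    bty <- stats$bty[, jj, drop = FALSE] + stats$bty[, i]
    syy <- stats$syy[jj] + stats$syy[i]
    sz <- stats$sz[, jj, drop = FALSE] + stats$sz[, i]
    merged <- poly_logml(eng, m_i + mj, bty, syy, sz)
    delta[sel] <- merged - stats$score[i] - stats$score[jj]
  }
  delta
}
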