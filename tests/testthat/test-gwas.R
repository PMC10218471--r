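test_that("de-regression solves the two-equation mixed-model system", {
  h2 <- 0.3; c_frac <- 0.1
  lambda <- (1 - h2) / h2
  for (case in list(c(ebv = 1.2, rel = 0.8, pa = 0.4, pa_rel = 0.2),
                    c(ebv = -0.7, rel = 0.55, pa = 0.1, pa_rel = 0.05),
                    c(ebv = 2.0, rel = 0.95, pa = -0.3, pa_rel = 0.3))) {
    d <- deregress_ebv(case["ebv"], case["rel"], case["pa"],
                       case["pa_rel"], h2 = h2, c_frac = c_frac)
    # oracle: build the 2x2 left-hand side explicitly and multiply through
    alpha <- 1 / (0.5 - case["pa_rel"])
    delta <- (0.5 - case["pa_rel"]) / (1 - case["rel"])
    zpz_pa <- lambda * (0.5 * alpha - 1)
    zpz_i <- delta * zpz_pa + 2 * lambda * (2 * delta - 1)
    lhs <- matrix(c(zpz_pa + 4 * lambda, -2 * lambda,
                    -2 * lambda, zpz_i + 2 * lambda), 2, byrow = TRUE)
    rhs <- lhs %*% c(case["pa"], case["ebv"])
    expect_equal(d$debv, unname(rhs[2] / zpz_i), tolerance = 1e-12)
  }
})

test_that("de-regressed value tends to ebv/rel as parent information vanishes", {
  d <- deregress_ebv(1.5, rel = 0.6, pa_ebv = 0, pa_rel = 1e-6, h2 = 0.3)
  expect_equal(d$debv, 1.5 / 0.6, tolerance = 1e-4)
})

test_that("forward blending round-trips EBV and reliability", {
  set.seed(7)
  n <- 50
  ebv <- rnorm(n); rel <- runif(n, 0.4, 0.9)
  pa_ebv <- rnorm(n, 0, 0.5); pa_rel <- runif(n, 0.05, 0.3)
  d <- deregress_ebv(ebv, rel, pa_ebv, pa_rel, h2 = 0.25, c_frac = 0.2)
  back <- blend_debv(d$debv, d$weight, pa_ebv, pa_rel, h2 = 0.25,
                     c_frac = 0.2)
  expect_equal(back$ebv, ebv, tolerance = 1e-8)
  expect_equal(back$rel, rel, tolerance = 1e-8)
})

test_that("weights shrink as the marker-uncaptured fraction grows", {
  w0 <- deregress_ebv(1, 0.8, 0, 0.2, c_frac = 0)$weight
  w5 <- deregress_ebv(1, 0.8, 0, 0.2, c_frac = 0.5)$weight
  expect_gt(w0, w5)
  expect_error(deregress_ebv(1, rel = 0.1, pa_rel = 0.2),
               "own information")
})

test_that("de-regressed values regress on true breeding values with slope 1", {
  cfg <- pop_sim_config(samples_per_pop = 500, n_loci = 600, seed = 41)
  g <- simulate_populations(cfg)
  bv <- simulate_breeding_values(
    g, breeding_sim_config(h2 = 0.4, n_causal = 150,
                           reliability_range = c(0.8, 0.8), seed = 42))
  d <- deregress_ebv(bv$ebv_table$ebv, bv$ebv_table$rel,
                     bv$ebv_table$pa_ebv, bv$ebv_table$pa_rel, h2 = 0.4)
  slope <- coef(lm(d$debv ~ bv$tbv))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("GRM has clone, HWE-diagonal and positive-definiteness properties", {
  set.seed(19)
  n <- 40; m <- 10000
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
  calls[1, ] <- calls[2, ]  # duplicated sample
  g <- toy_geno(calls)
  G <- build_grm(g)
  expect_equal(G[1, -(1:2)], G[2, -(1:2)], tolerance = 1e-12)
  expect_equal(G[1, 1], G[2, 2], tolerance = 1e-12)
  expect_equal(G[1, 2], G[1, 1] - 1e-6, tolerance = 1e-9)  # off-diag = diag - ridge
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  expect_identical(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  mono <- toy_geno(matrix(2L, 4, 5))
  expect_error(build_grm(mono), "monomorphic")
})

test_that("REML matches a dense matrix-formula oracle", {
  set.seed(29)
  n <- 80; m <- 200
  calls <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.8), each = n)), n)
  g <- toy_geno(calls)
  G <- build_grm(g)
  y <- as.vector(t(chol(G + diag(1e-6, n))) %*% rnorm(n)) + rnorm(n, 0, 0.7)
  fit <- fit_null_reml(y, G)
  X <- matrix(1, n, 1)
  dense_neg2 <- function(lam) {
    V <- G + diag(lam, n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    S <- as.numeric(t(r) %*% Vi %*% r)
    (n - 1) * log(S / (n - 1)) + determinant(V)$modulus[1] +
      determinant(XtViX)$modulus[1]
  }
  dense_opt <- optimize(function(l) dense_neg2(exp(l)), c(-12, 12))
  expect_equal(log(fit$lambda), dense_opt$minimum, tolerance = 1e-4)
  expect_equal(-2 * fit$loglik, dense_opt$objective, tolerance = 1e-6)
})

test_that("REML with an identity relationship splits the total variance", {
  set.seed(37)
  n <- 120
  y <- rnorm(n, 5, 2)
  fit <- fit_null_reml(y, diag(n))
  # likelihood is flat in the split; the identified total equals var(y)
  expect_equal(fit$sigma_a2 + fit$sigma_e2, var(y), tolerance = 1e-6)
})

test_that("REML recovers a planted variance ratio and vanishes under the null", {
  set.seed(47)
  n <- 500; m <- 300
  calls <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n)
  G <- build_grm(toy_geno(calls))
  L <- t(chol(G + diag(1e-6, n)))
  h2_hat <- sapply(1:3, function(i) {
    y <- as.vector(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
    fit_null_reml(y, G)$h2
  })
  expect_lt(abs(median(h2_hat) - 0.5), 0.1)
  null_hat <- sapply(1:5, function(i) fit_null_reml(rnorm(n), G)$h2)
  expect_lt(median(null_hat), 0.05)
})

test_that("scan equals ordinary least squares when G = I and ratio vanishes", {
  set.seed(57)
  n <- 150; m <- 60
  calls <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.8), each = n)), n)
  g <- toy_geno(calls)
  y <- rnorm(n)
  null <- fit_null_reml(y, diag(n))
  scan <- single_marker_scan(y, g, null)
  for (j in sample(m, 10)) {
    sm <- summary(lm(y ~ calls[, j]))$coefficients
    p_ols <- 2 * pnorm(-abs(sm[2, "t value"]))
    expect_equal(scan$beta[j], unname(sm[2, "Estimate"]), tolerance = 1e-8)
    expect_equal(scan$p[j], p_ols, tolerance = 1e-8)
  }
})

test_that("scan p-values are invariant to consistent sample permutation", {
  cfg <- pop_sim_config(samples_per_pop = 40, n_loci = 300, seed = 67)
  g <- simulate_populations(cfg)
  set.seed(68)
  y <- rnorm(n_samples(g))
  G <- build_grm(g)
  s1 <- single_marker_scan(y, g, fit_null_reml(y, G))
  perm <- sample(n_samples(g))
  gp <- subset_geno(g, samples = perm)
  s2 <- single_marker_scan(y[perm], gp,
                           fit_null_reml(y[perm], G[perm, perm]))
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
})

test_that("equal weights reproduce the unweighted fit, and monomorphics flag", {
  cfg <- pop_sim_config(samples_per_pop = 30, n_loci = 200, seed = 77)
  g <- simulate_populations(cfg)
  set.seed(78)
  y <- rnorm(n_samples(g))
  G <- build_grm(g)
  f1 <- fit_null_reml(y, G)
  f2 <- fit_null_reml(y, G, weights = rep(3.7, length(y)))
  expect_equal(f1$sigma_a2, f2$sigma_a2, tolerance = 1e-10)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)

  g$calls[, 5] <- 1L  # force a monomorphic marker
  s <- single_marker_scan(y, g, f1)
  expect_true(s$monomorphic[5])
  expect_equal(s$p[5], 1)
})

test_that("mixed model absorbs structure that inflates a naive scan", {
  cfg <- pop_sim_config(samples_per_pop = 60, n_loci = 1500,
                        target_fst = 0.15, seed = 87)
  g <- simulate_populations(cfg)
  pops <- attr(g, "pops")
  set.seed(88)
  y <- ifelse(pops == "pop1", 0, 1) + rnorm(n_samples(g), 0, 1)
  G <- build_grm(g)
  s_mm <- single_marker_scan(y, g, fit_null_reml(y, G))
  s_ols <- single_marker_scan(y, g, fit_null_reml(y, diag(n_samples(g))))
  lam_mm <- genomic_inflation(s_mm$p)
  lam_ols <- genomic_inflation(s_ols$p)
  expect_gt(lam_ols, 1.3)
  expect_lt(lam_mm, 1.15)
  expect_gt(lam_mm, 0.9)
})

test_that("significance thresholds default to 5e-8 and 1e-5", {
  thr <- significance_lines()
  expect_equal(thr$genomewide, 5e-8)
  expect_equal(thr$suggestive, 1e-5)
  expect_equal(significance_lines(1e-6, 1e-4)$genomewide, 1e-6)
  expect_error(significance_lines(-1), "positive")
})
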