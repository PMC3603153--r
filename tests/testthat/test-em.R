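# EM core: densities, posterior moments, M-step updates, likelihood and
# the full fitting loop.

test_that("group density matches closed forms and a dense oracle", {
  # D=1, K=1, L=0: standard normal at the origin
  expect_equal(group_density(0, matrix(0, 1, 1), 0, 1), 1 / sqrt(2 * pi))
  # D=2, K=1, L=(1,1)': covariance [[2,1],[1,2]], det 3
  d <- group_density(c(0, 0), matrix(c(1, 1), 2, 1), c(0, 0), c(1, 1))
  expect_equal(d, 1 / (2 * pi * sqrt(3)), tolerance = 1e-12)
  # integrates to 1 on a fine 1-D grid
  grid <- seq(-12, 12, by = 1e-3)
  dens <- group_density(matrix(grid, ncol = 1), matrix(0.8, 1, 1), 0.3, 0.5)
  expect_equal(sum(dens) * 1e-3, 1, tolerance = 1e-4)
  # random instances against the dense determinant/solve route
  set.seed(31)
  for (i in 1:10) {
    p <- rand_params(5, 2, 1)
    x <- rnorm(5)
    Sigma <- tcrossprod(p$loadings[[1]]) + diag(p$psi)
    expect_equal(group_density(x, p$loadings[[1]], p$means[[1]], p$psi, log = TRUE),
                 oracle_dmvnorm(x, p$means[[1]], Sigma, log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("posterior responsibilities normalize and follow density ratios", {
  set.seed(8)
  p <- rand_params(4, 2, 1)
  x <- matrix(rnorm(20), 5, 4)
  m1 <- list(loadings = p$loadings, means = p$means, psi = p$psi, proportions = 1)
  expect_equal(unname(posterior_responsibilities(m1, x)), matrix(1, 5, 1))
  # two identical components split 50/50
  m2 <- list(loadings = rep(p$loadings, 2), means = rep(p$means, 2),
             psi = p$psi, proportions = c(0.5, 0.5))
  expect_equal(unname(posterior_responsibilities(m2, x)), matrix(0.5, 5, 2))
  # univariate two-group case with means -1 and +1, unit variance
  mu <- list(-1, 1)
  L0 <- list(matrix(0, 1, 1), matrix(0, 1, 1))
  m3 <- list(loadings = L0, means = mu, psi = 1, proportions = c(0.5, 0.5))
  expect_equal(unname(posterior_responsibilities(m3, matrix(0))), matrix(0.5, 1, 2))
  h1 <- posterior_responsibilities(m3, matrix(1))
  # at x = 1 the group densities are proportional to exp(-2) and exp(0)
  r <- exp(-2) / (exp(-2) + 1)
  expect_equal(unname(h1), matrix(c(r, 1 - r), 1, 2), tolerance = 1e-12)
  # rows always sum to one
  pm <- rand_params(4, 2, 3)
  mm <- c(pm, list())
  h <- posterior_responsibilities(list(loadings = pm$loadings, means = pm$means,
                                       psi = pm$psi, proportions = pm$proportions), x)
  expect_equal(rowSums(h), rep(1, 5), tolerance = 1e-10)
})

test_that("hard responsibilities encode labels as indicator rows", {
  expect_equal(unname(hard_responsibilities(1:3)), diag(3))
  expect_equal(unname(hard_responsibilities(rep(1, 4), n_groups = 1)),
               matrix(1, 4, 1))
  g <- c(2, 1, 3, 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(hard_responsibilities(g)[perm, ],
               hard_responsibilities(g[perm]))
})

test_that("conditional factor moments match scalar arithmetic", {
  L <- matrix(c(1, 1), 2, 1)
  # x = mu or L = 0 give a zero posterior mean
  expect_equal(conditional_factor_mean(c(0.3, -1), L, c(0.3, -1), c(1, 1)), 0)
  expect_equal(conditional_factor_mean(c(2, 5), matrix(0, 2, 1), c(0, 0), c(1, 1)), 0)
  # worked 2-feature example: R = 3, E[f|x] = 2/3, E[ff'] = 1/3 + 4/9
  expect_equal(conditional_factor_mean(c(1, 1), L, c(0, 0), c(1, 1)), 2 / 3)
  expect_equal(conditional_factor_second_moment(c(1, 1), L, c(0, 0), c(1, 1)),
               matrix(7 / 9), tolerance = 1e-12)
  # prior limit: no loading, x at the mean
  expect_equal(conditional_factor_second_moment(c(0, 0), matrix(0, 2, 2),
                                                c(0, 0), c(1, 1)), diag(2))
  # second moment minus outer product of the mean is a covariance (PD)
  set.seed(12)
  for (i in 1:10) {
    p <- rand_params(5, 2, 1)
    x <- rnorm(5)
    m <- conditional_factor_mean(x, p$loadings[[1]], p$means[[1]], p$psi)
    sm <- conditional_factor_second_moment(x, p$loadings[[1]], p$means[[1]], p$psi)
    expect_true(all(eigen(sm - tcrossprod(m), symmetric = TRUE)$values > 0))
    expect_lt(max(abs(sm - t(sm))), 1e-8)
  }
})

test_that("regression predictor equals the Woodbury form", {
  set.seed(19)
  for (i in 1:100) {
    D <- sample(3:10, 1); K <- sample(1:3, 1)
    p <- rand_params(D, K, 1)
    x <- rnorm(D)
    lhs <- conditional_factor_mean(x, p$loadings[[1]], p$means[[1]], p$psi)
    Sigma <- tcrossprod(p$loadings[[1]]) + diag(p$psi)
    rhs <- drop(crossprod(p$loadings[[1]], solve(Sigma, x - p$means[[1]])))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("loading update reduces to weighted means and solves least squares", {
  set.seed(23)
  x <- matrix(rnorm(30), 10, 3)
  h <- cbind(runif(10, 0.2, 1))
  h <- h / rowSums(h)
  # K = 0: the augmented update is exactly the responsibility-weighted mean
  ms0 <- groupfa:::.gfa_mstep(x, h, list(matrix(0, 10, 0)),
                              list(matrix(0, 0, 0)), psi_floor = 1e-6)
  expect_equal(drop(ms0$L_aug[[1]]), colSums(h[, 1] * x) / sum(h),
               tolerance = 1e-12)
  # noiseless x = L f with the true scores supplied recovers L exactly
  Ltrue <- matrix(rnorm(8), 4, 2)
  f <- matrix(rnorm(40), 20, 2)
  xn <- f %*% t(Ltrue)
  ms <- groupfa:::.gfa_mstep(xn, matrix(1, 20, 1), list(f),
                             list(matrix(0, 2, 2)), psi_floor = 1e-6)
  expect_lt(max(abs(ms$L_aug[[1]][, 1:2] - Ltrue)), 1e-8)
  expect_lt(max(abs(ms$L_aug[[1]][, 3])), 1e-8)
  # zero residuals push psi to the floor
  expect_equal(unname(ms$psi), rep(1e-6, 4))
})

test_that("hard-label M-step uses only each group's own rows", {
  set.seed(29)
  x <- matrix(rnorm(40), 10, 4)
  g <- rep(1:2, each = 5)
  h <- hard_responsibilities(g)
  est <- lapply(1:2, function(j) list(fmean = matrix(rnorm(10), 10, 1),
                                      Rinv = matrix(0.5)))
  ms <- groupfa:::.gfa_mstep(x, h, lapply(est, `[[`, "fmean"),
                             lapply(est, `[[`, "Rinv"), 1e-6)
  # perturbing group 2 rows leaves group 1's loading untouched
  x2 <- x; x2[6:10, ] <- x2[6:10, ] + 100
  ms2 <- groupfa:::.gfa_mstep(x2, h, lapply(est, `[[`, "fmean"),
                              lapply(est, `[[`, "Rinv"), 1e-6)
  expect_equal(ms$L_aug[[1]], ms2$L_aug[[1]], tolerance = 1e-12)
})

test_that("psi update matches a loop-based summation oracle", {
  set.seed(37)
  N <- 3; D <- 2; K <- 1; M <- 2
  x <- matrix(rnorm(N * D), N, D)
  h <- matrix(runif(N * M), N, M); h <- h / rowSums(h)
  fmean <- replicate(M, matrix(rnorm(N * K), N, K), simplify = FALSE)
  Rinv <- replicate(M, matrix(runif(1, 0.1, 1), K, K), simplify = FALSE)
  ms <- groupfa:::.gfa_mstep(x, h, fmean, Rinv, psi_floor = 1e-12)
  # direct per-subject summation of the update formula
  psi_oracle <- numeric(D)
  for (j in 1:M) {
    Sxf <- matrix(0, D, K + 1); Sff <- matrix(0, K + 1, K + 1)
    for (i in 1:N) {
      fa <- c(fmean[[j]][i, ], 1)
      Sxf <- Sxf + h[i, j] * outer(x[i, ], fa)
      Eff <- rbind(cbind(Rinv[[j]] + tcrossprod(fmean[[j]][i, ]), fmean[[j]][i, ]),
                   c(fmean[[j]][i, ], 1))
      Sff <- Sff + h[i, j] * Eff
    }
    La <- Sxf %*% solve(Sff)
    for (i in 1:N) {
      fa <- c(fmean[[j]][i, ], 1)
      psi_oracle <- psi_oracle + h[i, j] * drop(x[i, ] - La %*% fa) * x[i, ]
    }
  }
  expect_equal(unname(ms$psi), pmax(psi_oracle / N, 1e-12), tolerance = 1e-12)
  # centered data with K = 0 and a single group: psi is the MLE variance
  xc <- sweep(x, 2, colMeans(x))
  msv <- groupfa:::.gfa_mstep(xc, matrix(1, N, 1), list(matrix(0, N, 0)),
                              list(matrix(0, 0, 0)), 1e-12)
  expect_equal(unname(msv$psi), colSums(xc^2) / N, tolerance = 1e-12)
})

test_that("log likelihood matches closed form and a brute-force oracle", {
  m <- list(loadings = list(matrix(0, 1, 1)), means = list(0), psi = 1,
            proportions = 1)
  expect_equal(gfa_loglik(m, newdata = matrix(0), groups = 1, mode = "supervised"),
               -0.5 * log(2 * pi))
  set.seed(43)
  for (i in 1:5) {
    p <- rand_params(2, 1, 2)
    x <- matrix(rnorm(8), 4, 2)
    g <- c(1, 1, 2, 2)
    m <- list(loadings = p$loadings, means = p$means, psi = p$psi,
              proportions = p$proportions, group_names = c("1", "2"))
    ll_sup <- ll_soft <- 0
    for (i2 in 1:4) {
      dj <- vapply(1:2, function(j) {
        oracle_dmvnorm(x[i2, ], p$means[[j]],
                       tcrossprod(p$loadings[[j]]) + diag(p$psi))
      }, numeric(1))
      ll_sup <- ll_sup + log(dj[g[i2]])
      ll_soft <- ll_soft + log(sum(p$proportions * dj))
    }
    expect_equal(gfa_loglik(m, x, g, mode = "supervised"), ll_sup, tolerance = 1e-10)
    expect_equal(gfa_loglik(m, x, mode = "soft"), ll_soft, tolerance = 1e-10)
    # the mixture marginal dominates any single weighted component
    expect_gte(gfa_loglik(m, x, mode = "soft"),
               gfa_loglik(m, x, g, mode = "supervised") + sum(log(p$proportions[g])))
  }
})

test_that("initialization is seeded and anchored at group statistics", {
  set.seed(51)
  x <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 1), 10, 4))
  g <- rep(1:2, each = 10)
  i1 <- groupfa:::.gfa_init(x, g, 2, 2, seed = 99, psi_floor = 1e-6)
  i2 <- groupfa:::.gfa_init(x, g, 2, 2, seed = 99, psi_floor = 1e-6)
  expect_identical(i1, i2)
  expect_equal(i1$means[[1]], colMeans(x[1:10, ]))
  expect_equal(i1$proportions, c(0.5, 0.5))
  # standardized data with equal group means: pooled residual variance near 1
  set.seed(52)
  z <- standardize_features(matrix(rnorm(4000), 1000, 4))$x
  iz <- groupfa:::.gfa_init(z, rep(1:2, 500), 2, 1, seed = 1, psi_floor = 1e-6)
  expect_true(all(abs(iz$psi - 1) < 0.15))
})

test_that("EM traces are monotone and the loop contract holds", {
  set.seed(61)
  for (rep in 1:8) {
    p <- rand_params(6, 2, 2)
    co <- rand_cohort(p, 80)
    fit <- group_fa(co$x, co$groups, 2, seed = rep, max_iter = 60)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    fsoft <- group_fa(co$x, co$groups, 2, mode = "soft", seed = rep, max_iter = 60)
    expect_true(all(diff(fsoft$loglik_trace) > -1e-8))
  }
  # tol = Inf returns after exactly one M-step with a 2-entry trace
  p <- rand_params(5, 1, 2)
  co <- rand_cohort(p, 40)
  f1 <- group_fa(co$x, co$groups, 1, tol = Inf, seed = 1)
  expect_identical(f1$n_iter, 1L)
  expect_length(f1$loglik_trace, 2L)
  expect_true(f1$converged)
})

test_that("final log likelihood is reproducible from the parameters", {
  set.seed(71)
  p <- rand_params(6, 2, 3)
  co <- rand_cohort(p, 120)
  fit <- group_fa(co$x, co$groups, 2, seed = 3)
  expect_equal(gfa_loglik(fit), fit$loglik, tolerance = 1e-8)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(group_fa(x, rep(1:2, 5), 3), "n_factors")
  expect_error(group_fa(x, c(rep(1, 9), 2), 1), "fewer than 2")
  x[1, 1] <- NA
  expect_error(group_fa(x, rep(1:2, 5), 1), "non-finite")
})

test_that("likelihood is invariant under orthogonal loading rotation", {
  set.seed(81)
  for (i in 1:20) {
    p <- rand_params(6, 3, 2)
    co <- rand_cohort(p, 50)
    m <- list(loadings = p$loadings, means = p$means, psi = p$psi,
              proportions = p$proportions, group_names = levels(co$groups))
    ll <- gfa_loglik(m, co$x, co$groups, mode = "supervised")
    m$loadings <- lapply(m$loadings, function(L) L %*% rand_orthogonal(3))
    llr <- gfa_loglik(m, co$x, co$groups, mode = "supervised")
    expect_equal(llr, ll, tolerance = 1e-8)
  }
})

test_that("single-group fit agrees with an independent covariance-form EM", {
  set.seed(91)
  L <- matrix(rnorm(16, 0, 0.7), 8, 2)
  spec <- cohort_spec(list(L), list(rnorm(8, 0, 0.3)), runif(8, 0.3, 0.8),
                      1, n_subjects = 600, seed = 17)
  co <- simulate_cohort(spec)
  fit <- group_fa(co$x, co$groups, 2, tol = 1e-11, max_iter = 20000, seed = 5)
  orc <- oracle_fa_em(co$x, 2, tol = 1e-11, max_iter = 20000)
  Sfit <- tcrossprod(fit$loadings[[1]]) + diag(fit$psi)
  expect_lt(sqrt(sum((Sfit - orc$model_cov)^2)), 1e-3)
})

test_that("single-group fit matches factanal on the MLE correlation scale", {
  set.seed(95)
  L <- matrix(c(rnorm(9, 0, 0.7), rep(0, 0)), 9, 1)
  spec <- cohort_spec(list(L), list(rep(0, 9)), runif(9, 0.3, 0.6), 1,
                      n_subjects = 1500, seed = 3)
  co <- simulate_cohort(spec)
  z <- standardize_features(co$x, mle_variance = TRUE)$x
  fit <- group_fa(z, co$groups, 1, tol = 1e-10, max_iter = 10000, seed = 2)
  fa <- stats::factanal(covmat = crossprod(sweep(z, 2, colMeans(z))) / nrow(z),
                        factors = 1, n.obs = nrow(z))
  Sfa <- tcrossprod(matrix(fa$loadings, ncol = 1)) + diag(fa$uniquenesses)
  Sfit <- tcrossprod(fit$loadings[[1]]) + diag(fit$psi)
  expect_lt(sqrt(sum((Sfit - Sfa)^2)), 0.02)
})
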