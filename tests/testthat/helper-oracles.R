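# Independent oracles used to check the package's computations. These are
# deliberately written along different routes than the implementation:
# plain dense linear algebra, covariance-form (sufficient statistics) EM,
# grid searches and brute-force enumeration.

# dense multivariate normal density, direct determinant/solve route
oracle_dmvnorm <- function(x, mu, Sigma, log = FALSE) {
  d <- length(mu)
  a <- as.numeric(x) - as.numeric(mu)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  q <- drop(a %*% solve(Sigma, a))
  out <- -0.5 * (d * log(2 * pi) + ld + q)
  if (log) out else exp(out)
}

# classical single-group factor analysis EM in covariance (sufficient
# statistics) form: Rubin-Thayer updates on the MLE covariance S.
#   beta = L' (L L' + Psi)^{-1}
#   E[ff'] = I - beta L + beta S beta'
#   L_new = S beta' E[ff']^{-1};  Psi_new = diag(S - L_new beta S)
oracle_fa_em <- function(x, K, tol = 1e-11, max_iter = 10000L, seed = 42L) {
  x <- as.matrix(x)
  N <- nrow(x); D <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x), `-`)
  S <- crossprod(xc) / N
  L <- withr::with_seed(seed, matrix(rnorm(D * K, 0, 0.1), D, K))
  psi <- pmax(diag(S), 1e-6)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Sigma <- tcrossprod(L) + diag(psi, D)
    beta <- t(solve(Sigma, L))                     # K x D
    Eff <- diag(K) - beta %*% L + beta %*% S %*% t(beta)
    Lnew <- S %*% t(beta) %*% solve(Eff)
    psi <- pmax(diag(S - Lnew %*% beta %*% S), 1e-8)
    L <- Lnew
    ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
    ll <- -0.5 * N * (D * log(2 * pi) + ld + sum(diag(solve(Sigma, S))))
    if (abs(ll - ll_old) / (abs(ll) + 1) < tol) break
    ll_old <- ll
  }
  list(loadings = L, psi = psi, model_cov = tcrossprod(L) + diag(psi, D),
       iterations = it)
}

# varimax criterion via the package's public definition, recomputed locally
oracle_varimax_criterion <- function(L) {
  L2 <- L^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

# best planar (K = 2) rotation by brute grid search over the angle
oracle_varimax_grid <- function(L, step = 0.001) {
  stopifnot(ncol(L) == 2L)
  thetas <- seq(0, pi / 2, by = step)
  best <- -Inf
  for (th in thetas) {
    H <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    cr <- oracle_varimax_criterion(L %*% H)
    if (cr > best) best <- cr
  }
  best
}

# minimum-cost assignment by enumerating every permutation
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- groupfa:::.permutations(n)
  best <- Inf; pick <- NULL
  for (q in seq_len(nrow(perms))) {
    v <- sum(cost[cbind(seq_len(n), perms[q, ])])
    if (v < best) { best <- v; pick <- perms[q, ] }
  }
  list(assignment = pick, cost = best)
}

# random orthogonal matrix via QR with a fixed sign convention
rand_orthogonal <- function(k) {
  qr_res <- qr(matrix(rnorm(k * k), k, k))
  Q <- qr.Q(qr_res)
  Q %*% diag(sign(diag(qr.R(qr_res))), k)
}

# random well-posed model parameters for property tests
rand_params <- function(D, K, M, psi_range = c(0.2, 1)) {
  list(
    loadings = replicate(M, matrix(rnorm(D * K, 0, 0.6), D, K), simplify = FALSE),
    means = replicate(M, rnorm(D, 0, 0.5), simplify = FALSE),
    psi = runif(D, psi_range[1], psi_range[2]),
    proportions = {
      p <- runif(M, 0.5, 1.5)
      p / sum(p)
    }
  )
}

# quick random labelled cohort from explicit parameters
rand_cohort <- function(par, N, label_names = NULL) {
  M <- length(par$loadings)
  spec <- cohort_spec(par$loadings, par$means, par$psi, par$proportions,
                      n_subjects = N, seed = sample.int(2^31 - 2, 1),
                      label_names = label_names)
  simulate_cohort(spec)
}
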