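# Group factor analysis model:
#   x_i | (group j) = mu_j + L_j f_i + u_i,  f_i ~ N(0, I_K),  u_i ~ N(0, Psi)
# with Psi diagonal and shared across the M groups, so the marginal
# covariance of group j is L_j L_j' + Psi. All densities are evaluated in
# log space through the Woodbury identity and the matrix determinant lemma
# so that only K x K systems are ever solved.

# per-group E-step quantities for an N x D data block
# returns conditional factor means (N x K), the shared conditional
# covariance R^{-1} (K x K) and per-subject log densities
.gfa_estep_group <- function(x, loadings, mean, psi) {
  D <- ncol(x)
  K <- ncol(loadings)
  A <- sweep(x, 2L, mean, `-`)
  psiinv <- 1 / psi
  W <- loadings * psiinv                       # Psi^{-1} L, D x K
  R <- crossprod(loadings, W) + diag(1, K)     # L' Psi^{-1} L + I
  Rchol <- tryCatch(chol(R), error = function(e) {
    stop("factor covariance numerically singular; reduce n_factors or check psi",
         call. = FALSE)
  })
  Rinv <- chol2inv(Rchol)
  AW <- A %*% W
  fmean <- AW %*% Rinv                         # E[f | w_j, x]
  logdet <- sum(log(psi)) + 2 * sum(log(diag(Rchol)))   # log|L L' + Psi|
  quad <- drop((A * A) %*% psiinv) - rowSums(fmean * AW)
  logdens <- -0.5 * (D * log(2 * pi) + logdet + quad)
  list(fmean = fmean, Rinv = Rinv, logdens = logdens)
}

# joint M-step: augmented loadings [L_j mu_j] by weighted least squares on
# the expected augmented scores, then the shared diagonal Psi
.gfa_mstep <- function(x, h, fmean_list, Rinv_list, psi_floor) {
  N <- nrow(x)
  M <- ncol(h)
  K <- ncol(fmean_list[[1L]])
  L_aug <- Sxf_list <- vector("list", M)
  for (j in seq_len(M)) {
    hj <- h[, j]
    Fa <- cbind(fmean_list[[j]], 1)            # E[f~ | w_j, x], N x (K+1)
    Sxf <- crossprod(x, hj * Fa)               # sum_i h_ij x_i E[f~_i]'
    Sff <- crossprod(Fa, hj * Fa)              # sum_i h_ij E[f~_i] E[f~_i]'
    if (K > 0L) {
      kk <- seq_len(K)
      # E[f f'] = Cov(f|x) + m m'; the covariance term is shared across i
      Sff[kk, kk] <- Sff[kk, kk] + sum(hj) * Rinv_list[[j]]
    }
    L_aug[[j]] <- tryCatch(t(solve(Sff, t(Sxf))), error = function(e) {
      stop("singular Gram matrix in the loading update; ",
           "try fewer factors or more data", call. = FALSE)
    })
    Sxf_list[[j]] <- Sxf
  }
  # Psi = diag( sum_ij h_ij (x_i - L~_j E[f~_i]) x_i' ) / N
  psi_raw <- colSums(x * x)
  for (j in seq_len(M)) {
    psi_raw <- psi_raw - rowSums(L_aug[[j]] * Sxf_list[[j]])
  }
  psi_raw <- psi_raw / N
  n_nonpos <- sum(psi_raw <= 0)
  list(L_aug = L_aug, psi = pmax(psi_raw, psi_floor),
       n_floored = sum(psi_raw < psi_floor), n_nonpos = n_nonpos)
}

# seeded parameter initialization: group sample means, small random
# loadings, pooled within-group residual variances, observed proportions
.gfa_init <- function(x, gindex, M, K, seed, psi_floor) {
  D <- ncol(x)
  means <- lapply(seq_len(M), function(j) colMeans(x[gindex == j, , drop = FALSE]))
  resid <- x - do.call(rbind, means)[gindex, , drop = FALSE]
  psi <- pmax(colSums(resid * resid) / nrow(x), max(psi_floor, 1e-6))
  draw <- function() lapply(seq_len(M), function(j) matrix(stats::rnorm(D * K, 0, 0.1), D, K))
  loadings <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(loadings = loadings, means = means, psi = psi,
       proportions = as.numeric(tabulate(gindex, M)) / nrow(x))
}

#' Gaussian density of one group's marginal model
#'
#' Evaluates the multivariate normal density with mean `mean` and low-rank
#' plus diagonal covariance `loadings %*% t(loadings) + diag(psi)`, the
#' marginal distribution of the data under one group's factor model.
#' Computation is done in log space via the Woodbury identity for numerical
#' stability.
#'
#' @param x numeric vector of length `D`, or an `N x D` matrix of rows to
#'   evaluate.
#' @param loadings `D x K` loading matrix.
#' @param mean numeric vector of length `D`.
#' @param psi strictly positive numeric vector of length `D`, the diagonal
#'   of the error covariance.
#' @param log logical; return the log density?
#' @return Numeric vector of (log) densities, one per row of `x`.
#' @export
group_density <- function(x, loadings, mean, psi, log = FALSE) {
  loadings <- as.matrix(loadings)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- .as_numeric_matrix(x, "x")
  if (any(psi <= 0)) stop("'psi' must be strictly positive", call. = FALSE)
  est <- .gfa_estep_group(x, loadings, mean, psi)
  if (log) est$logdens else exp(est$logdens)
}

#' Posterior group responsibilities
#'
#' Computes \eqn{h_{ij} = \pi_j N(x_i; \mu_j, L_j L_j' + \Psi) / \sum_u
#' \pi_u N(x_i; \mu_u, L_u L_u' + \Psi)}, the posterior probability that
#' subject `i` belongs to group `j` given the model. These are the soft
#' memberships used in the soft fitting mode and in post-hoc proportion
#' re-estimation.
#'
#' @param model a fitted [group_fa()] object, or any list with elements
#'   `loadings` (list of `D x K` matrices), `means` (list of length-`D`
#'   vectors), `psi` and `proportions`.
#' @param newdata optional `N x D` matrix; defaults to the data stored in a
#'   fitted model.
#' @return `N x M` matrix whose rows sum to 1.
#' @export
posterior_responsibilities <- function(model, newdata = NULL) {
  x <- if (is.null(newdata)) model$x else .as_numeric_matrix(newdata, "newdata")
  if (is.null(x)) stop("no data stored in 'model'; supply 'newdata'", call. = FALSE)
  M <- length(model$loadings)
  logd <- vapply(seq_len(M), function(j) {
    group_density(x, model$loadings[[j]], model$means[[j]], model$psi, log = TRUE)
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  lp <- sweep(logd, 2L, log(model$proportions), `+`)
  lse <- .row_logsumexp(lp)
  if (any(!is.finite(lse))) {
    stop("all group densities underflowed for at least one subject; ",
         "consider standardizing the features", call. = FALSE)
  }
  h <- exp(lp - lse)
  colnames(h) <- model$group_names
  h
}

#' Hard (diagnosis-fixed) responsibilities
#'
#' Encodes group labels as a binary membership matrix: row `i` is the
#' indicator of subject `i`'s diagnosed group, the fixed expectation used
#' throughout a supervised fit.
#'
#' @param groups per-subject group labels (factor, character or integer).
#' @param n_groups optional number of groups when `groups` is integer-coded
#'   and some trailing group might be unobserved.
#' @return `N x M` binary matrix with one 1 per row.
#' @export
hard_responsibilities <- function(groups, n_groups = NULL) {
  if (is.factor(groups) || is.character(groups)) {
    g <- if (is.factor(groups)) groups else factor(groups)
    idx <- as.integer(g)
    M <- nlevels(g)
    nms <- levels(g)
  } else {
    idx <- as.integer(groups)
    M <- if (is.null(n_groups)) max(idx) else as.integer(n_groups)
    nms <- as.character(seq_len(M))
  }
  h <- matrix(0, length(idx), M, dimnames = list(NULL, nms))
  h[cbind(seq_along(idx), idx)] <- 1
  h
}

#' Conditional mean of the factor scores
#'
#' The posterior (regression) factor-score predictor
#' \eqn{E[f | w_j, x] = (L'\Psi^{-1}L + I)^{-1} L'\Psi^{-1}(x - \mu)}.
#'
#' @inheritParams group_density
#' @return Length-`K` vector for a single data vector, or an `N x K` matrix.
#' @export
conditional_factor_mean <- function(x, loadings, mean, psi) {
  loadings <- as.matrix(loadings)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  est <- .gfa_estep_group(.as_numeric_matrix(x, "x"), loadings, mean, psi)
  if (vec) drop(est$fmean) else est$fmean
}

#' Conditional second moment of the factor scores
#'
#' Returns \eqn{E[f f' | w_j, x] = (L'\Psi^{-1}L + I)^{-1} + m m'} where `m`
#' is [conditional_factor_mean()]; the first term is the conditional
#' covariance of the scores, identical for every subject.
#'
#' @inheritParams group_density
#' @param x numeric vector of length `D`.
#' @return `K x K` symmetric positive definite matrix.
#' @export
conditional_factor_second_moment <- function(x, loadings, mean, psi) {
  loadings <- as.matrix(loadings)
  est <- .gfa_estep_group(matrix(as.numeric(x), nrow = 1L), loadings, mean, psi)
  m <- drop(est$fmean)
  est$Rinv + tcrossprod(m)
}

# log likelihood of data under a parameter set; supervised conditions on
# the labelled group, soft uses the mixture marginal
.gfa_loglik <- function(x, loadings, means, psi, proportions,
                        mode = c("supervised", "soft"), gindex = NULL) {
  mode <- match.arg(mode)
  M <- length(loadings)
  logd <- vapply(seq_len(M), function(j) {
    .gfa_estep_group(x, loadings[[j]], means[[j]], psi)$logdens
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  if (mode == "supervised") {
    if (is.null(gindex)) stop("supervised log likelihood requires group labels",
                              call. = FALSE)
    sum(logd[cbind(seq_len(nrow(x)), gindex)])
  } else {
    sum(.row_logsumexp(sweep(logd, 2L, log(proportions), `+`)))
  }
}

#' Log likelihood of a group factor analysis model
#'
#' @param model a fitted [group_fa()] object or a compatible parameter list
#'   (elements `loadings`, `means`, `psi`, `proportions`).
#' @param newdata optional data matrix; defaults to the fitted data.
#' @param groups group labels for `newdata` (required in supervised mode).
#' @param mode `"supervised"` (sum of each subject's own-group log density)
#'   or `"soft"` (mixture marginal). Defaults to the model's fitting mode.
#' @return A single number.
#' @export
gfa_loglik <- function(model, newdata = NULL, groups = NULL, mode = NULL) {
  x <- if (is.null(newdata)) model$x else .as_numeric_matrix(newdata, "newdata")
  if (is.null(mode)) mode <- if (is.null(model$mode)) "soft" else model$mode
  gindex <- NULL
  if (mode == "supervised") {
    g <- if (is.null(groups)) model$groups else groups
    if (is.null(g)) stop("supervised mode requires group labels", call. = FALSE)
    gindex <- if (is.factor(g)) {
      as.integer(g)
    } else if (is.null(model$group_names)) {
      as.integer(factor(g))
    } else {
      as.integer(factor(g, levels = model$group_names))
    }
    if (anyNA(gindex)) stop("unknown group label", call. = FALSE)
  }
  .gfa_loglik(x, model$loadings, model$means, model$psi, model$proportions,
              mode = mode, gindex = gindex)
}

#' Fit a group factor analysis model by EM
#'
#' Estimates, by maximum likelihood, a factor analysis model in which every
#' subject group has its own `D x K` loading matrix and mean vector while
#' all groups share one diagonal error covariance. In the default
#' `"supervised"` mode the group memberships are fixed to the provided
#' labels (clinical diagnoses) for the whole run; in `"soft"` mode the
#' memberships are recomputed each E-step as posterior responsibilities
#' under prior proportions taken from the label frequencies. The M-step
#' updates the augmented loadings `[L_j mu_j]` by responsibility-weighted
#' least squares and then the shared diagonal error variances.
#'
#' Standardizing the features first (see [standardize_features()]) is
#' recommended so that no feature dominates the loadings.
#'
#' @param x `N x D` numeric matrix or data frame of continuous features.
#' @param groups per-subject group labels; each group needs at least 2
#'   members.
#' @param n_factors number of latent factors `K`, `1 <= K < D`.
#' @param mode `"supervised"` (default) or `"soft"`.
#' @param max_iter maximum number of EM iterations.
#' @param tol convergence tolerance on the relative log-likelihood change,
#'   `|dLL| / (|LL| + 1)`.
#' @param seed integer seed for the random loading initialization; the
#'   caller's RNG state is left untouched. `NULL` uses (and advances) the
#'   current RNG state.
#' @param psi_floor lower bound applied elementwise to the error variances,
#'   preventing Heywood-case singularities. Floor events are recorded in
#'   the fit's `events` field.
#' @return An object of class `"group_fa"`: a list with the per-group
#'   `loadings` and `means`, shared `psi`, prior `proportions`, the final
#'   `loglik` and full `loglik_trace`, `n_iter`, `converged`, per-subject
#'   factor `scores` (conditional means for the assigned group) and
#'   `responsibilities`, plus the training data and labels.
#' @references Classical single-group maximum-likelihood factor analysis is
#'   recovered as the special case of a single group (`M = 1`).
#' @examples
#' spec <- ad_like_spec(n_subjects = 300, seed = 7)
#' cohort <- simulate_cohort(spec)
#' fit <- group_fa(cohort$x, cohort$groups, n_factors = 3, seed = 1)
#' fit
#' @export
group_fa <- function(x, groups, n_factors, mode = c("supervised", "soft"),
                     max_iter = 1000L, tol = 1e-6, seed = NULL,
                     psi_floor = 1e-6) {
  mode <- match.arg(mode)
  x <- .as_numeric_matrix(x, "x")
  g <- .as_group_factor(groups, min_size = 2L)
  if (length(g) != nrow(x)) stop("'groups' length must match rows of 'x'", call. = FALSE)
  N <- nrow(x); D <- ncol(x)
  M <- nlevels(g)
  gindex <- as.integer(g)
  K <- as.integer(n_factors)
  if (K < 1L || K >= D) {
    stop(sprintf("'n_factors' must satisfy 1 <= K < D (got K=%d, D=%d)", K, D),
         call. = FALSE)
  }
  if (N < M + 1L) stop("need at least M + 1 subjects", call. = FALSE)

  par <- .gfa_init(x, gindex, M, K, seed, psi_floor)
  h_hard <- hard_responsibilities(gindex, M)
  events <- character(0)
  trace <- numeric(0)
  n_iter <- 0L
  converged <- FALSE

  for (iter in 0:max_iter) {
    est <- lapply(seq_len(M), function(j) {
      .gfa_estep_group(x, par$loadings[[j]], par$means[[j]], par$psi)
    })
    logd <- vapply(est, `[[`, numeric(N), "logdens")
    logd <- matrix(logd, nrow = N)
    if (mode == "supervised") {
      h <- h_hard
      ll <- sum(logd[cbind(seq_len(N), gindex)])
    } else {
      lp <- sweep(logd, 2L, log(par$proportions), `+`)
      lse <- .row_logsumexp(lp)
      if (any(!is.finite(lse))) {
        stop(sprintf("likelihood underflow at iteration %d; consider standardizing", iter),
             call. = FALSE)
      }
      h <- exp(lp - lse)
      ll <- sum(lse)
    }
    if (!is.finite(ll)) {
      stop(sprintf("non-finite log likelihood at iteration %d", iter), call. = FALSE)
    }
    trace <- c(trace, ll)
    if (iter > 0L && abs(ll - trace[iter]) / (abs(ll) + 1) < tol) {
      converged <- TRUE
      break
    }
    if (iter == max_iter) break
    ms <- .gfa_mstep(x, h,
                     fmean_list = lapply(est, `[[`, "fmean"),
                     Rinv_list = lapply(est, `[[`, "Rinv"),
                     psi_floor = psi_floor)
    if (ms$n_nonpos > 0L) {
      events <- c(events, sprintf("iteration %d: %d non-positive psi entr%s before flooring",
                                  iter + 1L, ms$n_nonpos,
                                  if (ms$n_nonpos == 1L) "y" else "ies"))
    } else if (ms$n_floored > 0L) {
      events <- c(events, sprintf("iteration %d: %d psi entr%s floored at %g",
                                  iter + 1L, ms$n_floored,
                                  if (ms$n_floored == 1L) "y" else "ies", psi_floor))
    }
    par$loadings <- lapply(ms$L_aug, function(La) La[, seq_len(K), drop = FALSE])
    par$means <- lapply(ms$L_aug, function(La) La[, K + 1L])
    par$psi <- ms$psi
    n_iter <- iter + 1L
  }

  # factor scores for each subject's assigned group, from the final E-step
  scores <- matrix(0, N, K, dimnames = list(rownames(x), paste0("F", seq_len(K))))
  for (j in seq_len(M)) {
    rows <- gindex == j
    scores[rows, ] <- est[[j]]$fmean[rows, , drop = FALSE]
  }
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("V", seq_len(D))
  for (j in seq_len(M)) {
    dimnames(par$loadings[[j]]) <- list(fnames, paste0("F", seq_len(K)))
    names(par$means[[j]]) <- fnames
  }
  names(par$loadings) <- names(par$means) <- levels(g)
  names(par$psi) <- fnames

  structure(list(
    loadings = par$loadings,
    means = par$means,
    psi = par$psi,
    proportions = stats::setNames(par$proportions, levels(g)),
    n_factors = K,
    mode = mode,
    loglik = trace[length(trace)],
    loglik_trace = trace,
    n_iter = n_iter,
    converged = converged,
    scores = scores,
    responsibilities = h,
    x = x,
    groups = g,
    group_names = levels(g),
    feature_names = fnames,
    seed = seed,
    psi_floor = psi_floor,
    events = events,
    rotated = FALSE
  ), class = "group_fa")
}
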