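# Descriptive and inferential companions to the fit: how many factors to
# keep, whether the estimated scores look standard normal (as the model
# asserts), which features differ across groups, and how similar the
# per-group loading matrices end up being.

#' Eigenvalue scree of a feature matrix
#'
#' Eigenvalues of the sample covariance in descending order together with
#' the cumulative percentage of variance they explain, plus the Kaiser
#' criterion count (eigenvalues exceeding 1, meaningful for standardized
#' features where the covariance is the correlation matrix). The usual
#' basis for choosing the number of factors.
#'
#' @param x `N x D` feature matrix, or a `D x D` covariance matrix when
#'   `covariance = TRUE`.
#' @param covariance logical; is `x` already a covariance matrix?
#' @return A list of class `"gfa_scree"`: `eigenvalues` (descending),
#'   `cum_var_pct`, and `kaiser_k`.
#' @examples
#' scree_eigen(diag(c(3, 2, 1)), covariance = TRUE)$cum_var_pct
#' @export
scree_eigen <- function(x, covariance = FALSE) {
  S <- if (covariance) as.matrix(x) else stats::cov(.as_numeric_matrix(x, "x"))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  structure(list(eigenvalues = ev,
                 cum_var_pct = 100 * cumsum(ev) / sum(ev),
                 kaiser_k = sum(ev > 1)),
            class = "gfa_scree")
}

#' @export
print.gfa_scree <- function(x, ...) {
  cat("Scree of", length(x$eigenvalues), "eigenvalues;",
      x$kaiser_k, "exceed 1 (Kaiser criterion)\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 4),
                   cum_var_pct = round(x$cum_var_pct, 2)))
  invisible(x)
}

#' Kolmogorov-Smirnov test of factor scores against N(0, 1)
#'
#' One-sample KS test of a score vector against the standard normal — the
#' distribution the model asserts for the latent factors — using the
#' asymptotic two-sided p-value. Note the null is the fixed N(0, 1), not a
#' normal with estimated moments.
#'
#' @param scores numeric vector, at least 5 values.
#' @return Named vector with `statistic` (the ECDF sup-distance `D`) and
#'   `p` (asymptotic two-sided p-value).
#' @export
ks_normality <- function(scores) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("'scores' contains missing or non-finite values", call. = FALSE)
  }
  if (length(scores) < 5L) stop("need at least 5 scores", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(scores, "pnorm", exact = FALSE))
  c(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' One-way ANOVA for each feature
#'
#' Classical fixed-effects one-way analysis of variance of every feature
#' column on the group labels: `F = MS_between / MS_within` on
#' `(M - 1, N - M)` degrees of freedom. Used to flag features whose mean
#' differs across diagnostic groups.
#'
#' @param x `N x D` feature matrix.
#' @param groups per-subject labels, at least 2 groups with 2+ members each.
#' @return Data frame with one row per feature: `feature`, `F`, `p`. When a
#'   feature has zero variance both between and within groups the test is
#'   undefined and `p = 1`, `F = 0` are reported by convention (with a
#'   message).
#' @export
anova_per_feature <- function(x, groups) {
  x <- .as_numeric_matrix(x, "x")
  g <- .as_group_factor(groups, min_size = 2L)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(g) != nrow(x)) stop("'groups' length must match rows of 'x'", call. = FALSE)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(d) {
    if (stats::var(x[, d]) < .Machine$double.eps^0.75) {
      # no variation between or within groups: the F ratio is 0/0
      message(sprintf("feature '%s': no variance between or within groups; p = 1 by convention",
                      nms[d]))
      return(c(0, 1))
    }
    tab <- stats::anova(stats::lm(x[, d] ~ g))
    c(tab$`F value`[1L], tab$`Pr(>F)`[1L])
  })
  res <- do.call(rbind, res)
  data.frame(feature = nms, F = res[, 1L], p = res[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare aligned loading matrices across groups
#'
#' Pairwise Frobenius distances and Pearson correlations (of the vectorized
#' matrices) between per-group loading matrices, plus the mean of the
#' upper-triangle distances as an aggregate. Only meaningful after the
#' matrices have been rotated and aligned (see [align_model()]).
#'
#' @param L_list list of `M` aligned loading matrices of identical shape.
#' @return A list of class `"loading_comparison"`: `pairwise_distance`
#'   (`M x M`, zero diagonal), `aggregate_distance`, `pairwise_corr`
#'   (`M x M`, unit diagonal).
#' @export
compare_loadings <- function(L_list) {
  M <- length(L_list)
  L_list <- lapply(L_list, as.matrix)
  dist <- matrix(0, M, M)
  corr <- diag(1, M)
  nms <- names(L_list)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      if (a == b) next
      dist[a, b] <- sqrt(sum((L_list[[a]] - L_list[[b]])^2))
      corr[a, b] <- stats::cor(as.vector(L_list[[a]]), as.vector(L_list[[b]]))
    }
  }
  dimnames(dist) <- dimnames(corr) <- list(nms, nms)
  agg <- if (M > 1L) mean(dist[upper.tri(dist)]) else 0
  structure(list(pairwise_distance = dist, aggregate_distance = agg,
                 pairwise_corr = corr),
            class = "loading_comparison")
}

#' @export
print.loading_comparison <- function(x, ...) {
  cat("Pairwise Frobenius distance between loading matrices:\n")
  print(round(x$pairwise_distance, 4))
  cat(sprintf("Aggregate (mean upper-triangle) distance: %.4f\n",
              x$aggregate_distance))
  cat("Pairwise correlation of vectorized loadings:\n")
  print(round(x$pairwise_corr, 4))
  invisible(x)
}

#' Re-estimate group proportions from posterior responsibilities
#'
#' After fitting, the soft posterior memberships can be averaged over
#' subjects, \eqn{\hat\pi_j = N^{-1} \sum_i h_{ij}}, giving the
#' model-adjusted group proportions. When groups overlap these are no
#' longer the binary diagnosis frequencies.
#'
#' @inheritParams posterior_responsibilities
#' @param percent logical; return percentages rounded to two decimals?
#' @return Numeric vector of length `M` summing to 1 (or 100%).
#' @export
reestimate_proportions <- function(model, newdata = NULL, percent = FALSE) {
  h <- posterior_responsibilities(model, newdata)
  p <- colMeans(h)
  if (percent) round(100 * p, 2) else p
}

#' Per-group association between a factor score and a covariate
#'
#' Ordinary least squares of a covariate (for instance a cognitive score
#' such as the MMSE) on one factor score, fitted separately within each
#' group, together with the within-group Pearson correlation.
#'
#' @param scores numeric vector of per-subject factor scores.
#' @param covariate numeric vector of the same length.
#' @param groups per-subject group labels (3+ subjects per group).
#' @return Data frame with one row per group: `group`, `n`, `slope`,
#'   `intercept`, `r`. A group with constant scores gets `NA` slope and
#'   correlation.
#' @export
score_covariate_association <- function(scores, covariate, groups) {
  scores <- as.numeric(scores)
  covariate <- as.numeric(covariate)
  g <- .as_group_factor(groups, min_size = 3L)
  stopifnot(length(scores) == length(g), length(covariate) == length(g))
  if (any(!is.finite(covariate))) stop("'covariate' must be finite", call. = FALSE)
  out <- lapply(levels(g), function(lev) {
    s <- scores[g == lev]; y <- covariate[g == lev]
    if (stats::var(s) <= 0) {
      return(data.frame(group = lev, n = length(s), slope = NA_real_,
                        intercept = NA_real_, r = NA_real_))
    }
    fit <- stats::lm(y ~ s)
    data.frame(group = lev, n = length(s),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = stats::cor(s, y))
  })
  do.call(rbind, out)
}

#' Full diagnostics report for a fitted model
#'
#' Assembles the standard post-fit report: the eigenvalue scree of the
#' data, per-feature ANOVA across groups, a Kolmogorov-Smirnov normality
#' table of the factor scores (group by factor), the cross-group loading
#' comparison (marked not applicable for a single group), and the
#' re-estimated soft proportions.
#'
#' @param model a [group_fa()] fit, or a parameter list compatible with
#'   [posterior_responsibilities()].
#' @param x data matrix; defaults to the data stored in the fit.
#' @param groups labels for `x`; default the stored labels.
#' @param covariate optional per-subject covariate; when given, the
#'   per-group regression of the covariate on each factor score is added.
#' @return A list of class `"gfa_diagnostics"`.
#' @export
diagnose <- function(model, x = NULL, groups = NULL, covariate = NULL) {
  if (is.null(x)) x <- model$x
  if (is.null(groups)) groups <- model$groups
  x <- .as_numeric_matrix(x, "x")
  if (ncol(x) != length(model$psi)) {
    stop(sprintf("data has %d features but the model expects %d",
                 ncol(x), length(model$psi)), call. = FALSE)
  }
  g <- .as_group_factor(groups)
  M <- length(model$loadings)
  K <- ncol(model$loadings[[1L]])
  gindex <- as.integer(g)

  scores <- matrix(0, nrow(x), K)
  for (j in seq_len(M)) {
    rows <- gindex == j
    if (!any(rows)) next
    scores[rows, ] <- matrix(conditional_factor_mean(
      x[rows, , drop = FALSE], model$loadings[[j]], model$means[[j]], model$psi
    ), ncol = K)
  }
  ks <- expand.grid(group = levels(g), factor = paste0("F", seq_len(K)),
                    stringsAsFactors = FALSE)
  kv <- t(apply(ks, 1L, function(row) {
    idx <- g == row[["group"]]
    k <- match(row[["factor"]], paste0("F", seq_len(K)))
    if (sum(idx) >= 5L) ks_normality(scores[idx, k]) else c(statistic = NA, p = NA)
  }))
  ks$statistic <- kv[, 1L]
  ks$p <- kv[, 2L]

  out <- list(
    scree = scree_eigen(x),
    anova = if (M >= 2L) anova_per_feature(x, g) else NULL,
    ks = ks,
    loading_comparison = if (M >= 2L) compare_loadings(model$loadings) else NULL,
    loading_comparison_applicable = M >= 2L,
    reestimated_proportions = reestimate_proportions(model, x),
    n_subjects = nrow(x),
    n_groups = M
  )
  if (!is.null(covariate)) {
    out$covariate_association <- lapply(seq_len(K), function(k) {
      score_covariate_association(scores[, k], covariate, g)
    })
    names(out$covariate_association) <- paste0("F", seq_len(K))
  }
  structure(out, class = "gfa_diagnostics")
}

#' @export
print.gfa_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics for %d subjects in %d group(s)\n", x$n_subjects, x$n_groups))
  cat(sprintf("  Kaiser criterion retains %d factor(s); top-3 cumulative variance %.1f%%\n",
              x$scree$kaiser_k,
              x$scree$cum_var_pct[min(3L, length(x$scree$cum_var_pct))]))
  cat("  Re-estimated proportions:",
      paste(sprintf("%.2f%%", 100 * x$reestimated_proportions), collapse = ", "), "\n")
  if (x$loading_comparison_applicable) {
    cat(sprintf("  Aggregate loading distance: %.4f\n",
                x$loading_comparison$aggregate_distance))
  } else {
    cat("  Loading comparison: not applicable (single group)\n")
  }
  invisible(x)
}
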