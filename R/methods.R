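#' @export
print.group_fa <- function(x, ...) {
  cat(sprintf("Group factor analysis (%s mode)\n", x$mode))
  cat(sprintf("  %d subjects, %d features, %d groups, %d factors\n",
              nrow(x$x), length(x$psi), length(x$loadings), x$n_factors))
  cat(sprintf("  log likelihood %.3f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  group proportions:",
      paste(sprintf("%s %.2f%%", x$group_names, 100 * x$proportions),
            collapse = ", "), "\n")
  if (x$rotated) cat("  loadings are varimax-rotated and aligned\n")
  invisible(x)
}

#' Summarize a group factor analysis fit
#'
#' @param object a [group_fa()] fit.
#' @param digits number of digits for the printed loadings.
#' @param ... unused.
#' @return An object of class `"summary.group_fa"`.
#' @export
summary.group_fa <- function(object, digits = 3, ...) {
  structure(list(fit = object, digits = digits), class = "summary.group_fa")
}

#' @export
print.summary.group_fa <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nShared error variances (psi):\n")
  print(round(f$psi, x$digits))
  for (g in f$group_names) {
    cat(sprintf("\nLoadings, group %s (mean in last column):\n", g))
    print(round(cbind(f$loadings[[g]], mean = f$means[[g]]), x$digits))
  }
  invisible(x)
}

#' @export
coef.group_fa <- function(object, ...) object$loadings

#' @export
logLik.group_fa <- function(object, ...) {
  M <- length(object$loadings)
  D <- length(object$psi)
  K <- object$n_factors
  val <- object$loglik
  attr(val, "df") <- M * D * (K + 1) + D + (M - 1)
  attr(val, "nobs") <- nrow(object$x)
  class(val) <- "logLik"
  val
}

#' Factor scores and fitted values for new subjects
#'
#' `type = "scores"` returns the conditional factor means
#' \eqn{E[f_i | w_j, x_i]} for each subject's group; `type = "response"`
#' returns the model reconstruction \eqn{\mu_j + L_j E[f_i | w_j, x_i]}.
#' The group is either supplied (`groups`), or taken as the posterior-mode
#' group under the fitted proportions.
#'
#' @param object a [group_fa()] fit.
#' @param newdata `N x D` matrix; defaults to the training data.
#' @param groups optional labels assigning each row to a group; when
#'   omitted, the argmax posterior responsibility is used.
#' @param type `"scores"` or `"response"`.
#' @param ... unused.
#' @return `N x K` score matrix or `N x D` reconstruction.
#' @export
predict.group_fa <- function(object, newdata = NULL, groups = NULL,
                             type = c("scores", "response"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else .as_numeric_matrix(newdata, "newdata")
  if (is.null(groups)) {
    h <- posterior_responsibilities(object, x)
    gindex <- max.col(h, ties.method = "first")
  } else {
    g <- if (is.factor(groups)) groups else factor(groups, levels = object$group_names)
    if (anyNA(g)) stop("unknown group label in 'groups'", call. = FALSE)
    gindex <- as.integer(g)
  }
  K <- object$n_factors
  out <- matrix(0, nrow(x), if (type == "scores") K else ncol(x))
  for (j in seq_along(object$loadings)) {
    rows <- which(gindex == j)
    if (!length(rows)) next
    fm <- conditional_factor_mean(x[rows, , drop = FALSE],
                                  object$loadings[[j]], object$means[[j]], object$psi)
    fm <- matrix(fm, ncol = K)
    if (type == "scores") {
      out[rows, ] <- fm
    } else {
      out[rows, ] <- sweep(tcrossprod(fm, object$loadings[[j]]), 2L,
                           object$means[[j]], `+`)
    }
  }
  colnames(out) <- if (type == "scores") paste0("F", seq_len(K)) else object$feature_names
  out
}

#' @export
fitted.group_fa <- function(object, ...) {
  predict(object, groups = object$groups, type = "response")
}

#' @export
residuals.group_fa <- function(object, ...) {
  object$x - fitted(object)
}

#' Simulate cohorts from a fitted group factor analysis model
#'
#' Draws new subjects from the fitted generative model: group labels from
#' the fitted proportions, standard-normal factors, Gaussian noise with the
#' fitted diagonal covariance.
#'
#' @param object a [group_fa()] fit.
#' @param nsim number of cohorts to draw.
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @param n_subjects cohort size, defaulting to the training size.
#' @param ... unused.
#' @return A list of `nsim` cohorts as returned by [simulate_cohort()].
#' @export
simulate.group_fa <- function(object, nsim = 1, seed = NULL,
                              n_subjects = nrow(object$x), ...) {
  base_seed <- if (is.null(seed)) sample.int(2^31 - 2, 1) else as.integer(seed)
  lapply(seq_len(nsim), function(s) {
    spec <- cohort_spec(loadings = object$loadings, means = object$means,
                        psi = object$psi, proportions = object$proportions,
                        n_subjects = n_subjects, seed = base_seed + s - 1L,
                        label_names = object$group_names)
    simulate_cohort(spec)
  })
}

#' Plot method for group factor analysis fits
#'
#' Draws one loading profile panel per group (features on the x axis, one
#' line per factor) plus the EM log-likelihood trace.
#'
#' @param x a [group_fa()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.group_fa <- function(x, ...) {
  M <- length(x$loadings)
  oldpar <- graphics::par(mfrow = c(1, M + 1), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(oldpar))
  ylim <- range(unlist(x$loadings))
  for (g in x$group_names) {
    graphics::matplot(x$loadings[[g]], type = "b", pch = 16, lty = 1,
                      ylim = ylim, xaxt = "n", ylab = "loading", main = g, ...)
    graphics::axis(1, at = seq_along(x$feature_names), labels = x$feature_names,
                   las = 2, cex.axis = 0.7)
    graphics::abline(h = 0, col = "grey70")
  }
  graphics::plot(seq_along(x$loglik_trace) - 1L, x$loglik_trace, type = "l",
                 xlab = "EM iteration", ylab = "log likelihood",
                 main = "EM trace")
  invisible(x)
}
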