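#' Normalize structure volumes by intracranial volume
#'
#' Converts absolute regional volumes into intracranial-volume (ICV) ratios,
#' the conventional correction that removes head-size differences before any
#' morphometric analysis: each subject's row of volumes is divided by that
#' subject's estimated total intracranial volume.
#'
#' @param volumes numeric matrix or data frame, subjects in rows and regional
#'   volumes in columns. All entries must be finite.
#' @param icv numeric vector of strictly positive intracranial volumes, one
#'   per subject (same units as `volumes`).
#' @return A numeric matrix of volume ratios with the dimnames of `volumes`.
#' @examples
#' volume_normalize(rbind(c(3, 6), c(5, 10)), icv = c(3, 5))
#' @export
volume_normalize <- function(volumes, icv) {
  volumes <- .as_numeric_matrix(volumes, "volumes")
  icv <- as.numeric(icv)
  if (length(icv) != nrow(volumes)) {
    stop(sprintf("'icv' has length %d but 'volumes' has %d rows",
                 length(icv), nrow(volumes)), call. = FALSE)
  }
  bad <- which(!is.finite(icv) | icv <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or missing ICV for subject(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  volumes / icv
}

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Centers every column at its pooled (all-subject) mean and scales it to
#' unit sample variance (unbiased, `N-1` denominator). This is the single
#' global preprocessing pass applied before group modelling, so that no
#' feature dominates the loadings merely through its measurement scale. The
#' removed means and standard deviations are returned so the transformation
#' can be inverted.
#'
#' @param x numeric matrix or data frame of continuous features, subjects in
#'   rows. Columns must be non-constant.
#' @param mle_variance logical; if `TRUE`, scale by the maximum-likelihood
#'   standard deviation (`N` denominator) instead of the sample one. Default
#'   `FALSE`.
#' @return A list of class `"feature_scaling"` with elements `x` (the
#'   standardized matrix), `center` and `scale` (the per-feature means and
#'   standard deviations removed).
#' @seealso [unstandardize_features()]
#' @examples
#' s <- standardize_features(matrix(rnorm(40, 5, 4), 10, 4))
#' round(colMeans(s$x), 12)
#' @export
standardize_features <- function(x, mle_variance = FALSE) {
  x <- .as_numeric_matrix(x, "x")
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (mle_variance) sds <- sds * sqrt((nrow(x) - 1) / nrow(x))
  const <- which(!is.finite(sds) | sds <= 0)
  if (length(const)) {
    nm <- colnames(x)[const]
    if (is.null(nm)) nm <- as.character(const)
    stop(sprintf("constant feature(s) cannot be standardized: %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, ctr, `-`), 2L, sds, `/`)
  structure(list(x = z, center = ctr, scale = sds),
            class = "feature_scaling")
}

#' Invert a feature standardization
#'
#' @param x standardized numeric matrix.
#' @param scaling a `"feature_scaling"` object (or any list with `center`
#'   and `scale`) as returned by [standardize_features()].
#' @return The matrix on the original measurement scale.
#' @export
unstandardize_features <- function(x, scaling) {
  x <- .as_numeric_matrix(x, "x")
  sweep(sweep(x, 2L, scaling$scale, `*`), 2L, scaling$center, `+`)
}

#' Observed group proportions
#'
#' Computes the proportion of subjects in each diagnostic group,
#' \eqn{\pi_j = n_j / N}. These proportions act as the prior group
#' probabilities of the model when responsibilities are re-estimated.
#'
#' @param groups vector (factor, character or integer) of per-subject group
#'   labels; every level must be observed at least once.
#' @param percent logical; if `TRUE`, return percentages rounded to two
#'   decimals.
#' @return Named numeric vector of length `M` summing to 1 (or to 100 up to
#'   rounding of the components when `percent = TRUE`).
#' @examples
#' group_proportions(rep(c("NL", "vAD", "AD"), c(316, 70, 30)), percent = TRUE)
#' @export
group_proportions <- function(groups, percent = FALSE) {
  g <- if (is.factor(groups)) groups else factor(groups)
  if (anyNA(g)) stop("group labels contain missing values", call. = FALSE)
  cnt <- table(g)
  if (any(cnt == 0L)) {
    stop(sprintf("empty group(s): %s",
                 paste(names(cnt)[cnt == 0L], collapse = ", ")),
         call. = FALSE)
  }
  p <- as.numeric(cnt) / length(g)
  names(p) <- names(cnt)
  if (percent) round(100 * p, 2) else p
}
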