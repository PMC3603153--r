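# Seeded cohort generation straight from the generative model: a group
# label per subject, standard-normal latent factors, group loadings and
# mean, shared diagonal Gaussian noise. Ground truth is kept so parameter
# recovery can be measured end to end.

#' Specify a synthetic cohort
#'
#' Bundles and validates the ground-truth parameters from which
#' [simulate_cohort()] draws subjects.
#'
#' @param loadings list of `M` loading matrices, all `D x K`.
#' @param means list of `M` mean vectors of length `D`.
#' @param psi non-negative vector of length `D` (diagonal error covariance;
#'   zero entries give noiseless features).
#' @param proportions `M` group probabilities summing to 1.
#' @param n_subjects cohort size.
#' @param seed integer seed making the draw reproducible.
#' @param label_names optional `M` group names.
#' @param fixed_sizes logical; if `TRUE`, group sizes are set
#'   deterministically to `round(proportions * n_subjects)` instead of
#'   multinomially sampled.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(loadings, means, psi, proportions, n_subjects,
                        seed = 1L, label_names = NULL, fixed_sizes = FALSE) {
  loadings <- lapply(loadings, as.matrix)
  M <- length(loadings)
  D <- nrow(loadings[[1L]])
  K <- ncol(loadings[[1L]])
  stopifnot(M >= 1L, length(means) == M, length(proportions) == M,
            all(vapply(loadings, function(L) all(dim(L) == c(D, K)), TRUE)),
            all(lengths(means) == D), length(psi) == D)
  psi <- as.numeric(psi)
  if (any(psi < 0)) stop("'psi' must be non-negative", call. = FALSE)
  proportions <- as.numeric(proportions)
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions <= 0)) {
    stop("'proportions' must be positive and sum to 1", call. = FALSE)
  }
  if (is.null(label_names)) label_names <- paste0("G", seq_len(M))
  structure(list(loadings = loadings, means = lapply(means, as.numeric),
                 psi = psi, proportions = proportions,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 label_names = as.character(label_names),
                 fixed_sizes = isTRUE(fixed_sizes)),
            class = "cohort_spec")
}

#' Draw a synthetic cohort from a specification
#'
#' Samples `n_subjects` subjects: a group label from the specification's
#' proportions (or deterministic sizes when `fixed_sizes`), a standard
#' normal `K`-vector of factor scores, and Gaussian noise with the shared
#' diagonal covariance; the observed vector is `mu_j + L_j f + u`. The same
#' seed yields bit-identical output. If multinomial sampling leaves any
#' group empty the labels are redrawn (deterministically within the seeded
#' stream) up to 10 times before erroring.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `"gfa_cohort"`: `x` (`N x D`, named columns),
#'   `groups` (factor), `scores` (`N x K` true factor scores), `ids`, and
#'   the originating `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  M <- length(spec$loadings)
  D <- nrow(spec$loadings[[1L]])
  K <- ncol(spec$loadings[[1L]])
  N <- spec$n_subjects
  sim <- withr::with_seed(spec$seed, {
    if (spec$fixed_sizes) {
      sizes <- round(spec$proportions * N)
      sizes[M] <- N - sum(sizes[-M])
      gindex <- rep.int(seq_len(M), sizes)
    } else {
      for (attempt in seq_len(10L)) {
        gindex <- sample.int(M, N, replace = TRUE, prob = spec$proportions)
        if (min(tabulate(gindex, M)) >= 1L) break
        if (attempt == 10L) {
          stop("a group remained empty after 10 label redraws; increase n_subjects",
               call. = FALSE)
        }
      }
    }
    f <- matrix(stats::rnorm(N * K), N, K)
    u <- matrix(stats::rnorm(N * D), N, D) %*% diag(sqrt(spec$psi), D)
    x <- matrix(0, N, D)
    for (j in seq_len(M)) {
      rows <- gindex == j
      x[rows, ] <- sweep(tcrossprod(f[rows, , drop = FALSE], spec$loadings[[j]]),
                         2L, spec$means[[j]], `+`)
    }
    list(x = x + u, gindex = gindex, f = f)
  })
  fnames <- rownames(spec$loadings[[1L]])
  if (is.null(fnames)) fnames <- paste0("V", seq_len(D))
  x <- sim$x
  colnames(x) <- fnames
  ids <- sprintf("S%04d", seq_len(N))
  rownames(x) <- ids
  structure(list(x = x,
                 groups = factor(spec$label_names[sim$gindex],
                                 levels = spec$label_names),
                 scores = sim$f, ids = ids, spec = spec),
            class = "gfa_cohort")
}

#' @export
print.gfa_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d features, %d groups (seed %d)\n",
              nrow(x$x), ncol(x$x), nlevels(x$groups), x$spec$seed))
  print(table(x$groups))
  invisible(x)
}

#' An Alzheimer's-like synthetic cohort specification
#'
#' Builds a ground-truth specification mimicking a subcortical-volume study
#' of dementia: 15 intracranial-volume-normalized features (7 bilateral
#' structure pairs plus the brain stem), three diagnostic groups (healthy
#' controls `NL`, very mild dementia `vAD`, moderate dementia `AD`) with
#' proportions 75.96% / 16.83% / 7.21%, and `K = 3` simple-structure
#' factors — limbic (hippocampus, amygdala, accumbens), striatal (caudate,
#' putamen, pallidum) and diencephalic (thalamus, brain stem). Bilateral
#' pairs share their loading, each feature loads on exactly one factor
#' (dominant loadings 0.65-0.85, communalities around 0.63-0.74 with the
#' shared error variance of 0.25), and the patient groups have downward
#' mean shifts of 0.3-0.9 concentrated on limbic and diencephalic
#' structures so that groups overlap and posterior memberships stay
#' non-binary.
#'
#' @param n_subjects cohort size (default 416).
#' @param seed integer seed stored in the spec.
#' @param fixed_sizes see [cohort_spec()].
#' @return A `"cohort_spec"`.
#' @export
ad_like_spec <- function(n_subjects = 416L, seed = 1L, fixed_sizes = FALSE) {
  features <- c("thalamus_l", "thalamus_r", "caudate_l", "caudate_r",
                "putamen_l", "putamen_r", "pallidum_l", "pallidum_r",
                "hippocampus_l", "hippocampus_r", "amygdala_l", "amygdala_r",
                "accumbens_l", "accumbens_r", "brainstem")
  # factor membership (exactly one loading per feature); bilateral pairs share
  factor_of <- c(thalamus = 3, caudate = 2, putamen = 2, pallidum = 2,
                 hippocampus = 1, amygdala = 1, accumbens = 1, brainstem = 3)
  base_mag <- c(thalamus = 0.85, caudate = 0.80, putamen = 0.85,
                pallidum = 0.70, hippocampus = 0.85, amygdala = 0.75,
                accumbens = 0.70, brainstem = 0.65)
  struct <- sub("_(l|r)$", "", features)
  make_loadings <- function(scale_by_factor) {
    L <- matrix(0, length(features), 3,
                dimnames = list(features, paste0("F", 1:3)))
    for (i in seq_along(features)) {
      k <- factor_of[[struct[i]]]
      L[i, k] <- base_mag[[struct[i]]] * scale_by_factor[k]
    }
    L
  }
  loadings <- list(
    NL  = make_loadings(c(1.00, 1.00, 1.00)),
    vAD = make_loadings(c(0.90, 1.00, 0.95)),
    AD  = make_loadings(c(0.80, 0.90, 0.90))
  )
  # downward atrophy shifts for patient groups, strongest where dementia
  # hits first (hippocampus, amygdala, thalamus, putamen)
  shift <- function(limbic, dien, striatal, other) {
    s <- numeric(length(features))
    s[struct %in% c("hippocampus", "amygdala")] <- limbic
    s[struct %in% c("thalamus", "putamen")] <- dien
    s[struct %in% c("caudate", "pallidum")] <- striatal
    s[struct %in% c("accumbens", "brainstem")] <- other
    s
  }
  means <- list(
    NL  = rep(0.10, length(features)),
    vAD = shift(-0.45, -0.35, -0.25, -0.15),
    AD  = shift(-0.90, -0.80, -0.50, -0.30)
  )
  cohort_spec(loadings = loadings, means = means,
              psi = rep(0.25, length(features)),
              proportions = c(0.7596, 0.1683, 0.0721),
              n_subjects = n_subjects, seed = seed,
              label_names = c("NL", "vAD", "AD"), fixed_sizes = fixed_sizes)
}
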