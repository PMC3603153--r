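# Orthogonal rotation leaves the model untouched: for any K x K orthogonal
# H, (LH)(LH)' + Psi = L L' + Psi, so loadings are only identified up to
# rotation, column permutation and column sign. Varimax picks an
# interpretable representative per group; the alignment step then matches
# columns and signs across groups so the M solutions are comparable.

#' Varimax criterion of a loading matrix
#'
#' The variance of the squared loadings summed over factors,
#' \eqn{\sum_k [ \sum_d \lambda_{dk}^4 / D - (\sum_d \lambda_{dk}^2 / D)^2 ]},
#' the objective that varimax rotation maximizes.
#'
#' @param loadings `D x K` numeric matrix.
#' @return A single number.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- as.matrix(loadings)^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

#' Varimax rotation
#'
#' Rotates a loading matrix by an orthogonal matrix maximizing the varimax
#' criterion, using the standard singular-value-decomposition ascent
#' algorithm. With Kaiser normalization (the default) rows are scaled to
#' unit communality before rotation and rescaled afterwards, which weights
#' all features equally in the criterion.
#'
#' @param loadings `D x K` numeric matrix.
#' @param kaiser logical; apply Kaiser row normalization?
#' @param tol relative convergence tolerance on the ascent objective.
#' @param max_iter maximum number of ascent iterations.
#' @return A list with `loadings` (the rotated matrix, exactly
#'   `loadings %*% rotmat`), the orthogonal `rotmat`, the achieved
#'   `criterion` and the iteration count.
#' @examples
#' L <- matrix(rnorm(30), 10, 3)
#' r <- varimax_rotate(L, kaiser = FALSE)
#' varimax_criterion(r$loadings) >= varimax_criterion(L)
#' @export
varimax_rotate <- function(loadings, kaiser = TRUE, tol = 1e-10,
                           max_iter = 1000L) {
  L <- as.matrix(loadings)
  D <- nrow(L); K <- ncol(L)
  if (K < 1L) stop("'loadings' needs at least one column", call. = FALSE)
  if (K == 1L) {
    return(list(loadings = L, rotmat = matrix(1, 1, 1),
                criterion = varimax_criterion(L), iterations = 0L))
  }
  if (kaiser) {
    comm <- sqrt(rowSums(L^2))
    zero <- which(comm < .Machine$double.eps)
    if (length(zero)) {
      nm <- rownames(L)[zero]
      if (is.null(nm)) nm <- as.character(zero)
      stop(sprintf("zero-communality row(s) with kaiser normalization: %s",
                   paste(nm, collapse = ", ")), call. = FALSE)
    }
    Lw <- L / comm
  } else {
    Lw <- L
  }
  H <- diag(K)
  d <- 0
  it <- 0L
  for (it in seq_len(max_iter)) {
    B <- Lw %*% H
    G <- crossprod(Lw, B^3 - B %*% diag(drop(rep(1, D) %*% B^2) / D, K))
    sv <- La.svd(G)
    H <- sv$u %*% sv$vt
    dpast <- d
    d <- sum(sv$d)
    if (d < dpast * (1 + tol)) break
  }
  # row scaling commutes with right-multiplication, so the raw-scale result
  # is exactly L %*% H
  out <- L %*% H
  dimnames(out) <- dimnames(L)
  list(loadings = out, rotmat = H, criterion = varimax_criterion(out),
       iterations = it)
}

#' Column-matching cost matrix between two loading matrices
#'
#' Builds the `K x K` assignment cost used to match factors across groups:
#' `cost[a, b]` is minus the absolute Pearson correlation between column
#' `a` of the reference and column `b` of the target. Zero-variance columns
#' get cost 0 (no similarity credit). Correlation is sign-blind here because
#' a factor and its negation describe the same axis.
#'
#' @param L_ref,L_tgt `D x K` numeric matrices.
#' @return `K x K` matrix of costs in `[-1, 0]`.
#' @export
alignment_cost <- function(L_ref, L_tgt) {
  L_ref <- as.matrix(L_ref); L_tgt <- as.matrix(L_tgt)
  stopifnot(all(dim(L_ref) == dim(L_tgt)))
  -abs(.safe_cor(L_ref, L_tgt))
}

# column-by-column Pearson correlation with zero-variance columns mapped to 0
.safe_cor <- function(A, B) {
  va <- apply(A, 2L, stats::var)
  vb <- apply(B, 2L, stats::var)
  C <- matrix(0, ncol(A), ncol(B))
  ok_a <- va > 0; ok_b <- vb > 0
  if (any(ok_a) && any(ok_b)) {
    C[ok_a, ok_b] <- stats::cor(A[, ok_a, drop = FALSE], B[, ok_b, drop = FALSE])
  }
  C
}

# minimum-cost perfect assignment on an n x n matrix by the shortest
# augmenting path (Jonker-Volgenant) formulation of the Hungarian method;
# returns assignment[row] = column
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1L) return(1L)
  u <- numeric(n)                 # row potentials
  v <- numeric(n + 1L)            # column potentials, slot 1 = virtual column
  p <- integer(n + 1L)            # p[j+1] = row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

#' Align factor loadings across groups
#'
#' Resolves the residual column-permutation and column-sign indeterminacy of
#' per-group factor solutions so that factor `k` means the same thing in
#' every group. For each non-reference group the `K x K` matching that
#' maximizes total absolute column correlation with the reference group is
#' found — with the Hungarian algorithm (`method = "hungarian"`, the
#' default) or by exhaustive enumeration of all `2^(K*M) * (K!)^M`
#' sign-and-permutation candidates (`method = "exhaustive"`, guarded to
#' `K <= 4`, `M <= 3`). Signs are chosen so matched correlations are
#' non-negative, with ties resolving to `+1`.
#'
#' @param L_list list of `M` loading matrices of identical shape.
#' @param reference index of the reference group (its map is the identity).
#' @param method `"hungarian"` or `"exhaustive"`.
#' @return An object of class `"factor_alignment"`: list with
#'   `permutations` (per group, `perm[k]` = source column matched to
#'   reference column `k`), `signs`, `reference`, `method`, the total
#'   matched `similarity`, and for the exhaustive path the enumerated
#'   candidate-space size `n_candidates`.
#' @export
align_loadings <- function(L_list, reference = 1L,
                           method = c("hungarian", "exhaustive")) {
  method <- match.arg(method)
  M <- length(L_list)
  L_list <- lapply(L_list, as.matrix)
  K <- ncol(L_list[[1L]])
  stopifnot(M >= 1L, reference >= 1L, reference <= M,
            all(vapply(L_list, function(L) all(dim(L) == dim(L_list[[1L]])), TRUE)))
  if (method == "exhaustive") return(.align_exhaustive(L_list, reference))

  perms <- rep(list(seq_len(K)), M)
  signs <- rep(list(rep(1, K)), M)
  total <- 0
  for (j in setdiff(seq_len(M), reference)) {
    C <- .safe_cor(L_list[[reference]], L_list[[j]])
    a <- .hungarian(-abs(C))
    perms[[j]] <- a
    matched <- C[cbind(seq_len(K), a)]
    signs[[j]] <- ifelse(matched < 0, -1, 1)   # ties (0) resolve to +1
    total <- total + sum(abs(matched))
  }
  structure(list(permutations = perms, signs = signs, reference = reference,
                 method = method, similarity = total),
            class = "factor_alignment")
}

# exhaustive search over the full candidate space the recurrence describes:
# every group (the reference included) tries all 2^K sign vectors and all
# K! column permutations; the objective is the total signed correlation of
# aligned columns with the aligned reference. The scan is organised as, for
# each reference candidate, a table lookup over each other group's
# candidates, which visits the same (2^K K!)^M space without materializing
# it. The winning map is canonicalized so the reference map is identity/+1.
.align_exhaustive <- function(L_list, reference) {
  M <- length(L_list)
  K <- ncol(L_list[[1L]])
  if (K > 4L || M > 3L) {
    stop(sprintf("exhaustive alignment would enumerate 2^%d * (%d!)^%d candidates; use method = 'hungarian'",
                 K * M, K, M), call. = FALSE)
  }
  perm_tab <- .permutations(K)                      # K! x K
  sign_tab <- as.matrix(expand.grid(rep(list(c(1, -1)), K)))[, seq_len(K), drop = FALSE]
  np <- nrow(perm_tab); ns <- nrow(sign_tab)
  others <- setdiff(seq_len(M), reference)
  Cs <- lapply(L_list, function(L) .safe_cor(L_list[[reference]], L))

  best <- -Inf
  best_ref <- NULL
  best_grp <- vector("list", M)
  for (pr in seq_len(np)) {
    for (sr in seq_len(ns)) {
      sigma0 <- perm_tab[pr, ]
      s0 <- sign_tab[sr, ]
      total <- 0
      grp_choice <- vector("list", M)
      for (j in others) {
        # row-permute and row-sign the correlation table by the reference map
        Cp <- Cs[[j]][sigma0, , drop = FALSE] * s0
        gbest <- -Inf; gpick <- NULL
        for (q in seq_len(np)) {
          v <- Cp[cbind(seq_len(K), perm_tab[q, ])]
          sc <- as.numeric(sign_tab %*% v)
          w <- which.max(sc)
          if (sc[w] > gbest) {
            gbest <- sc[w]
            gpick <- list(perm = perm_tab[q, ], sign = sign_tab[w, ])
          }
        }
        total <- total + gbest
        grp_choice[[j]] <- gpick
      }
      if (total > best) {
        best <- total
        best_ref <- list(perm = sigma0, sign = s0)
        best_grp <- grp_choice
      }
    }
  }

  # canonical form: compose with the inverse of the reference candidate so
  # the reference group keeps identity order and +1 signs
  perms <- rep(list(seq_len(K)), M)
  signs <- rep(list(rep(1, K)), M)
  for (j in others) {
    p <- integer(K); s <- numeric(K)
    for (k in seq_len(K)) {
      m <- best_ref$perm[k]
      p[m] <- best_grp[[j]]$perm[k]
      s[m] <- best_ref$sign[k] * best_grp[[j]]$sign[k]
    }
    perms[[j]] <- p
    signs[[j]] <- s
  }
  structure(list(permutations = perms, signs = signs, reference = reference,
                 method = "exhaustive", similarity = best,
                 n_candidates = (2^K * factorial(K))^M),
            class = "factor_alignment")
}

#' @export
print.factor_alignment <- function(x, ...) {
  cat(sprintf("Factor alignment (%s), reference group %d, total similarity %.4f\n",
              x$method, x$reference, x$similarity))
  for (j in seq_along(x$permutations)) {
    cat(sprintf("  group %d: columns (%s), signs (%s)\n", j,
                paste(x$permutations[[j]], collapse = ", "),
                paste(ifelse(x$signs[[j]] < 0, "-", "+"), collapse = ", ")))
  }
  invisible(x)
}

#' Apply a sign/permutation map to loadings and scores
#'
#' Jointly permutes and sign-flips the columns of a loading matrix and the
#' corresponding factor-score columns. Because each loading column and its
#' score column carry the same flip, the model contribution `L %*% t(S)` is
#' unchanged.
#'
#' @param loadings `D x K` matrix.
#' @param scores optional `N x K` score matrix transformed jointly.
#' @param permutation integer vector; output column `k` is input column
#'   `permutation[k]`.
#' @param signs vector of `+1`/`-1` applied to the output columns.
#' @return List with transformed `loadings` and (if given) `scores`.
#' @export
apply_alignment <- function(loadings, scores = NULL, permutation, signs) {
  L <- as.matrix(loadings)
  K <- ncol(L)
  stopifnot(length(permutation) == K, length(signs) == K,
            all(sort(permutation) == seq_len(K)), all(signs %in% c(-1, 1)))
  Lout <- sweep(L[, permutation, drop = FALSE], 2L, signs, `*`)
  colnames(Lout) <- colnames(L)
  out <- list(loadings = Lout)
  if (!is.null(scores)) {
    S <- as.matrix(scores)
    Sout <- sweep(S[, permutation, drop = FALSE], 2L, signs, `*`)
    colnames(Sout) <- colnames(S)
    out$scores <- Sout
  }
  out
}

#' Varimax-rotate and align a fitted model
#'
#' Post-processes a [group_fa()] fit for interpretation: each group's
#' loadings are varimax-rotated (subjects' scores are rotated by the same
#' orthogonal matrix, so the model is unchanged), then columns are matched
#' and sign-fixed across groups against a reference group. The returned fit
#' has comparable loading matrices; its likelihood is identical to the
#' input's.
#'
#' @param object a [group_fa()] fit.
#' @param kaiser logical, Kaiser normalization for varimax.
#' @param reference reference group index for the alignment.
#' @param method alignment method, see [align_loadings()].
#' @return The fit with rotated/aligned `loadings` and `scores`, plus
#'   `rotation` (per-group orthogonal matrices) and `alignment` fields.
#' @export
align_model <- function(object, kaiser = TRUE, reference = 1L,
                        method = "hungarian") {
  stopifnot(inherits(object, "group_fa"))
  M <- length(object$loadings)
  gindex <- as.integer(object$groups)
  rotation <- vector("list", M)
  for (j in seq_len(M)) {
    vr <- varimax_rotate(object$loadings[[j]], kaiser = kaiser)
    object$loadings[[j]] <- vr$loadings
    rotation[[j]] <- vr$rotmat
    rows <- gindex == j
    # f* = H' f, so row-vector scores transform as S H
    object$scores[rows, ] <- object$scores[rows, , drop = FALSE] %*% vr$rotmat
  }
  amap <- align_loadings(object$loadings, reference = reference, method = method)
  for (j in seq_len(M)) {
    rows <- gindex == j
    ap <- apply_alignment(object$loadings[[j]],
                          object$scores[rows, , drop = FALSE],
                          amap$permutations[[j]], amap$signs[[j]])
    object$loadings[[j]] <- ap$loadings
    object$scores[rows, ] <- ap$scores
  }
  names(rotation) <- object$group_names
  object$rotation <- rotation
  object$alignment <- amap
  object$rotated <- TRUE
  object
}
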