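# internal helpers shared across the package

# coerce to a numeric matrix, preserving dimnames; error with the argument name
.as_numeric_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) {
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad)) {
      stop(sprintf("'%s' has non-numeric columns: %s", arg,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' contains a non-finite value at row %d, column %d",
                 arg, idx[1L], idx[2L]), call. = FALSE)
  }
  x
}

# row-wise log(sum(exp(m))), guarding all-(-Inf) rows
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# normalize groups to a factor and validate membership counts
.as_group_factor <- function(groups, min_size = 1L) {
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (anyNA(g)) stop("group labels contain missing values", call. = FALSE)
  cnt <- table(g)
  if (any(cnt < min_size)) {
    stop(sprintf("group(s) with fewer than %d members: %s", min_size,
                 paste(names(cnt)[cnt < min_size], collapse = ", ")),
         call. = FALSE)
  }
  g
}

# all permutations of 1..k as a (k!) x k integer matrix
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    shifted <- sub + (sub >= i)
    out[[i]] <- cbind(rep(i, nrow(sub)), shifted, deparse.level = 0L)
  }
  do.call(rbind, out)
}
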