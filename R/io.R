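# File interchange: cohort CSV (one id column, one label column, numeric
# feature columns), YAML/JSON run configuration, and pretty-printed JSON
# parameter artifacts with alphabetically sorted keys so reruns diff
# cleanly.

#' Read a cohort CSV
#'
#' @param path CSV file with a header row; comma separated, `.` decimal.
#' @param id_column,label_column names of the subject-id and group-label
#'   columns; every remaining column must be numeric and is taken as a
#'   feature.
#' @return A list of class `"gfa_cohort"` with `x`, `groups`, `ids`.
#' @export
read_cohort <- function(path, id_column = "subject_id", label_column = "group") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_column, label_column), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  feat <- setdiff(names(df), c(id_column, label_column))
  if (!length(feat)) stop("no feature columns found", call. = FALSE)
  x <- .as_numeric_matrix(df[feat], "features")
  rownames(x) <- as.character(df[[id_column]])
  structure(list(x = x,
                 groups = factor(df[[label_column]]),
                 ids = as.character(df[[id_column]])),
            class = "gfa_cohort")
}

#' Write a cohort CSV
#'
#' @param cohort a `"gfa_cohort"` (from [simulate_cohort()] or
#'   [read_cohort()]) or a list with `x`, `groups` and optionally `ids`.
#' @param path output file.
#' @param id_column,label_column column names to use.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, id_column = "subject_id",
                         label_column = "group") {
  ids <- cohort$ids
  if (is.null(ids)) ids <- rownames(cohort$x)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(cohort$x)))
  df <- data.frame(ids, as.character(cohort$groups),
                   cohort$x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c(id_column, label_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# recursively sort list keys so serialized JSON is byte-stable
.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else if (is.list(x)) {
    lapply(x, .sort_keys)
  } else x
}

.write_json <- function(x, path) {
  json <- jsonlite::toJSON(.sort_keys(x), pretty = TRUE, digits = NA,
                           auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Serialize fitted model parameters to JSON
#'
#' Writes `{groups: [{name, loading, mean}], psi, proportions, K, mode,
#' loglik, feature_names}` with sorted keys and full precision.
#'
#' @param model a [group_fa()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_params()]
#' @export
write_params <- function(model, path) {
  obj <- list(
    K = model$n_factors,
    feature_names = model$feature_names,
    groups = lapply(seq_along(model$loadings), function(j) {
      list(name = model$group_names[j],
           loading = unname(model$loadings[[j]]),
           mean = unname(model$means[[j]]))
    }),
    loglik = model$loglik,
    mode = model$mode,
    proportions = unname(model$proportions),
    psi = unname(model$psi)
  )
  .write_json(obj, path)
}

#' Read model parameters from JSON
#'
#' Rebuilds a parameter list usable with [posterior_responsibilities()],
#' [gfa_loglik()], [diagnose()] and [predict.group_fa()]-style score
#' computation.
#'
#' @param path a file written by [write_params()].
#' @return A list with `loadings`, `means`, `psi`, `proportions`,
#'   `n_factors`, `mode`, `loglik`, `group_names`, `feature_names`.
#' @export
read_params <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  loadings <- lapply(obj$groups, function(g) {
    L <- as.matrix(g$loading)
    dimnames(L) <- list(obj$feature_names, paste0("F", seq_len(ncol(L))))
    L
  })
  means <- lapply(obj$groups, function(g) {
    stats::setNames(as.numeric(g$mean), obj$feature_names)
  })
  gnames <- vapply(obj$groups, `[[`, character(1), "name")
  names(loadings) <- names(means) <- gnames
  list(loadings = loadings, means = means,
       psi = stats::setNames(as.numeric(obj$psi), obj$feature_names),
       proportions = stats::setNames(as.numeric(obj$proportions), gnames),
       n_factors = as.integer(obj$K), mode = obj$mode,
       loglik = as.numeric(obj$loglik),
       group_names = gnames, feature_names = obj$feature_names)
}

#' Read a cohort specification from YAML/JSON
#'
#' Accepts either a full specification (loadings, means, psi, proportions,
#' n_subjects, seed, label_names) or a shorthand
#' `{preset: "ad_like", n_subjects, seed}`.
#'
#' @param path YAML or JSON file.
#' @return A [cohort_spec()].
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$preset)) {
    if (!identical(obj$preset, "ad_like")) {
      stop(sprintf("unknown preset '%s'", obj$preset), call. = FALSE)
    }
    return(ad_like_spec(n_subjects = obj$n_subjects %||% 416L,
                        seed = obj$seed %||% 1L,
                        fixed_sizes = isTRUE(obj$fixed_sizes)))
  }
  required <- c("loadings", "means", "psi", "proportions", "n_subjects", "seed")
  missing_keys <- setdiff(required, names(obj))
  if (length(missing_keys)) {
    stop(sprintf("cohort spec %s is missing key(s): %s", path,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  feature_names <- obj$feature_names
  loadings <- lapply(obj$loadings, function(L) {
    L <- if (is.list(L)) do.call(rbind, lapply(L, as.numeric)) else as.matrix(L)
    rownames(L) <- feature_names
    L
  })
  cohort_spec(loadings = loadings,
              means = lapply(obj$means, as.numeric),
              psi = as.numeric(obj$psi),
              proportions = as.numeric(obj$proportions),
              n_subjects = obj$n_subjects, seed = obj$seed,
              label_names = obj$label_names,
              fixed_sizes = isTRUE(obj$fixed_sizes))
}

#' Write a cohort specification as JSON ground truth
#'
#' @param spec a [cohort_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  obj <- list(
    feature_names = rownames(spec$loadings[[1L]]),
    fixed_sizes = spec$fixed_sizes,
    label_names = spec$label_names,
    loadings = unname(lapply(spec$loadings, unname)),
    means = unname(lapply(spec$means, unname)),
    n_subjects = spec$n_subjects,
    proportions = spec$proportions,
    psi = spec$psi,
    seed = spec$seed
  )
  .write_json(obj, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration (YAML or JSON)
#'
#' Required keys: `input_path`, `K`, `seed`, `output_dir`. Optional keys
#' with defaults: `label_column` ("group"), `id_column` ("subject_id"),
#' `mode` ("supervised"), `tol` (1e-6), `max_iter` (1000), `kaiser`
#' (TRUE), `psi_floor` (1e-6), `reference` (1), `covariate_column`.
#'
#' @param path configuration file.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  as_run_config(obj)
}

#' @rdname read_run_config
#' @param config a named list of configuration values.
#' @export
as_run_config <- function(config) {
  required <- c("input_path", "K", "seed", "output_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop(sprintf("run config is missing key(s): %s",
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(label_column = "group", id_column = "subject_id",
                   mode = "supervised", tol = 1e-6, max_iter = 1000L,
                   kaiser = TRUE, psi_floor = 1e-6, reference = 1L,
                   covariate_column = NULL)
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  if (config$K < 1L) stop("config 'K' must be >= 1", call. = FALSE)
  structure(config, class = "run_config")
}
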