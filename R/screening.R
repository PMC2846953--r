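#' Rank candidate predictors by ensemble-tree importance
#'
#' Fits a random forest of \code{n_trees} regression trees to the encoded
#' analysis table and ranks every candidate column by permutation
#' (out-of-bag) variable importance. Permutation importance is used in
#' preference to impurity importance because it is robust to the mixed
#' continuous/indicator design; negative importances are truncated at
#' zero after ranking.
#'
#' All response-role columns and any columns named in \code{exclude}
#' (variables trivially related to the target) are removed from the
#' candidate set.
#'
#' @param enc an \code{encoded_table} (typically the imputed analysis
#'   partition).
#' @param response response column name.
#' @param n_trees number of trees (default 10000).
#' @param seed integer seed.
#' @param exclude further columns to exclude from the candidates.
#' @param analysis_only restrict to rows with \code{partition ==
#'   "analysis"} when partitions are assigned (default \code{TRUE}).
#' @return data frame with columns \code{variable} and \code{importance},
#'   sorted by decreasing importance.
#' @export
rank_variables <- function(enc, response, n_trees = 10000, seed = 1L,
                           exclude = character(), analysis_only = TRUE) {
  stopifnot(inherits(enc, "encoded_table"))
  df <- screening_frame(enc, analysis_only)
  responses <- enc$meta$name[enc$meta$role == "response"]
  candidates <- setdiff(names(df), c(responses, exclude))
  candidates <- candidates[vapply(df[candidates], function(x)
    stats::var(x) > 0, logical(1))]
  if (length(candidates) < 2L)
    stop("need at least 2 candidate predictors")
  fit <- ranger::ranger(
    x = df[candidates], y = df[[response]],
    num.trees = n_trees, importance = "permutation", seed = seed,
    num.threads = 1L)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  data.frame(variable = names(imp), importance = pmax(imp, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Data frame of encoded columns (optionally analysis rows only).
screening_frame <- function(enc, analysis_only = TRUE) {
  df <- enc$data
  if (!is.null(enc$smoking_status)) df$smoking_status <- enc$smoking_status
  if (analysis_only && !is.null(enc$partition) &&
      any(enc$partition == "analysis"))
    df <- df[enc$partition == "analysis", , drop = FALSE]
  df
}

#' Build nested predictor sets with cross-validated R-squared
#'
#' From an importance ranking, forms the nested sets {top-1, top-2, ...,
#' top-\code{max_size}} and attaches to each the k-fold cross-validated
#' R-squared of a random forest restricted to that set. The fold
#' assignment is seeded and shared across all sets so the R-squared
#' sequence is comparable; it is reported unsmoothed.
#'
#' @param ranking output of [rank_variables()].
#' @param enc the \code{encoded_table} used for ranking.
#' @param response response column name.
#' @param max_size size of the largest set (default 30).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed.
#' @param n_trees trees per cross-validation fit (default 300; the
#'   ranking forest, not these, carries the importance estimates).
#' @param analysis_only restrict to analysis rows (default \code{TRUE}).
#' @return list of \code{predictor_set} objects (fields
#'   \code{variables}, \code{cv_r2}, \code{size_class}).
#' @export
build_nested_sets <- function(ranking, enc, response, max_size = 30,
                              folds = 10, seed = 1L, n_trees = 300,
                              analysis_only = TRUE) {
  if (nrow(ranking) < max_size)
    stop("ranking has fewer than max_size variables")
  df <- screening_frame(enc, analysis_only)
  y <- df[[response]]
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  sst <- sum((y - mean(y))^2)
  sets <- vector("list", max_size)
  for (k in seq_len(max_size)) {
    vars <- ranking$variable[seq_len(k)]
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- ranger::ranger(
        x = df[!test, vars, drop = FALSE], y = y[!test],
        num.trees = n_trees, seed = seed + f, num.threads = 1L)
      pred[test] <- stats::predict(fit,
        data = df[test, vars, drop = FALSE])$predictions
    }
    cv_r2 <- 1 - sum((y - pred)^2) / sst
    sets[[k]] <- structure(
      list(variables = vars, cv_r2 = cv_r2, size_class = "none"),
      class = "predictor_set")
  }
  sets
}

#' Choose large, medium and small predictor sets
#'
#' The large set is the largest available (size 30 by construction). The
#' small and medium sets mark natural cut points in the cross-validated
#' R-squared sequence: small is the smallest set within
#' \code{tol_small} (default 0.02) of the maximum R-squared, medium the
#' smallest within \code{tol_medium} (default 0.005), constrained to be
#' at least as large as small. A flat (degenerate) sequence collapses
#' both to size 1 with a warning.
#'
#' @param sets list of \code{predictor_set}s from [build_nested_sets()].
#' @param tol_small,tol_medium R-squared tolerances defining the cut
#'   points.
#' @return list with elements \code{large}, \code{medium}, \code{small}
#'   (each a \code{predictor_set} with \code{size_class} filled in).
#' @export
choose_set_sizes <- function(sets, tol_small = 0.02, tol_medium = 0.005) {
  if (length(sets) < 3L) stop("need at least 3 predictor sets")
  r2 <- vapply(sets, `[[`, numeric(1), "cv_r2")
  best <- max(r2)
  if (diff(range(r2)) < .Machine$double.eps^0.5) {
    warning("flat cross-validated R-squared sequence; small = medium = 1")
    small_k <- medium_k <- 1L
  } else {
    small_k <- which(r2 >= best - tol_small)[1L]
    medium_k <- which(r2 >= best - tol_medium)[1L]
    medium_k <- max(medium_k, small_k)
  }
  large <- sets[[length(sets)]]; large$size_class <- "large"
  medium <- sets[[medium_k]]; medium$size_class <- "medium"
  small <- sets[[small_k]]; small$size_class <- "small"
  list(large = large, medium = medium, small = small)
}

#' Augment predictor sets with the nine BOE and smoking status
#'
#' Before spline fitting, every predictor set is augmented by adding all
#' nine biomarkers of exposure and a binary smoking-status indicator
#' (duplicates removed, original ranking order preserved).
#'
#' @param sets list of \code{predictor_set}s (e.g. from
#'   [choose_set_sizes()]).
#' @param enc the \code{encoded_table}; its metadata identifies the BOE.
#' @return the augmented sets.
#' @export
augment_predictor_sets <- function(sets, enc) {
  stopifnot(inherits(enc, "encoded_table"))
  boe <- enc$meta$name[enc$meta$role == "boe"]
  boe <- intersect(boe, names(enc$data))
  extra <- c(boe, "smoking_status")
  lapply(sets, function(s) {
    s$variables <- unique(c(s$variables, extra))
    s
  })
}

#' Screening report table
#'
#' @param ranking output of [rank_variables()].
#' @param sets output of [build_nested_sets()].
#' @return data frame with rank, variable, importance, and the
#'   (size, cv_r2) sequence merged in.
#' @export
screening_report <- function(ranking, sets) {
  r2 <- vapply(sets, `[[`, numeric(1), "cv_r2")
  k <- length(r2)
  data.frame(rank = seq_len(nrow(ranking)),
             variable = ranking$variable,
             importance = ranking$importance,
             set_size = c(seq_len(k),
                          rep(NA_integer_, max(0, nrow(ranking) - k))),
             set_cv_r2 = c(r2, rep(NA_real_, max(0, nrow(ranking) - k))),
             stringsAsFactors = FALSE)
}
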