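#' Run the full adaptive modeling workflow for one response
#'
#' End-to-end orchestration of the pipeline on a cohort:
#' \enumerate{
#'   \item preprocessing (BLLOQ substitution, 80/20 analysis/validation
#'     split, missing-response dropping, stratified median imputation,
#'     categorical encoding);
#'   \item ensemble-tree screening on the imputed analysis partition:
#'     importance ranking, nested predictor sets with cross-validated
#'     R-squared, large/medium/small set selection, augmentation with
#'     the nine BOE and smoking status;
#'   \item spline grid search over the control lattice and selection of
#'     the preferred (well-fitting, parsimonious) model;
#'   \item reparametrization into the threshold basis and complete-case
#'     OLS refit on the unimputed analysis partition;
#'   \item application and refit on the validation partition;
#'   \item marginal / delta R-squared group importance.
#' }
#'
#' @param cohort a \code{boph_cohort}.
#' @param response response variable name (one of the BOPH).
#' @param seed integer seed driving the split, screening and fold
#'   assignments.
#' @param split_fraction analysis fraction of the split (default 0.8).
#' @param n_trees_rank trees for the importance ranking (default 10000).
#' @param n_trees_cv trees per screening cross-validation fit.
#' @param screening_folds folds for the screening cross-validation.
#' @param max_set_size size of the large predictor set (default 30; use
#'   fewer than the candidate count).
#' @param model_types,max_basis,entry_penalties spline control lattice.
#' @param min_span minimum observations between candidate knots.
#' @param tolerance GCV R-squared tolerance of [select_preferred()].
#' @param exclude variables excluded from screening (on top of the
#'   responses, which are always excluded).
#' @return list with the preprocessing report, screening artifacts, grid
#'   records, the preferred spline model, its threshold form, analysis
#'   and validation fits, group importance, and the five summary
#'   statistics consumed by [fit_summary()].
#' @export
run_boph_pipeline <- function(cohort, response, seed = 1L,
                              split_fraction = 0.8,
                              n_trees_rank = 10000, n_trees_cv = 300,
                              screening_folds = 10, max_set_size = 30,
                              model_types = c(0, 1, 2),
                              max_basis = c(10, 20, 30, 60),
                              entry_penalties = c(0, 0.01),
                              min_span = 3, tolerance = 0.01,
                              exclude = character()) {
  pp <- preprocess_cohort(cohort, response, fraction = split_fraction,
                          seed = seed)
  enc <- pp$encoded

  ranking <- rank_variables(enc, response, n_trees = n_trees_rank,
                            seed = seed, exclude = exclude)
  max_set_size <- min(max_set_size, nrow(ranking))
  nested <- build_nested_sets(ranking, enc, response,
                              max_size = max_set_size,
                              folds = screening_folds, seed = seed,
                              n_trees = n_trees_cv)
  sizes <- choose_set_sizes(nested)
  sets <- augment_predictor_sets(sizes, enc)
  screening_cv_r2 <- sizes$large$cv_r2

  grid <- grid_search(enc, response, sets, model_types = model_types,
                      max_basis = max_basis,
                      entry_penalties = entry_penalties,
                      min_span = min_span, seed = seed)
  pref <- select_preferred(grid, tolerance = tolerance)
  tmodel <- hinge_to_threshold(pref$model, enc$provenance)

  raw <- pp$cohort$data
  analysis <- raw[raw$partition == "analysis", , drop = FALSE]
  validation <- raw[raw$partition == "validation", , drop = FALSE]
  refit <- refit_ols(tmodel, analysis, response)
  val <- validate_model(refit, validation, response)
  importance <- group_importance(refit, analysis, response)

  list(response = response,
       report = pp$report,
       ranking = ranking,
       nested_sets = nested,
       sets = sizes,
       grid = grid[, setdiff(names(grid), "id"), drop = FALSE],
       preferred = pref,
       threshold_model = tmodel,
       analysis_fit = refit,
       validation = val,
       importance = importance,
       screening_cv_r2 = screening_cv_r2,
       mars_gcv_r2 = pref$model$gcv_r2,
       analysis_r2 = refit$r2,
       validation_applied_r2 = val$applied_r2,
       validation_refit_r2 = val$refit$r2)
}

#' Write pipeline artifacts as CSV/JSON reports
#'
#' Emits the coefficient table, importance records, grid records,
#' screening report and a run manifest into a directory.
#'
#' @param result output of [run_boph_pipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$analysis_fit$coefficients,
                   file.path(dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(result$importance,
                   file.path(dir, "importance.csv"), row.names = FALSE)
  utils::write.csv(result$grid, file.path(dir, "grid.csv"),
                   row.names = FALSE)
  utils::write.csv(screening_report(result$ranking, result$nested_sets),
                   file.path(dir, "screening.csv"), row.names = FALSE)
  manifest <- list(
    response = result$response,
    set_sizes = lapply(result$sets, function(s) length(s$variables)),
    preferred = as.list(result$preferred$record),
    analysis_r2 = result$analysis_r2,
    validation_applied_r2 = result$validation_applied_r2,
    validation_refit_r2 = result$validation_refit_r2,
    dropped_cases = result$analysis_fit$n_dropped)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Warn about clustered knots on one variable
#'
#' Spline forward passes can place several knots of one variable within a
#' few observations of each other (near-adjacent thresholds). No merging
#' is performed — the printed final models themselves contain such
#' clusters — but this diagnostic flags them for review.
#'
#' @param model a \code{spline_model} or [threshold_model()].
#' @param data the fitting data (used to count observations between
#'   knots).
#' @param min_span the spacing threshold, in observations.
#' @return data frame of flagged (variable, knot, knot) pairs, invisibly;
#'   warns when any pair is flagged.
#' @export
check_knot_clusters <- function(model, data, min_span = 3) {
  df <- if (inherits(data, "boph_cohort")) data$data else data
  terms <- model$terms
  kf <- do.call(rbind, lapply(terms, function(t) {
    if (inherits(t$basis, "threshold_basis")) {
      b <- t$basis
      if (b$form %in% c("IFGT", "IFLT"))
        data.frame(variable = b$variable, knot = b$cutoff)
      else NULL
    } else if (!is.null(t$factors)) {
      f <- t$factors[t$factors$dir != 0, , drop = FALSE]
      if (nrow(f)) f[c("variable", "knot")] else NULL
    } else NULL
  }))
  flagged <- NULL
  if (!is.null(kf) && nrow(kf) > 1L) {
    for (vn in unique(kf$variable)) {
      ks <- sort(unique(kf$knot[kf$variable == vn]))
      if (length(ks) < 2L || !vn %in% names(df)) next
      x <- sort(df[[vn]][!is.na(df[[vn]])])
      for (i in seq_len(length(ks) - 1L)) {
        between <- sum(x > ks[i] & x <= ks[i + 1L])
        if (between < min_span)
          flagged <- rbind(flagged,
                           data.frame(variable = vn, knot_lo = ks[i],
                                      knot_hi = ks[i + 1L],
                                      n_between = between))
      }
    }
  }
  if (!is.null(flagged) && nrow(flagged))
    warning("knots closer than min_span observations on: ",
            paste(unique(flagged$variable), collapse = ", "))
  invisible(flagged)
}
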