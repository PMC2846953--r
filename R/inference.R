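#' Ordinary least-squares refit of a threshold-basis model
#'
#' Refits the selected basis functions by complete-case OLS on unimputed
#' data: rows with a missing response or any missing basis value are
#' dropped and the number dropped is recorded. Reports per-term
#' estimates, standard errors, t statistics and two-sided p values from
#' the t distribution with \code{n - p - 1} degrees of freedom.
#'
#' @param model a [threshold_model()] (its coefficients are ignored;
#'   only the basis set is refit), or a plain list of terms.
#' @param data a \code{boph_cohort} or raw data frame (typically the
#'   unimputed analysis partition).
#' @param response response variable name.
#' @return an object of class \code{"regression_fit"}: coefficient table,
#'   \code{r2}, \code{n_used}, \code{n_dropped}, residual SD
#'   \code{sigma}, and the refit basis as a \code{threshold_model}.
#' @export
refit_ols <- function(model, data, response) {
  terms <- if (inherits(model, "threshold_model")) model$terms
           else if (inherits(model, "regression_fit")) model$model$terms
           else model
  df <- if (inherits(data, "boph_cohort")) data$data else data
  if (!response %in% names(df))
    stop("response '", response, "' absent from data")
  X <- threshold_design(terms, df)
  y <- df[[response]]
  cc <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!cc)
  Xc <- X[cc, , drop = FALSE]
  yc <- y[cc]
  n <- length(yc)
  p <- ncol(Xc)
  if (n <= p + 1L) stop("too few complete cases (", n, ") for ", p,
                        " terms")
  W <- cbind(`(Intercept)` = 1, Xc)
  qrX <- qr(W)
  if (qrX$rank < p + 1L) {
    bad <- colnames(W)[qrX$pivot[(qrX$rank + 1L):(p + 1L)]]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yc)
  res <- yc - qr.fitted(qrX, yc)
  rss <- sum(res^2)
  dfree <- n - p - 1L
  sigma2 <- rss / dfree
  XtXinv <- chol2inv(chol(crossprod(W)))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dfree)
  sst <- sum((yc - mean(yc))^2)
  r2 <- 1 - rss / sst

  refit_terms <- terms
  for (i in seq_along(refit_terms))
    refit_terms[[i]]$coefficient <- unname(beta[i + 1L])
  structure(
    list(coefficients = data.frame(
           term = c("Intercept", colnames(X)),
           estimate = unname(beta), se = unname(se), t = unname(tval),
           p = unname(pval), stringsAsFactors = FALSE),
         r2 = r2, n_used = n, n_dropped = n_dropped,
         sigma = sqrt(sigma2), response = response,
         model = threshold_model(unname(beta[1L]), refit_terms)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS refit of %s: R^2 = %.4f (n = %d used, %d dropped)\n",
              x$response, x$r2, x$n_used, x$n_dropped))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 6)
  tab$se <- signif(tab$se, 4)
  tab$t <- round(tab$t, 2)
  tab$p <- ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p))
  names(tab) <- c("Parameters", "Value", "Std Error", "t value", "P value")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Apply and refit a model on the validation partition
#'
#' Two assessments of transferability: the \emph{applied} R-squared uses
#' the analysis-set coefficients unchanged on the validation rows
#' (denominator: squared deviations from the validation mean, so a
#' non-transferable model can score at or below zero), and the
#' \emph{refit} re-estimates the same basis by OLS on the validation
#' rows. Per-term significance (two-sided, alpha = 0.05, no multiplicity
#' correction) is compared between partitions.
#'
#' @param fit a \code{regression_fit} from the analysis partition.
#' @param data validation data (\code{boph_cohort} or data frame).
#' @param response response name; defaults to the fit's.
#' @return list with \code{applied_r2}, \code{refit} (a
#'   \code{regression_fit}), and \code{significance} (per-term p values
#'   and stability flags across partitions).
#' @export
validate_model <- function(fit, data, response = fit$response) {
  stopifnot(inherits(fit, "regression_fit"))
  df <- if (inherits(data, "boph_cohort")) data$data else data
  if (!nrow(df)) stop("validation set is empty")
  X <- threshold_design(fit$model$terms, df)
  y <- df[[response]]
  cc <- stats::complete.cases(X) & !is.na(y)
  if (!any(cc)) stop("no complete validation cases")
  beta <- fit$coefficients$estimate
  yhat <- beta[1L] + drop(X[cc, , drop = FALSE] %*% beta[-1L])
  yv <- y[cc]
  applied_r2 <- 1 - sum((yv - yhat)^2) / sum((yv - mean(yv))^2)
  refit <- refit_ols(fit$model, df, response)
  sig <- merge(
    fit$coefficients[c("term", "p")],
    refit$coefficients[c("term", "p")],
    by = "term", suffixes = c("_analysis", "_validation"), sort = FALSE)
  sig$significant_analysis <- sig$p_analysis < 0.05
  sig$significant_validation <- sig$p_validation < 0.05
  sig$stable <- sig$significant_analysis == sig$significant_validation
  list(applied_r2 = applied_r2, refit = refit, significance = sig)
}

#' Marginal and delta R-squared importance of variable groups
#'
#' For each group of basis terms (by default, all transformations of one
#' source variable form a group): the \emph{marginal} R-squared is the
#' R-squared of an OLS fit on the group's terms alone — the quality of
#' prediction from the group acting alone; the \emph{delta} R-squared is
#' the full-model R-squared minus the R-squared with the group removed —
#' the improvement the group adds to the other predictors. All fits use
#' the full model's complete-case rows, so nesting (delta >= 0, marginal
#' <= full R-squared) holds exactly.
#'
#' @param fit a \code{regression_fit} (or [threshold_model()], then
#'   \code{data}/\code{response} must match a completed fit).
#' @param data the data the model was fit on.
#' @param response response name.
#' @param groups optional named list mapping group label to term indices;
#'   defaults to grouping by source variable.
#' @return data frame of \code{group}, \code{marginal_r2},
#'   \code{delta_r2}, sorted by decreasing delta R-squared.
#' @export
group_importance <- function(fit, data, response = NULL, groups = NULL) {
  terms <- if (inherits(fit, "regression_fit")) fit$model$terms
           else if (inherits(fit, "threshold_model")) fit$terms
           else stop("fit must be a regression_fit or threshold_model")
  if (is.null(response)) {
    if (!inherits(fit, "regression_fit"))
      stop("response is required with a threshold_model")
    response <- fit$response
  }
  df <- if (inherits(data, "boph_cohort")) data$data else data
  X <- threshold_design(terms, df)
  y <- df[[response]]
  cc <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[cc, , drop = FALSE]
  yc <- y[cc]
  if (is.null(groups)) {
    src <- vapply(terms, function(t)
      if (t$basis$form == "hinge")
        paste(sort(unique(t$basis$factors$variable)), collapse = "*")
      else t$basis$variable, character(1))
    groups <- split(seq_along(terms), src)
  } else {
    absent <- setdiff(unlist(groups), seq_along(terms))
    if (length(absent))
      stop("groups reference absent term indices: ",
           paste(absent, collapse = ", "))
  }
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    f <- stats::lm.fit(cbind(1, Xc[, cols, drop = FALSE]), yc)
    1 - sum(f$residuals^2) / sum((yc - mean(yc))^2)
  }
  full <- r2_of(seq_along(terms))
  out <- data.frame(
    group = names(groups),
    marginal_r2 = vapply(groups, r2_of, numeric(1)),
    delta_r2 = vapply(groups, function(g)
      full - r2_of(setdiff(seq_along(terms), g)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  # exact nesting up to float error; snap tiny negatives to zero
  out$delta_r2 <- pmax(out$delta_r2, 0)
  attr(out, "full_r2") <- full
  out[order(-out$delta_r2), , drop = FALSE]
}

#' Assemble the cross-method fit-statistic summary
#'
#' One row per response with the five fit statistics of the workflow:
#' ensemble-screening cross-validated R-squared, spline GCV R-squared,
#' OLS refit R-squared on the analysis partition, applied R-squared on
#' the validation partition, and the validation refit R-squared. Flags
#' any response where analysis and validation refit R-squared differ by
#' more than 0.05, the workflow's reproducibility check.
#'
#' @param runs named list (one element per response); each element a list
#'   with fields \code{screening_cv_r2}, \code{mars_gcv_r2},
#'   \code{analysis_r2}, \code{validation_applied_r2},
#'   \code{validation_refit_r2} (a pipeline result from
#'   [run_boph_pipeline()] works directly).
#' @return data frame with one row per response.
#' @export
fit_summary <- function(runs) {
  rows <- lapply(names(runs), function(resp) {
    r <- runs[[resp]]
    data.frame(
      response = resp,
      screening_cv_r2 = r$screening_cv_r2,
      mars_gcv_r2 = r$mars_gcv_r2,
      analysis_r2 = r$analysis_r2,
      validation_applied_r2 = r$validation_applied_r2,
      validation_refit_r2 = r$validation_refit_r2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$agreement_flag <- abs(out$analysis_r2 - out$validation_refit_r2) > 0.05
  out
}
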