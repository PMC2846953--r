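#' Spline fit configuration
#'
#' Control parameters of the adaptive regression spline engine:
#' \describe{
#'   \item{model_type}{0 = simple linear model (no transformations),
#'     1 = additive model with hinge transformations but no interactions,
#'     2 = two-way interaction model with hinge transformations.}
#'   \item{max_basis}{maximum number of basis functions grown by the
#'     forward pass (the published grid uses 10, 20, 30, 60).}
#'   \item{entry_penalty}{penalty charged, on the fraction-of-variance
#'     scale, per new variable a candidate term brings into the model
#'     (the published grid uses 0 and 0.01).}
#'   \item{folds}{folds for [cv_r2()].}
#'   \item{min_span}{minimum number of observations between candidate
#'     knots (and between a knot and the data boundary).}
#'   \item{gcv_d}{per-knot complexity charge in the GCV penalty;
#'     defaults to 3 for interaction models and 2 otherwise.}
#' }
#'
#' @param model_type 0, 1 or 2.
#' @param max_basis maximum basis functions (>= 2).
#' @param entry_penalty nonnegative new-variable entry penalty.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @param min_span minimum observations between candidate knots.
#' @param gcv_d optional complexity charge per distinct knot.
#' @return an object of class \code{"fit_config"}.
#' @export
fit_config <- function(model_type = 1, max_basis = 30, entry_penalty = 0,
                       folds = 10, seed = 1L, min_span = 3,
                       gcv_d = NULL) {
  if (!model_type %in% 0:2) stop("model_type must be 0, 1 or 2")
  if (max_basis < 2) stop("max_basis must be at least 2")
  if (entry_penalty < 0) stop("entry_penalty must be nonnegative")
  if (is.null(gcv_d)) gcv_d <- if (model_type == 2) 3 else 2
  structure(list(model_type = model_type, max_basis = max_basis,
                 entry_penalty = entry_penalty, folds = folds,
                 seed = as.integer(seed), min_span = min_span,
                 gcv_d = gcv_d),
            class = "fit_config")
}

#' Generalized cross-validation criterion
#'
#' \code{gcv = (rss / n) / (1 - complexity / n)^2}: the average squared
#' residual inflated by a squared model-complexity penalty, used to
#' compare spline models of different sizes without refitting. A
#' complexity at or above \code{n} signals an infinite penalty (the model
#' is rejected).
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param complexity effective number of parameters \eqn{C(M)}.
#' @return the GCV value (possibly \code{Inf}).
#' @export
gcv <- function(rss, n, complexity) {
  if (complexity < 0) stop("complexity must be nonnegative")
  if (complexity >= n) return(Inf)
  (rss / n) / (1 - complexity / n)^2
}

#' GCV R-squared
#'
#' The ordinary R-squared with the error variance replaced by the GCV
#' statistic: \code{1 - gcv / (SST / n)}. Unlike the ordinary R-squared
#' it can be negative when the complexity penalty exceeds the fit.
#'
#' @param model a fitted \code{spline_model}, or a numeric GCV value.
#' @param response the response vector the model was fitted on.
#' @return the GCV R-squared.
#' @export
gcv_r2 <- function(model, response) {
  g <- if (inherits(model, "spline_model")) model$gcv else as.numeric(model)
  mst <- mean((response - mean(response))^2)
  if (mst <= 0) stop("response has zero variance; GCV R-squared undefined")
  1 - g / mst
}

# Resolve a fitting table to a numeric frame + candidate columns.
mars_frame <- function(table, response, candidates = NULL) {
  if (inherits(table, "encoded_table")) {
    df <- table$data
    if (!is.null(table$smoking_status))
      df$smoking_status <- table$smoking_status
    responses <- table$meta$name[table$meta$role == "response"]
  } else {
    df <- as.data.frame(table)
    responses <- response
  }
  if (!response %in% names(df))
    stop("response '", response, "' absent from table")
  y <- df[[response]]
  if (is.null(candidates)) candidates <- setdiff(names(df), responses)
  candidates <- intersect(candidates, setdiff(names(df), response))
  keep <- vapply(df[candidates], function(x)
    is.numeric(x) && stats::var(x) > 0, logical(1))
  list(df = df, y = y, candidates = candidates[keep])
}

# A forward-pass term: one or two hinge/linear factors.
new_term <- function(variable, knot, dir, parent_factors = NULL) {
  f <- data.frame(variable = variable, knot = knot, dir = as.integer(dir),
                  stringsAsFactors = FALSE)
  if (!is.null(parent_factors)) f <- rbind(parent_factors, f)
  list(factors = f)
}

# Column of a term's basis function on a data frame.
term_column <- function(data, term) eval_basis_factors(data, term$factors)

term_label <- function(term) {
  fmt <- function(z) format(z, trim = TRUE, scientific = FALSE,
                            drop0trailing = TRUE)
  paste(vapply(seq_len(nrow(term$factors)), function(i) {
    f <- term$factors[i, ]
    if (f$dir == 0) f$variable
    else if (f$dir > 0) sprintf("h(%s-%s)", f$variable, fmt(f$knot))
    else sprintf("h(%s-%s)", fmt(f$knot), f$variable)
  }, character(1)), collapse = "*")
}

term_vars <- function(term) unique(term$factors$variable)

# Distinct (variable, knot) pairs among a term list's hinge factors.
count_knots <- function(terms) {
  if (!length(terms)) return(0L)
  kf <- do.call(rbind, lapply(terms, function(t)
    t$factors[t$factors$dir != 0, c("variable", "knot")]))
  if (is.null(kf) || !nrow(kf)) return(0L)
  nrow(unique(kf))
}

#' Forward pass of the adaptive spline fit
#'
#' Greedily grows basis functions by exact search over all (variable,
#' observed-value knot) candidates. For model type 1 it adds reflected
#' hinge pairs \code{max(0, x - c)} / \code{max(0, c - x)}; for type 2,
#' products of an existing degree-1 basis function with a new hinge pair
#' in a different variable; for type 0, untransformed linear terms. A
#' candidate's gain is its residual-sum-of-squares reduction on the
#' fraction-of-variance scale, minus \code{entry_penalty} per new
#' variable it brings in; the pass stops when no candidate gains, or at
#' \code{max_basis} terms.
#'
#' Within a reflected pair, one side may be dropped when it is numerically
#' degenerate (e.g. a knot at the data boundary); surviving single-sided
#' terms are how one-sided printed transformations arise.
#'
#' @param table an \code{encoded_table} or all-numeric data frame.
#' @param response response column name.
#' @param config a [fit_config()].
#' @param candidates optional candidate column names (defaults to every
#'   non-response column).
#' @return an object of class \code{"mars_forward"}: the grown term list
#'   plus the fitting state consumed by [backward_pass()].
#' @export
forward_pass <- function(table, response, config = fit_config(),
                         candidates = NULL) {
  fr <- mars_frame(table, response, candidates)
  df <- fr$df; y <- fr$y; candidates <- fr$candidates
  n <- length(y)
  if (length(candidates) < 2L) stop("need at least 2 candidate variables")
  sst <- sum((y - mean(y))^2)
  state <- list(terms = list(), df = df, y = y, response = response,
                config = config, candidates = candidates)
  if (sst <= 0) {
    state$B <- matrix(1, n, 1)
    state$rss <- 0
    class(state) <- "mars_forward"
    return(state)
  }

  Zm <- as.matrix(df[candidates])
  B <- matrix(1, n, 1)
  fit <- stats::lm.fit(B, y)
  r <- fit$residuals
  rss <- sum(r^2)
  terms <- list()
  eps <- 1e-9

  repeat {
    if (length(terms) + (if (config$model_type == 0) 1 else 2) >
        config$max_basis) break
    Ginv <- chol2inv(chol(crossprod(B)))
    model_vars <- unique(unlist(lapply(terms, term_vars)))

    if (config$model_type == 0) {
      avail <- setdiff(candidates, model_vars)
      if (!length(avail)) break
      Zc <- Zm[, avail, drop = FALSE]
      V <- crossprod(B, Zc)
      U <- Ginv %*% V
      bb <- colSums(Zc^2)
      Mjj <- bb - colSums(V * U)
      cj <- drop(crossprod(Zc, r))
      ok <- bb > 0 & Mjj > eps * bb
      drss <- ifelse(ok, cj^2 / Mjj, -1)
      score <- drss / sst - config$entry_penalty
      if (max(score) <= 0) break
      j <- which.max(score)
      term <- new_term(avail[j], NA_real_, 0L)
      newcols <- Zc[, j, drop = FALSE]
      added <- list(term)
    } else {
      if (config$model_type == 1) {
        P <- matrix(1, n, 1)
        parents <- list(NULL)   # intercept
      } else {
        deg1 <- Filter(function(t) nrow(t$factors) == 1L, terms)
        P <- matrix(1, n, 1)
        if (length(deg1))
          P <- cbind(P, vapply(deg1, function(t) term_column(df, t),
                               numeric(n)))
        parents <- c(list(NULL), lapply(deg1, `[[`, "factors"))
      }
      allowed <- matrix(1L, length(parents), length(candidates))
      for (qi in seq_along(parents)) {
        pf <- parents[[qi]]
        if (!is.null(pf))
          allowed[qi, candidates %in% pf$variable] <- 0L
      }
      sc <- scan_hinge_pairs(B, Ginv, r, Zm, P, allowed,
                             as.integer(config$min_span), eps)
      # penalized comparison: gain on the R^2 scale minus the per-new-
      # variable entry charge
      score <- sc$drss / sst
      if (config$entry_penalty > 0) {
        for (qi in seq_along(parents)) {
          pvars <- if (is.null(parents[[qi]])) character(0)
                   else parents[[qi]]$variable
          n_new <- vapply(candidates, function(vn)
            length(setdiff(union(pvars, vn), model_vars)), numeric(1))
          score[qi, ] <- score[qi, ] - config$entry_penalty * n_new
        }
      }
      score[sc$drss < 0] <- -Inf
      if (all(!is.finite(score)) || max(score) <= 0) break
      best <- arrayInd(which.max(score), dim(score))
      qi <- best[1]; j <- best[2]
      knot <- sc$knot[qi, j]; kind <- sc$kind[qi, j]
      pf <- parents[[qi]]
      vj <- candidates[j]
      added <- list()
      newcols <- NULL
      if (kind %in% c(2L, 1L)) {
        t1 <- new_term(vj, knot, 1L, pf)
        added <- c(added, list(t1))
        newcols <- cbind(newcols, term_column(df, t1))
      }
      if (kind %in% c(2L, -1L)) {
        t2 <- new_term(vj, knot, -1L, pf)
        added <- c(added, list(t2))
        newcols <- cbind(newcols, term_column(df, t2))
      }
    }

    Bnew <- cbind(B, newcols)
    ch <- tryCatch(chol(crossprod(Bnew)), error = function(e) NULL)
    if (is.null(ch)) break  # numerically collinear addition: stop growing
    B <- Bnew
    terms <- c(terms, added)
    fit <- stats::lm.fit(B, y)
    r <- fit$residuals
    new_rss <- sum(r^2)
    if (new_rss > rss - 1e-12 * sst && config$entry_penalty == 0) {
      # no measurable improvement; drop the addition and stop
      terms <- terms[seq_len(length(terms) - length(added))]
      B <- B[, seq_len(ncol(B) - length(added)), drop = FALSE]
      break
    }
    rss <- new_rss
    if (rss <= 1e-12 * sst) break
  }

  state$terms <- terms
  state$B <- B
  state$rss <- rss
  class(state) <- "mars_forward"
  state
}

#' Backward pruning pass with GCV model selection
#'
#' Starting from the forward pass's term set, iteratively deletes the
#' term whose removal least increases the residual sum of squares, down
#' to the intercept-only model; among the resulting model sequence the
#' one with minimal [gcv()] is returned. Model complexity is
#' \code{C(M) = (#terms + 1) + d * #distinct knots} with \code{d}
#' from the configuration (3 for interaction models, 2 otherwise).
#'
#' @param terms a \code{mars_forward} object, or a term list (then
#'   \code{table} and \code{response} are required to rebuild the design).
#' @param table,response fitting data (unused when \code{terms} is a
#'   \code{mars_forward}).
#' @param config a [fit_config()]; defaults to the forward pass's.
#' @return an object of class \code{"spline_model"}: intercept, terms
#'   with coefficients, rss, n, complexity, gcv and gcv_r2.
#' @export
backward_pass <- function(terms, table = NULL, response = NULL,
                          config = NULL) {
  if (inherits(terms, "mars_forward")) {
    fwd <- terms
    if (is.null(config)) config <- fwd$config
    df <- fwd$df; y <- fwd$y; terms <- fwd$terms
    B <- fwd$B
  } else {
    if (is.null(table) || is.null(response))
      stop("table and response are required when terms is a plain list")
    if (is.null(config)) config <- fit_config()
    fr <- mars_frame(table, response)
    df <- fr$df; y <- fr$y
    B <- cbind(1, vapply(terms, function(t) term_column(df, t),
                         numeric(length(y))))
  }
  n <- length(y)
  M <- length(terms)
  G <- crossprod(B)
  h <- drop(crossprod(B, y))
  yy <- sum(y^2)

  rss_of <- function(keep) {  # keep: indices into terms; col 1 = intercept
    idx <- c(1L, keep + 1L)
    beta <- tryCatch(solve(G[idx, idx, drop = FALSE], h[idx]),
                     error = function(e) NULL)
    if (is.null(beta)) return(Inf)
    max(yy - sum(beta * h[idx]), 0)
  }
  complexity_of <- function(keep)
    (length(keep) + 1) + config$gcv_d * count_knots(terms[keep])

  keep <- seq_len(M)
  seq_models <- list(list(keep = keep, rss = rss_of(keep)))
  while (length(keep) > 0L) {
    incr <- vapply(seq_along(keep), function(i)
      rss_of(keep[-i]), numeric(1))
    drop_i <- which.min(incr)
    keep <- keep[-drop_i]
    seq_models <- c(seq_models,
                    list(list(keep = keep, rss = rss_of(keep))))
  }
  gcvs <- vapply(seq_models, function(mdl)
    gcv(mdl$rss, n, complexity_of(mdl$keep)), numeric(1))
  pick <- seq_models[[which.min(gcvs)]]

  idx <- c(1L, pick$keep + 1L)
  beta <- solve(G[idx, idx, drop = FALSE], h[idx])
  kept_terms <- terms[pick$keep]
  for (i in seq_along(kept_terms))
    kept_terms[[i]]$coefficient <- unname(beta[i + 1L])
  complexity <- complexity_of(pick$keep)
  g <- gcv(pick$rss, n, complexity)
  g_r2 <- if (stats::var(y) > 0) gcv_r2(g, y) else NA_real_
  structure(
    list(intercept = unname(beta[1L]), terms = kept_terms,
         rss = pick$rss, n = n, complexity = complexity,
         gcv = g, gcv_r2 = g_r2,
         model_type = config$model_type, config = config,
         response = if (!is.null(response)) response else fwd$response),
    class = "spline_model")
}

#' Fit an adaptive regression spline model (forward + backward pass)
#'
#' @inheritParams forward_pass
#' @return a \code{spline_model}.
#' @export
mars_fit <- function(table, response, config = fit_config(),
                     candidates = NULL) {
  fwd <- forward_pass(table, response, config, candidates)
  backward_pass(fwd)
}

#' Predict from a fitted spline model
#'
#' @param object a \code{spline_model}.
#' @param newdata data frame holding the model's variables.
#' @param ... unused.
#' @return numeric vector of fitted values.
#' @export
predict.spline_model <- function(object, newdata, ...) {
  out <- rep(object$intercept, nrow(newdata))
  for (t in object$terms)
    out <- out + t$coefficient * eval_basis_factors(newdata, t$factors)
  unname(out)
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf(
    "Spline model (type %d): %d terms, gcv = %.4g, gcv_r2 = %.4f\n",
    x$model_type, length(x$terms), x$gcv, x$gcv_r2))
  for (t in x$terms)
    cat(sprintf("  %+.6g * %s\n", t$coefficient, term_label(t)))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  invisible(x)
}

#' Cross-validated R-squared of a spline fit
#'
#' Seeded k-fold partition; each fold's model is fit (forward plus
#' backward pass) on the remaining folds and predicts the held-out fold.
#' Returns 1 minus the pooled held-out residual sum of squares over the
#' total sum of squares.
#'
#' @inheritParams forward_pass
#' @return the cross-validated R-squared.
#' @export
cv_r2 <- function(table, response, config = fit_config(),
                  candidates = NULL) {
  fr <- mars_frame(table, response, candidates)
  df <- fr$df; y <- fr$y
  n <- length(y)
  if (n < config$folds) stop("need at least as many rows as folds")
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$folds), n))
  pred <- numeric(n)
  for (f in seq_len(config$folds)) {
    test <- fold == f
    m <- mars_fit(df[!test, , drop = FALSE], response, config,
                  fr$candidates)
    pred[test] <- predict(m, df[test, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Grid search over spline control parameters and predictor sets
#'
#' Fits one spline model per cell of the control lattice: predictor set
#' (large / medium / small) x model type (0, 1, 2) x maximum basis
#' functions (10, 20, 30, 60) x entry penalty (0, 0.01) — 72 runs at the
#' defaults. Each record carries the fitted model's GCV R-squared,
#' parameter count and variable count, mirroring the diagnostics from
#' which a preferred model is selected.
#'
#' @param table an \code{encoded_table} or numeric data frame. When the
#'   table carries partition labels, fitting is restricted to the
#'   analysis partition.
#' @param response response column name.
#' @param sets named list of augmented \code{predictor_set}s (see
#'   [augment_predictor_sets()]).
#' @param model_types,max_basis,entry_penalties the control lattice.
#' @param min_span minimum observations between candidate knots.
#' @param seed integer seed recorded in each cell's configuration.
#' @param cv_folds if positive, additionally compute [cv_r2()] for each
#'   cell (off by default: model preference uses GCV R-squared).
#' @return data frame of grid records, sorted by decreasing GCV
#'   R-squared with stable ties; fitted models in \code{attr(, "models")}
#'   (named by record id).
#' @export
grid_search <- function(table, response, sets,
                        model_types = c(0, 1, 2),
                        max_basis = c(10, 20, 30, 60),
                        entry_penalties = c(0, 0.01),
                        min_span = 3, seed = 1L, cv_folds = 0) {
  if (inherits(table, "encoded_table")) {
    df <- table$data
    if (!is.null(table$smoking_status))
      df$smoking_status <- table$smoking_status
    if (!is.null(table$partition) && any(table$partition == "analysis"))
      df <- df[table$partition == "analysis", , drop = FALSE]
  } else df <- as.data.frame(table)

  records <- list()
  models <- list()
  id <- 0L
  for (set_name in names(sets)) {
    vars <- intersect(sets[[set_name]]$variables, names(df))
    for (mt in model_types) for (mb in max_basis)
      for (pen in entry_penalties) {
        id <- id + 1L
        cfg <- fit_config(model_type = mt, max_basis = mb,
                          entry_penalty = pen, seed = seed,
                          min_span = min_span)
        m <- mars_fit(df, response, cfg, candidates = vars)
        rec <- data.frame(
          id = id, set = set_name, model_type = mt, max_basis = mb,
          entry_penalty = pen,
          gcv_r2 = m$gcv_r2,
          n_params = length(m$terms) + 1L,
          n_vars = length(unique(unlist(lapply(m$terms, term_vars)))),
          stringsAsFactors = FALSE)
        if (cv_folds > 0) {
          cfg$folds <- cv_folds
          rec$cv_r2 <- cv_r2(df, response, cfg, candidates = vars)
        }
        records[[id]] <- rec
        models[[id]] <- m
      }
  }
  out <- do.call(rbind, records)
  ord <- order(-out$gcv_r2, out$id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Select the preferred model from grid-search results
#'
#' Models are preferred if they fit well (high GCV R-squared) and are
#' parsimonious (few predictors): among all models within
#' \code{tolerance} of the best GCV R-squared, the one with the fewest
#' distinct variables wins; ties break to fewer parameters, then lower
#' model type, then the first record in deterministic sort order.
#'
#' @param results output of [grid_search()].
#' @param tolerance GCV R-squared tolerance (default 0.01).
#' @return list with \code{record} (the chosen row) and \code{model}
#'   (the fitted \code{spline_model}).
#' @export
select_preferred <- function(results, tolerance = 0.01) {
  if (!nrow(results)) stop("empty grid results")
  best <- max(results$gcv_r2)
  pool <- results[results$gcv_r2 >= best - tolerance, , drop = FALSE]
  ord <- order(pool$n_vars, pool$n_params, pool$model_type, pool$id)
  rec <- pool[ord[1L], , drop = FALSE]
  list(record = rec, model = attr(results, "models")[[rec$id]])
}
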