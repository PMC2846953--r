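#' Threshold basis functions
#'
#' Interpretable basis functions used in the final regression models. A
#' basis function transforms one source variable:
#' \describe{
#'   \item{linear}{the variable itself (Form 1).}
#'   \item{EQ}{0/1 indicator that a categorical variable equals a level
#'     (Form 2), e.g. \code{RACE.EQ.BLACK}.}
#'   \item{GT}{0/1 cumulative indicator that an ordinal variable exceeds a
#'     level (Form 2), e.g. \code{DRINK.GT.1.PER.WK}.}
#'   \item{IFGT}{\code{x} if \code{x > c}, else \code{c} (Form 3), read
#'     "x if greater than c".}
#'   \item{IFLT}{\code{x} if \code{x < c}, else \code{c} (Form 3).}
#'   \item{hinge}{a product of hinge factors \code{max(0, +/-(x - c))};
#'     used only as a pass-through for interaction terms, which have no
#'     single-variable threshold form.}
#' }
#'
#' At the boundary \code{x == c} both IFGT and IFLT return \code{c}, so the
#' algebraic identity \code{IFGT(x, c) + IFLT(x, c) == x + c} holds for all
#' \code{x}.
#'
#' @param variable name of the source variable.
#' @param form one of \code{"linear"}, \code{"EQ"}, \code{"GT"},
#'   \code{"IFGT"}, \code{"IFLT"}, \code{"hinge"}.
#' @param cutoff numeric knot for \code{IFGT}/\code{IFLT}; character level
#'   for \code{EQ}/\code{GT}.
#' @param levels for \code{GT} (and optionally \code{EQ}) bases, the full
#'   ordered level set of the source variable.
#' @param factors for \code{"hinge"} bases, a data frame with columns
#'   \code{variable}, \code{knot}, \code{dir} (+1 for \code{max(0, x - c)},
#'   -1 for \code{max(0, c - x)}, 0 for a linear factor).
#' @return an object of class \code{"threshold_basis"}.
#' @export
threshold_basis <- function(variable, form, cutoff = NULL, levels = NULL,
                            factors = NULL) {
  form <- match.arg(form, c("linear", "EQ", "GT", "IFGT", "IFLT", "hinge"))
  if (form %in% c("IFGT", "IFLT")) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
      stop("IFGT/IFLT bases require a single finite numeric cutoff")
  }
  if (form %in% c("EQ", "GT") && (is.null(cutoff) || length(cutoff) != 1L))
    stop("EQ/GT bases require a single level as cutoff")
  if (form == "GT" && is.null(levels))
    stop("GT bases require the ordered level set of '", variable, "'")
  if (form == "hinge" && is.null(factors))
    stop("hinge bases require a factors data frame")
  structure(
    list(variable = variable, form = form, cutoff = cutoff,
         levels = levels, factors = factors),
    class = "threshold_basis"
  )
}

#' Evaluate a threshold basis function on a vector of values
#'
#' Missing inputs propagate to missing outputs, except for the special
#' level \code{"MISSING"}, whose EQ indicator is 1 exactly when the input
#' is missing (the missing-category rule for categorical predictors).
#'
#' A categorical EQ level that is not among the variable's declared levels
#' and equals \code{"Y"} (or \code{"N"}) is interpreted as "any category
#' above the first" ("none"), the mixed nominal coding under which an
#' ordinal consumption variable also carries a yes/no indicator such as
#' \code{DRINK.EQ.Y}.
#'
#' @param x vector of raw values of the basis's source variable (numeric
#'   for linear/IFGT/IFLT, character or factor for EQ/GT).
#' @param basis a [threshold_basis()].
#' @return numeric vector, same length as \code{x}.
#' @export
eval_threshold_basis <- function(x, basis) {
  stopifnot(inherits(basis, "threshold_basis"))
  switch(basis$form,
    linear = as.numeric(x),
    IFGT = {
      x <- as.numeric(x)
      ifelse(is.na(x), NA_real_, pmax(x, basis$cutoff))
    },
    IFLT = {
      x <- as.numeric(x)
      ifelse(is.na(x), NA_real_, pmin(x, basis$cutoff))
    },
    EQ = {
      x <- as.character(x)
      lev <- as.character(basis$cutoff)
      if (identical(lev, "MISSING")) {
        as.numeric(is.na(x) | x == "MISSING")
      } else if (!is.null(basis$levels) && !(lev %in% basis$levels) &&
                 lev %in% c("Y", "N")) {
        any_above <- as.numeric(x != basis$levels[1L])
        if (identical(lev, "N")) 1 - any_above else any_above
      } else {
        ifelse(is.na(x), NA_real_, as.numeric(x == lev))
      }
    },
    GT = {
      x <- as.character(x)
      pos <- match(x, basis$levels)
      cut_pos <- match(as.character(basis$cutoff), basis$levels)
      if (is.na(cut_pos))
        stop("level '", basis$cutoff, "' is not a level of '",
             basis$variable, "'")
      out <- as.numeric(pos > cut_pos)
      out[is.na(x)] <- NA_real_
      out
    },
    hinge = stop("hinge product bases are evaluated by eval_basis_factors()")
  )
}

# Evaluate one hinge factor on numeric values.
hinge_factor <- function(x, knot, dir) {
  if (dir == 0) return(as.numeric(x))
  if (dir > 0) pmax(0, x - knot) else pmax(0, knot - x)
}

# Evaluate a (possibly multi-factor) hinge basis on a data frame.
eval_basis_factors <- function(data, factors) {
  out <- rep(1, nrow(data))
  for (i in seq_len(nrow(factors))) {
    v <- factors$variable[i]
    if (!v %in% names(data)) stop("variable '", v, "' absent from data")
    out <- out * hinge_factor(as.numeric(data[[v]]), factors$knot[i],
                              factors$dir[i])
  }
  out
}

#' Canonical name of a threshold basis function
#'
#' Reconstructs the printed naming convention:
#' \code{<v.name>} (linear), \code{<v.name>.EQ.<level>},
#' \code{<v.name>.GT.<level>}, \code{<v.name>.IFGT.<c>},
#' \code{<v.name>.IFLT.<c>}. Numeric cutoffs are rendered without trailing
#' zeros.
#'
#' @param basis a [threshold_basis()].
#' @return a character scalar.
#' @export
basis_name <- function(basis) {
  stopifnot(inherits(basis, "threshold_basis"))
  fmt <- function(z) format(z, trim = TRUE, scientific = FALSE,
                            drop0trailing = TRUE)
  switch(basis$form,
    linear = basis$variable,
    IFGT = paste(basis$variable, "IFGT", fmt(basis$cutoff), sep = "."),
    IFLT = paste(basis$variable, "IFLT", fmt(basis$cutoff), sep = "."),
    EQ = paste(basis$variable, "EQ", as.character(basis$cutoff), sep = "."),
    GT = paste(basis$variable, "GT", as.character(basis$cutoff), sep = "."),
    hinge = paste(vapply(seq_len(nrow(basis$factors)), function(i) {
      f <- basis$factors[i, ]
      if (f$dir == 0) f$variable
      else if (f$dir > 0) sprintf("h(%s-%s)", f$variable, fmt(f$knot))
      else sprintf("h(%s-%s)", fmt(f$knot), f$variable)
    }, character(1)), collapse = "*")
  )
}

#' Construct a threshold-basis regression model
#'
#' A threshold model is an intercept plus a weighted sum of
#' [threshold_basis()] functions. It is the interpretable, fit-preserving
#' reparametrization of a hinge-basis spline model: coefficients read as
#' slopes on distinct intervals of each predictor.
#'
#' @param intercept numeric intercept.
#' @param terms list of terms, each a list with elements \code{basis}
#'   (a [threshold_basis()]) and \code{coefficient}.
#' @return an object of class \code{"threshold_model"}.
#' @export
threshold_model <- function(intercept, terms) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  for (tm in terms) {
    if (!inherits(tm$basis, "threshold_basis") ||
        !is.numeric(tm$coefficient))
      stop("each term needs a threshold_basis and a numeric coefficient")
  }
  structure(list(intercept = intercept, terms = terms),
            class = "threshold_model")
}

# Design matrix of a term list evaluated on raw data (one column per term).
threshold_design <- function(terms, data) {
  if (!length(terms))
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  cols <- lapply(terms, function(tm) {
    b <- tm$basis
    if (b$form == "hinge") eval_basis_factors(data, b$factors)
    else {
      if (!b$variable %in% names(data))
        stop("model references variable '", b$variable,
             "' absent from data")
      eval_threshold_basis(data[[b$variable]], b)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(terms, function(tm) basis_name(tm$basis),
                        character(1))
  m
}

#' Predict from a threshold model
#'
#' @param object a [threshold_model()].
#' @param newdata data frame holding the model's source variables in raw
#'   (unencoded) form.
#' @param ... unused.
#' @return numeric vector of fitted values.
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  X <- threshold_design(object$terms, newdata)
  beta <- vapply(object$terms, `[[`, numeric(1), "coefficient")
  unname(drop(object$intercept + X %*% beta))
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Threshold-basis model:", length(x$terms), "terms\n")
  df <- data.frame(
    Parameters = c("Intercept",
                   vapply(x$terms, function(tm) basis_name(tm$basis),
                          character(1))),
    Value = c(x$intercept,
              vapply(x$terms, `[[`, numeric(1), "coefficient"))
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Coefficient table of a threshold model
#'
#' Human-readable table in the layout of published final-model tables
#' (Parameters / Value, with inferential columns added by [refit_ols()]).
#'
#' @param model a [threshold_model()].
#' @return data frame with columns \code{Parameters} and \code{Value}.
#' @export
coef_table <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  data.frame(
    Parameters = c("Intercept",
                   vapply(model$terms, function(tm) basis_name(tm$basis),
                          character(1))),
    Value = c(model$intercept,
              vapply(model$terms, `[[`, numeric(1), "coefficient")),
    stringsAsFactors = FALSE
  )
}
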