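#' Reparametrize a hinge-basis spline model into the threshold basis
#'
#' Converts each hinge term into its interpretable threshold (Form 1/2/3)
#' equivalent, preserving fitted values exactly:
#' \itemize{
#'   \item \code{b * max(0, x - c)} becomes coefficient \code{b} on
#'     \code{x.IFGT.c}, with the intercept adjusted by \code{-b*c}
#'     (identity \code{max(0, x - c) = IFGT(x, c) - c});
#'   \item \code{b * max(0, c - x)} becomes coefficient \code{-b} on
#'     \code{x.IFLT.c}, intercept adjusted by \code{+b*c}
#'     (identity \code{max(0, c - x) = c - IFLT(x, c)});
#'   \item linear terms stay linear; terms on encoded indicator columns
#'     are mapped back to EQ/GT bases on the source categorical variable
#'     via the encoding provenance;
#'   \item two-way interaction terms have no single-variable threshold
#'     form and pass through as hinge products, with a warning.
#' }
#'
#' The conversion is an exact linear reparametrization: R-squared,
#' residuals and fitted values are unchanged.
#'
#' @param model a \code{spline_model} (type 0 or 1; interactions pass
#'   through).
#' @param provenance optional encoding provenance (the
#'   \code{$provenance} of an \code{encoded_table}) used to recognize
#'   indicator columns and name them by source variable and level.
#' @return a [threshold_model()].
#' @export
hinge_to_threshold <- function(model, provenance = NULL) {
  stopifnot(inherits(model, "spline_model"))
  intercept <- model$intercept
  out <- list()
  warned <- FALSE
  lookup <- function(col) {
    if (is.null(provenance)) return(NULL)
    row <- provenance[provenance$column == col, , drop = FALSE]
    if (!nrow(row) || row$form[1] == "linear") return(NULL)
    row[1, ]
  }
  for (t in model$terms) {
    beta <- t$coefficient
    if (nrow(t$factors) > 1L) {
      if (!warned) {
        warning("interaction terms have no threshold form; ",
                "passing through as hinge products")
        warned <- TRUE
      }
      out[[length(out) + 1L]] <- list(
        basis = threshold_basis(t$factors$variable[1], "hinge",
                                factors = t$factors),
        coefficient = beta)
      next
    }
    f <- t$factors[1, ]
    prov <- lookup(f$variable)
    if (!is.null(prov)) {
      levels <- if (is.na(prov$levels)) NULL
                else strsplit(prov$levels, "|", fixed = TRUE)[[1]]
      b <- threshold_basis(prov$source, prov$form, prov$level,
                           levels = levels)
      if (f$dir == 0 || (f$dir == 1 && f$knot == 0)) {
        # indicator itself: x or max(0, x - 0)
        out[[length(out) + 1L]] <- list(basis = b, coefficient = beta)
      } else if (f$dir == -1 && f$knot == 1) {
        # max(0, 1 - x) = 1 - x on a 0/1 column
        out[[length(out) + 1L]] <- list(basis = b, coefficient = -beta)
        intercept <- intercept + beta
      } else {
        stop("cannot reparametrize hinge at knot ", f$knot,
             " on indicator column ", f$variable)
      }
      next
    }
    if (f$dir == 0) {
      out[[length(out) + 1L]] <- list(
        basis = threshold_basis(f$variable, "linear"), coefficient = beta)
    } else if (f$dir == 1) {
      out[[length(out) + 1L]] <- list(
        basis = threshold_basis(f$variable, "IFGT", f$knot),
        coefficient = beta)
      intercept <- intercept - beta * f$knot
    } else {
      out[[length(out) + 1L]] <- list(
        basis = threshold_basis(f$variable, "IFLT", f$knot),
        coefficient = -beta)
      intercept <- intercept + beta * f$knot
    }
  }
  threshold_model(intercept, out)
}

#' Convert a threshold model back to hinge form
#'
#' Inverse of [hinge_to_threshold()] for numeric (linear / IFGT / IFLT /
#' hinge) terms, used to verify that the reparametrization is a
#' round-trip. Categorical indicator terms have no raw-variable hinge
#' form and are rejected.
#'
#' @param model a [threshold_model()].
#' @return a \code{spline_model}-like object (intercept plus hinge terms)
#'   whose predictions equal the threshold model's.
#' @export
threshold_to_hinge <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  intercept <- model$intercept
  terms <- list()
  for (t in model$terms) {
    b <- t$basis; beta <- t$coefficient
    if (b$form == "linear") {
      tm <- new_term(b$variable, NA_real_, 0L)
      tm$coefficient <- beta
    } else if (b$form == "IFGT") {
      # IFGT(x, c) = c + max(0, x - c)
      tm <- new_term(b$variable, b$cutoff, 1L)
      tm$coefficient <- beta
      intercept <- intercept + beta * b$cutoff
    } else if (b$form == "IFLT") {
      # IFLT(x, c) = c - max(0, c - x)
      tm <- new_term(b$variable, b$cutoff, -1L)
      tm$coefficient <- -beta
      intercept <- intercept + beta * b$cutoff
    } else if (b$form == "hinge") {
      tm <- list(factors = b$factors, coefficient = beta)
    } else {
      stop("categorical term ", basis_name(b), " has no hinge form")
    }
    terms[[length(terms) + 1L]] <- tm
  }
  structure(list(intercept = intercept, terms = terms,
                 model_type = 1, rss = NA_real_, n = NA_integer_,
                 complexity = NA_real_, gcv = NA_real_,
                 gcv_r2 = NA_real_, config = NULL, response = NULL),
            class = "spline_model")
}
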