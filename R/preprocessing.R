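#' BLLOQ substitution rule
#'
#' For a value carrying a below-lower-limit-of-quantification flag: if the
#' value is missing it is set to 0; if it is present it is left unchanged.
#' Unflagged values are untouched (missing stays missing, imputable
#' later). The rule is idempotent.
#'
#' @param value numeric vector (may contain \code{NA}).
#' @param flag 0/1 vector of BLLOQ flags, same length.
#' @return numeric vector with the rule applied.
#' @export
apply_blloq_rule <- function(value, flag) {
  stopifnot(length(value) == length(flag))
  flag <- as.integer(flag)
  ifelse(flag == 1L & is.na(value), 0, value)
}

#' Apply the BLLOQ rule to every flagged variable of a cohort
#'
#' @param cohort a \code{boph_cohort} whose metadata links each BOE to its
#'   flag column.
#' @return the cohort with the substitution applied; the number of
#'   substituted cells per variable is recorded in
#'   \code{attr(, "blloq_substitutions")}.
#' @export
apply_blloq <- function(cohort) {
  stopifnot(inherits(cohort, "boph_cohort"))
  meta <- cohort$meta
  flagged <- meta[!is.na(meta$blloq_flag_column), , drop = FALSE]
  subs <- integer(0)
  for (i in seq_len(nrow(flagged))) {
    vn <- flagged$name[i]; fc <- flagged$blloq_flag_column[i]
    if (!fc %in% names(cohort$data)) next
    before <- sum(is.na(cohort$data[[vn]]) & cohort$data[[fc]] == 1L)
    cohort$data[[vn]] <- apply_blloq_rule(cohort$data[[vn]],
                                          cohort$data[[fc]])
    subs[vn] <- before
  }
  attr(cohort, "blloq_substitutions") <- subs
  cohort
}

#' Derive creatinine clearance
#'
#' Creatinine clearance as used here is 24 h urine creatinine excretion
#' divided by serum (plasma) creatinine, in dL/day — a kidney-function
#' proxy. Missing inputs propagate; nonpositive serum creatinine is
#' flagged invalid (output missing, with a warning).
#'
#' @param urine_creatinine_24h 24 h urine creatinine, mg/24 h.
#' @param serum_creatinine serum creatinine, mg/dL.
#' @return creatinine clearance, dL/day.
#' @export
derive_crcl <- function(urine_creatinine_24h, serum_creatinine) {
  bad <- !is.na(serum_creatinine) & serum_creatinine <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive serum creatinine value(s); ",
            "creatinine clearance set to missing")
    serum_creatinine[bad] <- NA_real_
  }
  urine_creatinine_24h / serum_creatinine
}

#' Randomly split a cohort into analysis and validation partitions
#'
#' Uniform random assignment without replacement: \code{round(fraction*n)}
#' subjects are labeled \code{analysis}, the rest \code{validation}.
#' Optionally stratified by smoking status (the split fraction is then
#' applied within each status stratum).
#'
#' @param cohort a \code{boph_cohort} with unassigned partitions.
#' @param fraction analysis fraction, in (0, 1); default 0.8 (an 80/20
#'   split).
#' @param seed integer seed.
#' @param stratify_by_status stratify the split by smoking status
#'   (default \code{FALSE}).
#' @return the cohort with \code{partition} filled in.
#' @export
split_analysis_validation <- function(cohort, fraction = 0.8, seed = 1L,
                                      stratify_by_status = FALSE) {
  stopifnot(inherits(cohort, "boph_cohort"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  n <- nrow(cohort$data)
  set.seed(seed)
  part <- rep("validation", n)
  if (stratify_by_status) {
    for (st in unique(cohort$data$smoking_status)) {
      idx <- which(cohort$data$smoking_status == st)
      take <- sample(idx, round(fraction * length(idx)))
      part[take] <- "analysis"
    }
  } else {
    part[sample.int(n, round(fraction * n))] <- "analysis"
  }
  cohort$data$partition <- part
  cohort
}

#' Drop subjects with a missing response
#'
#' Cases with a missing dependent variable are dropped, not imputed. The
#' number removed is attached as \code{attr(, "n_dropped")}.
#'
#' @param cohort a \code{boph_cohort}.
#' @param response response variable name.
#' @return the reduced cohort.
#' @export
drop_missing_response <- function(cohort, response) {
  stopifnot(inherits(cohort, "boph_cohort"))
  if (!response %in% names(cohort$data))
    stop("response '", response, "' absent from cohort")
  miss <- is.na(cohort$data[[response]])
  if (all(miss))
    warning("all values of response '", response, "' are missing; ",
            "the table is empty after dropping")
  cohort$data <- cohort$data[!miss, , drop = FALSE]
  if (!is.null(cohort$truth$linear_predictors))
    cohort$truth$linear_predictors <-
      cohort$truth$linear_predictors[!miss, , drop = FALSE]
  attr(cohort, "n_dropped") <- sum(miss)
  cohort
}

#' Impute missing continuous predictors by stratified medians
#'
#' Each missing continuous predictor value is replaced by the median of
#' the non-missing values of that variable within its (smoking status x
#' partition) stratum. Responses are never imputed; non-missing values
#' are untouched. A stratum with no observed values falls back to the
#' global median, with a warning.
#'
#' @param cohort a \code{boph_cohort} with partitions assigned and the
#'   BLLOQ rule already applied.
#' @return the imputed cohort; per-variable imputation counts in
#'   \code{attr(, "imputation_counts")}.
#' @export
impute_continuous_medians <- function(cohort) {
  stopifnot(inherits(cohort, "boph_cohort"))
  data <- cohort$data
  meta <- cohort$meta
  if (all(data$partition == "unassigned"))
    warning("partitions unassigned; imputation strata collapse to ",
            "smoking status alone")
  vars <- meta$name[meta$type == "continuous" & meta$role != "response"]
  vars <- intersect(vars, names(data))
  strata <- interaction(data$smoking_status, data$partition, drop = TRUE)
  counts <- integer(0)
  for (vn in vars) {
    x <- data[[vn]]
    miss <- is.na(x)
    if (!any(miss)) next
    for (st in levels(strata)) {
      idx <- which(strata == st & miss)
      if (!length(idx)) next
      obs <- x[strata == st & !miss]
      if (!length(obs)) {
        warning("stratum ", st, " has no observed values of ", vn,
                "; using the global median")
        obs <- x[!miss]
      }
      data[[vn]][idx] <- stats::median(obs)
    }
    counts[vn] <- sum(miss)
  }
  cohort$data <- data
  attr(cohort, "imputation_counts") <- counts
  cohort
}

#' Encode categorical variables as indicator columns
#'
#' Nominal variables with k levels become k 0/1 indicator columns
#' \code{<var>.EQ.<level>} (the full set; downstream model fitting selects
#' among individual indicators). Ordinal variables with ordered levels
#' become k-1 cumulative indicators \code{<var>.GT.<level>}, equal to 1
#' when the value exceeds that level. A missing categorical value becomes
#' its own \code{MISSING} category before encoding (for ordinals, an
#' additional \code{<var>.EQ.MISSING} indicator with the cumulative
#' indicators set to 0). Continuous variables pass through unchanged.
#'
#' @param cohort a \code{boph_cohort} (or a data frame plus \code{meta}).
#' @param meta variable metadata; defaults to the cohort's own.
#' @return an object of class \code{"encoded_table"}: list with
#'   \code{data} (all-numeric design), \code{provenance} (one row per
#'   derived column: source variable, encoding form, level, ordered level
#'   set), \code{partition}, and \code{meta}.
#' @export
encode_categoricals <- function(cohort, meta = NULL) {
  if (inherits(cohort, "boph_cohort")) {
    data <- cohort$data
    if (is.null(meta)) meta <- cohort$meta
  } else {
    data <- cohort
    if (is.null(meta)) stop("meta is required when encoding a data frame")
  }
  out <- list()
  prov <- list()
  add <- function(col, values, source, form, level, levels) {
    out[[col]] <<- values
    prov[[length(prov) + 1L]] <<- data.frame(
      column = col, source = source, form = form,
      level = if (is.null(level)) NA_character_ else level,
      levels = if (is.null(levels)) NA_character_
               else paste(levels, collapse = "|"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(meta))) {
    vn <- meta$name[i]
    if (!vn %in% names(data)) next
    if (meta$type[i] == "continuous" || meta$role[i] == "response") {
      add(vn, as.numeric(data[[vn]]), vn, "linear", NULL, NULL)
      next
    }
    levels <- strsplit(meta$levels[i], "|", fixed = TRUE)[[1]]
    x <- as.character(data[[vn]])
    unseen <- setdiff(stats::na.omit(unique(x)), levels)
    if (length(unseen))
      stop("variable '", vn, "' has level(s) not declared in metadata: ",
           paste(unseen, collapse = ", "))
    has_missing <- anyNA(x)
    if (meta$type[i] == "ordinal") {
      for (lev in levels[-length(levels)]) {
        col <- paste(vn, "GT", lev, sep = ".")
        ind <- as.numeric(match(x, levels) > match(lev, levels))
        ind[is.na(x)] <- 0
        add(col, ind, vn, "GT", lev, levels)
      }
      if (has_missing)
        add(paste(vn, "EQ", "MISSING", sep = "."),
            as.numeric(is.na(x)), vn, "EQ", "MISSING", levels)
    } else {
      enc_levels <- if (has_missing) c(levels, "MISSING") else levels
      xx <- ifelse(is.na(x), "MISSING", x)
      for (lev in enc_levels)
        add(paste(vn, "EQ", lev, sep = "."),
            as.numeric(xx == lev), vn, "EQ", lev, levels)
    }
  }
  structure(
    list(data = as.data.frame(out, optional = TRUE, check.names = FALSE),
         provenance = do.call(rbind, prov),
         partition = if ("partition" %in% names(data)) data$partition
                     else NULL,
         smoking_status = if ("smoking_status" %in% names(data))
                            data$smoking_status else NULL,
         meta = meta),
    class = "encoded_table"
  )
}

#' Decode a categorical value from its indicator columns
#'
#' Inverse of [encode_categoricals()] for one source variable, used to
#' verify that encoding is information-preserving.
#'
#' @param enc an \code{encoded_table}.
#' @param variable source variable name.
#' @return character vector of original values (\code{NA} for the missing
#'   category).
#' @export
decode_categorical <- function(enc, variable) {
  stopifnot(inherits(enc, "encoded_table"))
  prov <- enc$provenance[enc$provenance$source == variable, , drop = FALSE]
  if (!nrow(prov)) stop("no encoded columns for '", variable, "'")
  if (any(prov$form == "GT")) {
    levels <- strsplit(prov$levels[prov$form == "GT"][1], "|",
                       fixed = TRUE)[[1]]
    gt_cols <- prov$column[prov$form == "GT"]
    counts <- Reduce(`+`, lapply(gt_cols, function(cl) enc$data[[cl]]))
    out <- levels[1L + counts]
    miss_col <- prov$column[prov$form == "EQ" & prov$level == "MISSING"]
    if (length(miss_col)) out[enc$data[[miss_col]] == 1] <- NA_character_
    out
  } else {
    out <- rep(NA_character_, nrow(enc$data))
    for (i in seq_len(nrow(prov))) {
      hit <- enc$data[[prov$column[i]]] == 1
      out[hit] <- prov$level[i]
    }
    out[out == "MISSING"] <- NA_character_
    out
  }
}

#' Prepare a cohort for modeling one response
#'
#' Runs the data-preparation sequence in its fixed order: BLLOQ
#' substitution, analysis/validation split, dropping of
#' missing-response cases, stratified median imputation, and categorical
#' encoding. Two parallel outputs are produced: an imputed encoded table
#' (input to screening and spline fitting) and the unimputed cohort
#' (input to the final complete-case refits).
#'
#' @param cohort a \code{boph_cohort}.
#' @param response response variable name.
#' @param fraction analysis fraction of the split.
#' @param seed split seed.
#' @param stratify_by_status passed to [split_analysis_validation()].
#' @return list with elements \code{encoded} (imputed, encoded),
#'   \code{cohort} (post-BLLOQ, post-split, unimputed),
#'   and \code{report} (imputation/BLLOQ/dropped-case counts).
#' @export
preprocess_cohort <- function(cohort, response, fraction = 0.8, seed = 1L,
                              stratify_by_status = FALSE) {
  stopifnot(inherits(cohort, "boph_cohort"))
  cohort <- apply_blloq(cohort)
  blloq_subs <- attr(cohort, "blloq_substitutions")
  if (all(cohort$data$partition == "unassigned"))
    cohort <- split_analysis_validation(cohort, fraction, seed,
                                        stratify_by_status)
  cohort <- drop_missing_response(cohort, response)
  n_dropped <- attr(cohort, "n_dropped")
  imputed <- impute_continuous_medians(cohort)
  enc <- encode_categoricals(imputed)
  list(encoded = enc,
       cohort = cohort,
       report = list(response = response,
                     blloq_substitutions = blloq_subs,
                     dropped_missing_response = n_dropped,
                     imputation_counts = attr(imputed, "imputation_counts"),
                     split = table(cohort$data$partition)))
}
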