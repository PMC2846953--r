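#' Default per-variable marginal specifications for the synthetic cohort
#'
#' Returns the variable schema the generator draws from: the four BOPH
#' responses, the nine biomarkers of exposure (BOE), clinical-lab
#' covariates, demographics/lifestyle variables, and (optionally) decoy
#' variables carrying no signal. Each entry describes a marginal
#' distribution (lognormal or normal for continuous variables, level
#' probabilities for categoricals), by smoking status where the two
#' populations differ. BOE marginals are stochastically larger in smokers,
#' emulating exposure biomarkers that are frequently below the limit of
#' quantification in nonsmokers.
#'
#' Distribution shapes and correlation magnitudes are conventions chosen
#' to be clinically plausible (the source study never reports them); see
#' the package vignette for the rationale behind each default.
#'
#' @param include_decoys include ~25 uninformative decoy variables
#'   (default \code{TRUE}), exercising the screening stage.
#' @return a list of per-variable spec lists with fields \code{name},
#'   \code{role} (\code{response}/\code{boe}/\code{covariate}/\code{decoy}),
#'   \code{type}, \code{units}, \code{group}, and distribution parameters.
#' @export
default_predictor_specs <- function(include_decoys = TRUE) {
  lnorm2 <- function(med_s, sd_s, med_n = med_s, sd_n = sd_s)
    list(kind = "lnorm", meanlog = c(smoker = log(med_s), nonsmoker = log(med_n)),
         sdlog = c(smoker = sd_s, nonsmoker = sd_n))
  norm1 <- function(mean, sd, lo = -Inf, hi = Inf)
    list(kind = "norm", mean = c(smoker = mean, nonsmoker = mean),
         sd = c(smoker = sd, nonsmoker = sd), lo = lo, hi = hi)
  v <- function(name, role, type, units, group, dist = NULL, levels = NULL,
                probs = NULL)
    list(name = name, role = role, type = type, units = units,
         group = group, dist = dist, levels = levels, probs = probs)

  specs <- list(
    # responses (values filled from the generating models)
    v("DEH11", "response", "continuous", "ng/24 hr urine", "BOPH"),
    v("EPI8",  "response", "continuous", "ng/24 hr urine", "BOPH"),
    v("WBC",   "response", "continuous", "x10^3/uL",       "BOPH"),
    v("HDL",   "response", "continuous", "ng/dL",          "BOPH"),
    # nine biomarkers of exposure, elevated in smokers
    v("COTIN", "boe", "continuous", "ng/mL",          "BOE", lnorm2(150, 0.8, 1,   1.0)),
    v("TOTNN", "boe", "continuous", "ng/24 hr urine", "BOE", lnorm2(400, 1.0, 5,   1.0)),
    v("OHP",   "boe", "continuous", "ng/24 hr urine", "BOE", lnorm2(300, 0.8, 80,  0.7)),
    v("NICEQ", "boe", "continuous", "mg/24 hr urine", "BOE", lnorm2(10,  0.6, 0.05, 1.0)),
    v("HPMA3", "boe", "continuous", "ug/24 hr urine", "BOE", lnorm2(800, 0.7, 150, 0.7)),
    v("DHBMA", "boe", "continuous", "ug/24 hr urine", "BOE", lnorm2(400, 0.5, 250, 0.5)),
    v("MHBMA", "boe", "continuous", "ug/24 hr urine", "BOE", lnorm2(3,   0.8, 0.4, 0.8)),
    v("ABP",   "boe", "continuous", "pg/g Hb",        "BOE", lnorm2(60,  0.5, 15,  0.5)),
    v("COHB",  "boe", "continuous", "%",              "BOE", lnorm2(5,   0.5, 1,   0.4)),
    # clinical labs
    v("UCRCAL", "covariate", "continuous", "mg/24 hr urine", "lab", lnorm2(1500, 0.35)),
    v("SCREAT", "covariate", "continuous", "mg/dL", "lab", lnorm2(1.0, 0.15)),
    v("AST",    "covariate", "continuous", "U/L",   "lab", lnorm2(24, 0.6)),
    v("ALKPH",  "covariate", "continuous", "U/L",   "lab", lnorm2(70, 0.4)),
    v("CRP",    "covariate", "continuous", "mg/L",  "lab", lnorm2(2, 1.1)),
    v("PLATE",  "covariate", "continuous", "x10^3/uL", "lab", norm1(250, 60, lo = 50)),
    v("HGB",    "covariate", "continuous", "g/dL",  "lab", norm1(14.5, 1.4, lo = 7)),
    v("TRIG",   "covariate", "continuous", "mg/dL", "lab", lnorm2(110, 0.6)),
    # demographics and lifestyle
    v("AGE",     "covariate", "continuous", "yrs", "demographics", norm1(42, 13, lo = 18, hi = 80)),
    v("WEIGHTK", "covariate", "continuous", "kg",  "demographics", norm1(80, 17, lo = 40, hi = 180)),
    v("SEX",  "covariate", "nominal", "", "demographics",
      levels = c("M", "F"), probs = c(0.55, 0.45)),
    v("RACE", "covariate", "nominal", "", "demographics",
      levels = c("CAUCASIAN", "BLACK", "ASIAN", "NATIVE.AMER",
                 "MULTI.RACIAL", "OTHER"),
      probs = c(0.70, 0.15, 0.04, 0.02, 0.03, 0.06)),
    v("DRINK", "covariate", "ordinal", "", "lifestyle",
      levels = c("NO", "LT.1.PER.WK", "1.PER.WK", "GT.1.PER.WK",
                 "GE.1.PER.DAY"),
      probs = c(0.30, 0.25, 0.15, 0.20, 0.10)),
    v("NSAID",   "covariate", "nominal", "", "lifestyle",
      levels = c("NO", "YES"), probs = c(0.75, 0.25)),
    v("VITAMIN", "covariate", "nominal", "", "lifestyle",
      levels = c("NO", "YES"), probs = c(0.65, 0.35)),
    v("SMKYRS", "covariate", "continuous", "yrs", "cumulative"),
    v("CRCL",   "covariate", "continuous", "dL/day", "lab")
  )

  if (include_decoys) {
    dc <- function(name, dist) v(name, "decoy", "continuous", "", "decoy", dist)
    decoys <- list(
      dc("ALT",   lnorm2(22, 0.5)),  dc("GGT",   lnorm2(25, 0.6)),
      dc("BUN",   norm1(14, 4, lo = 3)), dc("GLUC", norm1(95, 15, lo = 40)),
      dc("SODIUM", norm1(140, 3)),   dc("POTAS", norm1(4.2, 0.4, lo = 2)),
      dc("CALC",  norm1(9.5, 0.5)),  dc("CHOL",  norm1(195, 38, lo = 80)),
      dc("LDL",   norm1(120, 33, lo = 30)), dc("RBC", norm1(4.8, 0.45, lo = 2.5)),
      dc("HCT",   norm1(42, 4, lo = 20)), dc("MCV", norm1(90, 6)),
      dc("BILI",  lnorm2(0.6, 0.4)), dc("ALB",   norm1(4.3, 0.35, lo = 2)),
      dc("URIC",  norm1(5.4, 1.3, lo = 1)), dc("FEV1", norm1(3.3, 0.8, lo = 0.5)),
      dc("FVC",   norm1(4.2, 0.9, lo = 1)), dc("PULSE", norm1(72, 10, lo = 40)),
      dc("SYSBP", norm1(122, 14, lo = 80)), dc("DIABP", norm1(76, 9, lo = 40)),
      dc("TEMPC", norm1(36.7, 0.3)), dc("RESPRATE", norm1(15, 2, lo = 8)),
      v("REGION", "decoy", "nominal", "", "decoy",
        levels = c("NE", "SE", "MW", "WE"), probs = rep(0.25, 4)),
      v("INCOME", "decoy", "ordinal", "", "decoy",
        levels = c("LT25K", "25.50K", "50.100K", "GT100K"),
        probs = c(0.30, 0.35, 0.25, 0.10)),
      v("EDUC", "decoy", "ordinal", "", "decoy",
        levels = c("HS", "SOMECOLL", "COLLEGE", "GRAD"),
        probs = c(0.30, 0.30, 0.28, 0.12)),
      v("EXERCISE", "decoy", "ordinal", "", "decoy",
        levels = c("NONE", "OCCAS", "WEEKLY", "DAILY"),
        probs = c(0.35, 0.30, 0.25, 0.10))
    )
    specs <- c(specs, decoys)
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Variable metadata table for a set of predictor specs
#'
#' The metadata sidecar: per-variable role, measurement type, units,
#' importance group, ordered levels, and the name of the linked BLLOQ
#' (below-lower-limit-of-quantification) flag column for the nine BOE.
#'
#' @param specs output of [default_predictor_specs()].
#' @return data frame with one row per variable.
#' @export
default_variable_meta <- function(specs = default_predictor_specs()) {
  data.frame(
    name = vapply(specs, `[[`, character(1), "name"),
    role = vapply(specs, `[[`, character(1), "role"),
    type = vapply(specs, `[[`, character(1), "type"),
    units = vapply(specs, `[[`, character(1), "units"),
    group = vapply(specs, `[[`, character(1), "group"),
    levels = vapply(specs, function(s)
      if (is.null(s$levels)) NA_character_
      else paste(s$levels, collapse = "|"), character(1)),
    blloq_flag_column = vapply(specs, function(s)
      if (identical(s$role, "boe")) paste0(s$name, "_BLLOQ")
      else NA_character_, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles everything the generator needs: cohort sizes (defaults: 3585
#' smokers and 1077 nonsmokers, the source study's enrolment), per-variable
#' marginal specs, latent correlations, the four generating threshold
#' models, the target R-squared of each response (defaults: the published
#' values 0.29 DEH11, 0.41 EPI8, 0.29 WBC, 0.39 HDL), the
#' missing-completely-at-random rate for predictors, the nonsmoker
#' quantile that sets each BOE's limit of quantification, and the seed.
#'
#' Latent correlations default to 0.5 among the nine BOE and 0.3 between
#' BOE and the smoking-sensitive labs CRP and TRIG, creating realistic
#' collinearity for the screening stage.
#'
#' @param n_smokers,n_nonsmokers cohort sizes (both > 0 unless one
#'   population is deliberately empty).
#' @param predictor_specs per-variable marginal specs.
#' @param generating_models named list of four [threshold_model()]s.
#' @param target_r2 named vector in (0, 1], population R-squared of each
#'   generated response.
#' @param missing_rate MCAR masking rate for predictor cells, in [0, 0.2].
#' @param blloq_rate_nonsmokers nonsmoker quantile of each BOE used as its
#'   quantification threshold (so, approximately, the fraction of
#'   nonsmoker values flagged BLLOQ).
#' @param boe_cor,boe_lab_cor latent correlation within the BOE block and
#'   between BOE and the linked labs.
#' @param seed integer seed; identical configs generate identical cohorts.
#' @return an object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_smokers = 3585, n_nonsmokers = 1077,
                             predictor_specs = default_predictor_specs(),
                             generating_models = boph_models(),
                             target_r2 = boph_target_r2(),
                             missing_rate = 0.02,
                             blloq_rate_nonsmokers = 0.6,
                             boe_cor = 0.5, boe_lab_cor = 0.3,
                             seed = 1L) {
  if (n_smokers < 0 || n_nonsmokers < 0 || n_smokers + n_nonsmokers <= 0)
    stop("cohort sizes must be nonnegative and sum to > 0")
  if (any(target_r2 <= 0) || any(target_r2 > 1))
    stop("target_r2 values must lie in (0, 1]")
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must lie in [0, 0.2]")
  if (blloq_rate_nonsmokers < 0 || blloq_rate_nonsmokers >= 1)
    stop("blloq_rate_nonsmokers must lie in [0, 1)")
  spec_names <- vapply(predictor_specs, `[[`, character(1), "name")
  for (resp in names(generating_models)) {
    mod <- generating_models[[resp]]
    used <- vapply(mod$terms, function(tm)
      if (tm$basis$form == "hinge") tm$basis$factors$variable[1]
      else tm$basis$variable, character(1))
    missing_vars <- setdiff(used, spec_names)
    if (length(missing_vars))
      stop("generating model for ", resp, " references variables absent ",
           "from predictor_specs: ", paste(missing_vars, collapse = ", "))
    if (!resp %in% names(target_r2))
      stop("no target_r2 entry for response ", resp)
  }
  structure(
    list(n_smokers = as.integer(n_smokers),
         n_nonsmokers = as.integer(n_nonsmokers),
         predictor_specs = predictor_specs,
         generating_models = generating_models,
         target_r2 = target_r2,
         missing_rate = missing_rate,
         blloq_rate_nonsmokers = blloq_rate_nonsmokers,
         boe_cor = boe_cor, boe_lab_cor = boe_lab_cor,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Compact generator configuration for fast end-to-end runs
#'
#' An 800-subject cohort (615 smokers, 185 nonsmokers, preserving the
#' study's smoker fraction) with the 25 core predictors and no decoys.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to [generator_config()].
#' @return a \code{generator_config}.
#' @export
small_cohort_config <- function(seed = 1L, ...) {
  generator_config(n_smokers = 615, n_nonsmokers = 185,
                   predictor_specs = default_predictor_specs(include_decoys = FALSE),
                   seed = seed, ...)
}

#' Noise variance that yields a target population R-squared
#'
#' Given the variance \eqn{V} of a model's linear predictor, returns the
#' Gaussian noise variance \eqn{\sigma^2 = V (1 - R^2) / R^2} such that
#' the population R-squared of the generated response equals
#' \code{target_r2}.
#'
#' @param linear_predictor_variance nonnegative variance of the noiseless
#'   linear predictor.
#' @param target_r2 desired R-squared, in (0, 1].
#' @return the noise variance (0 iff \code{target_r2 == 1}).
#' @export
calibrate_noise_variance <- function(linear_predictor_variance, target_r2) {
  if (!is.numeric(target_r2) || length(target_r2) != 1L ||
      is.na(target_r2) || target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must be a single value in (0, 1]")
  if (linear_predictor_variance < 0)
    stop("linear_predictor_variance must be nonnegative")
  linear_predictor_variance * (1 - target_r2) / target_r2
}

#' Generate a response vector from a threshold model plus Gaussian noise
#'
#' Evaluates a generating [threshold_model()] on a cohort's (clean,
#' pre-masking) predictor values and adds independent Gaussian noise.
#' With \code{noise_sd = 0} the output is an exact deterministic function
#' of the predictors.
#'
#' @param model a [threshold_model()].
#' @param cohort a \code{boph_cohort} or a data frame of raw predictors.
#' @param noise_sd noise standard deviation.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return numeric response vector.
#' @export
apply_generating_model <- function(model, cohort, noise_sd = 0, seed = NULL) {
  data <- if (inherits(cohort, "boph_cohort")) cohort$data else cohort
  if (!is.null(seed)) set.seed(seed)
  lp <- predict(model, data)
  if (anyNA(lp))
    stop("generating model evaluated to NA; predictors must be complete ",
         "at generation time (missingness is injected afterwards)")
  lp + stats::rnorm(length(lp), 0, noise_sd)
}

# Latent correlation matrix over predictor variables (Gaussian copula).
build_latent_correlation <- function(specs, boe_cor, boe_lab_cor) {
  vars <- names(specs)[vapply(specs, function(s) s$role != "response",
                              logical(1))]
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  boe <- vars[vapply(specs[vars], function(s) identical(s$role, "boe"),
                     logical(1))]
  R[boe, boe] <- boe_cor
  linked_labs <- intersect(c("CRP", "TRIG"), vars)
  R[boe, linked_labs] <- boe_lab_cor
  R[linked_labs, boe] <- boe_lab_cor
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent correlation matrix is not positive semi-definite")
  R
}

# Map a uniform column to its marginal per the variable spec.
marginal_quantile <- function(u, spec, smoker) {
  d <- spec$dist
  if (spec$type == "continuous") {
    status <- ifelse(smoker == 1L, "smoker", "nonsmoker")
    if (d$kind == "lnorm") {
      x <- stats::qlnorm(u, d$meanlog[status], d$sdlog[status])
    } else {
      x <- stats::qnorm(u, d$mean[status], d$sd[status])
      if (!is.null(d$lo)) x <- pmin(pmax(x, d$lo), d$hi)
    }
    x
  } else {
    cuts <- cumsum(spec$probs)
    idx <- findInterval(u, cuts, left.open = TRUE) + 1L
    idx[idx > length(spec$levels)] <- length(spec$levels)
    spec$levels[idx]
  }
}

#' Generate a seeded synthetic smoker/nonsmoker cohort
#'
#' Draws predictors from a Gaussian copula (latent multivariate normal
#' mapped through per-variable marginal quantile functions), derives
#' creatinine clearance and years smoked, generates the four BOPH
#' responses from the published threshold models with noise calibrated so
#' each response's population R-squared equals its target, and finally
#' injects missingness and BLLOQ flags (see
#' [inject_missingness_and_blloq()]).
#'
#' Identical configs (including seed) produce identical cohorts.
#'
#' @param config a [generator_config()].
#' @param inject inject missingness/BLLOQ after generation
#'   (default \code{TRUE}).
#' @return an object of class \code{"boph_cohort"}: a list with
#'   \code{data} (one row per subject: \code{subject_id},
#'   \code{smoking_status}, \code{partition}, variables, and
#'   \code{<BOE>_BLLOQ} flag columns), \code{meta} (the variable metadata
#'   sidecar), and \code{truth} (generating linear predictors and noise
#'   SDs, for diagnostics).
#' @export
generate_cohort <- function(config, inject = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  specs <- config$predictor_specs
  ns <- config$n_smokers; nn <- config$n_nonsmokers
  n <- ns + nn
  smoking_status <- c(rep(1L, ns), rep(0L, nn))

  R <- build_latent_correlation(specs, config$boe_cor, config$boe_lab_cor)
  vars <- colnames(R)
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- vars

  data <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                     smoking_status = smoking_status,
                     partition = rep("unassigned", n),
                     stringsAsFactors = FALSE)
  derived <- c("CRCL", "SMKYRS")
  for (vn in setdiff(vars, derived))
    data[[vn]] <- marginal_quantile(U[, vn], specs[[vn]], smoking_status)
  # years smoked: age minus an onset age of 16-22 for smokers, 0 otherwise
  if ("SMKYRS" %in% vars)
    data$SMKYRS <- ifelse(smoking_status == 1L,
                          round(pmax(data$AGE - (16 + 6 * U[, "SMKYRS"]), 0), 1),
                          0)
  if ("CRCL" %in% vars)
    data$CRCL <- derive_crcl(data$UCRCAL, data$SCREAT)

  lp_mat <- NULL
  noise_sd <- numeric(0)
  for (resp in names(config$generating_models)) {
    mod <- config$generating_models[[resp]]
    lp <- predict(mod, data)
    sigma2 <- calibrate_noise_variance(stats::var(lp),
                                       config$target_r2[[resp]])
    data[[resp]] <- lp + stats::rnorm(n, 0, sqrt(sigma2))
    lp_mat <- cbind(lp_mat, lp)
    noise_sd[resp] <- sqrt(sigma2)
  }
  colnames(lp_mat) <- names(config$generating_models)

  cohort <- structure(
    list(data = data, meta = default_variable_meta(specs),
         truth = list(linear_predictors = lp_mat, noise_sd = noise_sd)),
    class = "boph_cohort"
  )
  if (inject) cohort <- inject_missingness_and_blloq(cohort, config)
  cohort
}

#' Inject missingness and BLLOQ flags into a clean cohort
#'
#' Two mechanisms, mirroring the structure of the source data set:
#' \enumerate{
#'   \item For each of the nine BOE, a quantification threshold is set at
#'     the \code{blloq_rate_nonsmokers} quantile of the nonsmoker values;
#'     values below it receive a \code{<BOE>_BLLOQ} flag and, with
#'     probability 0.5, the value itself is removed (so both branches of
#'     the downstream BLLOQ substitution rule are exercised).
#'   \item Predictor cells are masked completely at random at
#'     \code{missing_rate}. Responses are never masked.
#' }
#'
#' @param cohort a \code{boph_cohort} with no missing markers set.
#' @param config the [generator_config()].
#' @param seed optional seed; when called from [generate_cohort()] the
#'   generator's RNG stream is used, keeping the whole cohort a function
#'   of the config seed alone.
#' @return the cohort with flags and missing values set.
#' @export
inject_missingness_and_blloq <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(cohort, "boph_cohort"))
  if (!is.null(seed)) set.seed(seed)
  data <- cohort$data
  meta <- cohort$meta
  boe <- meta$name[meta$role == "boe"]
  nonsmoker <- data$smoking_status == 0L
  loq <- numeric(0)
  for (vn in boe) {
    ref <- if (any(nonsmoker)) data[[vn]][nonsmoker] else data[[vn]]
    thr <- stats::quantile(ref, config$blloq_rate_nonsmokers, names = FALSE)
    flag <- as.integer(data[[vn]] < thr)
    drop_value <- flag == 1L & stats::runif(nrow(data)) < 0.5
    data[[vn]][drop_value] <- NA_real_
    data[[paste0(vn, "_BLLOQ")]] <- flag
    loq[vn] <- thr
  }
  if (config$missing_rate > 0) {
    predictors <- meta$name[meta$role %in% c("boe", "covariate", "decoy")]
    for (vn in predictors) {
      mask <- stats::runif(nrow(data)) < config$missing_rate
      data[[vn]][mask] <- NA
    }
  }
  cohort$data <- data
  cohort$truth$loq <- loq
  cohort
}

#' @export
print.boph_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d smokers, %d nonsmokers), %d variables\n",
              nrow(x$data), sum(x$data$smoking_status == 1L),
              sum(x$data$smoking_status == 0L), nrow(x$meta)))
  cat("partition:", paste(sprintf("%s=%d", names(table(x$data$partition)),
                                  table(x$data$partition)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a cohort as CSV plus a variable-metadata sidecar
#'
#' @param cohort a \code{boph_cohort}.
#' @param dir output directory (created if needed); writes
#'   \code{cohort.csv} and \code{variables.csv}.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "boph_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$data, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "variables.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding \code{cohort.csv} and \code{variables.csv}.
#' @return a \code{boph_cohort} (without generating-truth attributes).
#' @export
read_cohort <- function(dir) {
  data <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "variables.csv"),
                          stringsAsFactors = FALSE)
  structure(list(data = data, meta = meta, truth = NULL),
            class = "boph_cohort")
}
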