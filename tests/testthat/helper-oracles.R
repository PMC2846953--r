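# Independent oracles and hand-built fixtures used across the suite.

# Candidate knots of one variable under the forward pass's min_span rule:
# ascending order statistics at positions min_span, 2*min_span, ...,
# capped at n - min_span, deduplicated.
knot_candidates <- function(x, min_span = 3) {
  xs <- sort(x)
  n <- length(xs)
  ks <- seq(min_span, n, by = min_span)
  ks <- ks[ks + min_span <= n]
  unique(xs[ks])
}

# Brute-force search over all (variable, knot) reflected hinge pairs:
# refits the full OLS for every candidate and returns the minimizer.
brute_force_first_pair <- function(df, response, min_span = 3) {
  y <- df[[response]]
  vars <- setdiff(names(df), response)
  best <- list(rss = Inf, variable = NA, knot = NA)
  for (v in vars) {
    x <- df[[v]]
    for (c in knot_candidates(x, min_span)) {
      b1 <- pmax(0, x - c)
      b2 <- pmax(0, c - x)
      fit <- lm(y ~ b1 + b2, singular.ok = TRUE)
      rss <- sum(residuals(fit)^2)
      if (rss < best$rss - 1e-12)
        best <- list(rss = rss, variable = v, knot = c)
    }
  }
  best
}

# Independent evaluator of the published DEH11 model: plain arithmetic,
# no package basis machinery.
deh11_by_hand <- function(d) {
  -4045.3022 +
    1.4494 * pmax(d$COTIN, 11) +
    0.3531 * pmin(d$UCRCAL, 3036) +
    0.3698 * pmin(d$CRCL, 4325) +
    17.9064 * pmax(d$AST, 25) +
    -18.2428 * pmax(d$AST, 126) +
    3.1360 * pmin(d$ALKPH, 184) +
    30.7979 * pmax(d$ALKPH, 184) +
    -346.0560 * (d$NSAID == "YES") +
    -211.7183 * (d$VITAMIN == "YES")
}

# Tiny hand-built cohort for preprocessing tests.
make_micro_cohort <- function(n = 12) {
  meta <- data.frame(
    name = c("Y", "COTIN", "AST", "SEX", "DRINK"),
    role = c("response", "boe", "covariate", "covariate", "covariate"),
    type = c("continuous", "continuous", "continuous", "nominal",
             "ordinal"),
    units = c("", "ng/mL", "U/L", "", ""),
    group = c("BOPH", "BOE", "lab", "demographics", "lifestyle"),
    levels = c(NA, NA, NA, "M|F",
               "NO|LT.1.PER.WK|1.PER.WK|GT.1.PER.WK|GE.1.PER.DAY"),
    blloq_flag_column = c(NA, "COTIN_BLLOQ", NA, NA, NA),
    stringsAsFactors = FALSE)
  data <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    smoking_status = rep(c(1L, 0L), length.out = n),
    partition = rep("unassigned", n),
    Y = seq_len(n) + 0.5,
    COTIN = seq_len(n) * 10,
    AST = 20 + seq_len(n),
    SEX = rep(c("M", "F"), length.out = n),
    DRINK = rep(c("NO", "1.PER.WK", "GE.1.PER.DAY"), length.out = n),
    COTIN_BLLOQ = rep(0L, n),
    stringsAsFactors = FALSE)
  structure(list(data = data, meta = meta, truth = NULL),
            class = "boph_cohort")
}

# Random degree-1 hinge models for reparametrization checks.
random_hinge_model <- function(n_terms = 5, seed = 1) {
  set.seed(seed)
  vars <- paste0("x", seq_len(3))
  terms <- lapply(seq_len(n_terms), function(i) {
    list(factors = data.frame(
           variable = sample(vars, 1), knot = round(runif(1, -2, 2), 3),
           dir = sample(c(-1L, 1L), 1), stringsAsFactors = FALSE),
         coefficient = round(rnorm(1, 0, 3), 3))
  })
  structure(list(intercept = round(rnorm(1), 3), terms = terms,
                 model_type = 1, rss = NA, n = NA, complexity = NA,
                 gcv = NA, gcv_r2 = NA, config = NULL, response = NULL),
            class = "spline_model")
}
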