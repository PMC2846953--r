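tb <- threshold_basis

test_that("a noiseless threshold model is refit exactly", {
  set.seed(17)
  d <- data.frame(x = runif(200, 0, 10))
  tm <- threshold_model(1, list(list(basis = tb("x", "IFGT", 5),
                                     coefficient = 2)))
  d$y <- predict(tm, d)
  fit <- refit_ols(tm, d, "y")
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_lt(max(fit$coefficients$se), 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n_used, 200)
  expect_equal(fit$n_dropped, 0)
})

test_that("estimates and standard errors match the normal-equations oracle", {
  set.seed(18)
  n <- 200
  d <- data.frame(a = rnorm(n), b = runif(n, -2, 2), c = rnorm(n))
  d$y <- 1 + 0.5 * d$a - 2 * pmin(d$b, 0.5) + rnorm(n)
  terms <- list(list(basis = tb("a", "linear"), coefficient = 0),
                list(basis = tb("b", "IFLT", 0.5), coefficient = 0),
                list(basis = tb("c", "linear"), coefficient = 0))
  fit <- refit_ols(threshold_model(0, terms), d, "y")
  # closed-form OLS: beta = (X'X)^-1 X'y, Var = sigma^2 (X'X)^-1
  X <- cbind(1, d$a, pmin(d$b, 0.5), d$c)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  res <- d$y - X %*% beta
  s2 <- sum(res^2) / (n - 4)
  se <- sqrt(s2 * diag(solve(crossprod(X))))
  expect_equal(fit$coefficients$estimate, drop(beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, se, tolerance = 1e-8)
  expect_equal(fit$coefficients$t,
               fit$coefficients$estimate / fit$coefficients$se)
  expect_equal(fit$coefficients$p,
               2 * pt(-abs(fit$coefficients$t), n - 4), tolerance = 1e-12)
})

test_that("complete-case dropping is counted per fit", {
  set.seed(19)
  d <- data.frame(x = runif(100, 0, 10))
  d$y <- 2 + d$x + rnorm(100)
  d$x[1:5] <- NA
  tm <- threshold_model(0, list(list(basis = tb("x", "linear"),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d, "y")
  expect_equal(fit$n_dropped, 5)
  expect_equal(fit$n_used, 95)
})

test_that("rank deficiency errors and names the collinear terms", {
  set.seed(20)
  d <- data.frame(x = runif(100, 0, 10))
  d$y <- d$x + rnorm(100)
  terms <- list(list(basis = tb("x", "linear"), coefficient = 0),
                list(basis = tb("x", "linear"), coefficient = 0))
  expect_error(refit_ols(threshold_model(0, terms), d, "y"),
               "collinear.*x", ignore.case = TRUE)
})

test_that("validation on the analysis partition reproduces its R-squared", {
  set.seed(21)
  d <- data.frame(x = runif(300, 0, 10), w = rnorm(300))
  d$y <- 1 + 0.8 * pmax(d$x, 4) + rnorm(300)
  tm <- threshold_model(0, list(list(basis = tb("x", "IFGT", 4),
                                     coefficient = 0),
                                list(basis = tb("w", "linear"),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d, "y")
  val <- validate_model(fit, d)
  expect_equal(val$applied_r2, fit$r2, tolerance = 1e-12)
  expect_equal(val$refit$coefficients$estimate,
               fit$coefficients$estimate, tolerance = 1e-12)
  expect_true(all(c("p_analysis", "p_validation", "stable") %in%
                  names(val$significance)))
})

test_that("a permuted validation response yields applied R-squared <= 0", {
  set.seed(22)
  d <- data.frame(x = runif(400, 0, 10))
  d$y <- 2 * d$x + rnorm(400)
  tm <- threshold_model(0, list(list(basis = tb("x", "linear"),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d[1:300, ], "y")
  perm <- d[301:400, ]
  perm$y <- sample(perm$y)
  val <- validate_model(fit, perm)
  expect_lte(val$applied_r2, 0.02)
  expect_error(validate_model(fit, d[0, ]), "empty")
})

test_that("applied and refit validation R-squared agree in-distribution", {
  set.seed(23)
  deltas <- replicate(10, {
    n <- 2000
    d <- data.frame(x = runif(n, 0, 10), w = rnorm(n))
    d$y <- 1 + 0.8 * pmax(d$x, 4) + 0.5 * d$w + rnorm(n)
    idx <- sample(n, 0.8 * n)
    tm <- threshold_model(0, list(list(basis = tb("x", "IFGT", 4),
                                       coefficient = 0),
                                  list(basis = tb("w", "linear"),
                                       coefficient = 0)))
    fit <- refit_ols(tm, d[idx, ], "y")
    val <- validate_model(fit, d[-idx, ])
    abs(val$applied_r2 - val$refit$r2)
  })
  expect_lt(median(deltas), 0.03)
})

test_that("a single-group model collapses marginal and delta to full R2", {
  set.seed(24)
  d <- data.frame(x = runif(200, 0, 10))
  d$y <- pmax(d$x, 3) + rnorm(200)
  tm <- threshold_model(0, list(list(basis = tb("x", "IFGT", 3),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d, "y")
  imp <- group_importance(fit, d)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$marginal_r2, fit$r2, tolerance = 1e-12)
  expect_equal(imp$delta_r2, fit$r2, tolerance = 1e-12)
})

test_that("orthogonal predictors split the R-squared additively", {
  # exactly orthogonal, mean-zero design
  x1 <- rep(c(-1, 1), 100)
  x2 <- rep(c(-1, -1, 1, 1), 50)
  set.seed(25)
  d <- data.frame(x1 = x1, x2 = x2)
  d$y <- x1 + 2 * x2 + rnorm(200)
  tm <- threshold_model(0, list(list(basis = tb("x1", "linear"),
                                     coefficient = 0),
                                list(basis = tb("x2", "linear"),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d, "y")
  imp <- group_importance(fit, d)
  expect_equal(sum(imp$delta_r2), fit$r2, tolerance = 1e-10)
  expect_equal(sum(imp$marginal_r2), fit$r2, tolerance = 1e-10)
})

test_that("delta R-squared is nonnegative and marginal bounded by full", {
  set.seed(26)
  for (rep in 1:5) {
    n <- 300
    d <- data.frame(a = rnorm(n), b = rnorm(n) + 0.5 * rnorm(n),
                    c = rnorm(n))
    d$b <- d$b + 0.6 * d$a  # correlated groups
    d$y <- d$a + 0.5 * pmax(d$b, 0) + rnorm(n)
    tm <- threshold_model(0, list(
      list(basis = tb("a", "linear"), coefficient = 0),
      list(basis = tb("b", "IFGT", 0), coefficient = 0),
      list(basis = tb("c", "linear"), coefficient = 0)))
    fit <- refit_ols(tm, d, "y")
    imp <- group_importance(fit, d)
    expect_true(all(imp$delta_r2 >= 0))
    expect_true(all(imp$marginal_r2 <= fit$r2 + 1e-10))
    expect_true(all(diff(imp$delta_r2) <= 1e-12))  # sorted descending
  }
})

test_that("a group unrelated to everything carries no marginal R-squared", {
  set.seed(27)
  n <- 5000
  d <- data.frame(a = rnorm(n), junk = rnorm(n))
  d$y <- 2 * d$a + rnorm(n)
  tm <- threshold_model(0, list(list(basis = tb("a", "linear"),
                                     coefficient = 0),
                                list(basis = tb("junk", "linear"),
                                     coefficient = 0)))
  fit <- refit_ols(tm, d, "y")
  imp <- group_importance(fit, d)
  expect_lt(imp$marginal_r2[imp$group == "junk"], 0.01)
})

test_that("fit summaries assemble one row per response with the flag", {
  runs <- list(
    DEH11 = list(screening_cv_r2 = 0.28, mars_gcv_r2 = 0.28,
                 analysis_r2 = 0.29, validation_applied_r2 = 0.25,
                 validation_refit_r2 = 0.27),
    HDL = list(screening_cv_r2 = 0.40, mars_gcv_r2 = 0.37,
               analysis_r2 = 0.39, validation_applied_r2 = 0.40,
               validation_refit_r2 = 0.48))
  fs <- fit_summary(runs)
  expect_equal(nrow(fs), 2)
  expect_equal(fs$agreement_flag, c(FALSE, TRUE))
  expect_equal(names(fs),
               c("response", "screening_cv_r2", "mars_gcv_r2",
                 "analysis_r2", "validation_applied_r2",
                 "validation_refit_r2", "agreement_flag"))
})
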