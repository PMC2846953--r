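test_that("GCV and GCV R-squared match their closed forms", {
  expect_equal(gcv(10, 10, 2), 1.5625)
  expect_equal(gcv(0, 100, 5), 0)
  expect_equal(gcv(10, 10, 0), 1)
  expect_identical(gcv(10, 10, 10), Inf)  # complexity >= n: rejected
  expect_error(gcv(10, 10, -1), "nonnegative")
  y2 <- sqrt(2) * c(rep(0, 5), rep(2, 5))  # SST/n = 2
  expect_equal(gcv_r2(1.5625, y2), 0.21875)
})

test_that("gcv_r2 handles models, plain values and degenerate input", {
  y <- c(1, 3, 5, 7)  # mean 4, SST/n = 5
  expect_equal(gcv_r2(0, y), 1)
  expect_equal(gcv_r2(2.5, y), 0.5)
  expect_error(gcv_r2(1, rep(2, 10)), "zero variance")
  # intercept-only fit with complexity 1 at small n: penalty exceeds fit
  set.seed(1)
  yy <- rnorm(10)
  rss0 <- sum((yy - mean(yy))^2)
  expect_lt(gcv_r2(gcv(rss0, 10, 1), yy), 0)
})

test_that("noiseless single-hinge data is recovered exactly", {
  set.seed(2)
  x <- rep(c(0, 0.5, 1, 1.5, 2), 40)
  df <- data.frame(x = x, z = rnorm(200), y = pmax(0, x - 1))
  fwd <- forward_pass(df, "y", fit_config(model_type = 1, max_basis = 10))
  expect_equal(fwd$terms[[1]]$factors$variable, "x")
  expect_equal(fwd$terms[[1]]$factors$knot, 1)
  expect_lt(fwd$rss, 1e-20)
  m <- backward_pass(fwd)
  # held-out prediction is exact: the knot is an observed value
  new <- data.frame(x = runif(100, 0, 2), z = rnorm(100))
  expect_equal(predict(m, new), pmax(0, new$x - 1), tolerance = 1e-10)
})

test_that("type-0 fits reduce to plain linear regression", {
  set.seed(3)
  df <- data.frame(x = rnorm(300), w = rnorm(300))
  df$y <- 2 * df$x + rnorm(300, 0, 0.1)
  m <- mars_fit(df, "y", fit_config(model_type = 0, max_basis = 10))
  xt <- m$terms[[which(vapply(m$terms, function(t)
    t$factors$variable[1], character(1)) == "x")]]
  ols <- coef(lm(y ~ x + w, df))[["x"]]
  expect_equal(xt$coefficient, ols, tolerance = 0.05)
  expect_equal(xt$factors$dir, 0L)
})

test_that("a constant response yields an intercept-only model", {
  df <- data.frame(x = rnorm(50), z = rnorm(50), y = rep(2, 50))
  fwd <- forward_pass(df, "y", fit_config())
  expect_length(fwd$terms, 0)
  m <- backward_pass(fwd)
  expect_length(m$terms, 0)
  expect_equal(predict(m, df), rep(2, 50))
})

test_that("the first forward term matches the brute-force knot search", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(15:30, 1)
    df <- data.frame(a = rnorm(n), b = runif(n, -2, 2), c = rnorm(n))
    df$y <- 1.5 * pmax(0, df$a - quantile(df$a, 0.4)) -
      0.8 * df$b + rnorm(n, 0, 0.3)
    cfg <- fit_config(model_type = 1, max_basis = 4, min_span = 2)
    fwd <- forward_pass(df, "y", cfg)
    oracle <- brute_force_first_pair(df, "y", min_span = 2)
    f1 <- fwd$terms[[1]]$factors
    expect_equal(f1$variable[1], oracle$variable)
    expect_equal(f1$knot[1], oracle$knot)
    # achieved rss after the first pair equals the brute-force minimum
    pair <- cbind(1, pmax(0, df[[oracle$variable]] - oracle$knot),
                  pmax(0, oracle$knot - df[[oracle$variable]]))
    rss1 <- sum(lm.fit(pair, df$y)$residuals^2)
    expect_equal(rss1, oracle$rss, tolerance = 1e-8)
  }
})

test_that("the backward pass prunes noise terms by GCV", {
  kept_noise <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 500
    df <- data.frame(x = runif(n, 0, 4), noise = rnorm(n))
    df$y <- 2 * pmax(0, df$x - 2) + rnorm(n)
    m <- mars_fit(df, "y", fit_config(model_type = 1, max_basis = 10))
    vars <- unique(unlist(lapply(m$terms, function(t)
      t$factors$variable)))
    if ("noise" %in% vars) kept_noise <- kept_noise + 1
    expect_true("x" %in% vars)
  }
  expect_lte(kept_noise, 1)  # pruned in at least 90% of replicates
})

test_that("forward pass never increases training rss as terms are added", {
  set.seed(6)
  n <- 300
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  df$y <- pmax(0, df$a) + 0.5 * df$b + rnorm(n, 0, 0.5)
  sst <- sum((df$y - mean(df$y))^2)
  prev <- sst
  for (mb in c(2, 4, 6, 8, 10)) {
    fwd <- forward_pass(df, "y", fit_config(max_basis = mb,
                                            entry_penalty = 0))
    expect_lte(fwd$rss, prev + 1e-8)
    prev <- fwd$rss
  }
})

test_that("gcv_r2 never exceeds the ordinary R-squared when penalized", {
  set.seed(7)
  df <- data.frame(x = rnorm(400), w = rnorm(400))
  df$y <- pmax(0, df$x - 0.5) + rnorm(400, 0, 0.4)
  m <- mars_fit(df, "y", fit_config(max_basis = 10))
  r2 <- 1 - m$rss / sum((df$y - mean(df$y))^2)
  expect_gt(m$complexity, 0)
  expect_lt(m$gcv_r2, r2)
})

test_that("model predictions equal the term-by-term basis expansion", {
  set.seed(8)
  df <- data.frame(a = rnorm(300), b = runif(300, -1, 3))
  df$y <- 2 * pmax(0, df$a - 0.3) - pmax(0, 1 - df$b) + rnorm(300, 0, 0.2)
  m <- mars_fit(df, "y", fit_config(max_basis = 10))
  new <- data.frame(a = rnorm(50), b = runif(50, -1, 3))
  manual <- rep(m$intercept, 50)
  for (t in m$terms) {
    f <- t$factors
    col <- rep(1, 50)
    for (i in seq_len(nrow(f))) {
      x <- new[[f$variable[i]]]
      col <- col * if (f$dir[i] == 0) x
                   else if (f$dir[i] > 0) pmax(0, x - f$knot[i])
                   else pmax(0, f$knot[i] - x)
    }
    manual <- manual + t$coefficient * col
  }
  expect_equal(predict(m, new), manual, tolerance = 1e-12)
})

test_that("the entry penalty discourages new variables", {
  set.seed(9)
  n <- 300
  df <- data.frame(x = runif(n, 0, 4), w1 = rnorm(n), w2 = rnorm(n),
                   w3 = rnorm(n))
  df$y <- 2 * pmax(0, df$x - 2) + rnorm(n)
  n_vars <- function(pen) {
    fwd <- forward_pass(df, "y", fit_config(max_basis = 12,
                                            entry_penalty = pen))
    length(unique(unlist(lapply(fwd$terms, function(t)
      t$factors$variable))))
  }
  expect_lte(n_vars(0.01), n_vars(0))
})

test_that("cross-validated R-squared tracks the population value", {
  set.seed(10)
  n <- 1000
  df <- data.frame(x = rnorm(n), w = rnorm(n))
  df$y <- df$x + rnorm(n)  # population R^2 = 0.5
  cfg <- fit_config(model_type = 1, max_basis = 6, folds = 5, seed = 3)
  r2 <- cv_r2(df, "y", cfg)
  expect_equal(r2, 0.5, tolerance = 0.05)
  expect_identical(cv_r2(df, "y", cfg), r2)  # seeded determinism
  # pure noise: no spurious skill
  df$y <- rnorm(n)
  expect_lte(cv_r2(df, "y", cfg), 0.02)
  expect_error(cv_r2(df[1:3, ], "y", cfg), "folds")
})

test_that("grid search enumerates the control lattice", {
  set.seed(11)
  n <- 150
  df <- data.frame(a = runif(n, 0, 2), b = rnorm(n), c = rnorm(n),
                   d = rnorm(n))
  df$y <- pmax(0, df$a - 1) + 0.3 * df$b + rnorm(n, 0, 0.3)
  sets <- list(
    large = structure(list(variables = c("a", "b", "c", "d"), cv_r2 = NA,
                           size_class = "large"), class = "predictor_set"),
    medium = structure(list(variables = c("a", "b", "c"), cv_r2 = NA,
                            size_class = "medium"), class = "predictor_set"),
    small = structure(list(variables = c("a", "b"), cv_r2 = NA,
                           size_class = "small"), class = "predictor_set"))
  grid <- grid_search(df, "y", sets, seed = 11)
  expect_equal(nrow(grid), 72)  # 3 sets x 3 types x 4 sizes x 2 penalties
  expect_true(all(diff(grid$gcv_r2) <= 1e-12))
  expect_length(attr(grid, "models"), 72)
  one <- grid_search(df, "y", sets["small"], model_types = 1,
                     max_basis = 10, entry_penalties = 0, seed = 11)
  expect_equal(nrow(one), 1)
})

test_that("preferred-model selection trades fit for parsimony", {
  # hand-constructed records: within the 0.01 tolerance of the best
  # (0.40), the 6-variable model at 0.395 wins over the 12-variable best
  recs <- data.frame(id = 1:3, set = "large", model_type = c(2, 1, 1),
                     max_basis = 30, entry_penalty = 0,
                     gcv_r2 = c(0.40, 0.395, 0.37),
                     n_params = c(14, 8, 4), n_vars = c(12, 6, 3))
  attr(recs, "models") <- list("m1", "m2", "m3")
  pick <- select_preferred(recs, tolerance = 0.01)
  expect_equal(pick$record$n_vars, 6)
  expect_identical(pick$model, "m2")
  # single candidate: itself
  pick1 <- select_preferred(recs[1, , drop = FALSE])
  expect_equal(pick1$record$id, 1)
  # exact ties resolve to the first record in sort order
  recs2 <- recs
  recs2$gcv_r2 <- 0.4; recs2$n_vars <- 5; recs2$n_params <- 8
  recs2$model_type <- 1
  expect_equal(select_preferred(recs2)$record$id, 1)
})
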