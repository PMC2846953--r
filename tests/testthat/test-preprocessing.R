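test_that("BLLOQ rule substitutes zero only for flagged missing values", {
  expect_equal(apply_blloq_rule(NA_real_, 1L), 0)
  expect_equal(apply_blloq_rule(0.7, 1L), 0.7)
  expect_true(is.na(apply_blloq_rule(NA_real_, 0L)))
  expect_equal(apply_blloq_rule(3.2, 0L), 3.2)
  # idempotence: applying twice equals applying once
  v <- c(NA, 0.7, NA, 5)
  f <- c(1L, 1L, 0L, 0L)
  once <- apply_blloq_rule(v, f)
  expect_identical(apply_blloq_rule(once, f), once)
})

test_that("cohort-level BLLOQ application counts substitutions", {
  co <- make_micro_cohort()
  co$data$COTIN[1:2] <- NA
  co$data$COTIN_BLLOQ[1:3] <- 1L
  out <- apply_blloq(co)
  expect_equal(out$data$COTIN[1:2], c(0, 0))
  expect_equal(out$data$COTIN[3], co$data$COTIN[3])
  expect_equal(unname(attr(out, "blloq_substitutions")["COTIN"]), 2L)
})

test_that("creatinine clearance is the urine/serum quotient", {
  expect_equal(derive_crcl(1500, 1.0), 1500)
  expect_equal(derive_crcl(0, 1.2), 0)
  expect_true(is.na(derive_crcl(1500, NA)))
  expect_true(is.na(derive_crcl(NA, 1.0)))
  expect_warning(out <- derive_crcl(1500, 0), "nonpositive")
  expect_true(is.na(out))
})

test_that("split sizes, determinism and partition property hold", {
  co <- make_micro_cohort(4662)
  s <- split_analysis_validation(co, 0.8, seed = 1)
  expect_equal(sum(s$data$partition == "analysis"), 3730)
  expect_equal(sum(s$data$partition == "validation"), 932)
  s2 <- split_analysis_validation(co, 0.8, seed = 1)
  expect_identical(s$data$partition, s2$data$partition)
  s3 <- split_analysis_validation(make_micro_cohort(10), 0.5, seed = 2)
  expect_equal(unname(table(s3$data$partition)["analysis"]), 5L)
  expect_true(all(s$data$partition %in% c("analysis", "validation")))
  expect_error(split_analysis_validation(co, 1.2), "fraction")
})

test_that("missing responses are dropped and counted", {
  co <- make_micro_cohort(100)
  co$data$Y[c(5, 50, 99)] <- NA
  out <- drop_missing_response(co, "Y")
  expect_equal(nrow(out$data), 97)
  expect_equal(attr(out, "n_dropped"), 3L)
  # identity when nothing is missing
  out2 <- drop_missing_response(make_micro_cohort(10), "Y")
  expect_equal(nrow(out2$data), 10)
  expect_equal(attr(out2, "n_dropped"), 0L)
  co$data$Y <- NA_real_
  expect_warning(out3 <- drop_missing_response(co, "Y"), "all values")
  expect_equal(nrow(out3$data), 0)
})

test_that("median imputation is stratified and touches only missing cells", {
  co <- make_micro_cohort(16)
  co$data$partition <- rep(c("analysis", "validation"), each = 8)
  # smoker analysis stratum: values 1, 2, 4 and one missing -> median 2
  smk_an <- which(co$data$smoking_status == 1L &
                  co$data$partition == "analysis")
  co$data$AST[smk_an[1:4]] <- c(1, 2, NA, 4)
  # nonsmoker analysis stratum: median 10 among c(8, 10, 12), one missing
  non_an <- which(co$data$smoking_status == 0L &
                  co$data$partition == "analysis")
  co$data$AST[non_an[1:4]] <- c(8, 10, 12, NA)
  before <- co$data$AST
  out <- impute_continuous_medians(co)
  expect_equal(out$data$AST[smk_an[3]], 2)
  expect_equal(out$data$AST[non_an[4]], 10)
  untouched <- !is.na(before)
  expect_identical(out$data$AST[untouched], before[untouched])
  expect_false(anyNA(out$data$AST))
  # responses are never imputed
  co2 <- make_micro_cohort(8)
  co2$data$partition <- "analysis"
  co2$data$Y[2] <- NA
  out2 <- impute_continuous_medians(co2)
  expect_true(is.na(out2$data$Y[2]))
  # no missing values: identity
  co3 <- make_micro_cohort(8)
  co3$data$partition <- "analysis"
  expect_identical(impute_continuous_medians(co3)$data, co3$data)
})

test_that("stratum medians after imputation equal pre-imputation medians", {
  set.seed(21)
  co <- make_micro_cohort(60)
  co$data$partition <- sample(c("analysis", "validation"), 60, TRUE)
  co$data$AST[sample(60, 12)] <- NA
  strata <- interaction(co$data$smoking_status, co$data$partition)
  pre <- tapply(co$data$AST, strata, median, na.rm = TRUE)
  out <- impute_continuous_medians(co)
  post <- tapply(out$data$AST, strata, median)
  expect_equal(unname(post), unname(pre))
})

test_that("categorical encoding follows the printed dummy conventions", {
  co <- make_micro_cohort(10)
  co$data$SEX[3] <- NA
  enc <- encode_categoricals(co)
  d <- enc$data
  # nominal: full indicator set, one per level plus MISSING
  expect_true(all(c("SEX.EQ.M", "SEX.EQ.F", "SEX.EQ.MISSING") %in%
                  names(d)))
  expect_equal(d$SEX.EQ.MISSING[3], 1)
  expect_equal(sum(d$SEX.EQ.M + d$SEX.EQ.F + d$SEX.EQ.MISSING == 1), 10)
  # ordinal: cumulative indicators; value 1.PER.WK exceeds NO and <1/wk
  i <- which(co$data$DRINK == "1.PER.WK")[1]
  expect_equal(d$DRINK.GT.NO[i], 1)
  expect_equal(d$DRINK.GT.LT.1.PER.WK[i], 1)
  expect_equal(d$DRINK.GT.1.PER.WK[i], 0)
  expect_equal(d$DRINK.GT.GT.1.PER.WK[i], 0)
  # indicator columns are 0/1 and provenance covers all derived columns
  cat_cols <- enc$provenance$column[enc$provenance$form != "linear"]
  for (cl in cat_cols) expect_true(all(d[[cl]] %in% 0:1))
  expect_setequal(enc$provenance$column, names(d))
  # unseen level errors, naming the variable
  co$data$SEX[1] <- "X"
  expect_error(encode_categoricals(co), "SEX")
})

test_that("encoding round-trips every categorical value", {
  co <- make_micro_cohort(15)
  co$data$DRINK[4] <- NA
  enc <- encode_categoricals(co)
  expect_equal(decode_categorical(enc, "SEX"), co$data$SEX)
  expect_equal(decode_categorical(enc, "DRINK"), co$data$DRINK)
})

test_that("preprocess_cohort runs the fixed order and reports counts", {
  co <- generate_cohort(small_cohort_config(seed = 13))
  pp <- preprocess_cohort(co, "DEH11", seed = 13)
  expect_s3_class(pp$encoded, "encoded_table")
  expect_false(anyNA(pp$encoded$data[
    setdiff(names(pp$encoded$data),
            c("WBC", "EPI8", "DEH11", "HDL"))]))
  expect_true(all(pp$cohort$data$partition %in%
                  c("analysis", "validation")))
  expect_true(is.numeric(pp$report$dropped_missing_response))
  # unimputed cohort still carries missing predictor cells
  expect_true(anyNA(pp$cohort$data$AST) || anyNA(pp$cohort$data$TRIG))
})
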