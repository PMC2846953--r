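#' Published final threshold-basis models for the four BOPH
#'
#' Returns the four published all-subjects regression models for the
#' biomarkers of potential harm — DEH11 (24 h urine
#' 11-dehydro-thromboxane B2), EPI8 (24 h urine 8-epi-prostaglandin
#' F2-alpha), WBC (white blood cell count) and HDL (HDL cholesterol) — as
#' [threshold_model()] objects. These models are the generating truth of
#' the synthetic cohort simulator: every downstream stage of the pipeline
#' can be exercised against known coefficients without access to the
#' proprietary study data.
#'
#' Each model carries an attribute \code{target_r2}, the reported
#' coefficient of determination of the model on its analysis data set
#' (0.29 DEH11, 0.41 EPI8, 0.29 WBC, 0.39 HDL), used to calibrate the
#' generator's noise variance.
#'
#' @return named list of four \code{threshold_model} objects
#'   (\code{DEH11}, \code{EPI8}, \code{WBC}, \code{HDL}).
#' @seealso [generate_cohort()], [calibrate_noise_variance()]
#' @export
boph_models <- function() {
  drink_levels <- c("NO", "LT.1.PER.WK", "1.PER.WK", "GT.1.PER.WK",
                    "GE.1.PER.DAY")
  tb <- threshold_basis
  trm <- function(basis, coefficient) list(basis = basis,
                                           coefficient = coefficient)

  deh11 <- threshold_model(-4045.3022, list(
    trm(tb("COTIN", "IFGT", 11), 1.4494),
    trm(tb("UCRCAL", "IFLT", 3036), 0.3531),
    trm(tb("CRCL", "IFLT", 4325), 0.3698),
    trm(tb("AST", "IFGT", 25), 17.9064),
    trm(tb("AST", "IFGT", 126), -18.2428),
    trm(tb("ALKPH", "IFLT", 184), 3.1360),
    trm(tb("ALKPH", "IFGT", 184), 30.7979),
    trm(tb("NSAID", "EQ", "YES"), -346.0560),
    trm(tb("VITAMIN", "EQ", "YES"), -211.7183)
  ))
  attr(deh11, "target_r2") <- 0.29

  epi8 <- threshold_model(1383.0200, list(
    trm(tb("TOTNN", "IFLT", 57), 5.1813),
    trm(tb("TOTNN", "IFGT", 57), 0.5548),
    trm(tb("TOTNN", "IFGT", 1452), -1.4595),
    trm(tb("OHP", "IFLT", 473), 0.8552),
    trm(tb("CRCL", "linear"), 0.6268),
    trm(tb("AST", "IFGT", 22), -135.4800),
    trm(tb("AST", "IFGT", 24), 247.4960),
    trm(tb("AST", "IFGT", 26), -108.4000),
    trm(tb("AST", "IFLT", 106), 12.2512),
    trm(tb("WEIGHTK", "linear"), 6.2845),
    trm(tb("VITAMIN", "EQ", "YES"), -250.7700)
  ))
  attr(epi8, "target_r2") <- 0.41

  wbc <- threshold_model(-6.4951, list(
    trm(tb("TOTNN", "IFGT", 51), -0.0055),
    trm(tb("TOTNN", "IFLT", 471), 0.0078),
    trm(tb("TOTNN", "IFGT", 471), 0.0065),
    trm(tb("CRP", "IFLT", 2), 0.3426),
    trm(tb("CRP", "IFGT", 2), 0.0715),
    trm(tb("CRP", "IFGT", 20), -0.0477),
    trm(tb("PLATE", "IFLT", 245), 0.0106),
    trm(tb("PLATE", "IFGT", 245), 0.0070),
    trm(tb("HGB", "IFLT", 14), 0.3242),
    trm(tb("TRIG", "IFLT", 171), 0.0051),
    trm(tb("TRIG", "IFGT", 503), 0.0025),
    trm(tb("RACE", "EQ", "BLACK"), -0.6790)
  ))
  attr(wbc, "target_r2") <- 0.29

  hdl <- threshold_model(55.4292, list(
    trm(tb("COTIN", "IFGT", 31), -0.0291),
    trm(tb("COTIN", "IFGT", 193), 0.0258),
    trm(tb("TRIG", "IFGT", 52), -0.5819),
    trm(tb("TRIG", "IFGT", 64), 0.4830),
    trm(tb("TRIG", "IFGT", 177), 0.0753),
    trm(tb("WEIGHTK", "IFLT", 76), -0.2670),
    trm(tb("WEIGHTK", "IFGT", 76), -0.0834),
    trm(tb("AGE", "IFLT", 55), 0.3119),
    trm(tb("SEX", "EQ", "F"), 6.7200),
    trm(tb("DRINK", "EQ", "Y", levels = drink_levels), 2.0567),
    trm(tb("DRINK", "GT", "1.PER.WK", levels = drink_levels), 7.8750)
  ))
  attr(hdl, "target_r2") <- 0.39

  list(DEH11 = deh11, EPI8 = epi8, WBC = wbc, HDL = hdl)
}

#' Reported R-squared of the published BOPH models
#'
#' @return named numeric vector of analysis-set R-squared values for the
#'   four published models.
#' @export
boph_target_r2 <- function() {
  c(DEH11 = 0.29, EPI8 = 0.41, WBC = 0.29, HDL = 0.39)
}
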