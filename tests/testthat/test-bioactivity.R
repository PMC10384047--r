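test_that("censored values parse, format and validate", {
  expect_identical(parse_censored(">500")$censor, "gt")
  expect_identical(parse_censored(">500")$value, 500)
  expect_identical(parse_censored("-")$censor, "missing")
  expect_identical(parse_censored(8)$censor, "exact")
  expect_identical(format(parse_censored(">500")), ">500")
  expect_error(parse_censored("abc"), class = "ampchem_parse_error")
})

test_that("MBC/MIC ratios propagate censoring conservatively", {
  r1 <- mbc_mic_ratio(activity_record("x", "S. aureus", "positive", 8, 8))
  expect_identical(r1$value, 1)
  expect_identical(r1$censor, "exact")
  r2 <- mbc_mic_ratio(activity_record("x", "E. coli", "negative", 31, 62))
  expect_identical(r2$value, 2)
  r3 <- mbc_mic_ratio(activity_record("x", "s", "negative", 500, ">500"))
  expect_identical(r3$censor, "gt")
  expect_identical(r3$value, 1)
  expect_error(
    mbc_mic_ratio(activity_record("x", "s", "negative", ">500", ">500")),
    class = "ampchem_undefined_ratio")
  # MBC below MIC warns at record construction
  expect_warning(activity_record("x", "s", "positive", 62, 31),
                 class = "ampchem_mbc_below_mic")
})

test_that("HC50 interpolates the first upward 50% crossing", {
  h <- hc50(hemolysis_curve(c(100, 200), c(40, 60)))
  expect_identical(h$value, 150)
  expect_identical(h$censor, "exact")
  # sub-50% curves are censored at the top concentration
  h2 <- hc50(hemolysis_curve(c(50, 100, 200), c(10, 20, 30)))
  expect_identical(h2$censor, "gt")
  expect_identical(h2$value, 200)
  # invariant to points appended above the first crossing
  h3 <- hc50(hemolysis_curve(c(100, 200, 400, 800), c(40, 60, 40, 90)))
  expect_identical(h3$value, 150)
  # logistic-generated curve: interpolated HC50 near the generator midpoint
  conc <- c(12.5, 25, 50, 75, 100, 150, 200, 300)
  yl <- 100 / (1 + (80 / conc)^3)  # 4PL with midpoint 80, hill 3
  h4 <- hc50(hemolysis_curve(conc, yl))
  expect_lt(abs(h4$value - 80) / 80, 0.05)
})

test_that("selectivity indices carry lower bounds through", {
  expect_identical(selectivity_index(censored(64), censored(16))$value, 4)
  si <- selectivity_index(">200", 31)
  expect_identical(si$censor, "gt")
  expect_equal(si$value, 200 / 31, tolerance = 1e-12)
  expect_error(selectivity_index(censored(64), ">500"),
               class = "ampchem_undefined_ratio")
})

test_that("unit conversion is exact and invertible", {
  expect_equal(convert_concentration(1, "ug/mL", "uM", molar_mass = 500), 2)
  expect_identical(convert_concentration(7, "uM", "uM"), 7)
  x <- 123.456
  back <- convert_concentration(
    convert_concentration(x, "uM", "ug/mL", molar_mass = 437.5),
    "ug/mL", "uM", molar_mass = 437.5)
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(convert_concentration(1, "uM", "ug/mL"),
               class = "ampchem_conversion_error")
})

test_that("dilution snapping reports the smallest grid value at or above", {
  expect_identical(snap_to_dilution(7)$value, 8)
  expect_identical(snap_to_dilution(600)$censor, "gt")
  expect_identical(snap_to_dilution(600)$value, 500)
  # grid values are fixed points
  for (g in c(500, 62, 8, 2))
    expect_identical(snap_to_dilution(g)$value, g)
})

test_that("the transcribed activity tables load with censoring intact", {
  trp <- read_activity_table(system.file("extdata", "mic_tryptophan.csv",
                                         package = "ampchem"))
  phe <- read_activity_table(system.file("extdata", "mic_phenylalanine.csv",
                                         package = "ampchem"))
  frm <- read_activity_table(system.file("extdata", "mic_formulations.csv",
                                         package = "ampchem"))
  expect_length(trp, 40)  # 4 homologs + reference compound x 8 strains
  expect_length(phe, 24)
  expect_length(frm, 32)
  # spot-check specific cells, including censored and missing ones
  r <- Filter(function(x) x$compound == "C12TC3NH3Cl" &&
                x$strain == "S. aureus", trp)[[1]]
  expect_identical(r$mic$value, 8)
  expect_identical(r$mbc$value, 8)
  r2 <- Filter(function(x) x$compound == "C8TC3NH3Cl" &&
                 x$strain == "K. aerogenes", trp)[[1]]
  expect_identical(r2$mic$censor, "gt")
  r3 <- Filter(function(x) x$compound == "BAC", trp)[[1]]
  expect_identical(r3$mbc$censor, "missing")
  r4 <- Filter(function(x) x$compound == "DPPC60_C12T40" &&
                 x$strain == "L. monocytogenes", frm)[[1]]
  expect_identical(r4$mic$censor, "missing")
  expect_identical(r4$mbc$censor, "gt")
  # summary reports the actual ratio range and flags values beyond 2
  sm <- summarize_mbc_mic(trp)
  expect_true(sm$any_censored)
  expect_identical(sm$range[1], 1)
  expect_true(sm$exceeds_bactericidal_range)  # e.g. 500/125 = 4
})
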