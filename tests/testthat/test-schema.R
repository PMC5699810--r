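test_that("schema covers all variables once, with the stated unknown rules", {
  sc <- copd_schema()
  expect_false(anyDuplicated(sc$name) > 0)
  expect_setequal(unique(sc$group),
                  c("profile", "comorbidity", "symptom", "vital", "baseline_vital"))
  no_unknown <- sc$name[!sc$allows_unknown]
  expect_setequal(no_unknown,
                  c("age", "weight", "height", "gender", "baseline_mmrc",
                    sc$name[sc$group == "symptom"]))
})

test_that("validate_case flags range violations, missing variables and illegal unknowns", {
  sc <- copd_schema()
  expect_true(validate_case(make_case(), sc)$pass)
  expect_length(validate_case(make_case(), sc)$violations, 0)

  r <- validate_case(make_case(gold_stage = "5"), sc)
  expect_false(r$pass)
  expect_match(r$violations, "range violation: gold_stage", all = FALSE)

  r <- validate_case(make_case(cough = "unknown"), sc)
  expect_false(r$pass)
  expect_match(r$violations, "unknown not permitted: cough", all = FALSE)

  r <- validate_case(make_case(o2sat = 150), sc)
  expect_match(r$violations, "range violation: o2sat", all = FALSE)

  case <- make_case(); case$cough <- NULL
  r <- validate_case(case, sc)
  expect_match(r$violations, "incomplete case: cough", all = FALSE)

  # unknown is fine where permitted
  expect_true(validate_case(make_case(gold_stage = "unknown", o2sat = NA), sc)$pass)
})

test_that("vital bins follow the printed half-open convention", {
  F <- encode_features(make_case(o2sat = 88))
  o2cols <- grep("^O2Sat_\\(", colnames(F), value = TRUE)
  expect_equal(as.numeric(F[, "O2Sat_(87, 89]"]), 1)
  expect_equal(sum(F[, o2cols]), 1)

  # boundary value goes to the right-closed bin
  F89 <- encode_features(make_case(o2sat = 89))
  expect_equal(as.numeric(F89[, "O2Sat_(87, 89]"]), 1)
  F89b <- encode_features(make_case(o2sat = 89.01))
  expect_equal(as.numeric(F89b[, "O2Sat_(89, 91]"]), 1)
})

test_that("categorical one-hots and the combined sputum feature encode as named", {
  F <- encode_features(make_case(cough = "3", sputum_col = "yes", sputum_vol = "no"))
  expect_equal(as.numeric(F[, "cough_3"]), 1)
  expect_equal(as.numeric(F[, "cough_1"]), 0)
  expect_equal(as.numeric(F[, "sputum(col+vol)_1"]), 1)
  expect_equal(as.numeric(F[, "sputum_col_1"]), 1)
  expect_equal(as.numeric(F[, "sputum_vol_1"]), 0)
  F2 <- encode_features(make_case(), single_sputum = FALSE)
  expect_false("sputum_col_1" %in% colnames(F2))
  expect_true("sputum(col+vol)_0" %in% colnames(F2))
})

test_that("zero FEV1 change lands in the bin containing 0 per the interval convention", {
  # brute-force bin lookup over the configured edges
  edges <- default_bins()$dfev1
  lookup <- function(x) {
    for (i in seq_len(length(edges) - 1))
      if (x > edges[i] && x <= edges[i + 1]) return(i)
    NA
  }
  F <- encode_features(make_case(fev1 = 60, baseline_fev1 = 60))
  labs <- grep("^dfev1_\\(", colnames(F), value = TRUE)
  expect_equal(as.numeric(F[, "dfev1_(-5, 0]"]), 1)
  expect_equal(which(F[, labs] == 1), lookup(0), ignore_attr = TRUE)
  # and a spot check away from zero
  F2 <- encode_features(make_case(fev1 = 54, baseline_fev1 = 60))  # -10%
  expect_equal(which(F2[, labs] == 1), lookup(-10), ignore_attr = TRUE)
})

test_that("delta features are unknown unless both current and baseline are known", {
  F <- encode_features(make_case(baseline_fev1 = NA))
  expect_equal(as.numeric(F[, "dfev1_unknown"]), 1)
  expect_equal(sum(F[, grep("^dfev1_\\(", colnames(F))]), 0)
  F2 <- encode_features(make_case(o2sat = NA))
  expect_equal(as.numeric(F2[, "dO2Sat_unknown"]), 1)
})

test_that("the O2-sat change block is gated on baseline < 93 and left-closed", {
  F <- encode_features(make_case(o2sat = 88, baseline_o2sat = 91))  # delta -3
  expect_equal(as.numeric(F[, "dO2Sat_[-4, -2)_base<93"]), 1)
  # delta exactly -2 is excluded from [-4, -2) and joins [-2, 0)
  F2 <- encode_features(make_case(o2sat = 89, baseline_o2sat = 91))
  expect_equal(as.numeric(F2[, "dO2Sat_[-4, -2)_base<93"]), 0)
  expect_equal(as.numeric(F2[, "dO2Sat_[-2, 0)_base<93"]), 1)
  # baseline at or above 93: gate closes, indicator records it
  F3 <- encode_features(make_case(o2sat = 93, baseline_o2sat = 96))
  expect_equal(sum(F3[, grep("^dO2Sat_\\[", colnames(F3))]), 0)
  expect_equal(as.numeric(F3[, "dO2Sat_base>=93"]), 1)
})

test_that("bin indicators plus unknown indicators partition every binned variable", {
  co <- small_cohort()
  F <- encode_features(co)
  groups <- list(
    c(grep("^O2Sat_\\(", colnames(F), value = TRUE), "O2Sat_unknown"),
    c(grep("^hr_", colnames(F), value = TRUE), "hr_unknown"),
    c(grep("^temp_\\(", colnames(F), value = TRUE), "temp_unknown"),
    c(grep("^fev1_\\(", colnames(F), value = TRUE), "fev1_unknown"),
    c(grep("^dfev1_\\(", colnames(F), value = TRUE), "dfev1_unknown"),
    c(grep("^dO2Sat_\\[", colnames(F), value = TRUE),
      "dO2Sat_base>=93", "dO2Sat_unknown"))
  for (g in groups) {
    g <- unique(g)
    expect_true(all(rowSums(F[, g, drop = FALSE]) == 1))
  }
})

test_that("unknown source values zero the level indicators and set the unknown flag", {
  F <- encode_features(make_case(gold_stage = "unknown", heartrate = NA))
  expect_equal(as.numeric(F[, "gold_stage_unknown"]), 1)
  expect_equal(sum(F[, paste0("gold_stage_", 1:4)]), 0)
  expect_equal(as.numeric(F[, "hr_unknown"]), 1)
})

test_that("decoding the one-hot block round-trips the categorical levels", {
  co <- small_cohort()
  F <- encode_features(co)
  dec <- decode_categoricals(F)
  sc <- copd_schema()
  for (nm in sc$name[sc$kind == "categorical"]) {
    orig <- as.character(co[[nm]])
    orig[is.na(orig)] <- "unknown"
    expect_equal(dec[[nm]], orig, info = nm)
  }
})

test_that("encoding is deterministic and BMI uses the imperial formula", {
  c1 <- make_case()
  expect_identical(encode_features(c1), encode_features(c1))
  F <- encode_features(make_case(weight = 150, height = 65))
  expect_equal(as.numeric(F[, "bmi"]), 703 * 150 / 65^2)
})

test_that("bad bin configuration is rejected", {
  bad <- default_bins(); bad$o2sat <- c(0, 90, 85)
  expect_error(encode_features(make_case(), bins = bad), "bad bin config")
})
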