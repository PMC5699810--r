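toy_policy <- function(weights = c(cough_3 = 2, shortbreath_3 = 3, infection_1 = 1),
                       thresholds = c(1, 3, 5), bias = 0, noise_sd = 0,
                       id = "dr1") {
  rater_policy(id, weights = weights, thresholds = thresholds,
               exac_weights = weights, exac_threshold = 2.5,
               bias = bias, noise_sd = noise_sd)
}

test_that("severity score is the weighted feature sum plus bias", {
  F <- encode_features(make_case(cough = "3", shortbreath = "3", infection = "yes"))
  expect_equal(severity_score(F, toy_policy(weights = c(cough_3 = 0))), 0)
  expect_equal(severity_score(F, toy_policy(weights = c(cough_3 = 0), bias = 1.5)), 1.5)
  expect_equal(severity_score(F, toy_policy(weights = c(cough_3 = 2.5))), 2.5)
  # 3-feature hand computation
  expect_equal(severity_score(F, toy_policy()), 2 + 3 + 1)
  # unweighted features are ignored, weights on absent names contribute 0
  expect_equal(severity_score(F, toy_policy(weights = c(not_a_feature = 9))), 0)
})

test_that("noiseless rating maps scores through thresholds deterministically", {
  quiet_case <- make_case()  # cough 2, shortbreath 2: score 0 < t1
  r <- rate_case(quiet_case, toy_policy())
  expect_equal(r$triage, 1L)
  expect_gt(r$triage_conf, 0)
  severe <- make_case(cough = "3", shortbreath = "3", infection = "yes")  # 6 > t3
  expect_equal(rate_case(severe, toy_policy())$triage, 4L)
  expect_identical(rate_case(severe, toy_policy(), seed = 1),
                   rate_case(severe, toy_policy(), seed = 99))
})

test_that("triage is a non-decreasing step function of the latent score", {
  pol <- rater_policy("p", weights = c(age = 1), thresholds = c(50, 60, 70),
                      exac_weights = c(age = 1), exac_threshold = 60)
  ages <- seq(40, 90, by = 1)
  cases <- do.call(rbind, lapply(seq_along(ages), function(i)
    make_case(case_id = paste0("c", i), age = ages[i])))
  r <- rate_case(cases, pol)
  expect_true(all(diff(r$triage) >= 0))
  expect_equal(sort(unique(r$triage)), 1:4)
  # boundary: score <= t1 maps to category 1
  expect_equal(r$triage[ages == 50], 1L)
  expect_equal(r$triage[ages == 51], 2L)
})

test_that("raising the bias by the threshold span never lowers the category", {
  co <- small_cohort()
  base <- toy_policy(noise_sd = 0)
  span <- base$thresholds[3] - base$thresholds[1]
  shifted <- toy_policy(bias = span, noise_sd = 0)
  r0 <- rate_case(co, base)
  r1 <- rate_case(co, shifted)
  expect_true(all(r1$triage >= r0$triage))
  expect_gt(mean(r1$triage), mean(r0$triage))
})

test_that("simulate_panel fills every rater-case pair and respects split scoping", {
  co <- small_cohort()
  pols <- default_panel(co, n_raters = 3, seed = 2)
  pols[[3]]$splits <- "validation"
  lab <- simulate_panel(co, pols, seed = 2)
  expect_s3_class(lab, "copd_labels")
  expect_equal(sum(lab$rater_id == "dr1"), nrow(co))
  expect_equal(sum(lab$rater_id == "dr3"), sum(co$split == "validation"))
  expect_true(all(lab$triage %in% 1:4))
  expect_true(all(lab$exacerbation %in% 0:1))
  expect_true(all(lab$triage_conf >= 0 & lab$triage_conf <= 100))
})

test_that("a single noiseless policy reproduces rate_case; identical policies are unanimous", {
  co <- small_cohort()
  pol <- toy_policy(noise_sd = 0)
  lab <- simulate_panel(co, list(pol), seed = 7)
  direct <- rate_case(co, pol, seed = 7)
  expect_equal(lab$triage, direct$triage)
  triplet <- lapply(c("a", "b", "c"), function(id) toy_policy(id = id))
  lab3 <- simulate_panel(co, triplet, seed = 7)
  V <- do.call(cbind, lapply(c("a", "b", "c"), function(id)
    lab3$triage[lab3$rater_id == id]))
  expect_true(all(V[, 1] == V[, 2] & V[, 2] == V[, 3]))
})

test_that("duplicate rater ids are rejected", {
  co <- small_cohort()
  expect_error(simulate_panel(co, list(toy_policy(), toy_policy()), seed = 1),
               "panel misconfigured")
})

test_that("the default panel contains an extreme over-triager", {
  lab <- small_panel_labels()
  d <- label_distributions(lab)$triage
  er <- d$shares[, "4"]
  others_sd <- sd(er)
  expect_gt(er["dr2"], mean(er) + 2 * others_sd)
  # and dr2 is flagged by the 2-SD rule
  expect_true(d$flags["dr2", "4"])
})

test_that("per-rater label distributions sum to one", {
  lab <- small_panel_labels()
  d <- label_distributions(lab)
  expect_equal(unname(rowSums(d$triage$shares)), rep(1, 9))
  expect_equal(unname(rowSums(d$exacerbation$shares)), rep(1, 9))
})
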