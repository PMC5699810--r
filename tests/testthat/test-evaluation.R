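test_that("build_confusion matches a brute-force tally", {
  set.seed(21)
  pred <- sample(1:4, 50, replace = TRUE)
  cons <- sample(1:4, 50, replace = TRUE)
  cm <- build_confusion(pred, cons, K = 4)
  for (i in 1:4) for (j in 1:4)
    expect_equal(cm[i, j], sum(cons == i & pred == j))
  expect_equal(sum(cm), 50)
  expect_error(build_confusion(1:3, 1:4), "alignment error")
  # single case above the diagonal
  cm1 <- build_confusion(4, 3, K = 4)
  expect_equal(cm1[3, 4], 1L)
  expect_equal(sum(cm1), 1)
})

test_that("triage and medical-attention formulas equal the per-case tally oracle", {
  set.seed(22)
  for (trial in 1:300) {
    n <- sample(3:50, 1)
    pred <- sample(1:4, n, replace = TRUE)
    cons <- sample(1:4, n, replace = TRUE)
    m <- triage_metrics(build_confusion(pred, cons, 4))
    o <- oracle_triage_metrics(pred, cons)
    for (k in c("ACC", "TPR", "TNR", "PPV", "NPV", "UTP", "EG1"))
      expect_identical(m[[k]], o[[k]])
    mm <- medical_attention_metrics(pred, cons)
    oo <- oracle_medical_metrics(pred, cons)
    for (k in names(oo)) expect_identical(mm[[k]], oo[[k]])
  }
})

test_that("the worked 101-case matrices reproduce the printed statistics", {
  m <- triage_metrics(gb_style_confusion())
  expect_equal(round(m$ACC, 1), 88.1)   # 89/101
  expect_equal(round(m$UTP, 1), 96.0)   # 1 - 4/101
  expect_equal(m$EG1, 0)
  s <- safety_summary(gb_style_confusion())
  expect_equal(round(s$under_rate, 1), 4.0)          # under-triage < 4% of cases
  expect_equal(round(s$under_share_of_errors, 1), 33.3)
  s2 <- safety_summary(top_dr_style_confusion())
  expect_equal(round(s2$under_rate, 1), 22.8)
  expect_equal(round(s2$under_share_of_errors, 1), 88.5)
})

test_that("missing 11 of 80 attention cases gives the printed sensitivity", {
  cons <- c(rep(3, 80), rep(2, 21))
  pred <- c(rep(3, 69), rep(2, 11), rep(2, 21))
  mm <- medical_attention_metrics(pred, cons)
  expect_equal(mm$TPR_M, 100 * 69 / 80)     # 86.25, printed 86.3
  expect_equal(mm$TP_M + mm$FN_M, 80)
  # an algorithm that never misses the need for attention
  pred2 <- c(rep(4, 80), rep(3, 10), rep(2, 11))
  mm2 <- medical_attention_metrics(pred2, cons)
  expect_equal(mm2$TPR_M, 100)
})

test_that("a rater missing 30% of consensus-ER cases has 70% ER sensitivity", {
  cons <- c(rep(4, 30), rep(2, 20))
  pred <- c(rep(4, 21), rep(3, 9), rep(2, 20))
  expect_equal(triage_metrics(build_confusion(pred, cons, 4))$TPR, 70)
})

test_that("perfect agreement yields a diagonal matrix with perfect metrics", {
  cons <- rep(1:4, each = 5)
  m <- triage_metrics(build_confusion(cons, cons, 4))
  expect_equal(m$ACC, 100); expect_equal(m$UTP, 100); expect_equal(m$EG1, 0)
  expect_equal(m$TPR, 100); expect_equal(m$TNR, 100)
  expect_equal(m$PPV, 100); expect_equal(m$NPV, 100)
  s <- safety_summary(build_confusion(cons, cons, 4))
  expect_equal(s$under_rate, 0); expect_equal(s$over_rate, 0)
  expect_true(is.na(s$under_share_of_errors))
})

test_that("zero-denominator metrics are undefined, not zero", {
  # no consensus-ER cases: TPR undefined
  m <- triage_metrics(build_confusion(c(1, 2, 3), c(1, 2, 3), 4))
  expect_true(is.na(m$TPR))
  expect_false(is.na(m$TNR))
  # all consensus no-attention: TPR_M undefined, TNR_M defined
  mm <- medical_attention_metrics(c(1, 2, 3), c(1, 2, 2))
  expect_true(is.na(mm$TPR_M))
  expect_false(is.na(mm$TNR_M))
})

test_that("under-rate, over-rate and accuracy partition every 4x4 matrix", {
  set.seed(23)
  for (trial in 1:50) {
    n <- sample(5:60, 1)
    pred <- sample(1:4, n, replace = TRUE)
    cons <- sample(1:4, n, replace = TRUE)
    cm <- build_confusion(pred, cons, 4)
    m <- triage_metrics(cm)
    s <- safety_summary(cm)
    expect_equal(s$under_rate + s$over_rate + m$ACC, 100)
    expect_equal(m$UTP, 100 - s$under_rate)
    # medical-attention collapse preserves n
    expect_equal(medical_attention_metrics(pred, cons)$n, n)
  }
})

test_that("outlier raters are flagged at 2 SD; identical raters are not", {
  same <- lapply(1:8, function(i) rep(c(1, 2, 3, 4), 10))
  names(same) <- paste0("r", 1:8)
  lab <- make_labels(same)
  d <- label_distributions(lab)$triage
  expect_equal(unname(d$sd), rep(0, 4))
  expect_false(any(d$flags))
  # one all-ER rater in a 9-member panel of otherwise uniform raters
  votes <- c(same, list(r9 = rep(4, 40)))
  d2 <- label_distributions(make_labels(votes))$triage
  expect_true(d2$flags["r9", "4"])
})
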