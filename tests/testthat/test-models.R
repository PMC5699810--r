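# binary feature matrix with deterministic threshold labels
separable_data <- function(n = 300, p = 8, seed = 31) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(x[, 1] == 1)  # labels determined by f1 alone
  list(x = x, y = y)
}

test_that("logistic regression separates a threshold-labeled construction", {
  d <- separable_data()
  m <- train_and_tune(d$x, d$y, "lr", task = "exacerbation", seed = 1)
  expect_gte(mean(m$cv_results[which.max(rowMeans(m$cv_results)), ]), 99)
  expect_equal(as.numeric(predict(m, d$x)), d$y)
})

test_that("a size-one grid is selected as-is and CV results are deterministic", {
  d <- separable_data()
  g <- data.frame(max_depth = 4, eta = 0.2, nrounds = 40)
  m1 <- train_and_tune(d$x, d$y, "gb", grid = g, seed = 7)
  expect_equal(m1$hyperparameters, g)
  m2 <- train_and_tune(d$x, d$y, "gb", grid = g, seed = 7)
  expect_identical(m1$cv_results, m2$cv_results)
  m3 <- train_and_tune(d$x, d$y, "rf", seed = 7)
  m4 <- train_and_tune(d$x, d$y, "rf", seed = 7)
  expect_identical(m3$cv_results, m4$cv_results)
})

test_that("degenerate labels are rejected", {
  d <- separable_data()
  expect_error(train_and_tune(d$x, rep(1, nrow(d$x)), "lr"), "degenerate labels")
})

test_that("every family trains, predicts in-range and tunes over its grid", {
  co <- small_cohort()
  F <- encode_features(co)
  lab <- small_panel_labels(noise_sd = 0)
  cons <- consensus_labels(lab)
  y <- cons$triage[match(co$case_id, cons$case_id)]
  for (fam in model_families()) {
    g <- default_grid(fam, ncol(F))[1, , drop = FALSE]
    m <- train_and_tune(F, y, fam, grid = g, seed = 2)
    p <- predict(m, F)
    expect_true(all(p %in% 1:4), info = fam)
    expect_equal(length(p), nrow(F), info = fam)
  }
})

test_that("selection ranks records by out-of-sample accuracy", {
  d <- separable_data()
  tr <- seq_len(200); va <- 201:300
  good <- train_and_tune(d$x[tr, ], d$y[tr], "lr", task = "exacerbation", seed = 1)
  # a model trained on permuted labels cannot beat the faithful one
  set.seed(5)
  bad <- train_and_tune(d$x[tr, ], sample(d$y[tr]), "knn",
                        task = "exacerbation",
                        grid = data.frame(k = 3), seed = 1)
  sel <- select_top_models(list(good, bad), d$x[va, ], d$y[va])
  expect_equal(sel$top2[[1]]$family, "lr")
  expect_equal(nrow(sel$table), 2)
  expect_equal(sel$per_family$lr$family, "lr")
  sel1 <- select_top_models(list(good), d$x[va, ], d$y[va])
  expect_equal(sel1$top2[[1]]$family, "lr")
  expect_error(select_top_models(list(), d$x, d$y), "nothing to select")
})

test_that("GB importance is a normalized sample-fraction ranking", {
  d <- separable_data(n = 400)
  m <- train_and_tune(d$x, d$y, "gb",
                      grid = data.frame(max_depth = 2, eta = 0.3, nrounds = 30),
                      seed = 3)
  imp <- importance_gb(m)
  expect_equal(sum(imp$score), 1, tolerance = 1e-9)
  expect_true(all(imp$score >= 0))
  expect_true(all(diff(imp$score) <= 0))        # sorted non-increasing
  expect_equal(imp$feature[1], "f1")            # the label-determining feature
  # a feature the labels are independent of never dominates
  expect_gt(imp$score[1], 10 * max(imp$score[imp$feature != "f1"]))
  expect_error(importance_gb(train_and_tune(d$x, d$y, "lr", seed = 1)),
               "gradient-boosting")
})

test_that("an ensemble using a single feature assigns it importance one", {
  set.seed(33)
  # only f1 varies; the rest are constant and dropped at training
  x <- cbind(f1 = rbinom(200, 1, 0.5), f2 = 1, f3 = 0)
  y <- x[, "f1"]
  m <- train_and_tune(x, y, "gb",
                      grid = data.frame(max_depth = 1, eta = 0.5, nrounds = 10),
                      seed = 1)
  imp <- importance_gb(m)
  expect_equal(imp$score[imp$feature == "f1"], 1)
})

test_that("average coefficient ranks equal hand computation on toy models", {
  # 4 one-vs-rest models with hand-set coefficients, 3 features
  B <- cbind(m1 = c(3, 2, 1), m2 = c(0.5, 2, 1), m3 = c(2, 1, 3),
             m4 = c(-4, 0, 1))
  # per-model ranks by |coef|: m1: 1,2,3; m2: 3,1,2; m3: 2,3,1; m4: 1,3,2
  hand <- c((1 + 3 + 2 + 1) / 4, (2 + 1 + 3 + 3) / 4, (3 + 2 + 1 + 2) / 4)
  expect_equal(unname(copdtriage:::avg_coef_ranks(B)), hand)
  # single model: ranking equals the coefficient-magnitude order
  expect_equal(unname(copdtriage:::avg_coef_ranks(cbind(c(1, -5, 2)))),
               c(3, 1, 2))
})

test_that("LR importance ranks the label-determining feature first", {
  d <- separable_data(n = 400)
  m <- train_and_tune(d$x, d$y, "lr", task = "exacerbation", seed = 2)
  imp <- importance_lr(m)
  expect_equal(imp$feature[1], "f1")
  expect_true(all(diff(imp$avg_rank) >= 0))
  expect_true(all(diff(imp$score) <= 0))
  expect_error(importance_lr(train_and_tune(d$x, d$y, "gb",
    grid = data.frame(max_depth = 2, eta = 0.3, nrounds = 10), seed = 1)),
    "one-vs-rest")
})

test_that("a zero-coefficient feature gets the worst average rank", {
  set.seed(34)
  x <- matrix(rbinom(300 * 3, 1, 0.5), 300, 3,
              dimnames = list(NULL, c("a", "b", "const")))
  x[, "const"] <- x[, "const"] * 0 + rbinom(300, 1, 0.5)  # noise column
  y <- 1 + (x[, "a"] + x[, "b"] >= 1) + (x[, "a"] + x[, "b"] >= 2)
  m <- train_and_tune(x, y, "lr", task = "triage", seed = 2)
  imp <- importance_lr(m)
  expect_equal(imp$feature[nrow(imp)], "const")
})
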