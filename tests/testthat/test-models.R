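test_that("screening recovers perfect association and separated classes", {
  set.seed(40)
  y <- rep(0:1, each = 50)
  X <- data.frame(
    ident = as.numeric(y),
    shifted = rnorm(100) + 2 * y,
    noise = rnorm(100)
  )
  sc <- screen_features(X, y)
  ident <- sc[sc$feature == "ident", ]
  expect_equal(ident$r, 1, tolerance = 1e-9)
  expect_equal(ident$ks, 1)
  sh <- sc[sc$feature == "shifted", ]
  expect_lt(sh$r_p, 0.05)
  expect_lt(sh$ks_p, 0.05)

  expect_error(screen_features(X, rep(1, 100)), "both classes")
})

test_that("recursive elimination recovers the informative feature", {
  set.seed(41)
  n <- 200
  participants <- rep(sprintf("p%02d", 1:20), each = 10)
  y <- rep_len(0:1, n)
  X <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(X) <- paste0("noise", 1:9)
  X$informative <- rnorm(n) + 2 * y

  sel <- rfe_select(X, y, participants, seed = 7)
  expect_true("informative" %in% sel$consensus)
  # consensus is exactly the >= 3-of-5 vote rule
  expect_setequal(sel$consensus,
                  sel$votes$feature[sel$votes$n_selected >= 3])
  under <- sel$votes$feature[sel$votes$n_selected <= 2]
  expect_true(all(!under %in% sel$consensus))

  sel2 <- rfe_select(X, y, participants, seed = 7)
  expect_identical(sel$consensus, sel2$consensus)
  expect_identical(sel$subsets, sel2$subsets)

  expect_error(rfe_select(X, y, rep("p1", n), seed = 1), "participants")
})

test_that("collinearity reduction combines features until all VIFs pass", {
  set.seed(42)
  n <- 150
  ortho <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(ortho) <- paste0("f", 1:4)
  red <- vif_reduce(ortho)
  expect_equal(sort(names(red$features)), sort(names(ortho)))
  expect_equal(nrow(red$combined), 0)
  expect_true(all(red$vif$vif <= 2.5))

  # a duplicated column forces exactly one merge of the pair
  dup <- ortho
  dup$f1_copy <- dup$f1 + rnorm(n, 0, 1e-6)
  red2 <- vif_reduce(dup)
  expect_equal(nrow(red2$combined), 1)
  expect_setequal(red2$combined$constituents[[1]], c("f1", "f1_copy"))
  expect_true(all(red2$vif$vif <= 2.5))

  # three mutually correlated features resolve within two merges
  base <- rnorm(n)
  tri <- data.frame(a = base + rnorm(n, 0, 0.4),
                    b = base + rnorm(n, 0, 0.4),
                    c = base + rnorm(n, 0, 0.4),
                    d = rnorm(n))
  red3 <- vif_reduce(tri)
  expect_lte(nrow(red3$combined), 2)
  expect_true(all(red3$vif$vif <= 2.5))

  cst <- ortho; cst$flat <- 1
  expect_error(vif_reduce(cst), "flat")
})

test_that("cross-validated classifiers behave at the extremes", {
  set.seed(43)
  n <- 200
  y <- rep(0:1, each = n / 2)
  sep <- data.frame(a = y * 10 + rnorm(n, 0, 0.1), b = rnorm(n))
  rep_sep <- train_evaluate(sep, y, seed = 1)
  expect_true(all(rep_sep$metrics$sensitivity == 1))
  expect_true(all(rep_sep$metrics$specificity == 1))
  expect_true(all(rep_sep$metrics$auc == 1))

  # shuffled labels give chance-level discrimination
  set.seed(44)
  n2 <- 300
  X0 <- data.frame(a = rnorm(n2), b = rnorm(n2), c = rnorm(n2))
  y0 <- sample(rep(0:1, each = n2 / 2))
  rep_null <- train_evaluate(X0, y0, seed = 2, models = "lr")
  expect_lt(abs(rep_null$metrics$auc - 0.5), 0.1)

  # fixed seed reproduces everything
  again <- train_evaluate(sep, y, seed = 1)
  expect_equal(rep_sep$metrics, again$metrics)
  expect_equal(rep_sep$predictions, again$predictions)

  expect_error(train_evaluate(sep, rep(0, n), seed = 1), "both classes")
})

test_that("logistic odds ratios exponentiate the coefficients", {
  expect_equal(odds_ratios(0), 1)
  expect_equal(odds_ratios(1.54), exp(1.54), tolerance = 1e-12)
  # the published rounded odds ratio is within coefficient-rounding slack
  expect_lt(abs(odds_ratios(1.54) - 4.64), 0.05)
  expect_equal(odds_ratios(-2.65), 0.0707, tolerance = 1e-3)
  expect_error(odds_ratios(Inf), "finite")
})

test_that("the published reference models reproduce their closed forms", {
  sc <- default_reference_scaling()
  at_mean <- as.data.frame(as.list(setNames(sc$mean, sc$feature)))
  names(at_mean) <- sc$feature

  expect_equal(reference_predict(at_mean, "user_based"),
               1 / (1 + exp(-0.90)), tolerance = 1e-9)
  expect_equal(reference_predict(at_mean, "error_based"),
               1 / (1 + exp(0.22)), tolerance = 1e-9)
  expect_equal(round(reference_predict(at_mean, "user_based"), 4), 0.7109)
  expect_equal(round(reference_predict(at_mean, "error_based"), 4), 0.4452)

  expect_error(reference_predict(at_mean[, -1], "user_based"), "missing feature")
})

test_that("reference probabilities are monotone with the coefficient signs", {
  sc <- default_reference_scaling()
  at_mean <- as.data.frame(as.list(setNames(sc$mean, sc$feature)))
  names(at_mean) <- sc$feature
  for (model in c("user_based", "error_based")) {
    ref <- reference_model(model)
    for (input in names(ref$coefficients)) {
      feats <- ref$bindings[[input]]
      bumped <- at_mean
      for (f in feats) bumped[[f]] <- bumped[[f]] + sc$sd[sc$feature == f]
      p0 <- reference_predict(at_mean, model)
      p1 <- reference_predict(bumped, model)
      if (ref$coefficients[[input]] > 0) expect_gt(p1, p0) else expect_lt(p1, p0)
    }
  }
})
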