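sep_data <- function(n = 100, seed = 3) {
  set.seed(seed)
  X <- cbind(x1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), x2 = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  list(X = X, y = y)
}

test_that("every family separates linearly separable data", {
  d <- sep_data()
  for (fam in fedaki:::MODEL_FAMILIES) {
    m <- train_model(model_spec(fam, seed = 1), d$X, d$y)
    expect_equal(auroc(predict_model(m, d$X), d$y), 1.0,
                 tolerance = 1e-9, label = fam)
  }
})

test_that("training is deterministic under a fixed seed", {
  d <- sep_data(200, seed = 4)
  for (fam in c("gradient_boosting", "random_forest", "neural_network")) {
    m1 <- train_model(model_spec(fam, seed = 7), d$X, d$y)
    m2 <- train_model(model_spec(fam, seed = 7), d$X, d$y)
    expect_identical(predict_model(m1, d$X), predict_model(m2, d$X),
                     label = fam)
  }
})

test_that("single-class labels and unimputed inputs are rejected", {
  d <- sep_data()
  expect_error(train_model(model_spec("logistic_regression"), d$X,
                           rep(1L, nrow(d$X))), "single class")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(train_model(model_spec("logistic_regression"), Xna, d$y),
               "imputed")
})

test_that("permuted labels give chance-level cross-validated AUROC", {
  set.seed(11)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(rep(0:1, each = n / 2))
  cv <- kfold_cv(model_spec("logistic_regression", seed = 1), X, y = y,
                 k = 5, seed = 2)
  expect_lt(abs(cv$auroc - 0.5), 0.08)
})

test_that("folds are a stratified, disjoint, exhaustive partition", {
  set.seed(5)
  y <- rbinom(103, 1, 0.3)
  fold <- fedaki:::stratified_folds(y, 5, seed = 1)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), 103L)
  prev <- tapply(y, fold, sum)
  expect_lte(diff(range(prev)), 1)
  counts <- table(fold)
  expect_lte(diff(range(counts)), 2)
  expect_error(fedaki:::stratified_folds(rbinom(3, 1, .5), 5, 1), "exceeds")
  # n = 10, k = 5 -> folds of size 2
  f10 <- fedaki:::stratified_folds(rep(0:1, 5), 5, 1)
  expect_true(all(table(f10) == 2))
})

test_that("LASSO keeps duplicated signal and can return empty on noise", {
  set.seed(21)
  n <- 1200
  x_inf <- rnorm(n)
  X <- cbind(a = x_inf, b = x_inf, c = rnorm(n), d = rnorm(n), e = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x_inf))
  sel <- lasso_select(X, y, seed = 1)
  expect_true(any(c("a", "b") %in% sel))
  # null signal: nothing or nearly nothing survives the 1-SE penalty
  y0 <- rbinom(n, 1, 0.5)
  sel0 <- tryCatch(lasso_select(X, y0, seed = 1), error = function(e) character(0))
  expect_lte(length(sel0), 1L)
})

test_that("Platt scaling recovers the identity on calibrated scores", {
  set.seed(31)
  n <- 10000
  s <- rnorm(n, 0, 1.5)              # true logits
  y <- rbinom(n, 1, plogis(s))
  cal <- platt_fit(s, y)
  # p = plogis(-(a*s + b)): on the logit scale the slope is -a
  expect_lt(abs(-cal$a - 1), 0.1)
  expect_lt(abs(cal$b), 0.1)
  expect_lt(cal$a, 0)                # strictly increasing map
})

test_that("Platt scaling is rank-preserving and guards degenerate input", {
  set.seed(32)
  s <- runif(300)
  y <- rbinom(300, 1, s)
  cal <- platt_fit(s, y)
  expect_equal(auroc(platt_apply(cal, s), y), auroc(s, y), tolerance = 1e-12)
  p <- platt_apply(cal, s)
  expect_true(all(p > 0 & p < 1))
  expect_error(platt_fit(s, rep(1L, 300)), "both classes")
  expect_error(platt_fit(rep(0.5, 50), rbinom(50, 1, .5)), "degenerate")
})

test_that("model artifacts round-trip through save/load", {
  d <- sep_data(80, seed = 6)
  for (fam in c("neural_network", "logistic_regression",
                "gradient_boosting")) {
    m <- train_model(model_spec(fam, seed = 2), d$X, d$y,
                     registry_hash = "abc12345")
    m$calibrator <- platt_fit(predict_model(m, d$X) +
                                rnorm(80, 0, 1e-6), d$y)
    dir <- withr::local_tempdir()
    save_model(m, dir)
    m2 <- load_model(dir)
    expect_equal(predict_model(m2, d$X), predict_model(m, d$X),
                 tolerance = 1e-10, label = fam)
    expect_equal(m2$registry_hash, "abc12345")
    expect_equal(m2$calibrator$a, m$calibrator$a, tolerance = 1e-12)
  }
})
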