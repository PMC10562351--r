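test_that("AUROC equals brute-force pair counting, ties included", {
  expect_equal(auroc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(.7, .4, .6, .3), c(1, 0, 1, 0)), 1.0)
  expect_error(auroc(1:4, rep(1, 4)), "single class")
  set.seed(41)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("threshold metrics match hand-computed confusion tables", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(.9, .8, .7, .6, .4, .3, .3, .2, .2, .1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  # tau = 0: everything called positive
  m0 <- threshold_metrics(scores, labels, 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
  expect_equal(m0$accuracy, mean(labels))
  # perfect classifier
  mp <- threshold_metrics(labels, labels, 0.5)
  expect_equal(unlist(mp[c("sensitivity", "specificity", "precision",
                           "accuracy")]), c(sensitivity = 1, specificity = 1,
                                            precision = 1, accuracy = 1))
})

test_that("calibration bins sit on the diagonal for exact probabilities", {
  probs <- rep(c(0.15, 0.45, 0.85), each = 200)
  labels <- unlist(lapply(c(0.15, 0.45, 0.85), function(p) {
    rep(c(1, 0), round(c(p, 1 - p) * 200))
  }))
  cc <- calibration_curve(probs, labels)
  expect_equal(cc$mean_predicted, cc$observed_fraction, tolerance = 1e-12)
  expect_equal(sum(cc$count), 600L)
  # all probs 1, all labels 0 -> single bin (1, 0, n)
  cc1 <- calibration_curve(rep(1, 40), rep(0, 40))
  expect_equal(nrow(cc1), 1L)
  expect_equal(cc1$mean_predicted, 1)
  expect_equal(cc1$observed_fraction, 0)
  expect_equal(cc1$count, 40L)
})

test_that("net benefit matches the closed form and its references", {
  # TP=3, FP=1, n=10 at p_t=0.2 -> 0.3 - 0.1*0.25 = 0.275
  probs <- c(.9, .9, .9, .9, .1, .1, .1, .1, .1, .1)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  nb <- net_benefit(probs, labels, thresholds = 0.2)
  expect_equal(nb$net_benefit, 0.275)
  expect_equal(nb$treat_all, 0.5 - 0.5 * 0.25)
  expect_equal(nb$treat_none, 0)
  # perfect classifier: NB = prevalence at every threshold
  y <- rep(c(1, 0), c(30, 70))
  nbp <- net_benefit(y, y)
  expect_true(all(abs(nbp$net_benefit - 0.3) < 1e-12))
  # treat-all tends to prevalence as p_t -> 0
  nb0 <- net_benefit(y, y, thresholds = 1e-6)
  expect_equal(nb0$treat_all, 0.3, tolerance = 1e-5)
  # no classifier beats prevalence
  set.seed(2)
  pr <- runif(500); yy <- rbinom(500, 1, 0.3)
  expect_true(all(net_benefit(pr, yy)$net_benefit <= mean(yy) + 1e-12))
})

test_that("permutation importance ranks the true signal first", {
  set.seed(51)
  n <- 1500
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("big", "mid", "small", "noise", "const")))
  X[, "const"] <- 1
  y <- rbinom(n, 1, plogis(2 * X[, "big"] + 0.8 * X[, "mid"] +
                             0.4 * X[, "small"]))
  m <- train_model(model_spec("logistic_regression", seed = 1), X, y)
  imp <- perm_importance(m, X, y, n_repeats = 5, seed = 3)
  expect_equal(imp$feature[1], "big")
  expect_equal(imp[feature == "const", mean_drop], 0)
  expect_lt(abs(imp[feature == "noise", mean_drop]), 0.01)
  # reproducible under seed
  imp2 <- perm_importance(m, X, y, n_repeats = 5, seed = 3)
  expect_identical(as.data.frame(imp), as.data.frame(imp2))
})

test_that("paired bootstrap AUROC comparison behaves at the edges", {
  set.seed(61)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  s <- runif(n)
  same <- compare_auroc(s, s, y, n_boot = 200, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # perfect vs random separates decisively
  sp <- as.numeric(y)
  cmp <- compare_auroc(s, sp, y, n_boot = 500, seed = 2)
  expect_gt(cmp$ci[1], 0)
  expect_lt(cmp$p, 0.01)
  # antisymmetry
  rev <- compare_auroc(sp, s, y, n_boot = 500, seed = 3)
  expect_equal(rev$delta, -cmp$delta, tolerance = 1e-12)
})

test_that("cohort summary reproduces textbook test statistics", {
  # identical groups: both tests are non-significant with p ~ 1
  d <- data.frame(a = rep(c(1, 2, 3), 20), g = gl(2, 30))
  cs <- cohort_summary(d["a"], d$g == 1)
  expect_gte(cs$p, 0.99)
  expect_false(cs$significant)
  # 2x2 table [[30,70],[70,30]] -> Pearson chi-square = 32
  x <- c(rep("yes", 30), rep("no", 70), rep("yes", 70), rep("no", 30))
  grp <- rep(c(TRUE, FALSE), each = 100)
  cs2 <- cohort_summary(data.frame(v = x), grp)
  expect_lt(cs2$p, 0.001)
  tab <- table(grp, x)
  expect_equal(unname(suppressWarnings(
    chisq.test(tab, correct = FALSE)$statistic)), 32, tolerance = 1e-12)
  # a 2-SD shift at n = 200 per group is decisively significant
  set.seed(71)
  v <- c(rnorm(200, 0, 1), rnorm(200, 2, 1))
  cs3 <- cohort_summary(data.frame(v = v), rep(c(TRUE, FALSE), each = 200))
  expect_lt(cs3$p, 0.001)
})

test_that("Mann-Whitney p matches an exhaustive rank computation (n <= 50)", {
  set.seed(72)
  for (i in 1:10) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    x <- sample(1:8, n1, replace = TRUE)  # heavy ties
    y <- sample(3:10, n2, replace = TRUE)
    # brute-force U and tie-corrected normal approximation
    u <- 0
    for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
    nn <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p_oracle <- 2 * pnorm(-abs(z))
    p_pkg <- cohort_summary(data.frame(v = c(x, y)),
                            rep(c(TRUE, FALSE), c(n1, n2)))$p
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  }
})

test_that("eval_report aggregates all components coherently", {
  set.seed(81)
  y <- rbinom(400, 1, 0.3)
  p <- plogis(rnorm(400) + 2 * y)
  r <- eval_report(p, y, threshold = 0.5)
  expect_gte(r$auroc, 0.5)
  expect_equal(sum(r$calibration$count), 400L)
  expect_equal(r$n, 400L)
  expect_equal(r$n_pos, sum(y))
  expect_output(print(r), "AUROC")
})
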