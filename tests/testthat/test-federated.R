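test_that("weight initialization is seeded and shape-correct", {
  spec <- mlp_spec(21)
  w1 <- init_weights(spec, 5)
  w2 <- init_weights(spec, 5)
  w3 <- init_weights(spec, 6)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  expect_equal(dim(w1$W1), c(64, 21))
  expect_equal(dim(w1$W2), c(32, 64))
  expect_equal(dim(w1$W3), c(1, 32))
  expect_equal(length(w1$b3), 1L)
})

test_that("fedavg is the weighted element-wise mean", {
  spec <- mlp_spec(4, hidden = 3)
  w <- init_weights(spec, 1)
  # identical inputs -> identity
  expect_equal(fedavg(list(w, w, w), c(2, 5, 1)), w)
  # symmetric inputs cancel
  wneg <- lapply(w, function(x) -x)
  z <- fedavg(list(w, wneg), c(3, 3))
  expect_true(all(vapply(z, function(x) all(abs(x) < 1e-15), logical(1))))
  # hand-computed weighted mean: scalars 0 and 4 with n = (1, 3) -> 3
  a <- list(W1 = matrix(0, 1, 1), b1 = 0)
  b <- list(W1 = matrix(4, 1, 1), b1 = 4)
  expect_equal(fedavg(list(a, b), c(1, 3))$W1[1, 1], 3)
  # permutation invariance
  expect_equal(fedavg(list(b, a), c(3, 1))$W1[1, 1], 3)
  # shape mismatch is an error
  expect_error(fedavg(list(w, init_weights(mlp_spec(5, hidden = 3), 1)),
                      c(1, 1)), "shapes")
})

test_that("analytic MLP gradients match central finite differences", {
  set.seed(91)
  X <- matrix(rnorm(28), 7, 4)
  y <- rbinom(7, 1, 0.5)
  w <- init_weights(mlp_spec(4, hidden = c(5, 3)), 2)
  g <- fedaki:::nn_grad(w, X, y)
  eps <- 1e-6
  for (nm in names(w)) {
    for (i in seq_along(w[[nm]])[seq_len(min(6, length(w[[nm]])))]) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (fedaki:::nn_loss(wp, X, y) - fedaki:::nn_loss(wm, X, y)) / (2 * eps)
      denom <- max(abs(fd), abs(g[[nm]][i]), 1e-8)
      expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-5)
    }
  }
})

test_that("local_train honors the epoch/batch contract", {
  set.seed(92)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rbinom(100, 1, 0.5)
  w <- init_weights(mlp_spec(4, hidden = 3), 1)
  # E = 0 is the identity
  expect_identical(local_train(w, X, y, epochs = 0)$weights, w)
  # ceil(n/B) updates per epoch: n=100, B=32 -> 4 batches
  res <- local_train(w, X, y, epochs = 1, batch_size = 32)
  expect_equal(res$state$t, 4L)
  expect_error(local_train(w, X[0, , drop = FALSE], numeric(0)), "empty")
  # two epochs of training do not increase the training loss (descent)
  set.seed(93)
  Xs <- matrix(rnorm(600 * 4), 600, 4)
  ys <- rbinom(600, 1, plogis(Xs %*% c(1.5, -1, .5, 0)))
  w0 <- init_weights(mlp_spec(4, hidden = c(8, 4)), 3)
  res2 <- local_train(w0, Xs, ys, epochs = 2, batch_size = 32,
                      learning_rate = 1e-2, seed = 4)
  expect_lt(fedaki:::nn_loss(res2$weights, Xs, ys),
            fedaki:::nn_loss(w0, Xs, ys))
})

test_that("a K=1 federated run equals plain training bit-near", {
  ft <- make_feature_table(400, d = 6, seed = 7)
  cfg <- fl_config(rounds = 4, local_epochs = 2, persist_state = TRUE,
                   seed = 11, hidden = c(8, 4))
  flr <- run_fl(list(solo = ft), cfg, registry = synth_registry(6))
  plain <- nn_fit(flr$sites$solo$X_train, flr$sites$solo$y_train,
                  hidden = c(8, 4), epochs = 8, batch_size = 32,
                  learning_rate = 1e-2, seed = 11, standardize = FALSE,
                  validation_fraction = 0)
  final <- flr$round_weights[[4]]
  for (nm in names(final)) {
    expect_lt(max(abs(final[[nm]] - plain[[nm]])), 1e-10)
  }
})

test_that("identical sites leave the aggregate equal to each local update", {
  ft <- make_feature_table(300, d = 5, seed = 8)
  cfg <- fl_config(rounds = 3, local_epochs = 1, seed = 3, hidden = c(6, 3))
  fl2 <- run_fl(list(a = copy(ft), b = copy(ft)), cfg, registry = synth_registry(5))
  fl1 <- run_fl(list(a = copy(ft)), cfg, registry = synth_registry(5))
  for (r in 1:3) {
    for (nm in names(fl1$round_weights[[r]])) {
      expect_equal(fl2$round_weights[[r]][[nm]],
                   fl1$round_weights[[r]][[nm]], tolerance = 1e-12)
    }
  }
})

test_that("the selected round maximizes mean validation AUROC", {
  ft1 <- make_feature_table(350, d = 5, seed = 9, site_id = "A")
  ft2 <- make_feature_table(300, d = 5, seed = 10, site_id = "B", shift = 0.3)
  cfg <- fl_config(rounds = 5, local_epochs = 1, seed = 2, hidden = c(6, 3))
  flr <- run_fl(list(A = ft1, B = ft2), cfg, registry = synth_registry(5))
  mv <- flr$mean_val_by_round
  expect_equal(flr$best_round, mv$round[which.max(mv$mean_auroc)])
  expect_true(all(mv$mean_auroc[flr$best_round] >= mv$mean_auroc))
  # full-run determinism
  flr2 <- run_fl(list(A = ft1, B = ft2), cfg, registry = synth_registry(5))
  expect_equal(flr$best_round, flr2$best_round)
  expect_identical(flr$best_weights, flr2$best_weights)
  expect_identical(as.data.frame(flr$history), as.data.frame(flr2$history))
})

test_that("only weight sets and scalar scores cross the site boundary", {
  ft <- make_feature_table(250, d = 4, seed = 12)
  cfg <- fl_config(rounds = 1, local_epochs = 1, seed = 1, hidden = c(4))
  flr <- run_fl(list(a = ft), cfg, registry = synth_registry(4))
  expect_setequal(flr$update_fields,
                  c("weights", "state", "n", "local_val_auroc"))
  # the exchanged payloads are numeric arrays and scalars only
  expect_true(all(vapply(flr$best_weights, is.numeric, logical(1))))
})

test_that("single-class sites are rejected before round 1", {
  ft <- make_feature_table(120, d = 4, seed = 13)
  ft[, label := 0L]
  expect_error(run_fl(list(a = ft), fl_config(rounds = 1, seed = 1),
                      registry = synth_registry(4)),
               "single class")
})

test_that("forcing the FL weights into the exported model zeroes every delta", {
  ft1 <- make_feature_table(300, d = 5, seed = 14, site_id = "A")
  ft2 <- make_feature_table(300, d = 5, seed = 15, site_id = "B")
  cfg <- fl_config(rounds = 2, local_epochs = 1, seed = 4, hidden = c(6, 3))
  flr <- run_fl(list(A = ft1, B = ft2), cfg, registry = synth_registry(5))
  forced <- structure(list(
    spec = model_spec("neural_network", seed = 1), fit = flr$best_weights,
    feature_names = paste0("f", 1:5), registry_hash = flr$registry_hash,
    calibrator = NULL, imputer = NULL), class = "aki_model")
  cmp <- evaluate_final(flr, forced, n_boot = 50, seed = 1)
  expect_true(all(abs(cmp$delta) < 1e-12))
})
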