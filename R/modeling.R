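# Classifier training, cross-validation, LASSO selection, Platt calibration.
#
# Gradient boosting and random forests are consumed from xgboost and ranger;
# logistic regression uses the base glm machinery; the neural network is the
# in-package MLP shared with the federated module so local and aggregated
# models are directly comparable.

MODEL_FAMILIES <- c("gradient_boosting", "neural_network", "random_forest",
                    "logistic_regression")

default_hyperparameters <- function(family) {
  switch(family,
    gradient_boosting = list(nrounds = 300L, max_depth = 4L, eta = 0.1),
    random_forest = list(num.trees = 500L),
    logistic_regression = list(),
    neural_network = list(hidden = c(64, 32), epochs = 40L,
                          batch_size = 32L, learning_rate = 1e-2))
}

#' Model specification
#'
#' @param family one of `"gradient_boosting"`, `"neural_network"`,
#'   `"random_forest"`, `"logistic_regression"`.
#' @param hyperparameters named list overriding the recorded defaults.
#' @param seed integer seed; training is deterministic given
#'   (spec, seed, data).
#' @return a `model_spec`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, hyperparameters = list(),
                       seed = 1L) {
  family <- match.arg(family)
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)), class = "model_spec")
}

#' Train one classifier
#'
#' @param spec a [model_spec()].
#' @param X imputed, finite numeric matrix (one column per registry feature).
#' @param y 0/1 labels; both classes must be present.
#' @param registry_hash optional registry fingerprint recorded in the
#'   artifact; prediction refuses mismatching features.
#' @return an `aki_model` (spec, fitted object, feature names, optional
#'   calibrator and imputer attached by the CV / pipeline layers).
#' @export
train_model <- function(spec, X, y, registry_hash = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stopf("X must be imputed and finite")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                     eta = hp$eta, nthread = 1L, seed = spec$seed)
      xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    random_forest = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0L, 1L))
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     probability = TRUE, num.trees = hp$num.trees,
                     seed = spec$seed, num.threads = 1L)
    },
    logistic_regression = {
      fit <- suppressWarnings(
        glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(coefficients = cf)
    },
    neural_network = nn_fit(X, y, hidden = hp$hidden, epochs = hp$epochs,
                            batch_size = hp$batch_size,
                            learning_rate = hp$learning_rate,
                            seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit, feature_names = colnames(X),
                 registry_hash = registry_hash, calibrator = NULL,
                 imputer = NULL),
            class = "aki_model")
}

#' Predict event scores/probabilities
#'
#' @param model an `aki_model`.
#' @param X numeric matrix with the model's feature columns.
#' @param calibrated apply the attached Platt calibrator (if any).
#' @return numeric vector in `[0, 1]`.
#' @export
predict_model <- function(model, X, calibrated = FALSE) {
  X <- as.matrix(X)
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$feature_names)) {
      if (!all(model$feature_names %in% colnames(X))) {
        stopf("feature columns do not match the model's registry")
      }
      X <- X[, model$feature_names, drop = FALSE]
    }
  }
  s <- switch(model$spec$family,
    gradient_boosting = predict(model$fit, xgboost::xgb.DMatrix(X)),
    random_forest = predict(model$fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions[, "1"],
    logistic_regression = as.numeric(
      plogis(cbind(1, X) %*% model$fit$coefficients)),
    neural_network = nn_predict(model$fit, X)
  )
  s <- as.numeric(s)
  if (calibrated && !is.null(model$calibrator)) {
    s <- platt_apply(model$calibrator, s)
  }
  s
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so fold prevalences differ by at most one subject.
stratified_folds <- function(y, k, seed) {
  if (k > length(y)) stopf("k (%d) exceeds n (%d)", k, length(y))
  fold <- integer(length(y))
  with_seed(derive_seed(seed, 401L), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation with in-fold imputation
#'
#' Folds are a disjoint, exhaustive, label-stratified partition. When raw
#' (unimputed) features are supplied, the mean imputer is refit inside each
#' training fold so no test-fold information leaks into imputation. Platt
#' scaling is fitted on the pooled out-of-fold scores.
#'
#' @param spec a [model_spec()].
#' @param features an `aki_features` table (possibly with `NA`s) or a
#'   numeric matrix.
#' @param y labels; defaults to `features$label`.
#' @param registry registry used for imputer refits (ignored for matrices).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param threshold operating threshold for fold metrics.
#' @return list: `fold_reports` (per-fold [eval_report()]s), `oof`
#'   (data.table of index, fold, score, label), `calibrator`, `auroc`
#'   (pooled out-of-fold AUROC), `fold` (assignments).
#' @export
kfold_cv <- function(spec, features, y = NULL, registry = NULL, k = 5L,
                     seed = 1L, threshold = 0.5) {
  is_feat <- inherits(features, "aki_features") ||
    (is.data.frame(features) && "label" %in% names(features))
  if (is.null(y)) {
    if (!is_feat) stopf("`y` required when `features` is a matrix")
    y <- features$label
  }
  y <- as.integer(y)
  fold <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (is_feat) {
      ftr <- features[tr]
      fte <- features[te]
      imp <- fit_imputer(ftr, registry %||% feature_registry())
      Xtr <- feature_matrix(apply_imputer(imp, ftr))
      Xte <- feature_matrix(apply_imputer(imp, fte))
    } else {
      Xtr <- as.matrix(features)[tr, , drop = FALSE]
      Xte <- as.matrix(features)[te, , drop = FALSE]
    }
    m <- train_model(spec, Xtr, y[tr])
    s <- predict_model(m, Xte)
    scores[te] <- s
    reports[[f]] <- eval_report(s, y[te], threshold = threshold)
  }
  cal <- platt_fit(scores, y)
  list(fold_reports = reports,
       oof = data.table(index = seq_along(y), fold = fold, score = scores,
                        label = y),
       calibrator = cal, auroc = auroc(scores, y), fold = fold)
}

#' LASSO-based parsimonious feature selection
#'
#' L1-penalized logistic regression over a logarithmic penalty path
#' (internally standardized), with the penalty chosen by cross-validated
#' AUROC under the one-standard-error rule; features with nonzero
#' coefficients at that penalty are returned in registry (column) order.
#'
#' @param X numeric matrix (imputed), columns in registry order.
#' @param y 0/1 labels.
#' @param k CV folds for the penalty choice.
#' @param seed fold seed.
#' @return character vector of selected feature names.
#' @export
lasso_select <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  foldid <- stratified_folds(y, k, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "auc",
                          foldid = foldid, standardize = TRUE, alpha = 1)
  if (max(cv$nzero) == 0L) {
    stopf("LASSO selection failed: all coefficients zero at every penalty")
  }
  cf <- as.matrix(coef(cv, s = "lambda.1se"))[-1L, 1L]
  colnames(X)[which(cf != 0)]
}

#' Fit a Platt calibrator on held-out scores
#'
#' Maximum-likelihood sigmoid `p = 1 / (1 + exp(a*s + b))` with the standard
#' `(N+1)/(N+2)` target smoothing, by Newton iteration with step halving.
#' `a < 0` after the fit, so the map is strictly increasing in the score and
#' leaves every rank statistic (AUROC included) unchanged.
#'
#' @param scores classifier scores on data not used for training.
#' @param labels 0/1 labels (both classes required).
#' @return a `platt_calibrator` with elements `a`, `b`.
#' @export
platt_fit <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("Platt fit needs both classes")
  if (max(scores) - min(scores) < 1e-12) {
    stopf("Platt fit degenerate: all scores equal")
  }
  t_hi <- (n1 + 1) / (n1 + 2)
  t_lo <- 1 / (n0 + 2)
  tt <- ifelse(labels == 1L, t_hi, t_lo)
  obj <- function(a, b) {
    u <- a * scores + b
    # -sum(t*log(p) + (1-t)*log(1-p)) with p = sigmoid(-u), stable form:
    # log(1 + e^u) - (1 - t) * u summed over observations
    sum(pmax(u, 0) + log1p(exp(-abs(u))) - (1 - tt) * u)
  }
  a <- 0; b <- log((n0 + 1) / (n1 + 1))
  f_old <- obj(a, b)
  for (it in 1:200) {
    p <- plogis(-(a * scores + b))
    d <- tt - p               # dF/du
    g <- c(sum(d * scores), sum(d))
    wgt <- pmax(p * (1 - p), 1e-12)
    H <- matrix(c(sum(wgt * scores^2), sum(wgt * scores),
                  sum(wgt * scores), sum(wgt)), 2L, 2L)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    lr <- 1
    repeat {
      a2 <- a - lr * step[1]; b2 <- b - lr * step[2]
      f_new <- obj(a2, b2)
      if (f_new <= f_old + 1e-12 || lr < 1e-10) break
      lr <- lr / 2
    }
    moved <- abs(a2 - a) + abs(b2 - b)
    a <- a2; b <- b2; f_old <- f_new
    if (moved < 1e-10) break
  }
  if (a >= 0) stopf("Platt fit produced a non-monotone map (a >= 0)")
  structure(list(a = a, b = b), class = "platt_calibrator")
}

#' Apply a Platt calibrator
#' @param calibrator a `platt_calibrator`.
#' @param scores numeric scores.
#' @return calibrated probabilities in (0, 1).
#' @export
platt_apply <- function(calibrator, scores) {
  plogis(-(calibrator$a * scores + calibrator$b))
}

#' Save / load a model artifact
#'
#' A directory with `spec.json` (family, hyperparameters, seed, registry
#' hash, feature names), `calibrator.json` and `imputer.json` when attached,
#' and the fitted parameters (`weights.json` flat arrays for the linear and
#' neural families; a binary blob for the tree ensembles).
#'
#' @param model an `aki_model`.
#' @param dir target directory.
#' @return `dir` invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(family = model$spec$family,
               hyperparameters = model$spec$hyperparameters,
               seed = model$spec$seed,
               registry_hash = model$registry_hash,
               feature_names = model$feature_names)
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(model$calibrator)) {
    jsonlite::write_json(unclass(model$calibrator),
                         file.path(dir, "calibrator.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(model$imputer)) {
    jsonlite::write_json(list(means = as.list(model$imputer$means),
                              registry_hash = model$imputer$registry_hash),
                         file.path(dir, "imputer.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  fam <- model$spec$family
  if (fam == "neural_network") {
    w <- model$fit
    payload <- list(weights = w[names(w)],
                    scaler = attr(w, "scaler"),
                    widths = attr(w, "spec")$widths)
    jsonlite::write_json(payload, file.path(dir, "weights.json"), digits = NA)
  } else if (fam == "logistic_regression") {
    jsonlite::write_json(as.list(model$fit$coefficients),
                         file.path(dir, "weights.json"), digits = NA)
  } else {
    saveRDS(model$fit, file.path(dir, "fit.rds"))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- model_spec(meta$family, as.list(meta$hyperparameters), meta$seed)
  fit <- if (meta$family == "neural_network") {
    payload <- jsonlite::read_json(file.path(dir, "weights.json"),
                                   simplifyVector = TRUE)
    w <- lapply(payload$weights,
                function(x) if (is.matrix(x)) x else as.numeric(x))
    if (!is.null(payload$scaler)) {
      attr(w, "scaler") <- list(mean = unlist(payload$scaler$mean),
                                sd = unlist(payload$scaler$sd))
    }
    attr(w, "spec") <- structure(list(widths = as.integer(payload$widths)),
                                 class = "mlp_spec")
    w
  } else if (meta$family == "logistic_regression") {
    cf <- jsonlite::read_json(file.path(dir, "weights.json"),
                              simplifyVector = TRUE)
    list(coefficients = unlist(cf))
  } else {
    readRDS(file.path(dir, "fit.rds"))
  }
  model <- structure(list(spec = spec, fit = fit,
                          feature_names = meta$feature_names,
                          registry_hash = meta$registry_hash,
                          calibrator = NULL, imputer = NULL),
                     class = "aki_model")
  cal_path <- file.path(dir, "calibrator.json")
  if (file.exists(cal_path)) {
    cal <- jsonlite::read_json(cal_path, simplifyVector = TRUE)
    model$calibrator <- structure(list(a = cal$a, b = cal$b),
                                  class = "platt_calibrator")
  }
  imp_path <- file.path(dir, "imputer.json")
  if (file.exists(imp_path)) {
    imp <- jsonlite::read_json(imp_path, simplifyVector = TRUE)
    model$imputer <- structure(list(means = unlist(imp$means),
                                    registry_hash = imp$registry_hash),
                               class = "aki_imputer")
  }
  model
}
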