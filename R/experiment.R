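# End-to-end study orchestration: single-site development, external
# validation of the frozen model, and the federated study, on the default
# five-site heterogeneous benchmark.

#' Experiment configuration
#'
#' @param sites list of [site_config()]s (site 1 is the model-development
#'   origin).
#' @param true_model shared [true_risk_model()].
#' @param grouping severity grouping defining the positive label.
#' @param registry registry name for the federated/parsimonious pipeline.
#' @param window_anchor see [case_window()].
#' @param fl an [fl_config()].
#' @param threshold operating threshold for reports.
#' @param seed master seed for generation and window draws.
#' @return an `experiment_config`; its `config_hash` fingerprints all
#'   settings and is embedded in every output.
#' @export
experiment_config <- function(sites, true_model = default_true_model(),
                              grouping = "all_stage",
                              registry = "parsimonious_21",
                              window_anchor = "end_24h_before",
                              fl = fl_config(), threshold = 0.5, seed = 1L) {
  cfg <- list(sites = sites, true_model = true_model, grouping = grouping,
              registry = registry, window_anchor = window_anchor, fl = fl,
              threshold = threshold, seed = as.integer(seed))
  cfg$config_hash <- fnv1a_hash(jsonlite::toJSON(
    cfg[c("grouping", "registry", "window_anchor", "threshold", "seed")],
    auto_unbox = TRUE))
  structure(cfg, class = "experiment_config")
}

#' Default five-site heterogeneous benchmark
#'
#' Five sites of `n_per_site` stays with AKI prevalences 0.30, 0.28, 0.33,
#' 0.31 and 0.62 (one high-prevalence site), site-specific covariate shifts
#' on informative latents, a 25% temporal era split, and a shared true
#' coefficient vector.
#'
#' @param n_per_site stays per site.
#' @param seed master seed.
#' @param fl an [fl_config()] (its seed is aligned with `seed`).
#' @return an `experiment_config`.
#' @export
default_benchmark_config <- function(n_per_site = 4000L, seed = 1L,
                                     fl = fl_config(seed = seed)) {
  shifts <- list(
    list(),
    list(location = c(pulse = 6, sysbp = -8, age = 4),
         scale = c(bun = 1.2)),
    list(location = c(urine_rate = -0.1, bun = 4, lactate = 5),
         scale = c(pulse = 1.15)),
    list(location = c(age = -6, sysbp = 10, hemoglobin = -0.8),
         scale = c(urine_rate = 1.1)),
    list(location = c(age = 8, urine_rate = -0.15, bun = 6, pulse = 8),
         scale = c(sysbp = 1.2))
  )
  prev <- c(0.30, 0.28, 0.33, 0.31, 0.62)
  sites <- lapply(1:5, function(k) {
    site_config(sprintf("S%d", k), n_per_site, prev[k],
                covariate_shift = shifts[[k]], era_split = 0.25,
                seed = k)
  })
  experiment_config(sites, fl = fl, seed = seed)
}

#' Generate, exclude, label and extract one site's feature table
#'
#' The single-site pipeline stage shared by all experiment drivers:
#' generation (unless a dataset is supplied), exclusion rules, KDIGO
#' labeling, window selection, feature extraction.
#'
#' @param config an `experiment_config`.
#' @param site_index which site of `config$sites` to run.
#' @param registry a [feature_registry()].
#' @param dataset optional pre-generated `aki_site_data`.
#' @return list: `features` (an `aki_features` table), `labels`, `tally`,
#'   `dataset` (the included cohort).
#' @export
site_pipeline <- function(config, site_index = 1L,
                          registry = feature_registry(config$registry),
                          dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- generate_site(config$sites[[site_index]], config$true_model,
                             config$seed)
  }
  ex <- apply_exclusions(dataset)
  labels <- label_stays(ex$included)
  w <- build_windows(ex$included, labels,
                     seed = derive_seed(config$seed, 600L + site_index),
                     window_anchor = config$window_anchor)
  feats <- extract_features(ex$included, w, registry, labels,
                            grouping = config$grouping)
  list(features = feats, labels = labels, tally = ex$tally,
       dataset = ex$included)
}

#' Single-site model development (origin site)
#'
#' On site 1: generate, exclude, label, extract both registries, run
#' stratified 5-fold cross-validation for every requested classifier family,
#' Platt-calibrate on the out-of-fold scores, and report on the temporal
#' era. Optionally adds a permutation-importance report for the
#' neural-network parsimonious model.
#'
#' @param config an `experiment_config`.
#' @param families classifier families to run.
#' @param registries registry names to run.
#' @param k cross-validation folds.
#' @param importance compute permutation importance (NN, first registry).
#' @return list of per-(family, registry) results: `cv` (from [kfold_cv()]),
#'   `model` (refit on the full derivation era, imputer + calibrator
#'   attached), `temporal_report`; plus `tally`, `config_hash`, and
#'   optionally `importance`.
#' @export
run_single_site <- function(config, families = MODEL_FAMILIES,
                            registries = c("full_60", "parsimonious_21"),
                            k = 5L, importance = FALSE) {
  out <- list(tally = NULL, reports = list(),
              config_hash = config$config_hash)
  for (reg_name in registries) {
    registry <- feature_registry(reg_name)
    pipe <- site_pipeline(config, 1L, registry)
    out$tally <- pipe$tally
    eras <- split_by_era(pipe$features)
    deriv <- eras$derivation
    temp <- eras$temporal
    imp <- fit_imputer(deriv, registry)
    Xd <- feature_matrix(apply_imputer(imp, deriv))
    Xt <- feature_matrix(apply_imputer(imp, temp))
    yd <- deriv$label
    yt <- temp$label
    for (fam in families) {
      spec <- model_spec(fam, seed = derive_seed(config$seed, 50L))
      cv <- kfold_cv(spec, deriv, registry = registry, k = k,
                     seed = config$seed, threshold = config$threshold)
      model <- train_model(spec, Xd, yd, registry_hash = registry_hash(registry))
      model$imputer <- imp
      model$calibrator <- cv$calibrator
      rep_t <- eval_report(predict_model(model, Xt, calibrated = TRUE), yt,
                           threshold = config$threshold)
      out$reports[[paste(fam, reg_name, sep = ".")]] <-
        list(cv = cv, model = model, temporal_report = rep_t)
    }
    if (importance && reg_name == registries[1] &&
        "neural_network" %in% families) {
      m <- out$reports[[paste("neural_network", reg_name, sep = ".")]]$model
      out$importance <- perm_importance(m, Xt, yt, n_repeats = 5L,
                                        seed = config$seed)
    }
  }
  out
}

#' External validation of a frozen origin-site model
#'
#' Applies the exported model -- weights, imputer and calibrator frozen --
#' to the other sites' full cohorts (derivation + temporal eras). Nothing is
#' refit: external site data never touch the imputer means.
#'
#' @param config an `experiment_config`.
#' @param model an `aki_model` with its `imputer` attached (e.g. from
#'   [run_single_site()]).
#' @param site_indices sites to validate on (default all but site 1).
#' @param registry the registry the model was trained on.
#' @return named list of per-site [eval_report()]s, with attribute
#'   `config_hash`.
#' @export
run_external_validation <- function(config, model,
                                    site_indices = seq_along(config$sites)[-1],
                                    registry = feature_registry(config$registry)) {
  if (is.null(model$imputer)) stopf("model must carry its frozen imputer")
  if (!is.null(model$registry_hash) &&
      !identical(model$registry_hash, registry_hash(registry))) {
    stopf("model registry does not match `registry`")
  }
  out <- list()
  for (si in site_indices) {
    pipe <- site_pipeline(config, si, registry)
    X <- feature_matrix(apply_imputer(model$imputer, pipe$features))
    y <- pipe$features$label
    out[[config$sites[[si]]$site_id]] <-
      eval_report(predict_model(model, X, calibrated = TRUE), y,
                  threshold = config$threshold)
  }
  attr(out, "config_hash") <- config$config_hash
  out
}

#' The full federated study
#'
#' Generates all sites, extracts the parsimonious features, trains the
#' origin-site (site 1) neural network on its own 80% derivation split with
#' the same epoch budget as the federated schedule (R x E epochs), runs
#' [run_fl()] across all sites' derivation eras, and compares the best
#' aggregated model against the exported origin model on every site's
#' temporal era.
#'
#' @param config an `experiment_config`.
#' @param n_boot bootstrap replicates for the per-site AUROC contrast.
#' @return list: `comparison` (table from [evaluate_final()]; `delta` is FL
#'   minus single-site), `fl_result`, `single_model`, `origin_site`,
#'   `config_hash`.
#' @export
run_fl_study <- function(config, n_boot = 500L) {
  registry <- feature_registry(config$registry)
  site_features <- vector("list", length(config$sites))
  names(site_features) <- vapply(config$sites, `[[`, "", "site_id")
  for (si in seq_along(config$sites)) {
    pipe <- site_pipeline(config, si, registry)
    site_features[[si]] <- pipe$features
    rm(pipe)
  }
  flr <- run_fl(site_features, config$fl, registry)
  origin <- flr$sites[[1]]
  w_single <- nn_fit(origin$X_train, origin$y_train,
                     hidden = config$fl$hidden,
                     epochs = config$fl$rounds * config$fl$local_epochs,
                     batch_size = config$fl$batch_size,
                     learning_rate = config$fl$learning_rate,
                     seed = config$fl$seed, standardize = FALSE)
  single_model <- structure(
    list(spec = model_spec("neural_network",
                           list(hidden = config$fl$hidden,
                                epochs = config$fl$rounds * config$fl$local_epochs,
                                batch_size = config$fl$batch_size,
                                learning_rate = config$fl$learning_rate),
                           seed = config$fl$seed),
         fit = w_single, feature_names = colnames(origin$X_train),
         registry_hash = registry_hash(registry),
         calibrator = NULL, imputer = origin$imputer),
    class = "aki_model")
  comparison <- evaluate_final(flr, single_model, n_boot = n_boot,
                               seed = config$seed)
  attr(comparison, "config_hash") <- config$config_hash
  list(comparison = comparison, fl_result = flr,
       single_model = single_model,
       origin_site = names(site_features)[1],
       config_hash = config$config_hash)
}
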