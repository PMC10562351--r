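# Federated averaging across sites.
#
# Protocol: each round the server broadcasts the global weight set; every
# site runs E local epochs of mini-batch Adam on its own 80% derivation
# split; the server forms the sample-size-weighted element-wise mean of the
# returned weight sets; the aggregated model is scored on every site's 20%
# validation split. The best aggregated model is the round with the highest
# mean validation AUROC; each site also tracks its best local model. Only
# weight sets and scalar validation scores cross the site boundary.

#' Federated learning configuration
#'
#' @param rounds federated rounds R.
#' @param local_epochs local epochs E per round.
#' @param batch_size mini-batch size B.
#' @param learning_rate Adam learning rate.
#' @param hidden MLP hidden-layer widths (shared architecture).
#' @param weighting `"by_size"` (canonical FedAvg, weights `n_k / sum n_k`)
#'   or `"uniform"`.
#' @param persist_state carry each site's Adam moments across rounds
#'   (default `FALSE`: sites restart stateless from the broadcast weights).
#' @param val_fraction held-out fraction of each site's derivation data.
#' @param threshold operating threshold for final reports.
#' @param seed master seed (initialization, splits, batch shuffles).
#' @return an `fl_config`.
#' @export
fl_config <- function(rounds = 30L, local_epochs = 2L, batch_size = 32L,
                      learning_rate = 1e-2, hidden = c(64, 32),
                      weighting = c("by_size", "uniform"),
                      persist_state = FALSE, val_fraction = 0.2,
                      threshold = 0.5, seed = 1L) {
  weighting <- match.arg(weighting)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, hidden = hidden,
                 weighting = weighting, persist_state = persist_state,
                 val_fraction = val_fraction, threshold = threshold,
                 seed = as.integer(seed)),
            class = "fl_config")
}

#' Federated averaging of weight sets
#'
#' Element-wise weighted mean with weights `n_k / sum(n_k)`.
#'
#' @param weight_sets list of weight sets with identical shapes.
#' @param n_k positive sample counts, one per site.
#' @return the aggregated weight set.
#' @export
fedavg <- function(weight_sets, n_k) {
  if (!length(weight_sets)) stopf("no weight sets to aggregate")
  if (length(weight_sets) != length(n_k)) stopf("one n_k per weight set required")
  if (any(n_k <= 0)) stopf("n_k must be positive")
  shapes <- lapply(weight_sets, function(w) lapply(w, dim_or_len))
  for (s in shapes[-1]) {
    if (!identical(s, shapes[[1]])) stopf("weight-set shapes differ across sites")
  }
  wts <- n_k / sum(n_k)
  out <- weight_sets[[1]]
  for (nm in names(out)) {
    acc <- weight_sets[[1]][[nm]] * wts[1]
    for (k in seq_along(weight_sets)[-1]) {
      acc <- acc + weight_sets[[k]][[nm]] * wts[k]
    }
    out[[nm]] <- acc
  }
  out
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)

# Per-site state: imputed matrices for the three partitions. Built once,
# before the round loop; the loop itself only sees weights and scalars.
prepare_fl_site <- function(features, registry, config) {
  feats <- as.data.table(features)
  deriv <- which(feats$era == "derivation")
  temp <- which(feats$era == "temporal")
  y_d <- as.integer(feats$label[deriv])
  if (length(unique(y_d)) < 2L) {
    stopf("site '%s': derivation data contain a single class",
          feats$site_id[1])
  }
  fold <- with_seed(derive_seed(config$seed, 571L), {
    f <- integer(length(y_d))
    for (cls in unique(y_d)) {
      idx <- which(y_d == cls)
      idx <- idx[sample.int(length(idx))]
      f[idx] <- rep(seq_len(ceiling(1 / config$val_fraction)),
                    length.out = length(idx))
    }
    f
  })
  val <- deriv[fold == 1L]
  train <- setdiff(deriv, val)
  if (length(unique(feats$label[train])) < 2L) {
    stopf("site '%s': training split contains a single class",
          feats$site_id[1])
  }
  imp <- fit_imputer(features[train], registry)
  Xall <- feature_matrix(apply_imputer(imp, features))
  # site-local preprocessing: z-scoring with the site's training moments
  scaler <- scale_fit(Xall[train, , drop = FALSE])
  Xall <- scale_apply(scaler, Xall)
  list(site_id = feats$site_id[1], scaler = scaler,
       X_train = Xall[train, , drop = FALSE],
       y_train = as.integer(feats$label[train]),
       X_val = Xall[val, , drop = FALSE],
       y_val = as.integer(feats$label[val]),
       X_temporal = Xall[temp, , drop = FALSE],
       y_temporal = as.integer(feats$label[temp]),
       imputer = imp, train_idx = train, val_idx = val, temporal_idx = temp)
}

#' Run the federated-averaging study loop
#'
#' @param site_features named list of `aki_features` tables (one per site,
#'   each with derivation and temporal eras and a `label` column).
#' @param config an [fl_config()].
#' @param registry the shared [feature_registry()].
#' @return an `fl_result`: `best_round`, `best_weights`, `history`
#'   (round x site validation AUROCs of the aggregated model and each local
#'   model), `mean_val_by_round`, `best_local` (per-site best local weights
#'   and round), `temporal_reports` (per-site [eval_report()] of the best
#'   aggregated model on the temporal era), `sites` (split indices, scaler
#'   and imputer per site), `round_weights` (the aggregated weight set after
#'   every round), `update_fields` (names of the only payloads sites return
#'   to the server), `config`.
#' @export
run_fl <- function(site_features, config = fl_config(),
                   registry = feature_registry("parsimonious_21")) {
  K <- length(site_features)
  if (K < 1L) stopf("at least one site required")
  sites <- lapply(site_features, prepare_fl_site, registry = registry,
                  config = config)
  spec <- mlp_spec(nrow(as.data.table(registry)), config$hidden)
  global <- init_weights(spec, derive_seed(config$seed, 311L))
  states <- vector("list", K)
  n_k <- vapply(sites, function(s) nrow(s$X_train), numeric(1))
  agg_w <- if (config$weighting == "by_size") n_k else rep(1, K)

  hist <- vector("list", config$rounds)
  best_local <- lapply(seq_len(K), function(k) list(auroc = -Inf))
  round_weights <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    # -- site side: only weight sets and scalar scores leave this block
    updates <- lapply(seq_len(K), function(k) {
      s <- sites[[k]]
      res <- local_train(global, s$X_train, s$y_train,
                         epochs = config$local_epochs,
                         batch_size = config$batch_size,
                         learning_rate = config$learning_rate,
                         seed = config$seed,
                         epoch_offset = (r - 1L) * config$local_epochs,
                         state = if (config$persist_state) states[[k]] else NULL)
      list(weights = res$weights, state = res$state, n = nrow(s$X_train),
           local_val_auroc = auroc(nn_predict(res$weights, s$X_val), s$y_val))
    })
    if (config$persist_state) states <- lapply(updates, `[[`, "state")
    # -- server side
    global <- fedavg(lapply(updates, `[[`, "weights"),
                     vapply(updates, `[[`, numeric(1), "n") *
                       (agg_w / n_k))
    agg_val <- vapply(seq_len(K), function(k) {
      auroc(nn_predict(global, sites[[k]]$X_val), sites[[k]]$y_val)
    }, numeric(1))
    for (k in seq_len(K)) {
      if (updates[[k]]$local_val_auroc > best_local[[k]]$auroc) {
        best_local[[k]] <- list(auroc = updates[[k]]$local_val_auroc,
                                round = r, weights = updates[[k]]$weights)
      }
    }
    round_weights[[r]] <- global
    hist[[r]] <- data.table(round = r, site = names(site_features),
                            agg_val_auroc = agg_val,
                            local_val_auroc = vapply(updates, `[[`,
                                                     numeric(1),
                                                     "local_val_auroc"))
  }
  history <- rbindlist(hist)
  mean_val <- history[, .(mean_auroc = mean(agg_val_auroc)), by = round]
  best_round <- mean_val$round[which.max(mean_val$mean_auroc)]
  best_weights <- round_weights[[best_round]]
  temporal_reports <- lapply(sites, function(s) {
    if (!length(s$y_temporal) || length(unique(s$y_temporal)) < 2L) return(NULL)
    eval_report(nn_predict(best_weights, s$X_temporal), s$y_temporal,
                threshold = config$threshold)
  })
  names(temporal_reports) <- names(site_features)
  structure(list(best_round = best_round, best_weights = best_weights,
                 history = history, mean_val_by_round = mean_val,
                 best_local = best_local,
                 temporal_reports = temporal_reports, sites = sites,
                 round_weights = round_weights, spec = spec, config = config,
                 update_fields = c("weights", "state", "n",
                                   "local_val_auroc"),
                 registry_hash = registry_hash(registry)),
            class = "fl_result")
}

#' Compare the aggregated FL model with an exported single-site model
#'
#' Per site, temporal-era AUROC of (a) the frozen single-site model and
#' (b) the best aggregated FL model, with the paired-bootstrap difference.
#' Both models see the same site-locally imputed inputs, so the contrast
#' isolates the weights.
#'
#' @param fl_result an `fl_result` from [run_fl()].
#' @param single_site_model an `aki_model` trained on the origin site with
#'   the same registry.
#' @param n_boot,seed bootstrap settings for [compare_auroc()].
#' @return data.table: `site`, `n_temporal`, `auroc_single`, `auroc_fl`,
#'   `delta` (FL minus single-site), `ci_lo`, `ci_hi`, `p`.
#' @export
evaluate_final <- function(fl_result, single_site_model, n_boot = 1000L,
                           seed = 1L) {
  if (!is.null(single_site_model$registry_hash) &&
      !identical(single_site_model$registry_hash, fl_result$registry_hash)) {
    stopf("single-site model and FL run use different registries")
  }
  rows <- lapply(names(fl_result$sites), function(nm) {
    s <- fl_result$sites[[nm]]
    y <- s$y_temporal
    if (!length(y) || length(unique(y)) < 2L) return(NULL)
    sc_single <- predict_model(single_site_model, s$X_temporal)
    sc_fl <- nn_predict(fl_result$best_weights, s$X_temporal)
    cmp <- compare_auroc(sc_single, sc_fl, y, n_boot = n_boot,
                         seed = derive_seed(seed, match(nm, names(fl_result$sites))))
    data.table(site = nm, n_temporal = length(y),
               auroc_single = cmp$auroc_a, auroc_fl = cmp$auroc_b,
               delta = cmp$delta, ci_lo = cmp$ci[1], ci_hi = cmp$ci[2],
               p = cmp$p)
  })
  rbindlist(rows)
}
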