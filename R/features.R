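# Prediction windows and feature extraction.
#
# One 6-h window per stay. AKI cases use (onset - 30, onset - 24]: the
# prediction time (window end) precedes onset by the 24-h lead time. The
# alternative reading, a window *starting* 24 h before onset, is available
# via `window_anchor = "start_24h_before"`. Controls use a random 6-h window
# starting uniformly in [30, discharge - 6]. All intervals are half-open
# (start, end].

#' Case feature window for an AKI onset
#'
#' @param onset AKI onset in hours from admission.
#' @param window_anchor `"end_24h_before"` (default; window
#'   `(onset-30, onset-24]`, a true 24-h lead time) or `"start_24h_before"`
#'   (window `(onset-24, onset-18]`).
#' @return list `(start, end, role = "case")`, or `NULL` when the onset is
#'   too early for a full in-stay window.
#' @export
case_window <- function(onset, window_anchor = c("end_24h_before",
                                                 "start_24h_before")) {
  window_anchor <- match.arg(window_anchor)
  start <- if (window_anchor == "end_24h_before") onset - 30 else onset - 24
  if (start < 0) return(NULL)
  list(start = start, end = start + 6, role = "case")
}

#' Random control feature window for a non-AKI stay
#'
#' @param discharge_time stay length in hours.
#' @return list `(start, end, role = "control")` with start drawn uniformly
#'   from `[30, discharge_time - 6]`, or `NULL` if the stay is shorter than
#'   36 h. Deterministic under a seeded RNG.
#' @export
control_window <- function(discharge_time) {
  if (discharge_time < 36) return(NULL)
  start <- runif(1, 30, discharge_time - 6)
  list(start = start, end = start + 6, role = "control")
}

#' Choose one prediction window per stay
#'
#' Stays with an AKI event get a case window anchored at onset; stays
#' without get a random control window. Infeasible stays (onset too early,
#' stay < 36 h for controls) are skipped and logged.
#'
#' @param dataset an `aki_site_data`.
#' @param labels labels table from [label_stays()] (computed if omitted).
#' @param seed integer seed for the control-window draws.
#' @param window_anchor see [case_window()].
#' @return data.table `stay_id, window_start, window_end, role` with
#'   attribute `skipped` (a table of stay_id + reason).
#' @export
build_windows <- function(dataset, labels = NULL, seed = 1L,
                          window_anchor = "end_24h_before") {
  if (is.null(labels)) labels <- label_stays(dataset)
  st <- as.data.table(dataset$stays)[, .(stay_id, discharge_time)]
  lab <- as.data.table(labels)[st, on = "stay_id"]
  is_case <- !is.na(lab$stage)
  off <- if (window_anchor == "end_24h_before") 30 else 24
  out <- with_seed(derive_seed(seed, 211L), {
    start <- numeric(nrow(lab))
    role <- character(nrow(lab))
    skip <- rep(NA_character_, nrow(lab))
    start[is_case] <- lab$onset[is_case] - off
    role[is_case] <- "case"
    skip[is_case & start < 0] <- "onset_too_early_for_full_window"
    n_ctrl <- sum(!is_case)
    # draws are made in stay order so the matrix is reproducible
    u <- runif(nrow(lab))
    feas <- lab$discharge_time >= 36
    start[!is_case] <- 30 + u[!is_case] *
      pmax(lab$discharge_time[!is_case] - 36, 0)
    role[!is_case] <- "control"
    skip[!is_case & !feas] <- "stay_shorter_than_36h"
    data.table(stay_id = lab$stay_id, window_start = start,
               window_end = start + 6, role = role, skip = skip)
  })
  skipped <- out[!is.na(skip), .(stay_id, reason = skip)]
  out <- out[is.na(skip)][, skip := NULL]
  setattr(out, "skipped", skipped)
  out[]
}

# -- extraction ---------------------------------------------------------------

LAST_LOOKBACK_H <- 48   # LOCF horizon for `last` aggregation
MED_LOOKBACK_H <- 168   # 7-day medication lookback

#' Extract the feature matrix for a set of windows
#'
#' Aggregates each stay's event streams over its window per the registry:
#' `mean` and `last` over `(start, end]` (`last` falls back to the most
#' recent value in the 48 h up to the window end), urine sums over the 8/24 h
#' trailing the window end, medication flags over the 7 days trailing the
#' window end, `static` from the stays table. Absent records leave `NA`
#' (the missing mask); imputation is a separate, fitted step.
#'
#' @param dataset an `aki_site_data`.
#' @param windows output of [build_windows()] (or a compatible table).
#' @param registry a [feature_registry()].
#' @param labels labels table from [label_stays()] (computed if omitted).
#' @param grouping severity grouping that defines the positive label.
#' @return an `aki_features` data.table: `stay_id`, `site_id`, `era`,
#'   `window_start`, `window_end`, `role`, `label`, then one column per
#'   registry feature; attribute `registry_hash` fingerprints the registry.
#' @export
extract_features <- function(dataset, windows, registry = feature_registry(),
                             labels = NULL, grouping = "all_stage") {
  if (is.null(labels)) labels <- label_stays(dataset)
  st <- as.data.table(dataset$stays)
  w <- as.data.table(windows)[, .(stay_id, window_start, window_end, role)]
  base <- st[, .(stay_id, site_id, era)][w, on = "stay_id", nomatch = 0L]
  lab <- as.data.table(labels)
  base[, label := as.integer(in_group(lab, grouping))[match(stay_id,
                                                            lab$stay_id)]]

  out <- copy(base)
  reg <- as.data.table(registry)
  win_of <- base[, .(stay_id, window_start, window_end)]

  agg_window <- function(stream, items, fun_name) {
    s <- as.data.table(dataset[[stream]])
    if (stream %in% c("creatinine", "urine")) s[, item := stream]
    s <- s[item %in% items]
    j <- s[win_of, on = .(stay_id), nomatch = 0L, allow.cartesian = TRUE]
    if (fun_name == "mean") {
      j <- j[time > window_start & time <= window_end]
      agg <- j[, .(v = mean(value)), by = .(stay_id, item)]
    } else { # last within (end - 48, end]
      j <- j[time > window_end - LAST_LOOKBACK_H & time <= window_end]
      setorder(j, stay_id, item, time)
      agg <- j[, .(v = value[.N]), by = .(stay_id, item)]
    }
    agg
  }

  for (src in unique(reg$source)) {
    rows <- reg[source == src]
    if (src == "stays") {
      for (nm in rows$name) {
        out[, (nm) := st[[nm]][match(out$stay_id, st$stay_id)]]
      }
    } else if (src == "medications") {
      med <- as.data.table(dataset$medications)
      j <- med[win_of, on = .(stay_id), nomatch = 0L, allow.cartesian = TRUE]
      j <- j[time > window_end - MED_LOOKBACK_H & time <= window_end]
      for (nm in rows$name) {
        got <- unique(j[drug_class == nm, stay_id])
        out[, (nm) := as.numeric(out$stay_id %in% got)]
      }
    } else if (src == "urine") {
      ur <- as.data.table(dataset$urine)
      j <- ur[win_of, on = .(stay_id), nomatch = 0L, allow.cartesian = TRUE]
      for (nm in rows$name) {
        hrs <- if (reg[name == nm, aggregation] == "sum_trailing_8h") 8 else 24
        agg <- j[time > window_end - hrs & time <= window_end,
                 .(v = sum(value)), by = stay_id]
        out[, (nm) := agg$v[match(out$stay_id, agg$stay_id)]]
      }
    } else {
      for (fun_name in unique(rows$aggregation)) {
        items <- rows[aggregation == fun_name, name]
        agg <- agg_window(src, items, if (fun_name == "last") "last" else "mean")
        for (nm in items) {
          a <- agg[item == nm]
          out[, (nm) := a$v[match(out$stay_id, a$stay_id)]]
        }
      }
    }
  }
  setattr(out, "class", c("aki_features", class(out)))
  setattr(out, "registry_hash", registry_hash(registry))
  setattr(out, "feature_names", reg$name)
  out[]
}

feature_matrix <- function(features, registry = NULL) {
  nms <- attr(features, "feature_names") %||% setdiff(
    names(features), c("stay_id", "site_id", "era", "window_start",
                       "window_end", "role", "label"))
  as.matrix(as.data.table(features)[, nms, with = FALSE])
}

# -- imputation ---------------------------------------------------------------

#' Fit a mean imputer on derivation-era feature vectors
#'
#' Means are computed on the supplied (fitting) vectors only, so later eras
#' or external sites never leak into the imputation. Binary features are
#' filled with 0.
#'
#' @param features an `aki_features` table (typically restricted to the
#'   derivation era of the fitting site).
#' @param registry the registry used for extraction.
#' @return an `aki_imputer` (named means + binary fill spec).
#' @export
fit_imputer <- function(features, registry = feature_registry()) {
  reg <- as.data.table(registry)
  X <- feature_matrix(features)
  means <- setNames(numeric(nrow(reg)), reg$name)
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    if (reg$kind[i] == "binary") {
      means[nm] <- 0
    } else {
      v <- X[, nm]
      if (all(is.na(v))) {
        stopf("cannot fit imputer: feature '%s' observed nowhere", nm)
      }
      means[nm] <- mean(v, na.rm = TRUE)
    }
  }
  structure(list(means = means, registry_hash = registry_hash(registry)),
            class = "aki_imputer")
}

#' Apply a fitted mean imputer
#'
#' @param imputer an `aki_imputer` from [fit_imputer()].
#' @param features an `aki_features` table (any era/site).
#' @return the features with every `NA` entry replaced by the fitted mean
#'   (0 for binary features).
#' @export
apply_imputer <- function(imputer, features) {
  stopifnot(inherits(imputer, "aki_imputer"))
  if (!is.null(attr(features, "registry_hash")) &&
      !identical(imputer$registry_hash, attr(features, "registry_hash"))) {
    stopf("imputer was fitted for a different feature registry")
  }
  out <- copy(as.data.table(features))
  for (nm in names(imputer$means)) {
    v <- out[[nm]]
    if (anyNA(v)) set(out, which(is.na(v)), nm, imputer$means[[nm]])
  }
  setattr(out, "class", class(features))
  setattr(out, "registry_hash", attr(features, "registry_hash"))
  setattr(out, "feature_names", attr(features, "feature_names"))
  out[]
}
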