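# Discrimination, calibration, clinical-utility and cohort statistics.

#' AUROC by the Mann-Whitney pair statistic
#'
#' `(wins + 0.5 * ties) / (n_pos * n_neg)`, computed from midranks, so it
#' equals brute-force pair counting exactly (ties included).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUROC undefined: labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Predicted positive iff `score >= threshold`. Precision is reported as 0
#' (with a message) when nothing is called positive.
#'
#' @param scores,labels as in [auroc()].
#' @param threshold operating threshold in `[0, 1]`.
#' @return named list: sensitivity, specificity, precision, accuracy and the
#'   confusion counts.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
  fn <- sum(!pos & labels == 1L); tn <- sum(!pos & labels == 0L)
  prec <- if (tp + fp == 0L) {
    message("no positive predictions at threshold ", threshold,
            "; precision reported as 0")
    0
  } else tp / (tp + fp)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = prec,
       accuracy = (tp + tn) / length(labels),
       tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold)
}

#' Reliability (calibration) curve over equal-width bins
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins number of equal-width bins on `[0, 1]`; empty bins are
#'   omitted.
#' @return data.table: `bin`, `mean_predicted`, `observed_fraction`, `count`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10L) {
  if (any(probs < 0 | probs > 1)) stopf("probs must lie in [0, 1]")
  labels <- as.integer(labels)
  bin <- pmin(pmax(ceiling(probs * n_bins), 1L), n_bins)
  dt <- data.table(bin = bin, p = probs, y = labels)
  out <- dt[, .(mean_predicted = mean(p), observed_fraction = mean(y),
                count = .N), by = bin]
  setorder(out, bin)
  out[]
}

#' Decision-curve net benefit
#'
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)` with a positive call iff
#' `prob >= p_t`, together with the treat-all and treat-none references.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param thresholds grid of decision thresholds in (0, 1); values at or
#'   beyond 1 are dropped.
#' @return data.table: `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
net_benefit <- function(probs, labels, thresholds = seq(0.05, 0.95, by = 0.05)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  out <- lapply(thresholds, function(pt) {
    pos <- probs >= pt
    tp <- sum(pos & labels == 1L)
    fp <- sum(pos & labels == 0L)
    odds <- pt / (1 - pt)
    data.table(threshold = pt, net_benefit = tp / n - (fp / n) * odds,
               treat_all = prev - (1 - prev) * odds, treat_none = 0)
  })
  rbindlist(out)
}

#' Permutation feature importance
#'
#' Mean AUROC drop over `n_repeats` independent within-column permutations.
#' A constant column permutes to itself, so its drop is exactly 0.
#'
#' @param model an `aki_model` (or an MLP weight set).
#' @param X imputed feature matrix the model was built for.
#' @param y 0/1 labels.
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @return data.table: `feature`, `mean_drop`, `baseline_auroc`,
#'   `n_repeats`, sorted by decreasing drop.
#' @export
perm_importance <- function(model, X, y, n_repeats = 5L, seed = 1L) {
  X <- as.matrix(X)
  pred <- function(M) {
    if (inherits(model, "aki_model")) predict_model(model, M)
    else nn_predict(model, M)
  }
  if (inherits(model, "aki_model") && !is.null(model$feature_names) &&
      !identical(colnames(X), model$feature_names)) {
    stopf("feature columns do not match the model's registry")
  }
  base <- auroc(pred(X), y)
  drops <- matrix(NA_real_, n_repeats, ncol(X))
  with_seed(derive_seed(seed, 733L), {
    for (r in seq_len(n_repeats)) {
      for (j in seq_len(ncol(X))) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        drops[r, j] <- base - auroc(pred(Xp), y)
      }
    }
  })
  out <- data.table(feature = colnames(X), mean_drop = colMeans(drops),
                    baseline_auroc = base, n_repeats = n_repeats)
  setorder(out, -mean_drop)
  out[]
}

#' Paired-bootstrap comparison of two AUROCs
#'
#' Resamples subjects (stratified by class so both classes persist) and
#' recomputes both AUROCs on each replicate. `delta = AUROC_B - AUROC_A`.
#'
#' @param scores_a,scores_b two score vectors over the same subjects.
#' @param labels shared 0/1 labels.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list: `delta`, `ci` (length 2), `p` (two-sided bootstrap sign
#'   test), `auroc_a`, `auroc_b`.
#' @export
compare_auroc <- function(scores_a, scores_b, labels, n_boot = 2000L,
                          seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stopf("score vectors and labels must have equal length")
  }
  i1 <- which(labels == 1L)
  i0 <- which(labels == 0L)
  if (!length(i1) || !length(i0)) stopf("labels contain a single class")
  a0 <- auroc(scores_a, labels)
  b0 <- auroc(scores_b, labels)
  deltas <- with_seed(derive_seed(seed, 839L), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(i1[sample.int(length(i1), replace = TRUE)],
               i0[sample.int(length(i0), replace = TRUE)])
      auroc(scores_b[idx], labels[idx]) - auroc(scores_a[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(delta = b0 - a0,
       ci = unname(quantile(deltas, c(alpha, 1 - alpha))),
       p = p, auroc_a = a0, auroc_b = b0)
}

#' Full evaluation report for one score vector
#'
#' @param scores scores or calibrated probabilities.
#' @param labels 0/1 outcomes.
#' @param threshold operating threshold for the confusion metrics.
#' @param n_bins calibration bins.
#' @param thresholds decision-curve grid.
#' @return an `eval_report` list: `auroc`, the threshold metrics, `n`,
#'   `n_pos`, `calibration`, `decision_curve`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5, n_bins = 10L,
                        thresholds = seq(0.05, 0.95, by = 0.05)) {
  labels <- as.integer(labels)
  tm <- threshold_metrics(scores, labels, threshold)
  probs <- pmin(pmax(scores, 0), 1)
  structure(list(auroc = auroc(scores, labels),
                 sensitivity = tm$sensitivity, specificity = tm$specificity,
                 precision = tm$precision, accuracy = tm$accuracy,
                 threshold = threshold, n = length(labels),
                 n_pos = sum(labels == 1L),
                 calibration = calibration_curve(probs, labels, n_bins),
                 decision_curve = net_benefit(probs, labels, thresholds)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("EvalReport: n=%d (%d events)\n  AUROC %.3f | sens %.3f",
                     " spec %.3f prec %.3f acc %.3f @ tau=%.2f\n"),
              x$n, x$n_pos, x$auroc, x$sensitivity, x$specificity,
              x$precision, x$accuracy, x$threshold))
  invisible(x)
}

#' Two-group cohort summary with hypothesis tests
#'
#' Continuous variables: median (IQR), Mann-Whitney U (normal approximation
#' with tie correction). Categorical variables: n (%), Pearson chi-square
#' without continuity correction. Significance flagged at p < 0.05.
#'
#' @param data data.frame of cohort variables.
#' @param group logical/0-1 vector splitting `data` into two groups
#'   (TRUE = group A).
#' @param variables columns to summarize (default: all except the group).
#' @return data.table: variable, summary_a, summary_b, test, p, significant.
#' @export
cohort_summary <- function(data, group, variables = NULL) {
  data <- as.data.frame(data)
  group <- as.logical(group)
  if (!any(group) || !any(!group)) stopf("both groups must be non-empty")
  if (is.null(variables)) variables <- names(data)
  fmt_cont <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- suppressWarnings(
        wilcox.test(x[group], x[!group], exact = FALSE, correct = FALSE)$p.value)
      if (is.na(p)) p <- 1  # zero-variance rank statistic (all ties)
      data.table(variable = v, summary_a = fmt_cont(x[group]),
                 summary_b = fmt_cont(x[!group]), test = "mann_whitney_u",
                 p = p)
    } else {
      tab <- table(factor(group, levels = c(TRUE, FALSE)), x)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      lvl <- colnames(tab)[which.max(colSums(tab))]
      n_a <- sum(x[group] == lvl, na.rm = TRUE)
      n_b <- sum(x[!group] == lvl, na.rm = TRUE)
      data.table(variable = v,
                 summary_a = sprintf("%s: %d (%.1f%%)", lvl, n_a,
                                     100 * n_a / sum(group)),
                 summary_b = sprintf("%s: %d (%.1f%%)", lvl, n_b,
                                     100 * n_b / sum(!group)),
                 test = "chi_square", p = p)
    }
  })
  out <- rbindlist(rows)
  out[, significant := p < 0.05]
  out[]
}
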