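# Cohort construction: study exclusion rules and era partitions.
#
# A stay is retained when all of the following hold: age >= 20; not (ESRD
# and on chronic renal replacement therapy); no AKI before ICU admission
# (the creatinine rules fire on pre-admission data, t < 0); no first
# hemodialysis within 24 h of admission; ICU stay >= 30 h (a stay of exactly
# 30.0 h is kept: the rule is "less than 30 h"); first ICU admission of the
# patient. A stay matching several criteria is tallied once, under the first
# matching criterion in that order, so the attrition tally is auditable:
# n_included + sum(tally) == n_input.

EXCLUSION_CRITERIA <- c("age_lt_20", "esrd_on_rrt", "aki_before_icu",
                        "hd_within_24h", "stay_lt_30h", "repeat_admission")

# Stays whose pre-admission creatinine (within `lookback` hours before
# admission) already satisfies a KDIGO creatinine criterion.
aki_before_admission <- function(dataset, lookback = 168) {
  cr <- as.data.table(dataset$creatinine)[time < 0 & time >= -lookback]
  if (!nrow(cr)) return(character(0))
  # pre-admission reference: lowest eligible pre-admission value
  bl <- cr[value < 4.0][, .(baseline = min(value),
                            anchor_time = time[which.min(value)][1L],
                            provenance = "pre_icu_lowest"), by = stay_id]
  if (!nrow(bl)) return(character(0))
  ev <- stage_creatinine_all(cr, bl)
  unique(ev$stay_id)
}

#' Apply the study exclusion criteria
#'
#' @param dataset an `aki_site_data` (stays plus event streams).
#' @param pre_icu_lookback hours before admission searched for pre-existing
#'   AKI (default 168).
#' @return list with `included` (the dataset restricted to retained stays,
#'   input order preserved) and `tally` (an `exclusion_tally`: per-criterion
#'   first-hit counts plus `n_input`, `n_included`).
#' @export
apply_exclusions <- function(dataset, pre_icu_lookback = 168) {
  st <- as.data.table(dataset$stays)
  req <- c("stay_id", "age", "esrd", "prior_rrt", "discharge_time",
           "patient_id", "stay_number")
  miss <- setdiff(req, names(st))
  if (length(miss)) stopf("stays table lacks required field(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(st$age)) {
    stopf("missing `age` for stay '%s'", st$stay_id[which(is.na(st$age))[1L]])
  }
  n_input <- nrow(st)
  tally <- setNames(integer(length(EXCLUSION_CRITERIA)), EXCLUSION_CRITERIA)
  if (!n_input) {
    return(list(included = dataset,
                tally = structure(list(counts = tally, n_input = 0L,
                                       n_included = 0L),
                                  class = "exclusion_tally")))
  }
  pre_aki_ids <- aki_before_admission(dataset, pre_icu_lookback)
  dial <- as.data.table(dataset$dialysis)
  hd24_ids <- if (nrow(dial)) unique(dial[time <= 24, stay_id]) else character(0)
  # chronic dialysis (ESRD + prior RRT) is not "first hemodialysis in ICU"
  hd24_ids <- setdiff(hd24_ids, st[esrd & prior_rrt, stay_id])

  hit <- matrix(FALSE, n_input, length(EXCLUSION_CRITERIA),
                dimnames = list(NULL, EXCLUSION_CRITERIA))
  hit[, "age_lt_20"] <- st$age < 20
  hit[, "esrd_on_rrt"] <- st$esrd & st$prior_rrt
  hit[, "aki_before_icu"] <- st$stay_id %in% pre_aki_ids
  hit[, "hd_within_24h"] <- st$stay_id %in% hd24_ids
  adm <- if ("admission_time" %in% names(st)) st$admission_time else 0
  hit[, "stay_lt_30h"] <- (st$discharge_time - adm) < 30
  hit[, "repeat_admission"] <- st$stay_number > 1L

  first_hit <- apply(hit, 1L, function(r) if (any(r)) which(r)[1L] else 0L)
  for (i in seq_along(EXCLUSION_CRITERIA)) {
    tally[i] <- sum(first_hit == i)
  }
  keep_ids <- st$stay_id[first_hit == 0L]
  included <- subset_stays(dataset, keep_ids)
  tally_obj <- structure(list(counts = tally, n_input = n_input,
                              n_included = length(keep_ids)),
                         class = "exclusion_tally")
  list(included = included, tally = tally_obj)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Exclusion tally: %d stays in, %d retained\n",
              x$n_input, x$n_included))
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

# Restrict every stream of a dataset to the given stays, preserving order.
subset_stays <- function(dataset, keep_ids) {
  pick <- function(x) {
    if (is.data.frame(x) && "stay_id" %in% names(x)) {
      as.data.table(x)[stay_id %in% keep_ids]
    } else x
  }
  out <- lapply(dataset, pick)
  out$stays <- out$stays[match(keep_ids, out$stays$stay_id)]
  class(out) <- class(dataset)
  out
}

#' Partition stays by era
#'
#' @param x a stays table, a feature table, or an `aki_site_data`; must carry
#'   an `era` column (`"derivation"` / `"temporal"`).
#' @return list with elements `derivation` and `temporal`; the partition is
#'   exhaustive and disjoint and preserves input order.
#' @export
split_by_era <- function(x) {
  if (inherits(x, "aki_site_data")) {
    era <- x$stays$era
    if (anyNA(era)) stopf("missing era tag")
    ids_d <- x$stays$stay_id[era == "derivation"]
    ids_t <- x$stays$stay_id[era == "temporal"]
    return(list(derivation = subset_stays(x, ids_d),
                temporal = subset_stays(x, ids_t)))
  }
  x <- as.data.table(x)
  if (!"era" %in% names(x) || anyNA(x$era)) stopf("missing era tag")
  list(derivation = x[era == "derivation"], temporal = x[era == "temporal"])
}
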