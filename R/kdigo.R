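# KDIGO 2012 AKI labeling from creatinine, urine output and dialysis.
#
# Creatinine rules, evaluated at every measurement time t (windows half-open
# (start, end]):
#   stage 1: value - min(values in (t-48 h, t]) >= 0.3 mg/dL, or
#            value >= 1.5 x reference;
#   stage 2: value >= 2.0 x reference;
#   stage 3: value >= 3.0 x reference, or value >= 4.0 mg/dL together with a
#            stage-1-qualifying acute rise (toggleable).
# The reference implements the "within 7 days" qualifier either as
# min(baseline, running minimum over the trailing 168 h) ("trailing7d", the
# default: the rise must have occurred within the prior 7 days) or as the
# baseline value gated to 168 h after the baseline measurement
# ("baseline_anchor").
#
# Urine rules, on roughly-hourly charting (gaps > 2 h break a span; mean rate
# = mean of recorded hourly volumes / weight):
#   stage 1: < 0.5 mL/kg/h over a 6-h span;  stage 2: over a 12-h span;
#   stage 3: < 0.3 mL/kg/h over 24 h, or anuria for >= 12 h.
# Any dialysis event implies stage 3.

#' Baseline creatinine with provenance
#'
#' Ward admissions use the lowest pre-admission (t < 0) value; direct
#' emergency-department admissions use the first available value. Values
#' >= 4 mg/dL are never baseline candidates.
#'
#' @param dataset an `aki_site_data` (or any list with `stays` and
#'   `creatinine` tables).
#' @param stay_id stay to compute the baseline for; may be omitted when the
#'   dataset holds a single stay.
#' @return list with `value`, `provenance` (`"pre_icu_lowest"` or
#'   `"ed_first_available"`) and `time` (anchor time of the measurement).
#'   Errors if no eligible value exists.
#' @export
baseline_creatinine <- function(dataset, stay_id = NULL) {
  if (is.null(stay_id)) {
    if (nrow(dataset$stays) != 1L) stopf("`stay_id` required for multi-stay data")
    stay_id <- dataset$stays$stay_id[1L]
  }
  all_b <- baselines_all(dataset)
  row <- all_b[all_b$stay_id == stay_id]
  if (nrow(row) != 1L) stopf("unknown stay_id '%s'", stay_id)
  if (is.na(row$baseline)) {
    stopf("baseline unavailable for stay '%s': no eligible creatinine < 4 mg/dL",
          stay_id)
  }
  list(value = row$baseline, provenance = row$provenance,
       time = row$anchor_time)
}

# Vectorized baseline computation; NA baseline marks 'unavailable'.
baselines_all <- function(dataset) {
  cr <- as.data.table(dataset$creatinine)[value < 4.0]
  st <- as.data.table(dataset$stays)[, .(stay_id, admission_source)]
  ward <- cr[st[admission_source == "ward"], on = "stay_id", nomatch = 0L]
  ward <- ward[time < 0]
  setorder(ward, stay_id, value, time)
  ward <- ward[, .(baseline = value[1L], anchor_time = time[1L],
                   provenance = "pre_icu_lowest"), by = stay_id]
  ed <- cr[st[admission_source != "ward"], on = "stay_id", nomatch = 0L]
  setorder(ed, stay_id, time)
  ed <- ed[, .(baseline = value[1L], anchor_time = time[1L],
               provenance = "ed_first_available"), by = stay_id]
  out <- rbind(ward, ed)
  out <- out[st[, .(stay_id)], on = "stay_id"]
  out[is.na(baseline), provenance := NA_character_]
  out[]
}

# Creatinine staging for many stays at once. `cr` must have stay_id, time,
# value; `bl` is the output of baselines_all(). Returns rows with stage >= 1.
stage_creatinine_all <- function(cr, bl, ratio_window = "trailing7d",
                                 scr4_requires_rise = TRUE) {
  cr <- as.data.table(cr)[bl, on = "stay_id", nomatch = 0L]
  cr <- cr[!is.na(baseline)]
  if (!nrow(cr)) {
    return(data.table(stay_id = character(0), time = numeric(0),
                      stage = integer(0)))
  }
  setorder(cr, stay_id, time)
  q <- cr[, .(stay_id, lo = time - 48, hi = time)]
  cr[, min48 := cr[q, on = .(stay_id, time > lo, time <= hi),
                   min(x.value), by = .EACHI]$V1]
  if (ratio_window == "trailing7d") {
    q$lo <- q$hi - 168
    cr[, min168 := cr[q, on = .(stay_id, time > lo, time <= hi),
                      min(x.value), by = .EACHI]$V1]
    cr[, ref := pmin(baseline, min168)]
    cr[, ratio_active := TRUE]
  } else {
    cr[, ref := baseline]
    cr[, ratio_active := time <= anchor_time + 168]
  }
  cr[, ratio := value / ref]
  cr[, s_delta := (value - min48) >= 0.3]
  cr[, stage := 0L]
  cr[s_delta | (ratio_active & ratio >= 1.5), stage := 1L]
  cr[ratio_active & ratio >= 2.0, stage := 2L]
  cr[ratio_active & ratio >= 3.0, stage := 3L]
  cr[, s1_so_far := cummax(as.integer(stage >= 1L)), by = stay_id]
  if (scr4_requires_rise) {
    cr[value >= 4.0 & s1_so_far == 1L, stage := 3L]
  } else {
    cr[value >= 4.0, stage := 3L]
  }
  cr[stage >= 1L, .(stay_id, time, stage)]
}

#' Stage the creatinine criteria of one measurement series
#'
#' @param series data.frame with `time` (hours) and `value` (mg/dL),
#'   strictly for one stay; times must be nondecreasing.
#' @param baseline either the list from [baseline_creatinine()] or a single
#'   number (its anchor then defaults to the first measurement time).
#' @param ratio_window `"trailing7d"` (default) or `"baseline_anchor"`; see
#'   the module notes above.
#' @param scr4_requires_rise if `TRUE` (default) the creatinine >= 4 mg/dL
#'   stage-3 rule also requires a prior or concurrent stage-1 acute rise.
#' @return data.table of `(time, stage)` for every time a criterion fires;
#'   zero rows when none does.
#' @export
stage_creatinine <- function(series, baseline, ratio_window = "trailing7d",
                             scr4_requires_rise = TRUE) {
  series <- as.data.table(series)
  if (!nrow(series)) stopf("creatinine series is empty")
  if (is.numeric(baseline)) {
    baseline <- list(value = baseline, time = series$time[1L])
  }
  cr <- data.table(stay_id = "s", time = series$time, value = series$value)
  bl <- data.table(stay_id = "s", baseline = baseline$value,
                   anchor_time = baseline$time %||% series$time[1L],
                   provenance = "supplied")
  stage_creatinine_all(cr, bl, ratio_window, scr4_requires_rise)[, .(time, stage)]
}

# Urine staging for many stays. `ur`: stay_id, time, value (mL per charting
# hour); `wt`: stay_id, weight. Returns rows with stage >= 1.
stage_urine_all <- function(ur, wt) {
  ur <- as.data.table(ur)
  if (!nrow(ur)) {
    return(data.table(stay_id = character(0), time = numeric(0),
                      stage = integer(0)))
  }
  ur <- ur[wt, on = "stay_id", nomatch = 0L]
  if (any(ur$weight <= 0)) stopf("weight must be positive")
  # snap records onto the hourly grid (record at t covers (t-1, t])
  ur[, grid_hour := ceiling(time)]
  ur <- ur[, .(vol = sum(value)), by = .(stay_id, weight, grid_hour)]
  setorder(ur, stay_id, grid_hour)
  grid <- ur[, .(grid_hour = seq_len(max(grid_hour))), by = .(stay_id, weight)]
  grid <- ur[grid, on = c("stay_id", "weight", "grid_hour")]
  setorder(grid, stay_id, grid_hour)
  grid[, idx := seq_len(.N), by = stay_id]
  grid[, present := !is.na(vol)]
  grid[, vol0 := fifelse(present, vol, 0)]
  prev_absent <- c(FALSE, !grid$present[-nrow(grid)])
  prev_absent[grid$idx == 1L] <- FALSE
  grid[, dbl := as.integer(!present & prev_absent)]
  roll <- function(x, k) frollsum(x, k, align = "right")
  for (k in c(6L, 12L, 24L)) {
    grid[, paste0("sum", k) := roll(vol0, k)]
    grid[, paste0("cnt", k) := roll(as.numeric(present), k)]
    # a gap > 2 h breaks the span; only missing-hour pairs that lie fully
    # inside the span count (the pair ending at the first slot references
    # the hour before the span start)
    grid[, paste0("bad", k) := roll(as.numeric(dbl), k - 1L)]
  }
  grid[, stage := 0L]
  ok <- function(k) {
    grid$present & grid$idx >= k & grid[[paste0("bad", k)]] == 0 &
      grid[[paste0("cnt", k)]] > 0
  }
  rate <- function(k) grid[[paste0("sum", k)]] /
    pmax(grid[[paste0("cnt", k)]], 1) / grid$weight
  grid[ok(6L) & rate(6L) < 0.5, stage := 1L]
  grid[ok(12L) & rate(12L) < 0.5, stage := 2L]
  grid[(ok(24L) & rate(24L) < 0.3) |
         (ok(12L) & grid$sum12 == 0), stage := 3L]
  grid[stage >= 1L, .(stay_id, time = as.numeric(grid_hour), stage)]
}

#' Stage the urine-output criteria of one hourly urine series
#'
#' @param series data.frame with `time` (hours) and `value` (mL voided over
#'   the preceding charting hour) for one stay.
#' @param weight body weight in kg (> 0).
#' @return data.table of `(time, stage)` rows where a criterion fires.
#' @export
stage_urine <- function(series, weight) {
  if (!is.numeric(weight) || weight <= 0) stopf("weight must be positive")
  ur <- data.table(stay_id = "s", time = series$time, value = series$value)
  stage_urine_all(ur, data.table(stay_id = "s", weight = weight))[, .(time, stage)]
}

#' Label AKI onset, stage and criterion for every stay
#'
#' Combines the creatinine, urine and dialysis rules: onset is the earliest
#' in-ICU time (t >= 0) at which any criterion fires; the stage is the
#' maximum stage attained during the stay; any dialysis event forces stage 3.
#'
#' @param dataset an `aki_site_data`.
#' @param ratio_window,scr4_requires_rise see [stage_creatinine()].
#' @return data.table with one row per stay (input order): `stay_id`,
#'   `onset`, `stage`, `criterion` (`creatinine`/`urine`/`dialysis`, the rule
#'   that fired first; ties broken in that order), `dialysis` (any RRT during
#'   the stay), `baseline`, `baseline_provenance`, `baseline_available`.
#'   Stays without AKI have `NA` onset/stage/criterion.
#' @export
label_stays <- function(dataset, ratio_window = "trailing7d",
                        scr4_requires_rise = TRUE) {
  st <- as.data.table(dataset$stays)
  bl <- baselines_all(dataset)
  ev_c <- stage_creatinine_all(dataset$creatinine, bl, ratio_window,
                               scr4_requires_rise)
  ev_c <- ev_c[time >= 0]
  ev_c[, criterion := "creatinine"]
  wt <- st[, .(stay_id, weight)]
  ev_u <- stage_urine_all(dataset$urine, wt)
  ev_u <- ev_u[time >= 0]
  ev_u[, criterion := "urine"]
  dial <- as.data.table(dataset$dialysis)
  ev_d <- if (nrow(dial)) {
    data.table(stay_id = dial$stay_id, time = dial$time, stage = 3L,
               criterion = "dialysis")
  } else {
    data.table(stay_id = character(0), time = numeric(0), stage = integer(0),
               criterion = character(0))
  }
  ev <- rbind(ev_c, ev_u, ev_d)
  agg <- if (nrow(ev)) {
    ev[, crit_rank := match(criterion, c("creatinine", "urine", "dialysis"))]
    setorder(ev, stay_id, time, crit_rank)
    ev[, .(onset = time[1L], criterion = criterion[1L],
           stage = max(stage)), by = stay_id]
  } else {
    data.table(stay_id = character(0), onset = numeric(0),
               criterion = character(0), stage = integer(0))
  }
  out <- agg[st[, .(stay_id)], on = "stay_id"]
  out[, dialysis := stay_id %in% dial$stay_id]
  out <- bl[out, on = "stay_id"]
  setnames(out, c("provenance"), c("baseline_provenance"))
  out[, baseline_available := !is.na(baseline)]
  out[, .(stay_id, onset, stage, criterion, dialysis, baseline,
          baseline_provenance, baseline_available)]
}

# Restrict a dataset to one stay (all streams).
subset_stay <- function(dataset, sid) {
  pick <- function(x) if (is.data.frame(x)) as.data.table(x)[stay_id == sid] else x
  out <- lapply(dataset, pick)
  class(out) <- class(dataset)
  out
}

#' Label one stay
#'
#' @param dataset an `aki_site_data`.
#' @param stay_id stay to label (may be omitted for single-stay data).
#' @inheritParams label_stays
#' @return a list (`onset`, `stage`, `criterion`, `dialysis`) or `NULL` when
#'   no criterion fires. Errors if the baseline is unavailable.
#' @export
label_aki <- function(dataset, stay_id = NULL, ratio_window = "trailing7d",
                      scr4_requires_rise = TRUE) {
  if (is.null(stay_id)) {
    if (nrow(dataset$stays) != 1L) stopf("`stay_id` required for multi-stay data")
    stay_id <- dataset$stays$stay_id[1L]
  }
  one <- subset_stay(dataset, stay_id)
  row <- label_stays(one, ratio_window, scr4_requires_rise)
  if (!row$baseline_available) {
    stopf("baseline unavailable for stay '%s'", stay_id)
  }
  if (is.na(row$stage)) return(NULL)
  list(onset = row$onset, stage = row$stage, criterion = row$criterion,
       dialysis = row$dialysis)
}

#' Severity-group membership of an AKI event
#'
#' Groupings nest: `dialysis` (course includes RRT) within `stage3` within
#' `stage2_plus` within `all_stage`.
#'
#' @param event result of [label_aki()] (`NULL` for no AKI), or the labels
#'   table from [label_stays()] for the vectorized form.
#' @param grouping one of `"all_stage"`, `"stage2_plus"`, `"stage3"`,
#'   `"dialysis"`.
#' @return logical flag (or vector, for a labels table).
#' @export
in_group <- function(event,
                     grouping = c("all_stage", "stage2_plus", "stage3",
                                  "dialysis")) {
  grouping <- match.arg(grouping)
  if (is.data.frame(event)) {
    stage <- event$stage
    dial <- event$dialysis %||% rep(FALSE, nrow(event))
    return(switch(grouping,
                  all_stage = !is.na(stage),
                  stage2_plus = !is.na(stage) & stage >= 2L,
                  stage3 = !is.na(stage) & stage == 3L,
                  dialysis = !is.na(stage) & dial))
  }
  if (is.null(event)) return(FALSE)
  switch(grouping,
         all_stage = TRUE,
         stage2_plus = event$stage >= 2L,
         stage3 = event$stage == 3L,
         dialysis = isTRUE(event$dialysis))
}
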