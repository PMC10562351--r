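# Multi-site synthetic ICU cohort generator.
#
# Every stay carries event streams (creatinine, hourly urine output, hourly
# vitals, 6-hourly labs, medication administrations, dialysis events) on a
# per-stay clock with ICU admission at t = 0 h and a pre-admission lookback
# down to -168 h. AKI occurrence is drawn from a logistic model on
# standardized stay-level latent features (the "true risk model"), and AKI
# trajectories are injected so that the KDIGO labeler recovers the intended
# onset and stage. This gives a computable Bayes AUROC and known recoverable
# risk structure for every downstream test.

# Reference population moments used to standardize latents inside the true
# risk model. Fixed constants, NOT per-sample statistics: site covariate
# shifts therefore move the linear predictor, which is the point.
gen_reference <- function() {
  num <- rbind(
    data.frame(name = "age", mean = 65, sd = 15),
    data.frame(name = "weight", mean = 68, sd = 13),
    data.frame(name = "baseline_scr", mean = 0.93, sd = 0.24),
    data.frame(name = "urine_rate", mean = 1.10, sd = 0.25),
    data.frame(name = "urine_output", mean = 74.8, sd = 22),
    data.frame(name = "pulse", mean = 88, sd = 14),
    data.frame(name = "sysbp", mean = 125, sd = 18),
    data.frame(name = "dbp", mean = 70, sd = 10),
    data.frame(name = "mbp", mean = 88, sd = 8.5),
    data.frame(name = "temp", mean = 36.8, sd = 0.5),
    data.frame(name = "rr", mean = 18, sd = 3.5),
    data.frame(name = "spo2", mean = 96, sd = 2),
    data.frame(name = "bun", mean = 19.9, sd = 9.4),
    data.frame(name = "hemoglobin", mean = 10.8, sd = 1.8),
    data.frame(name = "platelet", mean = 190, sd = 80),
    data.frame(name = "wbc", mean = 10.5, sd = 3.5),
    data.frame(name = "lactate", mean = 15.9, sd = 8.4),
    data.frame(name = "bilirubin", mean = 0.79, sd = 0.42),
    data.frame(name = "pt", mean = 11.5, sd = 1.5),
    data.frame(name = "sodium", mean = 139, sd = 4),
    data.frame(name = "potassium", mean = 4.0, sd = 0.5),
    data.frame(name = "chloride", mean = 104, sd = 4),
    data.frame(name = "calcium", mean = 8.6, sd = 0.7),
    data.frame(name = "magnesium", mean = 2.0, sd = 0.3),
    data.frame(name = "phosphate", mean = 3.5, sd = 0.8),
    data.frame(name = "glucose", mean = 145, sd = 45),
    data.frame(name = "albumin", mean = 3.2, sd = 0.6),
    data.frame(name = "ast", mean = 42, sd = 28),
    data.frame(name = "alt", mean = 34, sd = 23),
    data.frame(name = "alkp", mean = 87, sd = 36),
    data.frame(name = "bicarbonate", mean = 24, sd = 4),
    data.frame(name = "crp", mean = 6.9, sd = 6.5),
    data.frame(name = "inr", mean = 1.2, sd = 0.25),
    data.frame(name = "aptt", mean = 32, sd = 6),
    data.frame(name = "ldh", mean = 271, sd = 113),
    data.frame(name = "ck", mean = 153, sd = 122),
    data.frame(name = "uric_acid", mean = 5.5, sd = 1.8),
    data.frame(name = "ammonia", mean = 38, sd = 16),
    data.frame(name = "troponin", mean = 0.066, sd = 0.087),
    data.frame(name = "bnp", mean = 495, sd = 650),
    data.frame(name = "ph", mean = 7.38, sd = 0.06),
    data.frame(name = "pao2", mean = 95, sd = 25),
    data.frame(name = "paco2", mean = 40, sd = 8),
    data.frame(name = "fio2", mean = 0.45, sd = 0.15),
    data.frame(name = "base_excess", mean = 0, sd = 4)
  )
  meds <- data.frame(
    name = c("diuretic", "ras_blocker", "vasopressor", "nsaid", "glyco_amino",
             "colistin", "amphotericin_b", "contrast_media", "beta_blocker",
             "ccb", "statin", "ppi", "steroid", "insulin", "opioid"),
    p = c(0.25, 0.20, 0.30, 0.12, 0.12,
          0.03, 0.02, 0.15, 0.25, 0.20, 0.25, 0.35, 0.20, 0.30, 0.40)
  )
  list(numeric = num, meds = meds)
}

GEN_VITAL_ITEMS <- c(pulse = 6, sysbp = 8, dbp = 6, mbp = 5, temp = 0.25,
                     rr = 1.5, spo2 = 1.0)
GEN_LAB_ITEMS <- c("bun", "hemoglobin", "platelet", "wbc", "lactate",
                   "bilirubin", "pt", "sodium", "potassium", "chloride",
                   "calcium", "magnesium", "phosphate", "glucose", "albumin",
                   "ast", "alt", "alkp", "bicarbonate", "crp", "inr", "aptt",
                   "ldh", "ck", "uric_acid", "ammonia", "troponin", "bnp",
                   "ph", "pao2", "paco2", "fio2", "base_excess")

# Injection geometry constants. The low-output rate 0.47 mL/kg/h is chosen so
# that a 6-h rolling mean first drops below the 0.5 threshold no earlier than
# one charting hour before the intended onset (normal hours are floored at
# 0.60 mL/kg/h), keeping the onset recovery error within one interval.
URINE_LOW_RATE <- 0.47
URINE_NORMAL_FLOOR <- 0.60
ONSET_MIN <- 54      # earliest feasible onset: covers the case window and
                     # the trailing 24-h urine lookback before it
POST_ONSET_MARGIN <- 36  # stay must continue this long after onset

#' Site configuration for the synthetic generator
#'
#' @param site_id unique site identifier.
#' @param n_stays number of includable stays to generate (>= 1).
#' @param aki_prevalence target fraction of `n_stays` with AKI, in (0, 1).
#' @param covariate_shift list with optional named numeric vectors `location`
#'   and `scale`, applied to latent stay-level features as
#'   `x' = location + scale * x` before risk is computed. Models site
#'   heterogeneity; the risk coefficients themselves are shared across sites.
#' @param era_split fraction of stays tagged `"temporal"` (held-out later
#'   era), in `[0, 1)`.
#' @param missing_prob probability that a given lab analyte is unobserved for
#'   a given stay (exercises mean imputation).
#' @param exclusion_fraction fraction (of `n_stays`, appended on top) of
#'   extra stays each violating one cohort exclusion criterion; 0 by default
#'   so the prevalence contract applies to the whole site.
#' @param ward_fraction fraction admitted from the ward (the rest from the
#'   emergency department, which changes the baseline-creatinine provenance).
#' @param seed per-site seed offset, mixed with the master seed.
#' @return a `site_config` list.
#' @export
site_config <- function(site_id, n_stays, aki_prevalence,
                        covariate_shift = list(), era_split = 0.25,
                        missing_prob = 0.1, exclusion_fraction = 0,
                        ward_fraction = 0.55, seed = 0L) {
  if (!is.character(site_id) || length(site_id) != 1L) {
    stopf("`site_id` must be a single string")
  }
  if (!is.numeric(n_stays) || n_stays < 1) stopf("`n_stays` must be >= 1")
  if (!is.numeric(aki_prevalence) || aki_prevalence <= 0 ||
      aki_prevalence >= 1) {
    stopf("`aki_prevalence` must lie strictly in (0, 1)")
  }
  if (era_split < 0 || era_split >= 1) stopf("`era_split` must be in [0, 1)")
  structure(list(site_id = site_id, n_stays = as.integer(n_stays),
                 aki_prevalence = aki_prevalence,
                 covariate_shift = covariate_shift, era_split = era_split,
                 missing_prob = missing_prob,
                 exclusion_fraction = exclusion_fraction,
                 ward_fraction = ward_fraction, seed = as.integer(seed)),
            class = "site_config")
}

#' True (generator) risk model: a linear-logistic score on latent features
#'
#' @param coefficients named numeric vector; names must be generator latent
#'   features (see `gen_reference()`). Coefficients act on standardized
#'   latents (fixed reference moments), so they are comparable across
#'   features.
#' @param intercept baseline log-odds offset (per-site intercepts are
#'   recalibrated to hit the configured prevalence).
#' @return a `true_risk_model` list.
#' @export
true_risk_model <- function(coefficients, intercept = 0) {
  ref <- gen_reference()
  known <- c(ref$numeric$name, ref$meds$name)
  bad <- setdiff(names(coefficients), known)
  if (length(bad)) stopf("unknown generator features: %s",
                         paste(bad, collapse = ", "))
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "true_risk_model")
}

#' Default ground-truth risk model
#'
#' Low urine output, elevated baseline creatinine, diuretic exposure,
#' tachycardia, hypotension, azotemia, age, lactate and vasopressor use drive
#' AKI risk, echoing the predictors that dominate clinical AKI models.
#' @return a `true_risk_model`.
#' @export
default_true_model <- function() {
  true_risk_model(c(
    urine_output = -1.1, baseline_scr = 0.8, diuretic = 0.9, pulse = 0.55,
    sysbp = -0.45, bun = 0.6, age = 0.5, lactate = 0.35, vasopressor = 0.5
  ))
}

# Standardize a latent matrix/table against the fixed reference moments and
# evaluate the true linear predictor.
true_linear_predictor <- function(latents, model) {
  ref <- gen_reference()
  lp <- rep(model$intercept, nrow(latents))
  for (nm in names(model$coefficients)) {
    x <- latents[[nm]]
    i <- match(nm, ref$numeric$name)
    if (!is.na(i)) {
      z <- (x - ref$numeric$mean[i]) / ref$numeric$sd[i]
    } else {
      p <- ref$meds$p[match(nm, ref$meds$name)]
      z <- (x - p) / sqrt(p * (1 - p))
    }
    lp <- lp + model$coefficients[[nm]] * z
  }
  lp
}

draw_latents <- function(n, ward_fraction) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  dt <- data.table(
    age = clip(rnorm(n, 65, 15), 21, 95),
    weight = clip(rnorm(n, 68, 13), 40, 130),
    baseline_scr = clip(rlnorm(n, log(0.9), 0.25), 0.5, 1.8),
    urine_rate = clip(rnorm(n, 1.1, 0.25), 0.65, 2.2),
    pulse = clip(rnorm(n, 88, 14), 40, 180),
    sysbp = clip(rnorm(n, 125, 18), 70, 220),
    dbp = clip(rnorm(n, 70, 10), 40, 120),
    temp = rnorm(n, 36.8, 0.5),
    rr = clip(rnorm(n, 18, 3.5), 8, 40),
    spo2 = clip(rnorm(n, 96, 2), 70, 100),
    bun = rlnorm(n, log(18), 0.45),
    hemoglobin = clip(rnorm(n, 10.8, 1.8), 5, 18),
    platelet = clip(rnorm(n, 190, 80), 15, 600),
    wbc = clip(rnorm(n, 10.5, 3.5), 1, 40),
    lactate = rlnorm(n, log(14), 0.5),
    bilirubin = rlnorm(n, log(0.7), 0.5),
    pt = clip(rnorm(n, 11.5, 1.5), 8, 30),
    sodium = rnorm(n, 139, 4), potassium = rnorm(n, 4, 0.5),
    chloride = rnorm(n, 104, 4), calcium = rnorm(n, 8.6, 0.7),
    magnesium = rnorm(n, 2, 0.3), phosphate = rnorm(n, 3.5, 0.8),
    glucose = clip(rnorm(n, 145, 45), 50, 500),
    albumin = clip(rnorm(n, 3.2, 0.6), 1, 5.5),
    ast = rlnorm(n, log(35), 0.6), alt = rlnorm(n, log(28), 0.6),
    alkp = rlnorm(n, log(80), 0.4), bicarbonate = rnorm(n, 24, 4),
    crp = rlnorm(n, log(5), 0.8), inr = clip(rnorm(n, 1.2, 0.25), 0.8, 6),
    aptt = rnorm(n, 32, 6), ldh = rlnorm(n, log(250), 0.4),
    ck = rlnorm(n, log(120), 0.7),
    uric_acid = clip(rnorm(n, 5.5, 1.8), 0.5, 15),
    ammonia = rlnorm(n, log(35), 0.4), troponin = rlnorm(n, log(0.04), 1),
    bnp = rlnorm(n, log(300), 1), ph = rnorm(n, 7.38, 0.06),
    pao2 = clip(rnorm(n, 95, 25), 40, 300), paco2 = rnorm(n, 40, 8),
    fio2 = clip(rnorm(n, 0.45, 0.15), 0.21, 1), base_excess = rnorm(n, 0, 4)
  )
  dt[, mbp := (sysbp + 2 * dbp) / 3]
  meds <- gen_reference()$meds
  for (i in seq_len(nrow(meds))) {
    dt[, (meds$name[i]) := rbinom(n, 1L, meds$p[i])]
  }
  dt[, sex := sample(c("M", "F"), n, replace = TRUE, prob = c(0.62, 0.38))]
  dt[, admission_source := ifelse(runif(n) < ward_fraction, "ward", "ED")]
  dt
}

apply_covariate_shift <- function(latents, shift) {
  loc <- shift$location %||% numeric(0)
  sc <- shift$scale %||% numeric(0)
  for (nm in union(names(loc), names(sc))) {
    if (!nm %in% names(latents)) stopf("covariate_shift names unknown latent '%s'", nm)
    s <- if (nm %in% names(sc)) sc[[nm]] else 1
    l <- if (nm %in% names(loc)) loc[[nm]] else 0
    set(latents, j = nm, value = l + s * latents[[nm]])
  }
  latents
}

# -- trajectory builders ------------------------------------------------------

# Irregular measurement grids: first time `t0`, then gaps ~ U(gap_lo, gap_hi)
# until `t_end`. Returns a long table (row_id, time).
irregular_times <- function(t0, t_end, gap_lo, gap_hi) {
  n <- length(t0)
  n_max <- pmax(1L, ceiling((t_end - t0) / gap_lo) + 1L)
  idx <- rep(seq_len(n), n_max)
  dt <- data.table(row_id = idx)
  dt[, gap := runif(.N, gap_lo, gap_hi)]
  dt[, gap := {g <- gap; g[1] <- 0; cumsum(g)}, by = row_id]
  dt[, time := t0[row_id] + gap]
  dt <- dt[time <= t_end[row_id]]
  dt[, gap := NULL]
  dt
}

build_base_creatinine <- function(stays, latents) {
  n <- nrow(stays)
  b <- latents$baseline_scr
  ward <- stays$admission_source == "ward"
  # pre-ICU values for ward admissions; the minimum equals the latent baseline
  k <- sample(2:5, n, replace = TRUE)
  pre <- data.table(row_id = rep(which(ward), k[ward]))
  pre[, time := -runif(.N, 6, 168)]
  pre[, value := b[row_id] * runif(.N, 1.02, 1.15)]
  pre[, is_min := seq_len(.N) == sample(.N, 1L), by = row_id]
  pre[is_min == TRUE, value := b[row_id]]
  pre[, is_min := NULL]
  # in-ICU values every 6-24 h
  t0 <- runif(n, 0.5, 3)
  icu <- irregular_times(t0, stays$discharge_time, 6, 24)
  icu[, value := b[row_id] * runif(.N, 1.0, 1.12)]
  # ED baseline provenance: the first available value is the baseline
  firsts <- icu[row_id %in% which(!ward), .(first_i = .I[1]), by = row_id]
  icu[firsts$first_i, value := b[row_id]]
  cr <- rbind(pre, icu)
  cr[, stay_id := stays$stay_id[row_id]]
  setorder(cr, row_id, time)
  cr[, .(stay_id, time, value)]
}

build_base_urine <- function(stays, latents) {
  hours <- pmax(1L, floor(stays$discharge_time))
  row_id <- rep(seq_len(nrow(stays)), hours)
  time <- as.numeric(sequence(hours))
  rate <- pmax(latents$urine_rate[row_id] + rnorm(length(row_id), 0, 0.05),
               URINE_NORMAL_FLOOR)
  data.table(stay_id = stays$stay_id[row_id], time = time,
             value = rate * latents$weight[row_id])
}

build_vitals <- function(stays, latents) {
  hours <- pmax(1L, floor(stays$discharge_time))
  row_id <- rep(seq_len(nrow(stays)), hours)
  time <- as.numeric(sequence(hours))
  m <- length(row_id)
  items <- names(GEN_VITAL_ITEMS)
  vals <- lapply(items, function(nm) {
    latents[[nm]][row_id] + rnorm(m, 0, GEN_VITAL_ITEMS[[nm]])
  })
  data.table(stay_id = stays$stay_id[rep(row_id, length(items))],
             time = rep(time, length(items)),
             item = rep(items, each = m),
             value = unlist(vals, use.names = FALSE))
}

build_labs <- function(stays, latents, missing_prob) {
  ref <- gen_reference()$numeric
  n <- nrow(stays)
  t0 <- runif(n, 0, 6)
  m <- pmax(1L, floor((stays$discharge_time - t0) / 6) + 1L)
  row_id <- rep(seq_len(n), m)
  time <- t0[row_id] + 6 * (sequence(m) - 1)
  out <- vector("list", length(GEN_LAB_ITEMS))
  for (i in seq_along(GEN_LAB_ITEMS)) {
    nm <- GEN_LAB_ITEMS[i]
    observed <- runif(n) >= missing_prob
    keep <- which(observed[row_id])
    rid <- row_id[keep]
    sd_i <- 0.15 * ref$sd[match(nm, ref$name)]
    out[[i]] <- data.table(stay_id = stays$stay_id[rid], time = time[keep],
                           item = nm,
                           value = latents[[nm]][rid] +
                             rnorm(length(rid), 0, sd_i))
  }
  rbindlist(out)
}

build_medications <- function(stays, latents) {
  meds <- gen_reference()$meds$name
  out <- vector("list", length(meds))
  for (i in seq_along(meds)) {
    nm <- meds[i]
    on_drug <- which(latents[[nm]] == 1L)
    if (!length(on_drug)) { out[[i]] <- NULL; next }
    t0 <- runif(length(on_drug), -24, 12)
    adm <- irregular_times(t0, stays$discharge_time[on_drug], 8, 24)
    adm[, drug_class := nm]
    adm[, stay_id := stays$stay_id[on_drug[row_id]]]
    out[[i]] <- adm[, .(stay_id, drug_class, time)]
  }
  rbindlist(out)
}

# -- AKI injection ------------------------------------------------------------

# Shared vectorized injection used by both the generator and `inject_aki()`.
# `inj` columns: stay_id, onset, stage, criterion, baseline, weight,
# discharge_time.
inject_streams <- function(creatinine, urine, inj) {
  inj <- as.data.table(inj)
  inj_c <- inj[criterion == "creatinine"]
  inj_u <- inj[criterion == "urine"]
  if (nrow(inj_c)) {
    cr <- creatinine
    cr <- merge(cr, inj_c[, .(stay_id, onset)], by = "stay_id", all.x = TRUE)
    cr <- cr[is.na(onset) | time < onset]
    cr[, onset := NULL]
    b <- inj_c$baseline
    v1 <- ifelse(inj_c$stage == 1L, pmax(1.55 * b, b + 0.33),
                 ifelse(inj_c$stage == 2L, 2.1 * b, 3.15 * b))
    at_onset <- data.table(stay_id = inj_c$stay_id, time = inj_c$onset,
                           value = v1)
    later <- irregular_times(inj_c$onset + runif(nrow(inj_c), 8, 16),
                             inj_c$discharge_time, 8, 16)
    later[, value := v1[row_id] *
            runif(.N, 1.0, ifelse(inj_c$stage[row_id] == 3L, 1.05, 1.03))]
    later[, stay_id := inj_c$stay_id[row_id]]
    cr <- rbind(cr, at_onset, later[, .(stay_id, time, value)])
    setorder(cr, stay_id, time)
    creatinine <- cr
  }
  if (nrow(inj_u)) {
    inj_u <- copy(inj_u)
    inj_u[, onset := round(onset)]  # urine is charted on the hourly grid
    # stage 1: 8 h below threshold; stage 2: 14 h; stage 3: 13 h of anuria.
    # Sub-threshold hours start so that the first 6-h rolling mean drops
    # below 0.5 mL/kg/h exactly at onset: for anuria that point depends on
    # the surrounding normal rate r (k zeros needed, (6-k)*r < 3).
    n_low <- c(8L, 14L, 13L)[inj_u$stage]
    r_eff <- pmax(inj_u$rate %||% rep(1.1, nrow(inj_u)), URINE_NORMAL_FLOOR)
    k_anuria <- pmin(pmax(floor(6 - 3 / r_eff + 1e-9) + 1L, 1L), 6L)
    start_off <- ifelse(inj_u$stage == 3L, k_anuria - 1L, 5L)
    low <- data.table(row_id = rep(seq_len(nrow(inj_u)), n_low))
    low[, time := inj_u$onset[row_id] - start_off[row_id] + seq_len(.N) - 1,
        by = row_id]
    low[, stay_id := inj_u$stay_id[row_id]]
    low[, low_value := ifelse(inj_u$stage[row_id] == 3L, 0,
                              URINE_LOW_RATE * inj_u$weight[row_id])]
    urine <- merge(urine, low[, .(stay_id, time, low_value)],
                   by = c("stay_id", "time"), all.x = TRUE)
    urine[!is.na(low_value), value := low_value]
    urine[, low_value := NULL]
    setorder(urine, stay_id, time)
  }
  list(creatinine = creatinine, urine = urine)
}

#' Inject an AKI episode into one stay's event streams
#'
#' Rewrites the creatinine or urine stream of `stay_id` so that the KDIGO
#' labeler fires at `onset` (within one charting interval) with exactly the
#' requested stage: creatinine rises to 1.55x / 2.1x / 3.15x the baseline, or
#' urine output falls below 0.5 mL/kg/h for a stage-calibrated span (anuria
#' for stage 3). Pre-onset segments satisfy no KDIGO criterion.
#'
#' @param dataset an `aki_site_data` object (see [generate_site()]).
#' @param stay_id stay to modify.
#' @param onset target onset in hours from admission; must be >= 36 and leave
#'   >= 30 h of stay after it. Urine-criterion onsets are rounded to the
#'   hourly charting grid.
#' @param stage target KDIGO stage, 1, 2 or 3.
#' @param criterion `"creatinine"` or `"urine"`.
#' @param seed integer seed for the post-onset trajectory noise.
#' @return the modified dataset.
#' @export
inject_aki <- function(dataset, stay_id, onset, stage,
                       criterion = c("creatinine", "urine"), seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(stage %in% 1:3)
  sid <- stay_id
  row <- dataset$stays[dataset$stays$stay_id == sid]
  if (nrow(row) != 1L) stopf("unknown stay_id '%s'", sid)
  if (onset < 30 + 6) stopf("onset %.1f h is too early (must be >= 36 h)", onset)
  if (onset + 30 > row$discharge_time) {
    stopf("onset %.1f h leaves < 30 h of stay before discharge (%.1f h)",
          onset, row$discharge_time)
  }
  bl <- baseline_creatinine(dataset, sid)
  w <- if ("weight" %in% names(row)) row$weight else 70
  ur_pre <- as.data.table(dataset$urine)[stay_id == sid & time < onset]
  rate <- if (nrow(ur_pre)) mean(ur_pre$value) / w else 1.1
  inj <- data.table(stay_id = sid, onset = onset, stage = as.integer(stage),
                    criterion = criterion, baseline = bl$value, weight = w,
                    rate = rate, discharge_time = row$discharge_time)
  new <- with_seed(seed, inject_streams(dataset$creatinine, dataset$urine, inj))
  dataset$creatinine <- new$creatinine
  dataset$urine <- new$urine
  dataset
}

# -- site generation ----------------------------------------------------------

#' Generate one synthetic ICU site
#'
#' @param config a [site_config()].
#' @param true_model a [true_risk_model()]; AKI is drawn from
#'   `Bernoulli(plogis(lp + c_site))` where `c_site` is calibrated so the
#'   expected prevalence equals `config$aki_prevalence`.
#' @param master_seed integer master seed; generation is a pure function of
#'   `(config, true_model, master_seed)`.
#' @return an `aki_site_data` list with elements `stays`, `creatinine`,
#'   `urine`, `vitals`, `labs`, `medications`, `dialysis` (the event
#'   streams), `latents` and `truth` (generator ground truth), and `config`.
#' @export
generate_site <- function(config, true_model = default_true_model(),
                          master_seed = 1L) {
  stopifnot(inherits(config, "site_config"))
  seed <- derive_seed(master_seed, config$seed, 101L)
  with_seed(seed, generate_site_impl(config, true_model))
}

generate_site_impl <- function(config, true_model) {
  n <- config$n_stays
  n_extra <- round(config$exclusion_fraction * n)
  n_tot <- n + n_extra
  lat <- draw_latents(n_tot, config$ward_fraction)
  lat <- apply_covariate_shift(lat, config$covariate_shift)
  # hourly urine volume in mL/h, the quantity the urine features observe
  set(lat, j = "urine_output", value = lat$urine_rate * lat$weight)
  lp <- true_linear_predictor(lat, true_model)

  core <- seq_len(n)
  f <- function(c0) mean(plogis(lp[core] + c0)) - config$aki_prevalence
  c_site <- if (all(abs(lp[core] - lp[core][1]) < 1e-12)) {
    qlogis(config$aki_prevalence) - lp[core][1]
  } else {
    uniroot(f, c(-40, 40), tol = 1e-10)$root
  }
  p <- plogis(lp + c_site)
  aki <- rep(0L, n_tot)
  aki[core] <- rbinom(n, 1L, p[core])

  discharge <- pmin(36 + rexp(n_tot, 1 / 30), 240)
  is_aki <- aki == 1L
  discharge[is_aki] <- pmin(pmax(discharge[is_aki],
                                 90 + rexp(sum(is_aki), 1 / 20)), 240)
  onset <- rep(NA_real_, n_tot)
  stage <- rep(NA_integer_, n_tot)
  crit <- rep(NA_character_, n_tot)
  if (any(is_aki)) {
    onset[is_aki] <- runif(sum(is_aki), ONSET_MIN,
                           discharge[is_aki] - POST_ONSET_MARGIN)
    stage[is_aki] <- sample(1:3, sum(is_aki), replace = TRUE,
                            prob = c(0.45, 0.25, 0.30))
    crit[is_aki] <- sample(c("creatinine", "urine"), sum(is_aki),
                           replace = TRUE)
    onset[is_aki & crit == "urine"] <- floor(onset[is_aki & crit == "urine"])
  }

  era <- rep("derivation", n_tot)
  n_temp <- round(config$era_split * n_tot)
  if (n_temp > 0) era[sample(n_tot, n_temp)] <- "temporal"

  stays <- data.table(
    stay_id = sprintf("%s-%05d", config$site_id, seq_len(n_tot)),
    site_id = config$site_id,
    patient_id = sprintf("%s-P%05d", config$site_id, seq_len(n_tot)),
    stay_number = 1L,
    age = lat$age, sex = lat$sex, weight = lat$weight,
    admission_source = lat$admission_source,
    admission_time = 0, discharge_time = discharge,
    esrd = FALSE, prior_rrt = FALSE, era = era
  )

  # extra stays violating one exclusion criterion each (off by default)
  if (n_extra > 0) {
    kinds <- rep(c("age_lt_20", "esrd_on_rrt", "aki_before_icu",
                   "hd_within_24h", "stay_lt_30h", "repeat_admission"),
                 length.out = n_extra)
    xi <- n + seq_len(n_extra)
    stays[xi[kinds == "age_lt_20"], age := runif(sum(kinds == "age_lt_20"), 16, 19.5)]
    lat$age[xi[kinds == "age_lt_20"]] <- stays$age[xi[kinds == "age_lt_20"]]
    stays[xi[kinds == "esrd_on_rrt"], `:=`(esrd = TRUE, prior_rrt = TRUE)]
    stays[xi[kinds == "stay_lt_30h"],
          discharge_time := runif(sum(kinds == "stay_lt_30h"), 8, 29)]
    discharge[xi[kinds == "stay_lt_30h"]] <-
      stays$discharge_time[xi[kinds == "stay_lt_30h"]]
    rep_i <- xi[kinds == "repeat_admission"]
    if (length(rep_i)) {
      stays[rep_i, `:=`(patient_id = stays$patient_id[seq_along(rep_i)],
                        stay_number = 2L)]
    }
    stays[xi[kinds == "aki_before_icu"], admission_source := "ward"]
    lat$admission_source[xi[kinds == "aki_before_icu"]] <- "ward"
  } else {
    kinds <- character(0)
  }

  creatinine <- build_base_creatinine(stays, lat)
  urine <- build_base_urine(stays, lat)
  vitals <- build_vitals(stays, lat)
  labs <- build_labs(stays, lat, config$missing_prob)
  medications <- build_medications(stays, lat)

  # inject AKI trajectories
  if (any(is_aki)) {
    inj <- data.table(stay_id = stays$stay_id[is_aki], onset = onset[is_aki],
                      stage = stage[is_aki], criterion = crit[is_aki],
                      baseline = lat$baseline_scr[is_aki],
                      weight = lat$weight[is_aki],
                      rate = lat$urine_rate[is_aki],
                      discharge_time = discharge[is_aki])
    new <- inject_streams(creatinine, urine, inj)
    creatinine <- new$creatinine
    urine <- new$urine
    onset[is_aki & crit == "urine"] <-
      round(onset[is_aki & crit == "urine"])
  }

  # dialysis: about half of stage-3 AKI receives RRT after onset
  dial_i <- which(is_aki & stage == 3L & runif(n_tot) < 0.5)
  dialysis <- data.table(stay_id = character(0), time = numeric(0))
  if (length(dial_i)) {
    dialysis <- data.table(stay_id = stays$stay_id[dial_i],
                           time = onset[dial_i] + runif(length(dial_i), 4, 24))
  }

  # exclusion-type stream edits
  if (n_extra > 0) {
    xi <- n + seq_len(n_extra)
    pre_aki <- stays$stay_id[xi[kinds == "aki_before_icu"]]
    if (length(pre_aki)) {
      b <- lat$baseline_scr[match(pre_aki, stays$stay_id)]
      creatinine <- creatinine[!(stay_id %in% pre_aki & time < 0)]
      creatinine <- rbind(creatinine, data.table(
        stay_id = rep(pre_aki, each = 2L),
        time = rep(c(-96, -60), length(pre_aki)),
        value = as.vector(rbind(b, 1.9 * b))
      ))
      setorder(creatinine, stay_id, time)
    }
    hd24 <- stays$stay_id[xi[kinds == "hd_within_24h"]]
    if (length(hd24)) {
      dialysis <- rbind(dialysis, data.table(
        stay_id = hd24, time = runif(length(hd24), 2, 20)))
    }
    short <- stays$stay_id[xi[kinds == "stay_lt_30h"]]
    if (length(short)) {
      lim <- stays[match(short, stay_id), discharge_time]
      trunc_stream <- function(s) {
        s <- merge(s, data.table(stay_id = short, lim = lim),
                   by = "stay_id", all.x = TRUE)
        s <- s[is.na(lim) | time <= lim]
        s[, lim := NULL]
        s
      }
      creatinine <- trunc_stream(creatinine)
      urine <- trunc_stream(urine)
      vitals <- trunc_stream(vitals)
      labs <- trunc_stream(labs)
      medications <- trunc_stream(medications)
      setorder(creatinine, stay_id, time)
    }
  }

  lat_out <- copy(lat)
  lat_out[, stay_id := stays$stay_id]
  setcolorder(lat_out, "stay_id")
  truth <- data.table(stay_id = stays$stay_id, lp = lp, p = p, aki = aki,
                      onset = onset, stage = stage, criterion = crit,
                      exclusion_kind = c(rep(NA_character_, n), kinds))
  structure(list(stays = stays, creatinine = creatinine, urine = urine,
                 vitals = vitals, labs = labs, medications = medications,
                 dialysis = dialysis, latents = lat_out, truth = truth,
                 config = config),
            class = "aki_site_data")
}

#' Generate several sites at once
#'
#' @param configs list of [site_config()]s with unique `site_id`s.
#' @param true_model shared [true_risk_model()]; the coefficient vector is
#'   identical across sites so federated pooling has signal.
#' @param master_seed integer master seed.
#' @return named list of `aki_site_data`, one per site.
#' @export
generate_multisite <- function(configs, true_model = default_true_model(),
                               master_seed = 1L) {
  if (!length(configs)) stopf("`configs` must contain at least one site")
  ids <- vapply(configs, function(x) x$site_id, "")
  if (anyDuplicated(ids)) stopf("site_ids must be unique")
  out <- lapply(configs, generate_site, true_model = true_model,
                master_seed = master_seed)
  names(out) <- ids
  out
}

#' Bayes AUROC: discrimination of the true risk score
#'
#' Recomputes the true linear predictor from the stored latent features and
#' scores it against the labels the KDIGO labeler assigns. This is the
#' ceiling no trained classifier should exceed (beyond sampling noise).
#'
#' @param dataset an `aki_site_data` object.
#' @param true_model risk model to score with; defaults to the one implied by
#'   the stored latents (i.e. [default_true_model()] unless overridden).
#' @param labels optional precomputed 0/1 labels (must align with
#'   `dataset$stays`); if omitted the labeler is run.
#' @return AUROC in `[0, 1]`.
#' @export
bayes_auroc <- function(dataset, true_model = default_true_model(),
                        labels = NULL) {
  lp <- true_linear_predictor(dataset$latents, true_model)
  if (is.null(labels)) {
    lab <- label_stays(dataset)
    labels <- as.integer(!is.na(lab$stage))
  }
  if (length(unique(labels)) < 2L) {
    stopf("bayes_auroc undefined: labels contain a single class")
  }
  auroc(lp, labels)
}

# -- persistence --------------------------------------------------------------

#' Write a site dataset as a directory of CSV files
#'
#' One directory per site with `stays.csv`, `events_creatinine.csv`,
#' `events_urine.csv`, `events_vitals.csv`, `events_labs.csv`,
#' `medications.csv`, `dialysis.csv` (times in decimal hours, 0 at
#' admission), plus `truth.csv`/`latents.csv` when `include_truth`.
#'
#' @param dataset an `aki_site_data`.
#' @param dir output directory (created if needed).
#' @param include_truth also write generator ground truth.
#' @return `dir`, invisibly.
#' @export
write_site_data <- function(dataset, dir, include_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(dataset$stays, file.path(dir, "stays.csv"))
  fwrite(dataset$creatinine, file.path(dir, "events_creatinine.csv"))
  fwrite(dataset$urine, file.path(dir, "events_urine.csv"))
  fwrite(dataset$vitals, file.path(dir, "events_vitals.csv"))
  fwrite(dataset$labs, file.path(dir, "events_labs.csv"))
  fwrite(dataset$medications, file.path(dir, "medications.csv"))
  fwrite(dataset$dialysis, file.path(dir, "dialysis.csv"))
  if (include_truth) {
    fwrite(dataset$truth, file.path(dir, "truth.csv"))
    fwrite(dataset$latents, file.path(dir, "latents.csv"))
  }
  invisible(dir)
}

#' Read a site dataset written by [write_site_data()]
#' @param dir directory containing the CSV files.
#' @return an `aki_site_data` (without the generating `config`).
#' @export
read_site_data <- function(dir) {
  rd <- function(f) fread(file.path(dir, f))
  out <- list(stays = rd("stays.csv"),
              creatinine = rd("events_creatinine.csv"),
              urine = rd("events_urine.csv"),
              vitals = rd("events_vitals.csv"),
              labs = rd("events_labs.csv"),
              medications = rd("medications.csv"),
              dialysis = rd("dialysis.csv"),
              config = NULL)
  if (file.exists(file.path(dir, "truth.csv"))) out$truth <- rd("truth.csv")
  if (file.exists(file.path(dir, "latents.csv"))) out$latents <- rd("latents.csv")
  structure(out, class = "aki_site_data")
}
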