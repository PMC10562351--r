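# Independent brute-force oracles and fixture builders shared across tests.
# The oracles deliberately use plain loops over all measurement pairs and
# spans -- no code shared with the package implementation.

library(data.table)

# ---- brute-force AUROC by pair counting ------------------------------------
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1 else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# ---- brute-force KDIGO labeler ---------------------------------------------
# Mirrors the documented rules by exhaustive scans: all 48-h / 168-h
# creatinine pairs, all 6/12/24-h urine spans, dialysis events.
oracle_label <- function(stay) {
  st <- stay$stays
  cr <- as.data.frame(stay$creatinine)
  cr <- cr[order(cr$time), ]
  ur <- as.data.frame(stay$urine)
  ur <- ur[order(ur$time), ]
  dial <- as.data.frame(stay$dialysis)

  # baseline
  elig <- cr[cr$value < 4.0, ]
  if (st$admission_source == "ward") {
    pre <- elig[elig$time < 0, ]
    if (!nrow(pre)) return(list(error = "baseline"))
    i <- order(pre$value, pre$time)[1]
    baseline <- pre$value[i]
  } else {
    if (!nrow(elig)) return(list(error = "baseline"))
    i <- which.min(elig$time)
    baseline <- elig$value[i]
  }

  events <- list()
  s1_before <- rep(FALSE, nrow(cr))
  fired1 <- FALSE
  for (i in seq_len(nrow(cr))) {
    t <- cr$time[i]; v <- cr$value[i]
    s <- 0
    for (j in seq_len(nrow(cr))) {
      if (cr$time[j] > t - 48 && cr$time[j] <= t && v - cr$value[j] >= 0.3) s <- max(s, 1)
    }
    ref <- baseline
    for (j in seq_len(nrow(cr))) {
      if (cr$time[j] > t - 168 && cr$time[j] <= t) ref <- min(ref, cr$value[j])
    }
    if (v >= 1.5 * ref) s <- max(s, 1)
    if (v >= 2.0 * ref) s <- max(s, 2)
    if (v >= 3.0 * ref) s <- max(s, 3)
    if (s >= 1) fired1 <- TRUE
    if (v >= 4.0 && fired1) s <- max(s, 3)
    if (s >= 1) events[[length(events) + 1]] <- list(time = t, stage = s,
                                                     criterion = "creatinine")
  }

  w <- st$weight
  if (nrow(ur)) {
    for (i in seq_len(nrow(ur))) {
      t <- ur$time[i]
      for (L in c(6, 12, 24)) {
        if (t < L) next
        inw <- which(ur$time > t - L & ur$time <= t)
        if (!length(inw)) next
        times <- ur$time[inw]
        gaps <- diff(c(t - L, times))
        if (any(gaps > 2)) next
        rate <- mean(ur$value[inw]) / w
        s <- 0
        if (L == 6 && rate < 0.5) s <- 1
        if (L == 12 && rate < 0.5) s <- 2
        if (L == 24 && rate < 0.3) s <- 3
        if (L == 12 && all(ur$value[inw] == 0)) s <- 3
        if (s >= 1) events[[length(events) + 1]] <- list(time = t, stage = s,
                                                         criterion = "urine")
      }
    }
  }
  if (nrow(dial)) {
    for (i in seq_len(nrow(dial))) {
      events[[length(events) + 1]] <- list(time = dial$time[i], stage = 3,
                                           criterion = "dialysis")
    }
  }
  ev <- Filter(function(e) e$time >= 0, events)
  if (!length(ev)) return(NULL)
  times <- vapply(ev, `[[`, numeric(1), "time")
  stages <- vapply(ev, `[[`, numeric(1), "stage")
  crits <- vapply(ev, `[[`, character(1), "criterion")
  pri <- match(crits, c("creatinine", "urine", "dialysis"))
  o <- order(times, pri)[1]
  list(onset = times[o], stage = max(stages), criterion = crits[o])
}

# Random stay with short, adversarial creatinine/urine series for the
# oracle-equivalence scans.
random_oracle_stay <- function(seed) {
  set.seed(seed)
  discharge <- runif(1, 40, 110)
  source <- sample(c("ward", "ED"), 1)
  weight <- runif(1, 45, 110)
  stays <- data.table(stay_id = "X", site_id = "T", patient_id = "P",
                      stay_number = 1L, age = 60, sex = "M", weight = weight,
                      admission_source = source, admission_time = 0,
                      discharge_time = discharge, esrd = FALSE,
                      prior_rrt = FALSE, era = "derivation")
  n_pre <- if (source == "ward") sample(1:4, 1) else sample(0:2, 1)
  pre_t <- sort(-runif(n_pre, 2, 160))
  icu_t <- sort(runif(sample(3:9, 1), 0, discharge))
  cr <- data.table(stay_id = "X", time = c(pre_t, icu_t),
                   value = round(runif(n_pre + length(icu_t), 0.4, 4.6), 2))
  hours <- seq_len(floor(discharge))
  keep <- runif(length(hours)) > 0.15
  ur <- data.table(stay_id = "X", time = as.numeric(hours[keep]),
                   value = round(pmax(
                     weight * (runif(sum(keep), 0, 1.1) - 0.15), 0), 1))
  dial <- if (runif(1) < 0.15) {
    data.table(stay_id = "X", time = runif(1, 1, discharge))
  } else data.table(stay_id = character(0), time = numeric(0))
  structure(list(stays = stays, creatinine = cr, urine = ur,
                 vitals = data.table(stay_id = character(0), time = numeric(0),
                                     item = character(0), value = numeric(0)),
                 labs = data.table(stay_id = character(0), time = numeric(0),
                                   item = character(0), value = numeric(0)),
                 medications = data.table(stay_id = character(0),
                                          drug_class = character(0),
                                          time = numeric(0)),
                 dialysis = dial, config = NULL),
            class = "aki_site_data")
}

# ---- minimal hand-built dataset builders -----------------------------------
make_stay_dataset <- function(stay_rows, creatinine = NULL, urine = NULL,
                              dialysis = NULL, medications = NULL,
                              vitals = NULL, labs = NULL) {
  empty_ev <- data.table(stay_id = character(0), time = numeric(0),
                         value = numeric(0))
  empty_item <- data.table(stay_id = character(0), time = numeric(0),
                           item = character(0), value = numeric(0))
  structure(list(
    stays = as.data.table(stay_rows),
    creatinine = if (is.null(creatinine)) empty_ev else as.data.table(creatinine),
    urine = if (is.null(urine)) empty_ev else as.data.table(urine),
    vitals = if (is.null(vitals)) empty_item else as.data.table(vitals),
    labs = if (is.null(labs)) empty_item else as.data.table(labs),
    medications = if (is.null(medications)) {
      data.table(stay_id = character(0), drug_class = character(0),
                 time = numeric(0))
    } else as.data.table(medications),
    dialysis = if (is.null(dialysis)) {
      data.table(stay_id = character(0), time = numeric(0))
    } else as.data.table(dialysis),
    config = NULL), class = "aki_site_data")
}

basic_stay_row <- function(stay_id, ..., patient_id = paste0("P", stay_id)) {
  defaults <- list(stay_id = stay_id, site_id = "T", patient_id = patient_id,
                   stay_number = 1L, age = 55, sex = "M", weight = 70,
                   admission_source = "ward", admission_time = 0,
                   discharge_time = 60, esrd = FALSE, prior_rrt = FALSE,
                   era = "derivation")
  utils::modifyList(defaults, list(...))
}

# Attrition fixture: six stays violating one exclusion criterion each plus
# one clean stay. Every stay carries a labelable creatinine series.
exclusion_fixture <- function() {
  rows <- rbind(
    as.data.table(basic_stay_row("clean")),
    as.data.table(basic_stay_row("young", age = 18)),
    as.data.table(basic_stay_row("esrd", esrd = TRUE, prior_rrt = TRUE)),
    as.data.table(basic_stay_row("preaki")),
    as.data.table(basic_stay_row("hd24")),
    as.data.table(basic_stay_row("short", discharge_time = 20)),
    as.data.table(basic_stay_row("repeat", patient_id = "Pclean",
                                 stay_number = 2L))
  )
  flat <- function(id) data.table(stay_id = id,
                                  time = c(-30, 5, 25), value = c(1.0, 1.0, 1.05))
  cr <- rbind(flat("clean"), flat("young"), flat("esrd"),
              data.table(stay_id = "preaki", time = c(-80, -50, 5),
                         value = c(0.8, 1.6, 0.85)),
              flat("hd24"),
              data.table(stay_id = "short", time = c(-10, 5),
                         value = c(1.0, 1.0)),
              flat("repeat"))
  dial <- data.table(stay_id = "hd24", time = 10)
  make_stay_dataset(rows, creatinine = cr, dialysis = dial)
}

# Small synthetic feature table (already-extracted form) for model-layer and
# federated tests that do not need the full generator.
make_feature_table <- function(n, d = 6, seed = 1, era_frac = 0.25,
                               site_id = "A", beta = NULL, shift = 0) {
  set.seed(seed)
  if (is.null(beta)) beta <- c(1.5, -1.2, 0.9, rep(0, d - 3))
  X <- matrix(rnorm(n * d), n, d) + shift
  colnames(X) <- paste0("f", seq_len(d))
  y <- rbinom(n, 1, plogis(as.numeric(X %*% beta) - shift * sum(beta)))
  era <- rep("derivation", n)
  era[sample(n, round(era_frac * n))] <- "temporal"
  dt <- data.table(stay_id = sprintf("%s-%04d", site_id, seq_len(n)),
                   site_id = site_id, era = era, window_start = 30,
                   window_end = 36, role = "control", label = y)
  out <- cbind(dt, as.data.table(X))
  setattr(out, "class", c("aki_features", class(out)))
  setattr(out, "feature_names", colnames(X))
  out
}

# Registry matching the synthetic feature tables above.
synth_registry <- function(d) {
  feature_registry(data.frame(name = paste0("f", seq_len(d)),
                              source = "labs", aggregation = "mean",
                              kind = "numeric"))
}

# Cached heavy fixtures for the acceptance suite (computed once per session).
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
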