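test_that("baseline creatinine follows admission-source provenance", {
  d <- make_stay_dataset(
    basic_stay_row("w1"),
    creatinine = data.table(stay_id = "w1", time = c(-48, -24, 5),
                            value = c(1.2, 0.9, 1.0)))
  b <- baseline_creatinine(d, "w1")
  expect_equal(b$value, 0.9)
  expect_equal(b$provenance, "pre_icu_lowest")

  d <- make_stay_dataset(
    basic_stay_row("e1", admission_source = "ED"),
    creatinine = data.table(stay_id = "e1", time = c(1, 12),
                            value = c(1.1, 0.8)))
  b <- baseline_creatinine(d, "e1")
  expect_equal(b$value, 1.1)
  expect_equal(b$provenance, "ed_first_available")

  # values >= 4 mg/dL are never candidates
  d <- make_stay_dataset(
    basic_stay_row("w2"),
    creatinine = data.table(stay_id = "w2", time = c(-40, -20, 3),
                            value = c(4.2, 1.0, 1.1)))
  expect_equal(baseline_creatinine(d, "w2")$value, 1.0)

  # no eligible value -> explicit error
  d <- make_stay_dataset(
    basic_stay_row("w3"),
    creatinine = data.table(stay_id = "w3", time = 5, value = 1.0))
  expect_error(baseline_creatinine(d, "w3"), "baseline unavailable")
})

test_that("creatinine staging fires the documented thresholds", {
  # 0.3 mg/dL rise within 48 h
  ev <- stage_creatinine(data.frame(time = c(0, 24), value = c(1.0, 1.3)),
                         baseline = 1.0)
  expect_equal(ev$time, 24)
  expect_equal(ev$stage, 1L)

  # 2.0x baseline -> stage 2 (rise outside the 48-h delta window)
  ev <- stage_creatinine(data.frame(time = c(0, 72), value = c(1.0, 2.0)),
                         baseline = 1.0)
  expect_equal(ev[time == 72, stage], 2L)

  # constant series: nothing fires
  ev <- stage_creatinine(data.frame(time = c(0, 24, 48), value = rep(1, 3)),
                         baseline = 1.0)
  expect_equal(nrow(ev), 0L)

  # 3x baseline -> stage 3; >= 4 without acute rise does not fire by itself
  ev <- stage_creatinine(data.frame(time = c(0, 50), value = c(1.2, 3.7)),
                         baseline = 1.2)
  expect_equal(ev[time == 50, stage], 3L)
  ev <- stage_creatinine(data.frame(time = 0, value = 4.4), baseline = 4.4)
  expect_equal(nrow(ev), 0L)
})

test_that("urine staging fires on 6/12/24-h spans and anuria", {
  hours <- function(n) as.numeric(seq_len(n))
  # 30 mL/h at 70 kg = 0.43 mL/kg/h -> stage 1 at hour 6
  ev <- stage_urine(data.frame(time = hours(6), value = rep(30, 6)), 70)
  expect_equal(ev$time[1], 6)
  expect_equal(ev$stage[1], 1L)

  # 40 mL/h at 70 kg = 0.57 mL/kg/h -> nothing
  ev <- stage_urine(data.frame(time = hours(48), value = rep(40, 48)), 70)
  expect_equal(nrow(ev), 0L)

  # 12 h of anuria -> stage 3
  ev <- stage_urine(data.frame(time = hours(12), value = rep(0, 12)), 70)
  expect_equal(max(ev$stage), 3L)

  # charting gap > 2 h breaks the span
  t_gap <- c(1, 2, 3, 6, 7, 8)  # 3-h hole between hours 3 and 6
  ev <- stage_urine(data.frame(time = t_gap, value = rep(20, 6)), 70)
  expect_false(any(ev$time == 8 & ev$stage == 1L))

  expect_error(stage_urine(data.frame(time = 1, value = 10), weight = 0),
               "weight")
})

test_that("label_aki combines criteria: earliest onset, maximum stage", {
  # urine fires at 35 h, creatinine at 40 h -> onset 35, criterion urine
  d <- make_stay_dataset(
    basic_stay_row("s1", discharge_time = 80),
    creatinine = data.table(stay_id = "s1", time = c(-24, 10, 40),
                            value = c(1.0, 1.0, 1.6)),
    urine = data.table(stay_id = "s1", time = as.numeric(1:40),
                       value = c(rep(80, 29), rep(30, 11))))
  ev <- label_aki(d, "s1")
  expect_equal(ev$onset, 35)
  expect_equal(ev$criterion, "urine")

  # dialysis alone -> stage 3 at the event time
  d <- make_stay_dataset(
    basic_stay_row("s2", discharge_time = 80),
    creatinine = data.table(stay_id = "s2", time = c(-24, 10),
                            value = c(1.0, 1.0)),
    dialysis = data.table(stay_id = "s2", time = 50))
  ev <- label_aki(d, "s2")
  expect_equal(ev$stage, 3L)
  expect_equal(ev$onset, 50)
  expect_equal(ev$criterion, "dialysis")

  # clean stay -> NULL
  d <- make_stay_dataset(
    basic_stay_row("s3"),
    creatinine = data.table(stay_id = "s3", time = c(-24, 10),
                            value = c(1.0, 1.05)))
  expect_null(label_aki(d, "s3"))
})

test_that("severity groupings nest as documented", {
  ev2 <- list(onset = 40, stage = 2L, criterion = "creatinine",
              dialysis = FALSE)
  expect_true(in_group(ev2, "all_stage"))
  expect_true(in_group(ev2, "stage2_plus"))
  expect_false(in_group(ev2, "stage3"))
  expect_false(in_group(ev2, "dialysis"))
  expect_false(in_group(NULL, "all_stage"))
  ev1 <- list(onset = 40, stage = 1L, criterion = "urine", dialysis = FALSE)
  expect_false(in_group(ev1, "stage3"))
})

test_that("labeler matches the brute-force oracle on random stays", {
  mismatches <- 0
  for (s in 1:150) {
    stay <- random_oracle_stay(s)
    lab <- label_stays(stay)
    orc <- oracle_label(stay)
    if (!is.null(orc) && !is.null(orc$error)) next  # baseline unavailable
    if (!lab$baseline_available) next
    if (is.null(orc)) {
      if (!is.na(lab$stage)) mismatches <- mismatches + 1
    } else {
      ok <- !is.na(lab$stage) && lab$onset == orc$onset &&
        lab$stage == orc$stage && lab$criterion == orc$criterion
      if (!ok) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("raising creatinine never lowers the stage or delays onset", {
  for (s in 1:30) {
    stay <- random_oracle_stay(1000 + s)
    lab <- label_stays(stay)
    if (!lab$baseline_available) next
    bumped <- stay
    cr <- copy(stay$creatinine)
    i <- sample(which(cr$time >= 0), 1)
    cr[i, value := value + runif(1, 0.2, 1.5)]
    bumped$creatinine <- cr
    lab2 <- label_stays(bumped)
    if (!is.na(lab$stage)) {
      expect_false(is.na(lab2$stage))
      expect_gte(lab2$stage, lab$stage)
      expect_lte(lab2$onset, lab$onset)
    }
  }
})
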