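test_that("case windows respect the 24-h lead time convention", {
  w <- case_window(100)
  expect_equal(c(w$start, w$end), c(70, 76))
  w <- case_window(30)
  expect_equal(c(w$start, w$end), c(0, 6))
  expect_null(case_window(20))
  # alternative anchoring via the config flag
  w <- case_window(100, window_anchor = "start_24h_before")
  expect_equal(c(w$start, w$end), c(76, 82))
})

test_that("control windows are uniform over the feasible range", {
  set.seed(1)
  w <- control_window(60)
  expect_gte(w$start, 30); expect_lte(w$start, 54)
  expect_equal(w$end - w$start, 6)
  expect_equal(control_window(36)$start, 30)
  expect_null(control_window(31))
})

test_that("window assignment is reproducible and logs skipped stays", {
  cfg <- site_config("A", 80, 0.3, seed = 12)
  d <- generate_site(cfg, master_seed = 12)
  lab <- label_stays(d)
  w1 <- build_windows(d, lab, seed = 5)
  w2 <- build_windows(d, lab, seed = 5)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  w3 <- build_windows(d, lab, seed = 6)
  expect_false(identical(w1$window_start, w3$window_start))
  # constructed short stay is skipped with a reason
  short <- make_stay_dataset(
    basic_stay_row("sh", discharge_time = 31),
    creatinine = data.table(stay_id = "sh", time = c(-10, 2),
                            value = c(1, 1)))
  ws <- build_windows(short, label_stays(short))
  expect_equal(nrow(ws), 0L)
  expect_equal(attr(ws, "skipped")$reason, "stay_shorter_than_36h")
})

test_that("extraction honors aggregations and the 7-day drug lookback", {
  row <- basic_stay_row("x", discharge_time = 200, weight = 70, age = 61)
  d <- make_stay_dataset(
    row,
    creatinine = data.table(stay_id = "x", time = c(-24, 100, 130),
                            value = c(1.0, 1.0, 1.2)),
    urine = data.table(stay_id = "x", time = as.numeric(1:200), value = 50),
    vitals = data.table(stay_id = "x", time = c(131, 133, 135),
                        item = "pulse", value = c(80, 90, 100)),
    labs = data.table(stay_id = "x", time = 132, item = "bun", value = 22),
    medications = data.table(stay_id = "x",
                             drug_class = c("diuretic", "nsaid"),
                             time = c(136 - 100, 136 - 200)))
  w <- data.table(stay_id = "x", window_start = 130, window_end = 136,
                  role = "control")
  lab <- label_stays(d)
  f <- extract_features(d, w, feature_registry("parsimonious_21"), lab)
  expect_equal(f$urine_24h, 24 * 50)      # trailing 24-h sum
  expect_equal(f$urine_8h, 8 * 50)
  expect_equal(f$diuretic, 1)             # given 100 h before window end
  expect_equal(f$nsaid, 0)                # outside the 7-day lookback
  expect_equal(f$pulse, 90)               # in-window mean
  expect_equal(f$bun, 22)
  expect_equal(f$creatinine, 1.2)         # most recent value at window end
  expect_equal(f$age, 61)
  expect_true(is.na(f$lactate))           # no record -> missing mask
  expect_equal(f$label, 0L)
})

test_that("registry composition is fixed and fingerprinted", {
  full <- feature_registry("full_60")
  pars <- feature_registry("parsimonious_21")
  expect_equal(nrow(full), 60L)
  expect_equal(nrow(pars), 21L)
  expect_true(all(pars$name %in% full$name))
  expect_false(identical(attr(full, "registry_hash"),
                         attr(pars, "registry_hash")))
  expect_error(feature_registry(data.frame(name = "a")), "columns")
})

test_that("mean imputation fills from the fitting set only", {
  reg <- feature_registry(data.frame(
    name = c("lab1", "med1"), source = c("labs", "medications"),
    aggregation = c("mean", "binary_7d_lookback"),
    kind = c("numeric", "binary")))
  ft <- data.table(stay_id = c("a", "b", "c", "d"), site_id = "T",
                   era = c("derivation", "derivation", "derivation",
                           "temporal"),
                   window_start = 30, window_end = 36, role = "control",
                   label = 0L,
                   lab1 = c(1, 3, NA, 100), med1 = c(1, NA, 0, NA))
  setattr(ft, "class", c("aki_features", class(ft)))
  setattr(ft, "feature_names", c("lab1", "med1"))
  setattr(ft, "registry_hash", attr(reg, "registry_hash"))
  imp <- fit_imputer(ft[era == "derivation"], reg)
  expect_equal(unname(imp$means[["lab1"]]), 2)   # temporal 100 never leaks
  out <- apply_imputer(imp, ft)
  expect_equal(out$lab1, c(1, 3, 2, 100))
  expect_equal(out$med1, c(1, 0, 0, 0))          # binary fill is 0
  # no missing entries -> identity
  out2 <- apply_imputer(imp, out)
  expect_identical(as.data.frame(out2), as.data.frame(out))
  # a feature observed nowhere is a hard error
  ft_bad <- copy(ft)[, lab1 := NA_real_]
  setattr(ft_bad, "feature_names", c("lab1", "med1"))
  expect_error(fit_imputer(ft_bad[era == "derivation"], reg), "lab1")
})

test_that("the full feature matrix is reproducible end to end", {
  cfg <- site_config("A", 60, 0.3, seed = 13)
  d <- generate_site(cfg, master_seed = 13)
  lab <- label_stays(d)
  reg <- feature_registry("parsimonious_21")
  f1 <- extract_features(d, build_windows(d, lab, seed = 2), reg, lab)
  f2 <- extract_features(d, build_windows(d, lab, seed = 2), reg, lab)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # one feature vector per includable stay
  w <- build_windows(d, lab, seed = 2)
  expect_equal(nrow(f1) + nrow(attr(w, "skipped")), nrow(d$stays))
  expect_equal(anyDuplicated(f1$stay_id), 0L)
})
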