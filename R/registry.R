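# Feature registries: the ordered dictionary of model inputs.
#
# A registry row maps a feature name to a source stream and an aggregation
# over the 6-h feature window. The two shipped defaults are `full_60`
# (60 features: demographics, vitals, labs, urine sums, drug exposures) and
# `parsimonious_21` (the 21-feature reduced set: urine output over the
# trailing 8 and 24 h, diuretic use, pulse, creatinine, systolic/mean blood
# pressure, body temperature, BUN, renin-angiotensin-system blocker use,
# respiratory rate, age, hemoglobin, platelets, WBC, lactate, total
# bilirubin, prothrombin time, vasopressor use, NSAID use, and
# gentamicin/vancomycin exposure).

PARS_VITALS <- c("pulse", "sysbp", "mbp", "temp", "rr")
PARS_LABS   <- c("bun", "hemoglobin", "platelet", "wbc", "lactate",
                 "bilirubin", "pt")
PARS_MEDS   <- c("diuretic", "ras_blocker", "vasopressor", "nsaid",
                 "glyco_amino")

EXTRA_VITALS <- c("dbp", "spo2")
EXTRA_LABS <- c("sodium", "potassium", "chloride", "calcium", "magnesium",
                "phosphate", "glucose", "albumin", "ast", "alt", "alkp",
                "bicarbonate", "crp", "inr", "aptt", "ldh", "ck",
                "uric_acid", "ammonia", "troponin", "bnp", "ph", "pao2",
                "paco2", "fio2", "base_excess")
EXTRA_MEDS <- c("colistin", "amphotericin_b", "contrast_media",
                "beta_blocker", "ccb", "statin", "ppi", "steroid",
                "insulin", "opioid")

registry_row <- function(name, source, aggregation, kind) {
  data.table(name = name, source = source, aggregation = aggregation,
             kind = kind)
}

build_registry <- function(which) {
  rows <- list(
    registry_row("urine_8h", "urine", "sum_trailing_8h", "numeric"),
    registry_row("urine_24h", "urine", "sum_trailing_24h", "numeric"),
    registry_row("creatinine", "creatinine", "last", "numeric"),
    registry_row(PARS_VITALS, "vitals", "mean", "numeric"),
    registry_row(PARS_LABS, "labs", "mean", "numeric"),
    registry_row("age", "stays", "static", "numeric"),
    registry_row(PARS_MEDS, "medications", "binary_7d_lookback", "binary")
  )
  if (which == "full_60") {
    rows <- c(rows, list(
      registry_row("weight", "stays", "static", "numeric"),
      registry_row(EXTRA_VITALS, "vitals", "mean", "numeric"),
      registry_row(EXTRA_LABS, "labs", "mean", "numeric"),
      registry_row(EXTRA_MEDS, "medications", "binary_7d_lookback", "binary")
    ))
  }
  reg <- rbindlist(rows)
  setattr(reg, "class", c("feature_registry", class(reg)))
  setattr(reg, "registry_name", which)
  setattr(reg, "registry_hash", fnv1a_hash(paste(reg$name, reg$source,
                                                 reg$aggregation, reg$kind)))
  reg[]
}

#' Feature registry: the ordered feature dictionary used for extraction
#'
#' @param which `"full_60"` (default, 60 features) or `"parsimonious_21"`
#'   (the 21-feature reduced set), or a `data.frame` with columns
#'   `name`, `source`, `aggregation`, `kind` for a user-defined registry.
#' @return a `feature_registry` (a `data.table`) with attributes
#'   `registry_name` and `registry_hash`.
#' @details Supported aggregations: `mean` and `last` over the window
#'   (`last` looks back up to 48 h from the window end so sparsely charted
#'   analytes such as creatinine are carried forward to the prediction time),
#'   `sum_trailing_8h` / `sum_trailing_24h` (sums ending at the window end),
#'   `binary_7d_lookback` (1 iff any administration in the 168 h up to the
#'   window end), and `static` (per-stay constant).
#' @export
#' @examples
#' nrow(feature_registry("parsimonious_21")) # 21
feature_registry <- function(which = "full_60") {
  if (is.data.frame(which)) {
    req <- c("name", "source", "aggregation", "kind")
    if (!all(req %in% names(which))) {
      stopf("custom registry must have columns: %s", paste(req, collapse = ", "))
    }
    reg <- as.data.table(which)[, req, with = FALSE]
    if (anyDuplicated(reg$name)) stopf("registry feature names must be unique")
    ok_agg <- c("mean", "last", "sum_trailing_8h", "sum_trailing_24h",
                "binary_7d_lookback", "static")
    if (!all(reg$aggregation %in% ok_agg)) stopf("unknown aggregation in registry")
    setattr(reg, "class", c("feature_registry", class(reg)))
    setattr(reg, "registry_name", "custom")
    setattr(reg, "registry_hash", fnv1a_hash(paste(reg$name, reg$source,
                                                   reg$aggregation, reg$kind)))
    return(reg[])
  }
  which <- match.arg(which, c("full_60", "parsimonious_21"))
  build_registry(which)
}

registry_hash <- function(registry) attr(registry, "registry_hash")
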