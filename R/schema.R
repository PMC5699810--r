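#' Clinical variable schema for COPD triage cases
#'
#' Returns the schema of the 31 collected clinical variables (patient
#' profile, comorbidities, symptoms, current vital signs) plus the four
#' baseline vitals used for delta features and the profile design. Each row
#' describes one variable: its kind (categorical/continuous), admissible
#' levels or numeric range, units, whether the patient may answer "unknown",
#' and its group.
#'
#' "unknown" is disallowed exactly for age, weight, height, gender, baseline
#' dyspnea (MMRC) and the symptom-group variables; every other variable
#' admits it so that models can be trained on cases with missing data.
#'
#' @return A data.frame with one row per variable and columns `name`, `kind`,
#'   `group`, `allows_unknown`, `units`, `levels` (list column; `NULL` for
#'   continuous variables), `min`, `max` (NA for categorical variables).
#' @export
copd_schema <- function() {
  v <- function(name, kind, group, allows_unknown, units, levels = NULL,
                min = NA_real_, max = NA_real_) {
    list(name = name, kind = kind, group = group,
         allows_unknown = allows_unknown, units = units,
         levels = levels, min = min, max = max)
  }
  yn <- c("no", "yes")
  vars <- list(
    # patient profile
    v("age",            "continuous",  "profile", FALSE, "years", min = 30, max = 100),
    v("weight",         "continuous",  "profile", FALSE, "lb",    min = 70, max = 400),
    v("height",         "continuous",  "profile", FALSE, "inches", min = 48, max = 84),
    v("gender",         "categorical", "profile", FALSE, "", c("male", "female")),
    v("gold_stage",     "categorical", "profile", TRUE,  "", c("1", "2", "3", "4")),
    v("baseline_mmrc",  "categorical", "profile", FALSE, "", c("1", "2", "3", "4", "5")),
    v("recent_exac",    "categorical", "profile", TRUE,  "", yn),
    v("lives_alone",    "categorical", "profile", TRUE,  "", yn),
    v("smoker",         "categorical", "profile", TRUE,  "", yn),
    v("oxygen_user",    "categorical", "profile", TRUE,  "", yn),
    v("assisted_daily", "categorical", "profile", TRUE,  "", yn),
    # comorbidities
    v("chf",          "categorical", "comorbidity", TRUE, "", yn),
    v("hypertension", "categorical", "comorbidity", TRUE, "", yn),
    v("cad",          "categorical", "comorbidity", TRUE, "", yn),
    v("diabetes",     "categorical", "comorbidity", TRUE, "", yn),
    v("anemia",       "categorical", "comorbidity", TRUE, "", yn),
    v("pulm_htn",     "categorical", "comorbidity", TRUE, "", yn),
    v("acid_reflux",  "categorical", "comorbidity", TRUE, "", yn),
    # symptoms (levels 1,2,3 = less than usual / same as usual / more than usual)
    v("shortbreath",  "categorical", "symptom", FALSE, "", c("1", "2", "3")),
    v("cough",        "categorical", "symptom", FALSE, "", c("1", "2", "3")),
    v("wheeze",       "categorical", "symptom", FALSE, "", c("1", "2", "3")),
    v("sputum_col",   "categorical", "symptom", FALSE, "", yn),
    v("sputum_vol",   "categorical", "symptom", FALSE, "", yn),
    v("infection",    "categorical", "symptom", FALSE, "", yn),
    v("med_comp",     "categorical", "symptom", FALSE, "", c("1", "2", "3")),
    v("sleeplessness","categorical", "symptom", FALSE, "", yn),
    v("current_mmrc", "categorical", "symptom", FALSE, "", c("1", "2", "3", "4", "5")),
    # current vital signs
    v("o2sat",       "continuous", "vital", TRUE, "%",       min = 0,  max = 100),
    v("fev1",        "continuous", "vital", TRUE, "% predicted", min = 0, max = 100),
    v("heartrate",   "continuous", "vital", TRUE, "BPM",     min = 20, max = 250),
    v("temperature", "continuous", "vital", TRUE, "deg F",   min = 90, max = 108),
    # baseline vital signs (delta-feature anchors; part of the profile design)
    v("baseline_o2sat",       "continuous", "baseline_vital", TRUE, "%",        min = 0,  max = 100),
    v("baseline_fev1",        "continuous", "baseline_vital", TRUE, "% predicted", min = 0, max = 100),
    v("baseline_heartrate",   "continuous", "baseline_vital", TRUE, "BPM",      min = 20, max = 250),
    v("baseline_temperature", "continuous", "baseline_vital", TRUE, "deg F",    min = 90, max = 108)
  )
  out <- data.frame(
    name = vapply(vars, `[[`, "", "name"),
    kind = vapply(vars, `[[`, "", "kind"),
    group = vapply(vars, `[[`, "", "group"),
    allows_unknown = vapply(vars, `[[`, TRUE, "allows_unknown"),
    units = vapply(vars, `[[`, "", "units"),
    min = vapply(vars, `[[`, 0, "min"),
    max = vapply(vars, `[[`, 0, "max"),
    stringsAsFactors = FALSE
  )
  out$levels <- I(lapply(vars, `[[`, "levels"))
  class(out) <- c("copd_schema", "data.frame")
  out
}

#' Token used for "unknown" responses in files and categorical values
#' @keywords internal
UNKNOWN_TOKEN <- "unknown"

schema_row <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) stop("schema mismatch: unknown variable '", name, "'")
  schema[i, , drop = FALSE]
}

is_unknown_value <- function(x) {
  if (is.numeric(x)) return(is.na(x))
  is.na(x) | x == UNKNOWN_TOKEN
}

#' Validate a patient case against the schema
#'
#' Checks that every schema variable is present, that "unknown" only occurs
#' where permitted, that continuous values fall in their physiologic ranges
#' and that categorical codes are members of their declared level sets.
#' Continuous "unknown" is represented as `NA`; categorical as the literal
#' string `"unknown"`.
#'
#' @param case A one-row data.frame (or named list) with one entry per schema
#'   variable, plus optionally `case_id` and `split`.
#' @param schema Schema from [copd_schema()].
#' @return A list with `pass` (logical) and `violations` (character vector;
#'   empty when the case passes). Each violation names the rule, the variable
#'   and the offending value.
#' @export
validate_case <- function(case, schema = copd_schema()) {
  case <- as.list(case)
  if (is.null(case$case_id)) stop("case must have a case_id")
  viol <- character(0)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(case)) {
      viol <- c(viol, sprintf("incomplete case: %s missing", nm))
      next
    }
    x <- case[[nm]]
    if (is_unknown_value(x)) {
      if (!schema$allows_unknown[i])
        viol <- c(viol, sprintf("unknown not permitted: %s", nm))
      next
    }
    if (schema$kind[i] == "continuous") {
      x <- suppressWarnings(as.numeric(x))
      if (is.na(x)) {
        viol <- c(viol, sprintf("range violation: %s (non-numeric)", nm))
      } else if (x < schema$min[i] || x > schema$max[i]) {
        viol <- c(viol, sprintf("range violation: %s (%g outside [%g, %g])",
                                nm, x, schema$min[i], schema$max[i]))
      }
    } else {
      if (!as.character(x) %in% schema$levels[[i]])
        viol <- c(viol, sprintf("range violation: %s ('%s' not in {%s})",
                                nm, as.character(x),
                                paste(schema$levels[[i]], collapse = ",")))
    }
  }
  list(pass = length(viol) == 0L, violations = viol)
}

#' Validate a whole cohort
#'
#' @param cases Cohort data.frame, one row per case.
#' @param schema Schema from [copd_schema()].
#' @return Logical vector, one entry per case; attribute `"violations"`
#'   holds the per-case violation lists for failing cases.
#' @export
validate_cohort <- function(cases, schema = copd_schema()) {
  reports <- lapply(seq_len(nrow(cases)), function(i)
    validate_case(cases[i, , drop = FALSE], schema))
  ok <- vapply(reports, `[[`, TRUE, "pass")
  attr(ok, "violations") <- lapply(reports, `[[`, "violations")[!ok]
  ok
}

#' Default bin configuration for vital-sign features
#'
#' Cut points follow the printed feature names where available (oxygen
#' saturation 85/87/89/91/93; heart rate 100/110/120 with an open ">120"
#' bin; FEV1 percent-of-predicted in decades; FEV1 percent change
#' -100/-15/-5/0/10); the remaining edges (temperature, O2-saturation
#' change) are package defaults. Vital bins are half-open right-closed
#' "(a, b]" except the O2-saturation-change bins, which are left-closed
#' "[a, b)" as their printed names indicate.
#'
#' @return Named list of numeric edge vectors (strictly increasing), one per
#'   binned feature: `o2sat`, `heartrate`, `temperature`, `fev1`, `dfev1`
#'   (percent change from baseline), `do2sat` (absolute change from
#'   baseline, gated on baseline < 93).
#' @export
default_bins <- function() {
  list(
    o2sat = c(0, 85, 87, 89, 91, 93, 100),
    heartrate = c(20, 100, 110, 120, 250),
    temperature = c(90, 99, 100.4, 102, 108),
    fev1 = seq(0, 100, by = 10),
    dfev1 = c(-100, -15, -5, 0, 10, 400),
    do2sat = c(-100, -8, -4, -2, 0, 2, 100)
  )
}

check_bins <- function(bins) {
  for (nm in names(bins)) {
    e <- bins[[nm]]
    if (length(e) < 2 || any(diff(e) <= 0))
      stop("bad bin config: edges for '", nm, "' must be strictly increasing")
  }
  invisible(bins)
}

# interval label "(a, b]" / "[a, b)"; %g keeps 100.4 readable
bin_label <- function(a, b, left_closed = FALSE) {
  if (left_closed) sprintf("[%g, %g)", a, b) else sprintf("(%g, %g]", a, b)
}

# index of the half-open bin containing x; right_closed: (a,b]; else [a,b)
bin_index <- function(x, edges, right_closed = TRUE) {
  if (right_closed) {
    i <- findInterval(x, edges, left.open = TRUE)  # (a, b]
    i[!is.na(x) & x == edges[1]] <- 1L             # lowest edge joins first bin
  } else {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
  }
  i[i < 1 | i >= length(edges)] <- NA_integer_
  i
}

# feature names for one binned variable (prefix per printed convention)
bin_feature_names <- function(prefix, edges, left_closed = FALSE,
                              open_top = FALSE, suffix = "") {
  k <- length(edges) - 1
  labs <- character(k)
  for (i in seq_len(k)) {
    if (open_top && i == k) {
      labs[i] <- sprintf("%s_>%g%s", prefix, edges[i], suffix)
    } else {
      labs[i] <- paste0(prefix, "_", bin_label(edges[i], edges[i + 1], left_closed), suffix)
    }
  }
  labs
}

#' Feature-space definition for the encoder
#'
#' Enumerates every feature the encoder emits, in order, with the source
#' variable(s) each feature derives from.
#'
#' @param bins Bin configuration, see [default_bins()].
#' @param schema Schema from [copd_schema()].
#' @param combined_sputum Emit the joint `sputum(col+vol)_k` features
#'   (k = number of "yes" among color change / volume increase).
#' @param single_sputum Emit the single `sputum_col_1` / `sputum_vol_1`
#'   indicators alongside the combined feature.
#' @return data.frame with `feature` and `source` columns.
#' @export
feature_space <- function(bins = default_bins(), schema = copd_schema(),
                          combined_sputum = TRUE, single_sputum = TRUE) {
  check_bins(bins)
  feats <- list()
  add <- function(feature, source) feats[[length(feats) + 1]] <<- c(feature, source)

  # continuous profile covariates pass through numerically
  add("age", "age"); add("height", "height"); add("bmi", "weight+height")

  # one-hot categorical indicators: yes/no variables contribute only the
  # "yes" indicator (var_1); multi-level variables contribute every level
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] != "categorical") next
    nm <- schema$name[i]
    if (nm %in% c("sputum_col", "sputum_vol") && !single_sputum) next
    lv <- schema$levels[[i]]
    if (identical(lv, c("no", "yes"))) {
      add(paste0(nm, "_1"), nm)
    } else {
      for (l in lv) add(paste0(nm, "_", l), nm)
    }
    if (schema$allows_unknown[i]) add(paste0(nm, "_unknown"), nm)
  }
  if (combined_sputum) {
    for (k in 0:2) add(paste0("sputum(col+vol)_", k), "sputum_col+sputum_vol")
  }

  # binned current vitals
  for (nm in c("o2sat", "fev1", "heartrate", "temperature")) {
    prefix <- c(o2sat = "O2Sat", fev1 = "fev1", heartrate = "hr",
                temperature = "temp")[[nm]]
    open_top <- nm == "heartrate"
    for (f in bin_feature_names(prefix, bins[[nm]], open_top = open_top))
      add(f, nm)
    add(paste0(prefix, "_unknown"), nm)
  }

  # delta features: fev1 as percent change, O2 sat as absolute points
  for (f in bin_feature_names("dfev1", bins$dfev1)) add(f, "fev1+baseline_fev1")
  add("dfev1_unknown", "fev1+baseline_fev1")
  # O2-sat change gated on baseline < 93; left-closed bins as printed
  for (f in bin_feature_names("dO2Sat", bins$do2sat, left_closed = TRUE,
                              suffix = "_base<93"))
    add(f, "o2sat+baseline_o2sat")
  add("dO2Sat_base>=93", "o2sat+baseline_o2sat")
  add("dO2Sat_unknown", "o2sat+baseline_o2sat")

  out <- data.frame(
    feature = vapply(feats, `[[`, "", 1),
    source = vapply(feats, `[[`, "", 2),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$feature))
  out
}

#' Encode patient cases into the model feature space
#'
#' Emits, per case: numeric pass-through covariates (age, height, BMI from
#' imperial weight/height), one-hot level indicators for categorical
#' variables (plus an unknown indicator where "unknown" is admissible),
#' half-open-interval bin indicators for the current vitals, percent-change
#' FEV1 bins and absolute-change O2-saturation bins relative to baseline,
#' the combined sputum status feature, and the baseline-gated O2-saturation
#' change block (active only when baseline O2 sat < 93).
#'
#' For every binned variable the bin indicators plus the unknown indicator
#' (plus, for the gated block, the baseline >= 93 indicator) sum to one.
#' Delta features are "unknown" unless both current and baseline values are
#' known.
#'
#' @param cases Cohort data.frame (one row per case) or a single case.
#' @param bins Bin configuration, see [default_bins()].
#' @param schema Schema from [copd_schema()].
#' @param combined_sputum,single_sputum See [feature_space()].
#' @return Numeric matrix, cases x features, rownames = case ids, with
#'   attribute `"provenance"` (the [feature_space()] table).
#' @export
encode_features <- function(cases, bins = default_bins(), schema = copd_schema(),
                            combined_sputum = TRUE, single_sputum = TRUE) {
  check_bins(bins)
  fs <- feature_space(bins, schema, combined_sputum, single_sputum)
  n <- nrow(cases)
  M <- matrix(0, n, nrow(fs), dimnames = list(cases$case_id, fs$feature))

  num <- function(nm) suppressWarnings(as.numeric(ifelse(
    is_unknown_value(cases[[nm]]), NA, cases[[nm]])))
  chr <- function(nm) {
    x <- as.character(cases[[nm]])
    x[is.na(x)] <- UNKNOWN_TOKEN
    x
  }
  set <- function(feature, value) M[, feature] <<- value

  age <- num("age"); wt <- num("weight"); ht <- num("height")
  set("age", age); set("height", ht)
  set("bmi", 703 * wt / ht^2)  # imperial BMI

  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] != "categorical") next
    nm <- schema$name[i]
    x <- chr(nm)
    lv <- schema$levels[[i]]
    if (!(nm %in% c("sputum_col", "sputum_vol") && !single_sputum)) {
      if (identical(lv, c("no", "yes"))) {
        set(paste0(nm, "_1"), as.numeric(x == "yes"))
      } else {
        for (l in lv) set(paste0(nm, "_", l), as.numeric(x == l))
      }
      if (schema$allows_unknown[i])
        set(paste0(nm, "_unknown"), as.numeric(x == UNKNOWN_TOKEN))
    }
  }
  if (combined_sputum) {
    nyes <- (chr("sputum_col") == "yes") + (chr("sputum_vol") == "yes")
    for (k in 0:2) set(paste0("sputum(col+vol)_", k), as.numeric(nyes == k))
  }

  for (nm in c("o2sat", "fev1", "heartrate", "temperature")) {
    prefix <- c(o2sat = "O2Sat", fev1 = "fev1", heartrate = "hr",
                temperature = "temp")[[nm]]
    x <- num(nm)
    labs <- bin_feature_names(prefix, bins[[nm]], open_top = nm == "heartrate")
    idx <- bin_index(x, bins[[nm]])
    for (b in seq_along(labs))
      set(labs[b], as.numeric(!is.na(idx) & idx == b))
    set(paste0(prefix, "_unknown"), as.numeric(is.na(x)))
  }

  # FEV1 percent change from baseline
  f1 <- num("fev1"); f0 <- num("baseline_fev1")
  dfe <- ifelse(!is.na(f1) & !is.na(f0) & f0 > 0, 100 * (f1 - f0) / f0, NA)
  labs <- bin_feature_names("dfev1", bins$dfev1)
  idx <- bin_index(dfe, bins$dfev1)
  for (b in seq_along(labs)) set(labs[b], as.numeric(!is.na(idx) & idx == b))
  set("dfev1_unknown", as.numeric(is.na(dfe)))

  # O2 sat absolute change, gated on baseline < 93; left-closed bins
  s1 <- num("o2sat"); s0 <- num("baseline_o2sat")
  dsat <- s1 - s0
  known <- !is.na(dsat)
  gated <- known & s0 < 93
  labs <- bin_feature_names("dO2Sat", bins$do2sat, left_closed = TRUE,
                            suffix = "_base<93")
  idx <- bin_index(dsat, bins$do2sat, right_closed = FALSE)
  for (b in seq_along(labs))
    set(labs[b], as.numeric(gated & !is.na(idx) & idx == b))
  set("dO2Sat_base>=93", as.numeric(known & s0 >= 93))
  set("dO2Sat_unknown", as.numeric(!known))

  attr(M, "provenance") <- fs
  M
}

#' Decode the one-hot block of an encoded case back to categorical levels
#'
#' Inverse of the one-hot portion of [encode_features()]; used to check the
#' encoding round-trips.
#'
#' @param encoded Matrix from [encode_features()].
#' @param schema Schema from [copd_schema()].
#' @return data.frame of recovered categorical values (strings; "unknown"
#'   where the unknown indicator is set).
#' @export
decode_categoricals <- function(encoded, schema = copd_schema()) {
  out <- list()
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] != "categorical") next
    nm <- schema$name[i]
    lv <- schema$levels[[i]]
    if (identical(lv, c("no", "yes"))) {
      yes <- encoded[, paste0(nm, "_1")]
      val <- ifelse(yes == 1, "yes", "no")
    } else {
      cols <- paste0(nm, "_", lv)
      hit <- apply(encoded[, cols, drop = FALSE], 1, function(r)
        if (sum(r) == 0) NA_character_ else lv[which.max(r)])
      val <- hit
      val[is.na(val)] <- "no-level"
    }
    if (schema$allows_unknown[i]) {
      unk <- encoded[, paste0(nm, "_unknown")] == 1
      val[unk] <- UNKNOWN_TOKEN
    }
    out[[nm]] <- val
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
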