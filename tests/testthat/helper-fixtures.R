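# shared fixtures: built in code, cached per test file

# one fully populated, in-range case
make_case <- function(case_id = "c1", ...) {
  base <- list(
    case_id = case_id, split = "train",
    age = 70, weight = 180, height = 68, gender = "male",
    gold_stage = "2", baseline_mmrc = "2", recent_exac = "no",
    lives_alone = "no", smoker = "yes", oxygen_user = "no",
    assisted_daily = "no",
    chf = "no", hypertension = "yes", cad = "no", diabetes = "no",
    anemia = "no", pulm_htn = "no", acid_reflux = "no",
    shortbreath = "2", cough = "2", wheeze = "1", sputum_col = "no",
    sputum_vol = "no", infection = "no", med_comp = "3",
    sleeplessness = "no", current_mmrc = "2",
    o2sat = 95, fev1 = 60, heartrate = 80, temperature = 98.6,
    baseline_o2sat = 96, baseline_fev1 = 60, baseline_heartrate = 75,
    baseline_temperature = 98.2
  )
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

# small cached synthetic cohort (expensive stages shared across tests)
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(n_design = 30, n_total = 250, n_validation = 40,
                         n_candidates = 250, unknown_rate = 0.05, seed = 11)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

small_panel_labels <- function(noise_sd = 0.15) {
  key <- paste0("labels_", noise_sd)
  if (is.null(.fixture_env[[key]])) {
    co <- small_cohort()
    pan <- default_panel(co, n_raters = 9, seed = 5, noise_sd = noise_sd)
    .fixture_env[[key]] <- simulate_panel(co, pan, seed = 5)
  }
  .fixture_env[[key]]
}

# hand-specified label matrices: one list entry of triage votes per rater
make_labels <- function(triage_by_rater, exac = NULL) {
  raters <- names(triage_by_rater)
  n <- length(triage_by_rater[[1]])
  out <- do.call(rbind, lapply(raters, function(r) data.frame(
    rater_id = r, case_id = paste0("c", seq_len(n)),
    triage = triage_by_rater[[r]],
    exacerbation = if (is.null(exac)) rep(0L, n) else exac[[r]],
    triage_conf = 50, exac_conf = 50, stringsAsFactors = FALSE)))
  class(out) <- c("copd_labels", "data.frame")
  out
}

# --- independent per-case tally oracles for the evaluation formulas ---

pct_or_na <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

oracle_triage_metrics <- function(pred, cons) {
  n <- length(pred)
  TC <- sum(pred == cons)
  TP <- sum(pred == 4 & cons == 4); FN <- sum(pred != 4 & cons == 4)
  FP <- sum(pred == 4 & cons != 4); TN <- sum(pred != 4 & cons != 4)
  LT <- sum(pred < cons)
  CG1 <- sum(abs(pred - cons) > 1)
  list(ACC = pct_or_na(TC, n),
       TPR = pct_or_na(TP, TP + FN), TNR = pct_or_na(TN, TN + FP),
       PPV = pct_or_na(TP, TP + FP), NPV = pct_or_na(TN, TN + FN),
       UTP = 100 - 100 * LT / n, EG1 = 100 * CG1 / n,
       TC = TC, LT = LT, C_G1 = CG1)
}

oracle_medical_metrics <- function(pred, cons) {
  need <- cons >= 3; said <- pred >= 3
  TP <- sum(said & need); TN <- sum(!said & !need)
  FP <- sum(said & !need); FN <- sum(!said & need)
  list(ACC_M = pct_or_na(TP + TN, length(pred)),
       TPR_M = pct_or_na(TP, TP + FN), TNR_M = pct_or_na(TN, TN + FP),
       PPV_M = pct_or_na(TP, TP + FP), NPV_M = pct_or_na(TN, TN + FN))
}

# independent conservative-majority oracle: scan categories from the most
# conservative down, return the first that attains the maximal count
oracle_majority <- function(votes, categories) {
  best_count <- -1; best <- NA
  for (k in rev(categories)) {
    ck <- sum(votes == k)
    if (ck > best_count) { best_count <- ck; best <- k }
  }
  best
}

# a 4x4 confusion matrix with the stated diagonal/off-diagonal structure:
# all off-diagonal errors adjacent to the diagonal (no >1-category errors)
gb_style_confusion <- function() {
  cm <- matrix(0L, 4, 4, dimnames = list(consensus = 1:4, predicted = 1:4))
  diag(cm) <- c(20L, 25L, 24L, 20L)                    # 89 correct
  cm[1, 2] <- 3L; cm[2, 3] <- 3L; cm[3, 4] <- 2L       # 8 over-triage
  cm[2, 1] <- 1L; cm[3, 2] <- 1L; cm[4, 3] <- 2L       # 4 under-triage
  stopifnot(sum(cm) == 101, sum(cm) - sum(diag(cm)) == 12)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

top_dr_style_confusion <- function() {
  cm <- matrix(0L, 4, 4, dimnames = list(consensus = 1:4, predicted = 1:4))
  diag(cm) <- c(20L, 20L, 19L, 16L)                    # 75 correct
  cm[2, 1] <- 5L; cm[3, 2] <- 10L; cm[3, 1] <- 1L; cm[4, 3] <- 7L  # 23 under
  cm[1, 2] <- 2L; cm[2, 3] <- 1L                        # 3 over
  stopifnot(sum(cm) == 101, sum(cm) - sum(diag(cm)) == 26,
            sum(cm[lower.tri(cm)]) == 23)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}
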