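#' Construct a parametric rater policy
#'
#' A rater policy is the synthetic stand-in for one physician: a linear
#' severity score over encoded case features, three strictly increasing
#' thresholds mapping the (noisy) score to the four ordinal triage
#' categories, and a separate weighted rule for the binary exacerbation
#' call. `bias` is added to the severity score, so a positive bias makes the
#' rater an over-triager. Label confidence is a monotone function of the
#' distance between the score and the nearest threshold.
#'
#' @param rater_id Identifier (e.g. `"dr1"`).
#' @param weights Named numeric vector of severity weights over feature
#'   names (features not named get weight 0).
#' @param thresholds Numeric length-3, strictly increasing: score <= t1 maps
#'   to category 1 (Ok), ..., score > t3 to category 4 (ER).
#' @param exac_weights Named numeric vector for the exacerbation score.
#' @param exac_threshold Scalar: exacerbation = yes iff score > threshold.
#' @param bias Additive shift of the severity score (positive =
#'   over-triager).
#' @param noise_sd Standard deviation of the Gaussian latent noise
#'   (>= 0; 0 makes the rater deterministic).
#' @param splits Which cohort splits this rater labels (panel scoping).
#' @return List of class `rater_policy`.
#' @export
rater_policy <- function(rater_id, weights, thresholds, exac_weights,
                         exac_threshold, bias = 0, noise_sd = 0,
                         splits = c("train", "validation")) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0), noise_sd >= 0)
  structure(list(rater_id = rater_id, weights = weights,
                 thresholds = thresholds, exac_weights = exac_weights,
                 exac_threshold = exac_threshold, bias = bias,
                 noise_sd = noise_sd, splits = splits),
            class = "rater_policy")
}

# weighted sum of the features named in w (missing names contribute 0)
weighted_score <- function(features, w) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  keep <- intersect(names(w), colnames(features))
  if (length(keep) == 0) return(rep(0, nrow(features)))
  as.numeric(features[, keep, drop = FALSE] %*% w[keep])
}

#' Latent severity score of a case under a policy
#'
#' `score = sum(weights * features) + bias`; deterministic.
#'
#' @param case_features Encoded feature vector or matrix
#'   (see [encode_features()]).
#' @param policy A [rater_policy()].
#' @return Numeric score(s).
#' @export
severity_score <- function(case_features, policy) {
  weighted_score(case_features, policy$weights) + policy$bias
}

# map scores through thresholds: <= t1 -> 1, ..., > t3 -> 4
score_to_category <- function(score, thresholds) {
  1L + (score > thresholds[1]) + (score > thresholds[2]) + (score > thresholds[3])
}

# confidence: monotone in distance from the nearest threshold, in [0, 100)
confidence_from_distance <- function(score, thresholds, scale) {
  d <- vapply(score, function(s) min(abs(s - thresholds)), 0)
  100 * d / (d + scale)
}

#' Rate one or more cases under a policy
#'
#' Adds Gaussian noise (`noise_sd`) to the latent severity and exacerbation
#' scores, maps them through the thresholds, and attaches confidences.
#'
#' @param cases Cohort data.frame (or a single case row).
#' @param policy A [rater_policy()].
#' @param seed Integer seed for the noise draw.
#' @param bins Bin configuration for the feature encoding.
#' @return data.frame: `rater_id`, `case_id`, `triage` (1-4),
#'   `exacerbation` (0/1), `triage_conf`, `exac_conf` (percent).
#' @export
rate_case <- function(cases, policy, seed = 1, bins = default_bins()) {
  F <- encode_features(cases, bins)
  rate_encoded(F, cases$case_id, policy, seed)
}

rate_encoded <- function(F, case_ids, policy, seed) {
  n <- nrow(F)
  set.seed(seed)
  s <- severity_score(F, policy) +
    (if (policy$noise_sd > 0) rnorm(n, 0, policy$noise_sd) else 0)
  e <- weighted_score(F, policy$exac_weights) + policy$bias +
    (if (policy$noise_sd > 0) rnorm(n, 0, policy$noise_sd) else 0)
  th <- policy$thresholds
  scale_t <- max((th[3] - th[1]) / 4, 1e-9)
  data.frame(
    rater_id = policy$rater_id,
    case_id = case_ids,
    triage = score_to_category(s, th),
    exacerbation = as.integer(e > policy$exac_threshold),
    triage_conf = confidence_from_distance(s, th, scale_t),
    exac_conf = confidence_from_distance(e, policy$exac_threshold, scale_t),
    stringsAsFactors = FALSE
  )
}

#' Simulate a physician panel over a cohort
#'
#' Applies each policy to the cases in the splits it is scoped to
#' (`policy$splits`), so a study can use e.g. 6 raters on training cases and
#' 9 on validation cases. Each rater draws an independent noise stream
#' derived from `seed` and the rater's position, so results do not depend on
#' panel order.
#'
#' @param cases Cohort data.frame with a `split` column.
#' @param policies List of [rater_policy()] objects with unique ids.
#' @param seed Integer seed.
#' @param bins Bin configuration.
#' @return Long data.frame of class `copd_labels` with one row per
#'   rater x case: `rater_id`, `case_id`, `triage`, `exacerbation`,
#'   `triage_conf`, `exac_conf`.
#' @export
simulate_panel <- function(cases, policies, seed = 1, bins = default_bins()) {
  if (length(policies) == 0) stop("panel misconfigured: no policies")
  ids <- vapply(policies, `[[`, "", "rater_id")
  if (anyDuplicated(ids)) stop("panel misconfigured: duplicate rater_id")
  F <- encode_features(cases, bins)
  split <- if (is.null(cases$split)) rep("train", nrow(cases)) else cases$split
  out <- vector("list", length(policies))
  for (k in seq_along(policies)) {
    pol <- policies[[k]]
    keep <- split %in% pol$splits
    if (!any(keep)) next
    out[[k]] <- rate_encoded(F[keep, , drop = FALSE], cases$case_id[keep],
                             pol, seed = seed * 1000L + k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("copd_labels", "data.frame")
  res
}

#' Default severity weights shared by the panel constructor
#'
#' Positive weights on worsened symptoms, abnormal current vitals and
#' adverse deltas, echoing the additive severity-rating structure physicians
#' reported on (baseline, symptom and vital-sign severity on a 1-5 scale).
#'
#' @return Named numeric vector of feature weights.
#' @export
default_severity_weights <- function() {
  c(
    # symptoms
    shortbreath_3 = 2.0, shortbreath_1 = -0.5, cough_3 = 1.2, cough_1 = -0.3,
    wheeze_3 = 1.2, "sputum(col+vol)_1" = 0.8, "sputum(col+vol)_2" = 1.6,
    infection_1 = 1.0, sleeplessness_1 = 0.5, med_comp_3 = -0.4, med_comp_1 = 0.8,
    current_mmrc_4 = 1.0, current_mmrc_5 = 1.8,
    # current vitals (low O2 sat / FEV1, high HR / temp are severe)
    "O2Sat_(0, 85]" = 4.0, "O2Sat_(85, 87]" = 3.0, "O2Sat_(87, 89]" = 2.2,
    "O2Sat_(89, 91]" = 1.2, "O2Sat_(91, 93]" = 0.5,
    "fev1_(0, 20]" = 1.5, "fev1_(20, 30]" = 1.0, "fev1_(30, 40]" = 0.6,
    "hr_(100, 110]" = 0.8, "hr_(110, 120]" = 1.4, "hr_>120" = 2.2,
    "temp_(100.4, 102]" = 1.0, "temp_(102, 108]" = 2.0,
    # deltas from baseline
    "dfev1_(-100, -15]" = 2.0, "dfev1_(-15, -5]" = 1.0,
    "dO2Sat_[-100, -8)_base<93" = 3.0, "dO2Sat_[-8, -4)_base<93" = 2.0,
    "dO2Sat_[-4, -2)_base<93" = 1.2,
    # profile severity
    gold_stage_3 = 0.6, gold_stage_4 = 1.2, recent_exac_1 = 0.8,
    oxygen_user_1 = 0.6, baseline_mmrc_5 = 0.5, chf_1 = 0.5, pulm_htn_1 = 0.4
  )
}

#' Default exacerbation-rule weights
#'
#' Symptom-change dominated, per the clinical definition of an exacerbation
#' (worsened dyspnea, cough and/or sputum beyond day-to-day variation).
#'
#' @return Named numeric vector of feature weights.
#' @export
default_exacerbation_weights <- function() {
  c(
    shortbreath_3 = 2.2, cough_3 = 2.0, wheeze_3 = 1.5,
    "sputum(col+vol)_1" = 1.5, "sputum(col+vol)_2" = 2.5, infection_1 = 1.2,
    sleeplessness_1 = 0.5, med_comp_1 = 0.6,
    "dfev1_(-100, -15]" = 1.8, "dfev1_(-15, -5]" = 0.8,
    "dO2Sat_[-100, -8)_base<93" = 1.8, "dO2Sat_[-8, -4)_base<93" = 1.2,
    "O2Sat_(0, 85]" = 1.5, "O2Sat_(85, 87]" = 1.0,
    "temp_(100.4, 102]" = 0.8, "temp_(102, 108]" = 1.5
  )
}

#' Construct a heterogeneous default panel
#'
#' Builds `n_raters` policies around the shared default severity weights.
#' Thresholds are calibrated on the empirical score distribution of the
#' supplied cohort at target triage shares (default Ok/Plan/Doc/ER of about
#' 25/30/25/20 percent); each rater then receives multiplicative weight
#' jitter, threshold jitter, and latent noise. Two outlier styles echo the
#' heterogeneity seen in real panels: rater 2 is an extreme over-triager
#' (ER thresholds pulled far down, targeting roughly 63 percent ER) and
#' rater 3 an under-triager (Ok threshold pushed up, roughly 32 percent Ok).
#'
#' @param cases Cohort used to calibrate score quantiles.
#' @param n_raters Panel size (default 9, the validation panel).
#' @param seed Integer seed for the jitter draws.
#' @param noise_sd Latent noise SD as a fraction of the score SD.
#' @param quantiles Target cumulative shares for thresholds t1..t3.
#' @param bins Bin configuration.
#' @return List of [rater_policy()] objects (`dr1` ... `drN`).
#' @export
default_panel <- function(cases, n_raters = 9, seed = 1, noise_sd = 0.15,
                          quantiles = c(0.25, 0.55, 0.80),
                          bins = default_bins()) {
  F <- encode_features(cases, bins)
  w <- default_severity_weights()
  ew <- default_exacerbation_weights()
  s <- weighted_score(F, w)
  e <- weighted_score(F, ew)
  th0 <- as.numeric(quantile(s, quantiles))
  e_th0 <- as.numeric(quantile(e, 0.55))
  s_sd <- sd(s)
  set.seed(seed)
  pol <- vector("list", n_raters)
  for (k in seq_len(n_raters)) {
    wk <- w * exp(rnorm(length(w), 0, 0.15))
    th <- th0 + rnorm(3, 0, 0.08 * s_sd)
    th <- sort(th)
    if (any(diff(th) <= 0)) th <- th0
    if (k == 2) {
      # extreme over-triager: most cases to the ER
      th <- as.numeric(quantile(s, c(0.10, 0.20, 0.37)))
    } else if (k == 3) {
      # under-triager: large "no additional attention" share
      th <- as.numeric(quantile(s, c(0.32, 0.60, 0.85)))
    }
    pol[[k]] <- rater_policy(
      rater_id = paste0("dr", k),
      weights = wk,
      thresholds = th,
      exac_weights = ew * exp(rnorm(length(ew), 0, 0.10)),
      exac_threshold = e_th0 + rnorm(1, 0, 0.08 * sd(e)),
      bias = 0,
      noise_sd = noise_sd * s_sd
    )
  }
  pol
}
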