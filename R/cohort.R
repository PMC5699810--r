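#' Cohort generation configuration
#'
#' Bundles everything the two-stage case generator needs: the size of the
#' D-optimal profile design, the total cohort and validation-set sizes, the
#' per-variable marginal distributions used by the Monte Carlo completion,
#' the latent correlation matrix of the Gaussian copula, the
#' unknown-response injection rate, and the seed.
#'
#' Default sizes mirror the study structure: a 100-point profile design,
#' 2,501 total cases, 101 held out for validation. Default marginals and
#' correlations are package choices of clinically plausible values
#' (comorbidity prevalences in a COPD population, symptom-level frequencies,
#' current vitals drifting from baseline); they are configuration, not
#' estimates from data.
#'
#' @param n_design Number of D-optimal profile points.
#' @param n_total Total number of cases.
#' @param n_validation Cases held out for validation.
#' @param n_candidates Size of the random candidate set for the design.
#' @param unknown_rate Probability that an unknown-admitting variable is
#'   replaced by "unknown".
#' @param seed Integer seed for the whole generation.
#' @param marginals,correlation Optional overrides; see
#'   [default_marginals()] and [default_correlation()].
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_design = 100, n_total = 2501, n_validation = 101,
                          n_candidates = 1000, unknown_rate = 0.05, seed = 20171122,
                          marginals = default_marginals(),
                          correlation = default_correlation()) {
  stopifnot(n_design <= n_total, n_validation < n_total, unknown_rate >= 0,
            unknown_rate <= 1)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-8))
    stop("correlation must be symmetric with unit diagonal")
  structure(list(n_design = n_design, n_total = n_total,
                 n_validation = n_validation, n_candidates = n_candidates,
                 unknown_rate = unknown_rate, seed = seed,
                 marginals = marginals, correlation = correlation),
            class = "cohort_config")
}

#' Default marginal distributions for the Monte Carlo completion
#'
#' One entry per variable completed after the profile design (comorbidities,
#' symptoms, current vitals). Kinds: `bernoulli` (prob of "yes"),
#' `categorical` (probs over the schema levels), `delta_normal` (value =
#' baseline + Normal(mean, sd) shift, clamped to the schema range;
#' `relative = TRUE` applies the shift in percent of baseline).
#'
#' @return Named list of marginal specifications.
#' @export
default_marginals <- function() {
  bern <- function(p) list(kind = "bernoulli", p = p)
  cat3 <- function(p) list(kind = "categorical", probs = p)
  dn <- function(base, mean, sd, relative = FALSE)
    list(kind = "delta_normal", baseline = base, mean = mean, sd = sd,
         relative = relative)
  list(
    chf = bern(0.25), hypertension = bern(0.55), cad = bern(0.30),
    diabetes = bern(0.30), anemia = bern(0.15), pulm_htn = bern(0.15),
    acid_reflux = bern(0.35),
    shortbreath = cat3(c(0.25, 0.40, 0.35)),
    cough = cat3(c(0.20, 0.45, 0.35)),
    wheeze = cat3(c(0.30, 0.40, 0.30)),
    sputum_col = bern(0.30), sputum_vol = bern(0.35),
    infection = bern(0.25),
    med_comp = cat3(c(0.15, 0.25, 0.60)),
    sleeplessness = bern(0.40),
    current_mmrc = cat3(c(0.15, 0.20, 0.25, 0.20, 0.20)),
    o2sat = dn("baseline_o2sat", -1.5, 2.5),
    fev1 = dn("baseline_fev1", -5, 8, relative = TRUE),
    heartrate = dn("baseline_heartrate", 8, 12),
    temperature = dn("baseline_temperature", 0.5, 1.0)
  )
}

#' Default latent correlation for the Gaussian copula
#'
#' Block structure over the 20 completed variables: symptoms positively
#' intercorrelated (a sicker case reports several worsened symptoms),
#' comorbidities weakly intercorrelated, current O2 saturation and FEV1
#' shifts negatively correlated with the symptom block, heart rate and
#' temperature positively correlated with it.
#'
#' @return Symmetric correlation matrix with variable names as dimnames.
#' @export
default_correlation <- function() {
  vars <- names(default_marginals())
  k <- length(vars)
  R <- diag(k); dimnames(R) <- list(vars, vars)
  comorb <- c("chf", "hypertension", "cad", "diabetes", "anemia",
              "pulm_htn", "acid_reflux")
  sympt <- c("shortbreath", "cough", "wheeze", "sputum_col", "sputum_vol",
             "infection", "med_comp", "sleeplessness", "current_mmrc")
  set_block <- function(a, b, rho) {
    for (i in a) for (j in b) if (i != j) R[i, j] <<- R[j, i] <<- rho
  }
  set_block(comorb, comorb, 0.15)
  set_block(sympt, sympt, 0.30)
  set_block(c("o2sat", "fev1"), sympt, -0.20)
  set_block(c("heartrate", "temperature"), sympt, 0.20)
  set_block("o2sat", "fev1", 0.25)
  set_block("heartrate", "temperature", 0.20)
  set_block(c("o2sat", "fev1"), c("heartrate", "temperature"), -0.15)
  R
}

# clip eigenvalues to repair a non-PSD correlation matrix
repair_psd <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  warning("correlation matrix not positive semi-definite; repaired by eigenvalue clipping")
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  dimnames(R2) <- dimnames(R)
  R2
}

#' Complete profile points into full patient cases
#'
#' Fills the comorbidity, symptom and current-vital variables of each
#' profile point by sampling a Gaussian copula over the configured latent
#' correlation and pushing the latent quantiles through the per-variable
#' marginals; then replaces values of unknown-admitting variables with
#' "unknown" at the configured rate. Uses the current R random stream (set
#' the seed upstream, as [generate_cohort()] does).
#'
#' @param profiles data.frame with the profile + baseline-vital variables
#'   populated (one row per case to complete).
#' @param config A [cohort_config()].
#' @return Cohort data.frame: the profiles plus all completed variables.
#' @export
complete_cases <- function(profiles, config) {
  schema <- copd_schema()
  marg <- config$marginals
  vars <- names(marg)
  missing_m <- setdiff(
    schema$name[!schema$group %in% c("profile", "baseline_vital")], vars)
  if (length(missing_m))
    stop("config incomplete: no marginal for ", paste(missing_m, collapse = ", "))
  R <- repair_psd(config$correlation[vars, vars])
  n <- nrow(profiles)
  Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = R)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  U <- pnorm(Z); colnames(U) <- vars

  out <- profiles
  for (nm in vars) {
    m <- marg[[nm]]
    u <- U[, nm]
    row <- schema_row(schema, nm)
    if (m$kind == "bernoulli") {
      out[[nm]] <- ifelse(u > 1 - m$p, "yes", "no")
    } else if (m$kind == "categorical") {
      lv <- row$levels[[1]]
      stopifnot(length(m$probs) == length(lv))
      idx <- findInterval(u, cumsum(m$probs) / sum(m$probs)) + 1
      idx[idx > length(lv)] <- length(lv)
      out[[nm]] <- lv[idx]
    } else if (m$kind == "delta_normal") {
      base <- as.numeric(out[[m$baseline]])
      shift <- qnorm(u, mean = m$mean, sd = m$sd)
      val <- if (isTRUE(m$relative)) base * (1 + shift / 100) else base + shift
      out[[nm]] <- pmin(pmax(val, row$min), row$max)
    } else stop("unknown marginal kind: ", m$kind)
  }

  # unknown injection on unknown-admitting variables
  if (config$unknown_rate > 0) {
    allow <- schema$name[schema$allows_unknown]
    for (nm in allow) {
      hit <- runif(n) < config$unknown_rate
      if (!any(hit)) next
      if (schema_row(schema, nm)$kind == "continuous") {
        out[[nm]] <- as.numeric(out[[nm]]); out[[nm]][hit] <- NA_real_
      } else {
        out[[nm]] <- as.character(out[[nm]]); out[[nm]][hit] <- UNKNOWN_TOKEN
      }
    }
  }
  out
}

#' Complete a single profile point
#'
#' Single-case convenience wrapper around [complete_cases()].
#'
#' @param profile_point One-row data.frame of profile values.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return One-row cohort data.frame.
#' @export
complete_case <- function(profile_point, config, seed = config$seed) {
  set.seed(seed)
  complete_cases(profile_point, config)
}

#' Generate a full synthetic cohort
#'
#' Stage 1: draws a candidate set of profile points and selects an
#' `n_design`-point D-optimal subset by Fedorov exchange. Stage 2:
#' replicates the design profiles to `n_total` rows (each design point
#' appears at least once; the remainder resampled uniformly) and completes
#' every row by correlated Monte Carlo sampling. Finally a random subset of
#' `n_validation` cases is assigned to the validation split.
#'
#' @param config A [cohort_config()].
#' @return Cohort data.frame with `case_id`, `split` and every schema
#'   variable; attribute `"design"` carries the selected design
#'   (`row_ids`, `log_det`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  cand <- profile_candidates(config$n_candidates, seed = config$seed)
  des <- federov_exchange(cand$coded, config$n_design,
                          seed = config$seed + 1L, restarts = 5)
  profiles <- cand$raw[des$row_ids, , drop = FALSE]
  n_extra <- config$n_total - config$n_design
  idx <- c(seq_len(config$n_design),
           sample.int(config$n_design, n_extra, replace = TRUE))
  rows <- profiles[idx, , drop = FALSE]
  rownames(rows) <- NULL
  cohort <- complete_cases(rows, config)
  cohort <- cbind(case_id = sprintf("case_%05d", seq_len(config$n_total)),
                  split = "train", cohort, stringsAsFactors = FALSE)
  val <- sample.int(config$n_total, config$n_validation)
  cohort$split[val] <- "validation"
  attr(cohort, "design") <- des[c("row_ids", "log_det")]
  cohort
}
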