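#' Experiment configuration for the end-to-end pipeline
#'
#' @param cohort A [cohort_config()] controlling the synthetic cohort.
#' @param n_raters Panel size simulated on the validation split (the same
#'   first `n_train_raters` policies also label the training split).
#' @param n_train_raters Raters labeling training cases.
#' @param families Classifier families to train (see [model_families()]).
#' @param grids Optional named list of hyperparameter grids per family.
#' @param scenario Consensus membership scenario for training labels.
#' @param noise_sd Panel latent-noise level (fraction of score SD).
#' @param min_panel Smallest base size for the robustness curve.
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir Optional directory; when set, all artifacts (cohort,
#'   labels, consensus, metrics, importances, convergence curve, manifest)
#'   are written there as CSV/JSON.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(), n_raters = 9,
                              n_train_raters = 6,
                              families = c("gb", "lr"), grids = NULL,
                              scenario = "exclude_algo", noise_sd = 0.15,
                              min_panel = 5, seed = 1, out_dir = NULL) {
  stopifnot(n_train_raters <= n_raters)
  structure(list(cohort = cohort, n_raters = n_raters,
                 n_train_raters = n_train_raters, families = families,
                 grids = grids, scenario = scenario, noise_sd = noise_sd,
                 min_panel = min_panel, seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full triage-study pipeline
#'
#' Executes the stages end to end: cohort generation (D-optimal design +
#' Monte Carlo completion), panel simulation (training raters on the
#' training split, the full panel on validation), physician consensus,
#' per-family training with grid search and 5-fold CV, out-of-sample model
#' selection, the full evaluation suite (triage metrics, medical-attention
#' metrics, safety summary, per-rater label distributions, per-physician
#' agreement under three consensus scenarios), both feature-importance
#' rankings, and the panel-size consensus-robustness curve. Reproducible
#' bit-for-bit under the global seed.
#'
#' @param config An [experiment_config()].
#' @return List with the cohort, labels, consensus tables, model records,
#'   selection table, metrics, importances, convergence curve and a
#'   manifest (seed, sizes, package version).
#' @export
run_pipeline <- function(config = experiment_config()) {
  cfg <- config
  cohort <- generate_cohort(cfg$cohort)
  train <- cohort[cohort$split == "train", ]
  valid <- cohort[cohort$split == "validation", ]

  panel <- default_panel(cohort, n_raters = cfg$n_raters,
                         seed = cfg$seed, noise_sd = cfg$noise_sd)
  for (k in seq_along(panel))
    panel[[k]]$splits <- if (k <= cfg$n_train_raters)
      c("train", "validation") else "validation"
  labels <- simulate_panel(cohort, panel, seed = cfg$seed)
  train_labels <- labels[labels$case_id %in% train$case_id, ]
  valid_labels <- labels[labels$case_id %in% valid$case_id, ]

  train_consensus <- consensus_labels(train_labels, "exclude_algo")
  valid_consensus <- consensus_labels(valid_labels, "exclude_algo")

  Xtr <- encode_features(train)
  Xva <- encode_features(valid)
  ytr_t <- train_consensus$triage[match(train$case_id, train_consensus$case_id)]
  ytr_e <- train_consensus$exacerbation[match(train$case_id, train_consensus$case_id)]
  yva_t <- valid_consensus$triage[match(valid$case_id, valid_consensus$case_id)]
  yva_e <- valid_consensus$exacerbation[match(valid$case_id, valid_consensus$case_id)]

  fit_task <- function(y, task) {
    recs <- lapply(cfg$families, function(fam)
      train_and_tune(Xtr, y, fam, task = task,
                     grid = cfg$grids[[fam]], seed = cfg$seed))
    names(recs) <- cfg$families
    recs
  }
  recs_t <- fit_task(ytr_t, "triage")
  recs_e <- fit_task(ytr_e, "exacerbation")
  sel_t <- select_top_models(recs_t, Xva, yva_t)
  sel_e <- select_top_models(recs_e, Xva, yva_e)

  top_t <- sel_t$top2[[1]]
  top_e <- sel_e$top2[[1]]
  pred_t <- predict(top_t, Xva)
  pred_e <- predict(top_e, Xva)
  algo_votes <- data.frame(case_id = valid$case_id, triage = pred_t,
                           exacerbation = pred_e, stringsAsFactors = FALSE)

  # consensus including the algorithm's vote, and its agreement with it
  cons_all <- consensus_labels(valid_labels, "all_members",
                               algo_votes = algo_votes)
  yva_t_all <- cons_all$triage[match(valid$case_id, cons_all$case_id)]
  cm_t <- build_confusion(pred_t, yva_t_all, K = 4)
  cm_e <- build_confusion(pred_e + 1L,
                          cons_all$exacerbation[match(valid$case_id, cons_all$case_id)] + 1L,
                          K = 2)
  metrics <- list(
    triage = triage_metrics(cm_t),
    medical_attention = medical_attention_metrics(pred_t, yva_t_all),
    safety = safety_summary(cm_t),
    exacerbation_acc = 100 * mean((pred_e + 1L) ==
      (cons_all$exacerbation[match(valid$case_id, cons_all$case_id)] + 1L))
  )

  # per-physician agreement under the three membership scenarios
  rater_ids <- unique(valid_labels$rater_id)
  agreement <- lapply(rater_ids, function(r) {
    own <- valid_labels[valid_labels$rater_id == r, ]
    agree <- function(cons) {
      i <- match(own$case_id, cons$case_id)
      c(triage = 100 * mean(own$triage == cons$triage[i]),
        exacerbation = 100 * mean(own$exacerbation == cons$exacerbation[i]))
    }
    rbind(all_members = agree(cons_all),
          exclude_algo = agree(valid_consensus),
          leave_self_out = agree(consensus_labels(
            valid_labels, "leave_self_out", scored_member = r,
            algo_votes = algo_votes)))
  })
  names(agreement) <- rater_ids

  importances <- list(
    triage = list(gb = if ("gb" %in% names(recs_t)) importance_gb(recs_t$gb),
                  lr = if ("lr" %in% names(recs_t)) importance_lr(recs_t$lr)),
    exacerbation = list(gb = if ("gb" %in% names(recs_e)) importance_gb(recs_e$gb),
                        lr = if ("lr" %in% names(recs_e)) importance_lr(recs_e$lr)))

  curve <- convergence_curve(valid_labels, min_panel = cfg$min_panel,
                             algo_votes = algo_votes)
  dists <- label_distributions(valid_labels)

  manifest <- list(seed = cfg$seed, n_total = cfg$cohort$n_total,
                   n_design = cfg$cohort$n_design,
                   n_validation = cfg$cohort$n_validation,
                   n_raters = cfg$n_raters,
                   n_train_raters = cfg$n_train_raters,
                   families = cfg$families, scenario = cfg$scenario,
                   package_version = as.character(utils::packageVersion("copdtriage")))

  report <- list(cohort = cohort, labels = labels,
                 train_consensus = train_consensus,
                 valid_consensus = valid_consensus,
                 consensus_all_members = cons_all,
                 models = list(triage = recs_t, exacerbation = recs_e),
                 selection = list(triage = sel_t$table, exacerbation = sel_e$table),
                 algo_votes = algo_votes,
                 confusion = list(triage = cm_t, exacerbation = cm_e),
                 metrics = metrics, agreement = agreement,
                 importances = importances, convergence = curve,
                 distributions = dists, manifest = manifest)

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write pipeline artifacts to a directory
#'
#' @param report List returned by [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_cases(report$cohort, p("cohort.csv"))
  write_labels(report$labels, p("labels.csv"))
  write_consensus(report$valid_consensus, "exclude_algo", p("consensus_validation.csv"))
  write.csv(report$selection$triage, p("selection_triage.csv"), row.names = FALSE)
  write.csv(report$selection$exacerbation, p("selection_exacerbation.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(unclass(report$confusion$triage)),
            p("confusion_triage.csv"))
  write.csv(report$convergence, p("convergence_curve.csv"), row.names = FALSE)
  for (task in names(report$importances))
    for (fam in names(report$importances[[task]]))
      if (!is.null(report$importances[[task]][[fam]]))
        write.csv(head(report$importances[[task]][[fam]], 30),
                  p(sprintf("importance_%s_%s.csv", task, fam)),
                  row.names = FALSE)
  drop_cm <- report$metrics
  drop_cm$medical_attention$cm <- NULL
  drop_cm$safety$by_category <- NULL
  jsonlite::write_json(
    list(metrics = drop_cm, manifest = report$manifest),
    p("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
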