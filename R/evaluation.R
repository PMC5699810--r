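#' Build a confusion matrix of predictions against consensus
#'
#' Rows are the consensus (true) category, columns the predicted category,
#' both ordered from least to most conservative (Ok < Plan < Doc < ER for
#' triage; no < yes for exacerbation). Entries below the diagonal are
#' under-triage relative to consensus; entries above are over-triage.
#'
#' @param predicted Vector of predicted categories (integers in 1..K).
#' @param consensus Vector of consensus categories, same length.
#' @param K Number of categories (4 = triage, 2 = exacerbation).
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
build_confusion <- function(predicted, consensus, K = 4) {
  if (length(predicted) != length(consensus))
    stop("alignment error: predicted and consensus differ in length")
  stopifnot(all(predicted %in% 1:K), all(consensus %in% 1:K))
  cm <- matrix(0L, K, K, dimnames = list(consensus = 1:K, predicted = 1:K))
  for (i in seq_along(predicted))
    cm[consensus[i], predicted[i]] <- cm[consensus[i], predicted[i]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Triage performance metrics from a 4x4 confusion matrix
#'
#' Classification accuracy; emergency one-vs-rest sensitivity, specificity,
#' PPV and NPV (category 4 = ER treated as positive); upper-triangular
#' proximity `UTP = 100 * (1 - LT/n)` where `LT` counts below-diagonal
#' (under-triage) entries; and the greater-than-one-category error
#' `EG1 = 100 * CG1/n`. All rates in percent. Metrics with a zero
#' denominator are reported as `NA` (undefined), never coerced to 0.
#'
#' @param cm A 4x4 [build_confusion()] matrix (consensus rows,
#'   prediction columns).
#' @return List with rates `ACC`, `TPR`, `TNR`, `PPV`, `NPV`, `UTP`, `EG1`
#'   and integer components `TC`, `FC`, `TP_ER`, `TN_ER`, `FP_ER`, `FN_ER`,
#'   `LT`, `C_G1`, `n`.
#' @export
triage_metrics <- function(cm) {
  stopifnot(nrow(cm) == 4, ncol(cm) == 4)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  TC <- sum(diag(cm)); FC <- n - TC
  TP <- cm[4, 4]
  FN <- sum(cm[4, 1:3])
  FP <- sum(cm[1:3, 4])
  TN <- n - TP - FN - FP
  LT <- sum(cm[lower.tri(cm)])
  idx <- which(abs(row(cm) - col(cm)) > 1)
  C_G1 <- sum(cm[idx])
  list(ACC = pct(TC, n),
       TPR = pct(TP, TP + FN), TNR = pct(TN, TN + FP),
       PPV = pct(TP, TP + FP), NPV = pct(TN, TN + FN),
       UTP = 100 - pct(LT, n), EG1 = pct(C_G1, n),
       TC = TC, FC = FC, TP_ER = TP, TN_ER = TN, FP_ER = FP, FN_ER = FN,
       LT = LT, C_G1 = C_G1, n = n)
}

#' Medical-attention metrics (triage collapsed to attention vs none)
#'
#' Collapses triage categories {1,2} to "no medical attention" and {3,4}
#' (call the doctor / emergency care) to "attention needed" on both the
#' predicted and consensus vectors, then computes accuracy, sensitivity,
#' specificity, PPV and NPV on the 2x2 table. Rates in percent; zero
#' denominators give `NA`.
#'
#' @param predicted,consensus Triage category vectors (1..4).
#' @return List with `ACC_M`, `TPR_M`, `TNR_M`, `PPV_M`, `NPV_M` and
#'   components `TC_M`, `FC_M`, `TP_M`, `TN_M`, `FP_M`, `FN_M`, `n`,
#'   plus the collapsed 2x2 `cm` (rows consensus no/yes attention).
#' @export
medical_attention_metrics <- function(predicted, consensus) {
  if (length(predicted) != length(consensus))
    stop("alignment error: predicted and consensus differ in length")
  p <- as.integer(predicted >= 3) + 1L
  c_ <- as.integer(consensus >= 3) + 1L
  cm <- build_confusion(p, c_, K = 2)
  TP <- cm[2, 2]; TN <- cm[1, 1]; FP <- cm[1, 2]; FN <- cm[2, 1]
  n <- sum(cm)
  list(ACC_M = pct(TP + TN, n),
       TPR_M = pct(TP, TP + FN), TNR_M = pct(TN, TN + FP),
       PPV_M = pct(TP, TP + FP), NPV_M = pct(TN, TN + FN),
       TC_M = TP + TN, FC_M = FP + FN,
       TP_M = TP, TN_M = TN, FP_M = FP, FN_M = FN, n = n, cm = cm)
}

#' Under-/over-triage safety summary
#'
#' Reports the under-triage rate (below-diagonal share of all cases), the
#' over-triage rate, the under-triage share among misclassifications, the
#' count of greater-than-one-category errors, and a per-consensus-category
#' breakdown of misses.
#'
#' @param cm A 4x4 [build_confusion()] matrix.
#' @return List with `under_rate`, `over_rate`, `under_share_of_errors`
#'   (all percent; the share is `NA` for a diagonal matrix), `n_gt1`, and
#'   `by_category` (data.frame: consensus category, n, missed, under,
#'   over).
#' @export
safety_summary <- function(cm) {
  stopifnot(nrow(cm) == 4, ncol(cm) == 4)
  n <- sum(cm)
  TC <- sum(diag(cm))
  LT <- sum(cm[lower.tri(cm)])
  UT <- sum(cm[upper.tri(cm)])
  by_cat <- data.frame(
    consensus = 1:4,
    n = rowSums(cm),
    missed = rowSums(cm) - diag(cm),
    under = vapply(1:4, function(i) sum(cm[i, seq_len(i - 1)]), 0),
    over = vapply(1:4, function(i) if (i < 4) sum(cm[i, (i + 1):4]) else 0, 0)
  )
  list(under_rate = pct(LT, n), over_rate = pct(UT, n),
       under_share_of_errors = pct(LT, n - TC),
       n_gt1 = sum(cm[abs(row(cm) - col(cm)) > 1]),
       by_category = by_cat)
}

#' Per-rater label distributions with outlier flags
#'
#' Computes each rater's share of every triage and exacerbation category,
#' the cross-rater mean and standard deviation per category, and flags
#' raters whose share deviates from the mean by more than 2 standard
#' deviations (the criterion used to call out outlier physicians).
#'
#' @param labels A `copd_labels` data.frame.
#' @return List with `triage` and `exacerbation`, each holding `shares`
#'   (raters x categories, rows sum to 1), `mean`, `sd` (per category;
#'   `NULL` with a single rater) and `flags` (logical raters x categories).
#' @export
label_distributions <- function(labels) {
  one <- function(task, categories) {
    V <- votes_wide(labels, task)
    shares <- t(vapply(seq_len(ncol(V)), function(j)
      vapply(categories, function(k) mean(V[, j] == k), 0), numeric(length(categories))))
    dimnames(shares) <- list(colnames(V), categories)
    if (nrow(shares) < 2) return(list(shares = shares, mean = NULL,
                                      sd = NULL, flags = NULL))
    mu <- colMeans(shares)
    sdv <- apply(shares, 2, sd)
    flags <- sweep(abs(sweep(shares, 2, mu)), 2, 2 * sdv) > 0
    list(shares = shares, mean = mu, sd = sdv, flags = flags)
  }
  list(triage = one("triage", 1:4), exacerbation = one("exacerbation", 0:1))
}
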