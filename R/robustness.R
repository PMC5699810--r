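#' Panel-size consensus-robustness curve
#'
#' For each base panel size `s` from `min_panel` to one less than the member
#' count: enumerate every size-`s` member subset, compute its per-case
#' consensus (majority vote with the conservative tie-break), then for each
#' member not in the subset compute the percentage of cases whose consensus
#' changes when that member is added; average over added members, and
#' report the mean, max and min of that average over all size-`s` subsets.
#' Enumeration is exhaustive (no sampling), so the curve is bit-exactly
#' reproducible.
#'
#' The member pool is whatever the label matrix contains: pass physician
#' labels only, or append the algorithm's votes as an extra member (via
#' `algo_votes`) to study the panel-plus-algorithm pool.
#'
#' @param labels A `copd_labels` data.frame.
#' @param min_panel Smallest base panel size (default 5).
#' @param task `"triage"` (default) or `"exacerbation"`.
#' @param algo_votes Optional data.frame `case_id`, `triage`,
#'   `exacerbation` added to the pool as member `"algorithm"`.
#' @return data.frame of convergence points: `panel_size_from`,
#'   `panel_size_to`, `mean_change`, `max_change`, `min_change` (percent of
#'   cases whose consensus label changed).
#' @export
convergence_curve <- function(labels, min_panel = 5,
                              task = c("triage", "exacerbation"),
                              algo_votes = NULL) {
  task <- match.arg(task)
  if (min_panel < 1) stop("invalid panel size")
  if (!is.null(algo_votes)) {
    algo <- data.frame(rater_id = "algorithm", case_id = algo_votes$case_id,
                       triage = algo_votes$triage,
                       exacerbation = algo_votes$exacerbation,
                       triage_conf = NA_real_, exac_conf = NA_real_,
                       stringsAsFactors = FALSE)
    labels <- rbind(as.data.frame(labels)[names(algo)], algo)
  }
  categories <- if (task == "triage") 1:4 else 0:1
  V <- votes_wide(labels, task)
  m <- ncol(V); nc <- nrow(V); K <- length(categories)
  if (m < min_panel + 1) stop("invalid panel size: need more members than min_panel")
  # per-member one-hot count contributions (cases x K per member)
  member_counts <- lapply(seq_len(m), function(j) {
    mc <- vapply(categories, function(k) as.numeric(V[, j] == k), numeric(nc))
    if (nc == 1) mc <- matrix(mc, nrow = 1)
    mc
  })
  out <- list()
  for (s in min_panel:(m - 1)) {
    subsets <- combn(m, s)
    vals <- numeric(ncol(subsets))
    for (t in seq_len(ncol(subsets))) {
      sub <- subsets[, t]
      counts0 <- Reduce(`+`, member_counts[sub])
      cons0 <- categories[max.col(counts0, ties.method = "last")]
      adders <- setdiff(seq_len(m), sub)
      ch <- vapply(adders, function(j) {
        cons1 <- categories[max.col(counts0 + member_counts[[j]],
                                    ties.method = "last")]
        100 * mean(cons1 != cons0)
      }, 0)
      vals[t] <- mean(ch)
    }
    out[[length(out) + 1]] <- data.frame(
      panel_size_from = s, panel_size_to = s + 1,
      mean_change = mean(vals), max_change = max(vals),
      min_change = min(vals))
  }
  do.call(rbind, out)
}
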