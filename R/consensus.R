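#' Majority vote with conservative tie-break
#'
#' Returns the modal category; among categories tied for the maximal count,
#' the highest (most conservative medical decision) wins. For exacerbation
#' votes coded 0/1, "yes" (1) is the conservative category.
#'
#' @param votes Vector of ordinal categories (integers).
#' @param categories The admissible category set, in increasing
#'   conservativeness (default 1:4 triage).
#' @return A single category.
#' @export
majority_vote <- function(votes, categories = 1:4) {
  if (length(votes) == 0) stop("no votes")
  if (!all(votes %in% categories))
    stop("vote outside category set: ", paste(setdiff(votes, categories), collapse = ","))
  counts <- vapply(categories, function(k) sum(votes == k), 0L)
  categories[max(which(counts == max(counts)))]
}

# wide votes matrix (cases x members) from a copd_labels data.frame
votes_wide <- function(labels, task = c("triage", "exacerbation")) {
  task <- match.arg(task)
  raters <- unique(labels$rater_id)
  cases <- unique(labels$case_id)
  V <- matrix(NA_integer_, length(cases), length(raters),
              dimnames = list(cases, raters))
  V[cbind(match(labels$case_id, cases), match(labels$rater_id, raters))] <-
    as.integer(labels[[task]])
  if (anyNA(V)) stop("labels incomplete: not every rater labeled every case")
  V
}

# vectorized conservative majority over a wide votes matrix
majority_rows <- function(V, categories) {
  counts <- vapply(categories, function(k) rowSums(V == k),
                   numeric(nrow(V)))
  if (nrow(V) == 1) counts <- matrix(counts, nrow = 1)
  categories[max.col(counts, ties.method = "last")]
}

#' Per-case consensus labels under a membership scenario
#'
#' Computes the majority-with-conservative-tie-break consensus for triage
#' and exacerbation under one of the three membership scenarios:
#' `all_members` (physicians plus the algorithm's votes), `exclude_algo`
#' (physicians only), and `leave_self_out` (the consensus scored against a
#' member excludes that member's own votes).
#'
#' @param labels A `copd_labels` data.frame (see [simulate_panel()]).
#' @param scenario One of `"all_members"`, `"exclude_algo"`,
#'   `"leave_self_out"`.
#' @param scored_member Rater id whose votes are removed
#'   (`leave_self_out` only).
#' @param algo_votes Optional data.frame `case_id`, `triage`,
#'   `exacerbation`: the algorithm's votes. Required for `all_members`;
#'   under `leave_self_out` they are included in the member pool when
#'   supplied (both variants of the scenario are thereby available).
#' @return data.frame `case_id`, `triage`, `exacerbation`.
#' @export
consensus_labels <- function(labels,
                             scenario = c("exclude_algo", "all_members",
                                          "leave_self_out"),
                             scored_member = NULL, algo_votes = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "all_members" && is.null(algo_votes))
    stop("all_members scenario requires algo_votes")
  if (scenario == "leave_self_out" && is.null(scored_member))
    stop("member required for leave_self_out")
  if (!is.null(algo_votes)) {
    algo <- data.frame(rater_id = "algorithm", case_id = algo_votes$case_id,
                       triage = algo_votes$triage,
                       exacerbation = algo_votes$exacerbation,
                       triage_conf = NA_real_, exac_conf = NA_real_,
                       stringsAsFactors = FALSE)
    labels <- rbind(as.data.frame(labels)[names(algo)], algo)
  }
  if (scenario == "leave_self_out") {
    if (!scored_member %in% labels$rater_id)
      stop("scored_member '", scored_member, "' has no votes")
    labels <- labels[labels$rater_id != scored_member, , drop = FALSE]
    if (nrow(labels) == 0) stop("no votes left after removing scored member")
  }
  Vt <- votes_wide(labels, "triage")
  Ve <- votes_wide(labels, "exacerbation")
  data.frame(case_id = rownames(Vt),
             triage = majority_rows(Vt, 1:4),
             exacerbation = majority_rows(Ve, 0:1),
             stringsAsFactors = FALSE)
}
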