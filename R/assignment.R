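#' Per-patient disease counts within each cluster
#'
#' For every patient, counts how many of their distinct long-term conditions
#' fall in each cluster of the map. This count vector is the common input to
#' every assignment strategy: e.g. a person with four metabolic, two
#' respiratory-and-vascular and one alcohol-and-liver condition has the count
#' vector (4, 2, 1) over those three clusters and 0 elsewhere.
#'
#' @param x A [cohort()] or an event tibble
#'   (`patient_id, disease_id, ...`); one row per patient-disease pair.
#' @param map A [cluster_map()] covering every disease present.
#' @return A tibble of class `cluster_counts` in long format with one row per
#'   patient x cluster (zeros included): columns `patient_id`, `cluster_id`,
#'   `n`, and `n_total` (the patient's number of distinct diseases).
#' @export
cluster_counts <- function(x, map) {
  events <- if (inherits(x, "cohort")) x$events else as_tibble(x)
  check_columns(events, c("patient_id", "disease_id"), "event table")
  unknown <- setdiff(unique(events$disease_id), map$disease_id)
  if (length(unknown) > 0) {
    abort(paste0("disease_id(s) not in cluster map: ",
                 paste(utils::head(unknown, 5), collapse = ", ")),
          class = "mltc_referential_error")
  }
  events <- distinct(events, .data$patient_id, .data$disease_id)

  patients <- sort(unique(events$patient_id))
  clusters <- sort(unique(map$cluster_id))
  cl_of <- setNames(map$cluster_id, map$disease_id)

  # dense patient x cluster tabulation (fast path used by all strategies)
  i <- match(events$patient_id, patients)
  j <- match(cl_of[events$disease_id], clusters)
  m <- matrix(
    tabulate(i + (j - 1L) * length(patients),
             nbins = length(patients) * length(clusters)),
    nrow = length(patients), ncol = length(clusters),
    dimnames = list(patients, clusters)
  )

  totals <- rowSums(m)
  if (any(totals < 2)) {
    abort("every patient must have at least 2 distinct diseases",
          class = "mltc_validation_error")
  }
  out <- tibble(
    patient_id = rep(patients, each = length(clusters)),
    cluster_id = rep(clusters, times = length(patients)),
    n = as.integer(t(m)),
    n_total = rep(as.integer(totals), each = length(clusters))
  )
  structure(out, class = c("cluster_counts", class(out)),
            count_matrix = m)
}

count_matrix <- function(counts) {
  stopifnot(inherits(counts, "cluster_counts"))
  attr(counts, "count_matrix")
}

new_assignment <- function(counts, values, strategy, ties = NULL) {
  m <- count_matrix(counts)
  out <- tibble(
    patient_id = rep(rownames(m), each = ncol(m)),
    cluster_id = rep(colnames(m), times = nrow(m)),
    value = as.numeric(t(values)),
    strategy = strategy
  )
  structure(out, class = c("assignment_result", class(out)),
            strategy = strategy, value_matrix = values, ties = ties)
}

value_matrix <- function(assignment) attr(assignment, "value_matrix")

#' Assignment strategy of a result
#' @param assignment An `assignment_result`.
#' @return The strategy string.
#' @export
assignment_strategy <- function(assignment) attr(assignment, "strategy")

#' Modal tie flags of a modal assignment
#' @param assignment An `assignment_result` from [assign_modal()].
#' @return A tibble `patient_id, modal_tie`.
#' @export
modal_ties <- function(assignment) {
  ties <- attr(assignment, "ties")
  if (is.null(ties)) {
    abort("tie flags are defined only for the modal strategy")
  }
  ties
}

#' Threshold assignment: clusters with at least m diseases
#'
#' Assigns a cluster (value 1) to a patient when the patient has at least `m`
#' diseases in it. `m` = 1, 2, 3 give the one-or-more, two-or-more and
#' three-or-more strategies (`"ge1"`, `"ge2"`, `"ge3"`); any `m >= 1` is
#' accepted.
#'
#' @param counts A [cluster_counts()] table.
#' @param m Integer threshold, at least 1.
#' @return An `assignment_result` tibble (`patient_id, cluster_id, value,
#'   strategy`) with binary values.
#' @export
assign_threshold <- function(counts, m = 1L) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("threshold m must be an integer >= 1", class = "mltc_parameter_error")
  }
  cm <- count_matrix(counts)
  new_assignment(counts, (cm >= m) * 1L, paste0("ge", as.integer(m)))
}

#' Modal assignment: the single best-represented cluster
#'
#' Assigns exactly one cluster per patient: the cluster containing the modal
#' (largest) number of the patient's diseases. When two or more clusters tie
#' for the maximum, the winner is chosen uniformly at random among the tied
#' clusters and the patient's tie flag is set, so the tie rate is reportable.
#'
#' @param counts A [cluster_counts()] table.
#' @param seed Integer seed for the tie-break stream; draws are consumed in
#'   patient-id order so a given (cohort, seed) pair is reproducible.
#' @return An `assignment_result` with one-hot binary values; tie flags
#'   retrievable with [modal_ties()].
#' @export
assign_modal <- function(counts, seed = 1L) {
  cm <- count_matrix(counts)
  withr::with_seed(seed, {
    winner <- max.col(cm, ties.method = "random")
  })
  row_max <- cm[cbind(seq_len(nrow(cm)), winner)]
  tie <- rowSums(cm == row_max) >= 2L
  v <- matrix(0L, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  v[cbind(seq_len(nrow(cm)), winner)] <- 1L
  ties <- tibble(patient_id = rownames(cm), modal_tie = unname(tie))
  new_assignment(counts, v, "modal", ties = ties)
}

#' Majority assignment: the cluster holding over half the diseases
#'
#' Assigns a cluster when strictly more than 50% of a patient's diseases fall
#' in it. At most one cluster can qualify; a patient whose largest cluster
#' holds exactly half (or less) of their diseases is assigned no cluster.
#'
#' @param counts A [cluster_counts()] table.
#' @return An `assignment_result` with binary values and at most one nonzero
#'   per patient.
#' @export
assign_majority <- function(counts) {
  cm <- count_matrix(counts)
  v <- (cm / rowSums(cm) > 0.5) * 1L
  new_assignment(counts, v, "majority")
}

#' Proportion assignment: share of diseases in each cluster
#'
#' Represents each patient by the proportion of their diseases in each
#' cluster; rows sum to 1.
#'
#' @param counts A [cluster_counts()] table.
#' @return An `assignment_result` with values in `[0, 1]`.
#' @export
assign_proportion <- function(counts) {
  cm <- count_matrix(counts)
  new_assignment(counts, cm / rowSums(cm), "proportion")
}

#' Count assignment: number of diseases in each cluster
#'
#' Represents each patient by the raw count of their diseases in each
#' cluster (the count vector itself).
#'
#' @param counts A [cluster_counts()] table.
#' @return An `assignment_result` with nonnegative integer values.
#' @export
assign_count <- function(counts) {
  new_assignment(counts, count_matrix(counts) + 0L, "count")
}

#' Apply one of the seven assignment strategies
#'
#' Dispatches on the strategy name: thresholds `"ge1"`, `"ge2"`, `"ge3"`
#' (or any `"ge<m>"`), `"modal"`, `"majority"`, `"count"`, `"proportion"`.
#'
#' @param counts A [cluster_counts()] table.
#' @param strategy Strategy name.
#' @param seed Seed for the modal tie-break (ignored otherwise).
#' @return An `assignment_result`.
#' @export
assign_clusters <- function(counts, strategy, seed = 1L) {
  if (grepl("^ge[0-9]+$", strategy)) {
    return(assign_threshold(counts, as.integer(sub("^ge", "", strategy))))
  }
  switch(strategy,
    modal = assign_modal(counts, seed = seed),
    majority = assign_majority(counts),
    count = assign_count(counts),
    proportion = assign_proportion(counts),
    abort(paste0("unknown strategy: ", strategy),
          class = "mltc_parameter_error")
  )
}

#' Summarise assignment patterns for one strategy
#'
#' Computes the assignment-pattern metrics used to compare strategies: the
#' percentage of patients assigned to no cluster, exactly one, or more than
#' one; the percentage whose assigned clusters represent *all* their diseases
#' ("fully represented"); and the median and interquartile range of the
#' number of each patient's diseases left in unassigned clusters. For the
#' count and proportion strategies a cluster counts as assigned whenever its
#' value is nonzero, so these coincide with the one-or-more pattern. For the
#' modal strategy the percentage of patients with tied modal clusters is also
#' reported.
#'
#' @param assignment An `assignment_result`.
#' @param counts The [cluster_counts()] the assignment was computed from.
#' @return A one-row tibble: `strategy, pct_none, pct_one, pct_multi,
#'   pct_fully_represented, median_unassigned_ltcs, iqr_unassigned_lo,
#'   iqr_unassigned_hi, pct_modal_ties`.
#' @export
summarize_assignment <- function(assignment, counts) {
  cm <- count_matrix(counts)
  vm <- value_matrix(assignment)
  if (!identical(dimnames(vm), dimnames(cm))) {
    abort("assignment and counts cover different patients or clusters",
          class = "mltc_alignment_error")
  }
  assigned <- vm > 0
  n_assigned <- rowSums(assigned)
  n_pat <- nrow(cm)
  covered <- rowSums(cm * assigned)
  unassigned <- rowSums(cm) - covered
  q <- quantile(unassigned, c(0.25, 0.5, 0.75), names = FALSE)
  ties <- attr(assignment, "ties")
  tibble(
    strategy = assignment_strategy(assignment),
    pct_none = 100 * mean(n_assigned == 0),
    pct_one = 100 * mean(n_assigned == 1),
    pct_multi = 100 * mean(n_assigned > 1),
    pct_fully_represented = 100 * mean(unassigned == 0),
    median_unassigned_ltcs = q[2],
    iqr_unassigned_lo = q[1],
    iqr_unassigned_hi = q[3],
    pct_modal_ties = if (is.null(ties)) NA_real_ else 100 * mean(ties$modal_tie)
  )
}

#' Summarise assignment patterns across strategies
#'
#' Runs [summarize_assignment()] for each requested strategy and stacks the
#' rows, giving a strategy-comparison table of assignment patterns.
#'
#' @param counts A [cluster_counts()] table.
#' @param strategies Character vector of strategy names (default: all seven).
#' @param seed Seed for the modal tie-break.
#' @return A tibble with one row per strategy.
#' @export
summarize_assignments <- function(counts, strategies = strategy_names(),
                                  seed = 1L) {
  purrr::map_dfr(strategies, function(s) {
    summarize_assignment(assign_clusters(counts, s, seed = seed), counts)
  })
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> strategy '%s', %d patients x %d clusters\n",
              assignment_strategy(x), nrow(value_matrix(x)),
              ncol(value_matrix(x))))
  NextMethod()
}
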