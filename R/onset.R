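#' Median age at diagnosis per disease
#'
#' For each disease with at least one diagnosis event, the median of the
#' per-patient earliest diagnosis ages (each patient contributes one event
#' per disease). Even-sized samples use the midpoint of the two central
#' values.
#'
#' @param x A [cohort()] or an event tibble
#'   (`patient_id, disease_id, age_at_diagnosis`).
#' @return A tibble of class `onset_table`: `unit_id, level, median_age,
#'   n_events` with `level = "disease"`.
#' @export
median_onset_by_disease <- function(x) {
  events <- if (inherits(x, "cohort")) x$events else as_tibble(x)
  check_columns(events, c("patient_id", "disease_id", "age_at_diagnosis"),
                "event table")
  if (nrow(events) == 0) {
    abort("no diagnosis events", class = "mltc_validation_error")
  }
  out <- events |>
    group_by(unit_id = .data$disease_id) |>
    summarise(
      level = "disease",
      median_age = median(.data$age_at_diagnosis),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$unit_id)
  structure(out, class = c("onset_table", class(out)))
}

#' Median age at diagnosis per cluster
#'
#' For each cluster, the median age at diagnosis of *any* event of a member
#' disease: events are pooled across the cluster's diseases (event-weighted),
#' not averaged over per-disease medians. A cluster containing a single
#' disease therefore reproduces that disease's median exactly.
#'
#' @param x A [cohort()] or an event tibble.
#' @param map A [cluster_map()] covering every disease present.
#' @return A tibble of class `onset_table` with `level = "cluster"`.
#' @export
median_onset_by_cluster <- function(x, map) {
  events <- if (inherits(x, "cohort")) x$events else as_tibble(x)
  check_columns(events, c("patient_id", "disease_id", "age_at_diagnosis"),
                "event table")
  if (nrow(events) == 0) {
    abort("no diagnosis events", class = "mltc_validation_error")
  }
  unknown <- setdiff(unique(events$disease_id), map$disease_id)
  if (length(unknown) > 0) {
    abort(paste0("disease_id(s) not in cluster map: ",
                 paste(utils::head(unknown, 5), collapse = ", ")),
          class = "mltc_referential_error")
  }
  out <- events |>
    mutate(cluster_id = map$cluster_id[match(.data$disease_id,
                                             map$disease_id)]) |>
    group_by(unit_id = .data$cluster_id) |>
    summarise(
      level = "cluster",
      median_age = median(.data$age_at_diagnosis),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$unit_id)
  structure(out, class = c("onset_table", class(out)))
}

#' Combined disease- and cluster-level onset profile
#'
#' Convenience wrapper stacking [median_onset_by_disease()] and
#' [median_onset_by_cluster()] rows, with each disease annotated by its
#' cluster, ordered by cluster then disease — the layout used for
#' within-vs-between-cluster onset dot plots.
#'
#' @inheritParams median_onset_by_cluster
#' @return An `onset_table` tibble with an extra `cluster_id` column.
#' @export
onset_profile <- function(x, map) {
  dis <- median_onset_by_disease(x)
  cl <- median_onset_by_cluster(x, map)
  dis$cluster_id <- map$cluster_id[match(dis$unit_id, map$disease_id)]
  cl$cluster_id <- cl$unit_id
  out <- bind_rows(cl, dis) |>
    arrange(.data$cluster_id, .data$level, .data$unit_id)
  structure(out, class = c("onset_table", class(as_tibble(out))))
}
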