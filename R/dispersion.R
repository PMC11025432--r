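#' Adjusted odds ratios for clusters and their member diseases
#'
#' Combines two fits on the same cohort and outcome — a cluster-level model
#' (by convention the count strategy, so each cluster aOR is per additional
#' disease in the cluster) and the disease-level reference model — into one
#' table of adjusted odds ratios for the exposure terms only (covariate
#' coefficients are excluded). Disease rows are joined to their clusters so
#' within-cluster spread can be inspected. Diseases dropped at the design
#' stage (absent or collinear) appear with missing estimates and
#' `dropped = TRUE`.
#'
#' @param cluster_fit An `mltc_logit` whose exposures are clusters.
#' @param disease_fit An `mltc_logit` whose exposures are diseases.
#' @param map A [cluster_map()].
#' @param conf.level Confidence level for Wald intervals (default 0.95).
#' @return A tibble of class `or_table`: `term_id, cluster_id, level`
#'   (`"cluster"`/`"disease"`), `aOR, ci_low, ci_high, significant,
#'   separated` (the fit's separation flag: the estimate is reported but
#'   not usable), `dropped`, plus `outcome`.
#' @export
odds_ratio_table <- function(cluster_fit, disease_fit, map,
                             conf.level = 0.95) {
  stopifnot(inherits(cluster_fit, "mltc_logit"),
            inherits(disease_fit, "mltc_logit"))
  if (!identical(cluster_fit$outcome, disease_fit$outcome)) {
    abort("fits are for different outcomes", class = "mltc_alignment_error")
  }
  if (cluster_fit$n != disease_fit$n) {
    abort("fits are on different cohorts", class = "mltc_alignment_error")
  }
  if (!cluster_fit$converged || !disease_fit$converged) {
    warn("at least one fit did not converge; odds ratios may be unstable")
  }

  exposure_rows <- function(fit, ids, level, cluster_of) {
    est <- tidy(fit, exponentiate = TRUE, conf.level = conf.level) |>
      filter(.data$term %in% fit$exposure_cols)
    found <- match(ids, est$term)
    tibble(
      term_id = ids,
      cluster_id = cluster_of,
      level = level,
      aOR = est$estimate[found],
      ci_low = est$conf.low[found],
      ci_high = est$conf.high[found],
      significant = !is.na(found) &
        !(est$conf.low[found] <= 1 & est$conf.high[found] >= 1),
      separated = ids %in% fit$separation,
      dropped = is.na(found)
    )
  }

  clusters <- sort(unique(map$cluster_id))
  diseases <- sort(map$disease_id)
  out <- bind_rows(
    exposure_rows(cluster_fit, clusters, "cluster", clusters),
    exposure_rows(disease_fit, diseases, "disease",
                  map$cluster_id[match(diseases, map$disease_id)])
  )
  out$outcome <- cluster_fit$outcome
  if (any(out$dropped)) {
    warn(sprintf("%d exposure term(s) had no estimate (dropped at design/fit)",
                 sum(out$dropped)))
  }
  structure(out, class = c("or_table", class(as_tibble(out))))
}

#' Within- versus between-cluster dispersion of adjusted odds ratios
#'
#' Quantifies how consistently the diseases of a cluster relate to an
#' outcome. For each cluster, the *within range* is the spread (max minus
#' min, on the log-odds-ratio scale) of its member diseases' adjusted odds
#' ratios from the disease-level model; the *between range* is the spread of
#' the cluster-level estimates. The headline comparison asks whether the
#' median within-cluster range exceeds the between-cluster range — if so,
#' diseases within a cluster vary more in their outcome associations than
#' the clusters do among themselves, cautioning against ascribing
#' cluster-level effects to member diseases.
#'
#' Separation-flagged estimates are excluded from all ranges (with a
#' warning): their magnitudes are artefacts of quasi-complete separation,
#' not effect estimates, and a single one would dominate the range it
#' enters. Note that the all-diseases within-range retains a sampling-noise
#' floor set by the least-informative member diseases (rare conditions with
#' few outcome events); the significant-only variant largely removes that
#' floor by restricting to estimable associations.
#'
#' @param table An [odds_ratio_table()].
#' @param variant `"all_diseases"` uses every estimated disease row;
#'   `"significant_only"` restricts to diseases whose 95% CI excludes 1.
#' @return A list of class `dispersion_summary`: `per_cluster` (tibble
#'   `cluster_id, within_range, n_diseases_used`), `between_range`,
#'   `median_within_range`, `within_exceeds_between`, `variant`, `outcome`.
#'   Ranges are on the log-aOR scale.
#' @export
dispersion_summary <- function(table,
                               variant = c("all_diseases",
                                           "significant_only")) {
  stopifnot(inherits(table, "or_table"))
  variant <- match.arg(variant)

  # separation-flagged coefficients are not usable effect estimates; they
  # would dominate any range they enter
  usable <- filter(table, !is.na(.data$aOR), !.data$separated)
  n_sep <- sum(table$separated, na.rm = TRUE)
  if (n_sep > 0) {
    warn(sprintf("%d separation-flagged estimate(s) excluded from ranges",
                 n_sep))
  }
  cl <- filter(usable, .data$level == "cluster")
  if (nrow(cl) < 1) abort("no cluster-level estimates in table")
  between_range <- diff(range(log(cl$aOR)))

  dis <- filter(usable, .data$level == "disease")
  if (variant == "significant_only") dis <- filter(dis, .data$significant)

  per_cluster <- dis |>
    group_by(.data$cluster_id) |>
    summarise(
      within_range = if (dplyr::n() >= 2) diff(range(log(.data$aOR))) else NA_real_,
      n_diseases_used = dplyr::n(),
      .groups = "drop"
    )
  # clusters present in the map but with <2 usable disease rows
  missing_cl <- setdiff(unique(table$cluster_id), per_cluster$cluster_id)
  if (length(missing_cl) > 0) {
    per_cluster <- bind_rows(per_cluster, tibble(
      cluster_id = missing_cl, within_range = NA_real_,
      n_diseases_used = 0L
    )) |> arrange(.data$cluster_id)
  }
  n_undef <- sum(is.na(per_cluster$within_range))
  if (n_undef > 0) {
    warn(sprintf(
      "%d cluster(s) with fewer than 2 usable disease estimates excluded from the median within-range",
      n_undef
    ))
  }
  med <- median(per_cluster$within_range, na.rm = TRUE)

  structure(
    list(
      per_cluster = per_cluster,
      between_range = between_range,
      median_within_range = med,
      within_exceeds_between = isTRUE(med > between_range),
      variant = variant,
      outcome = table$outcome[1]
    ),
    class = "dispersion_summary"
  )
}

#' @export
glance.dispersion_summary <- function(x, ...) {
  tibble(
    outcome = x$outcome, variant = x$variant,
    median_within_range = x$median_within_range,
    between_range = x$between_range,
    within_exceeds_between = x$within_exceeds_between,
    n_clusters_used = sum(!is.na(x$per_cluster$within_range))
  )
}

#' @export
tidy.dispersion_summary <- function(x, ...) x$per_cluster

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dispersion_summary> outcome '%s' (%s):\n",
           "  median within-cluster log-aOR range %.3f %s between-cluster range %.3f\n"),
    x$outcome, x$variant, x$median_within_range,
    if (x$within_exceeds_between) ">" else "<=", x$between_range
  ))
  invisible(x)
}
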