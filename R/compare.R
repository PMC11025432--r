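#' Compare assignment strategies at explaining one-year outcomes
#'
#' Fits one logistic regression per (representation, outcome) cell on the
#' identical patient set: each of the requested cluster-assignment
#' strategies, plus (by default) the disease-level reference model using
#' every disease as a binary predictor. All models adjust for age, gender,
#' ethnicity and IMD decile. Performance is compared by AIC; since every
#' cluster strategy has the same number of exposure variables, a lower AIC
#' among them indicates greater explained variation.
#'
#' Patients flagged as de-registered are excluded first (equal follow-up);
#' pass a cohort already through [apply_followup_exclusion()] to make this a
#' no-op.
#'
#' @param x A [cohort()].
#' @param map A [cluster_map()].
#' @param strategies Cluster strategies to compare (default: all seven).
#' @param outcomes Outcomes to model (default: all three).
#' @param include_diseases Also fit the disease-level reference model.
#' @param seed Seed for the modal tie-break.
#' @param imd Passed to [build_design()].
#' @return An object of class `strategy_comparison`: a tibble with one row
#'   per cell (`outcome, representation, n, k, logLik, AIC, converged`),
#'   carrying the fitted models in an attribute (retrievable with
#'   [comparison_fits()]).
#' @export
compare_strategies <- function(x, map, strategies = strategy_names(),
                               outcomes = outcome_names(),
                               include_diseases = TRUE, seed = 1L,
                               imd = "categorical") {
  stopifnot(inherits(x, "cohort"))
  if (any(x$patients$deregistered)) {
    x <- apply_followup_exclusion(x)
  }
  counts <- cluster_counts(x, map)

  reps <- c(strategies, if (include_diseases) "diseases")
  designs <- lapply(setNames(reps, reps), function(r) {
    if (r == "diseases") {
      build_design(x, "diseases", map = map, imd = imd)
    } else {
      build_design(x, assign_clusters(counts, r, seed = seed), imd = imd)
    }
  })

  fits <- list()
  rows <- list()
  for (oc in outcomes) {
    for (r in reps) {
      f <- fit_logistic(designs[[r]], oc)
      fits[[paste(oc, r, sep = ".")]] <- f
      rows[[paste(oc, r, sep = ".")]] <- glance(f)
    }
  }
  tab <- bind_rows(rows) |>
    select(all_of(c("outcome", "representation", "n", "k",
                    "logLik", "AIC", "converged")))

  structure(tab,
    class = c("strategy_comparison", class(tab)),
    fits = fits, strategies = strategies,
    include_diseases = include_diseases
  )
}

#' Fitted models of a strategy comparison
#'
#' @param comparison A [compare_strategies()] result.
#' @param outcome,representation Optional selectors; with both supplied a
#'   single `mltc_logit` is returned, otherwise the full named list
#'   (`"<outcome>.<representation>"`).
#' @return An `mltc_logit` or a named list of them.
#' @export
comparison_fits <- function(comparison, outcome = NULL,
                            representation = NULL) {
  fits <- attr(comparison, "fits")
  if (is.null(outcome) && is.null(representation)) return(fits)
  fits[[paste(outcome, representation, sep = ".")]]
}

#' Per-outcome verdicts of a strategy comparison
#'
#' For each outcome: the cluster strategy with the lowest AIC, whether the
#' disease-level reference model beats every cluster strategy, and the AIC
#' gap between the best and worst cluster strategies.
#'
#' @param x A `strategy_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per outcome: `outcome,
#'   best_cluster_strategy, worst_cluster_strategy, diseases_beats_all,
#'   aic_range_clusters`.
#' @export
glance.strategy_comparison <- function(x, ...) {
  strategies <- attr(x, "strategies")
  tab <- as_tibble(x)
  tab |>
    group_by(.data$outcome) |>
    summarise(
      best_cluster_strategy =
        .data$representation[.data$representation %in% strategies][
          which.min(.data$AIC[.data$representation %in% strategies])],
      worst_cluster_strategy =
        .data$representation[.data$representation %in% strategies][
          which.max(.data$AIC[.data$representation %in% strategies])],
      diseases_beats_all = if ("diseases" %in% .data$representation) {
        .data$AIC[.data$representation == "diseases"] <
          min(.data$AIC[.data$representation %in% strategies])
      } else NA,
      aic_range_clusters =
        max(.data$AIC[.data$representation %in% strategies]) -
        min(.data$AIC[.data$representation %in% strategies]),
      .groups = "drop"
    )
}

#' @export
tidy.strategy_comparison <- function(x, ...) as_tibble(x)

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  print(as_tibble(x), ...)
  g <- glance(x)
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %s: best cluster strategy '%s'%s\n", g$outcome[i],
      g$best_cluster_strategy[i],
      if (isTRUE(g$diseases_beats_all[i])) {
        "; disease-level model beats all strategies"
      } else ""
    ))
  }
  invisible(x)
}
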