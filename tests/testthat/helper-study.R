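# The replicated synthetic study used by the ordering and dispersion
# acceptance checks: 10 runs at n = 20,000 patients, 212 diseases, 15
# clusters, within-cluster heterogeneity 0.5 (the generator defaults).
# Computed once per test session and cached.
run_study <- function(run_seed, n_patients = 20000, heterogeneity_sd = 0.5,
                      full_comparison = TRUE) {
  cfg <- sim_config(n_patients = n_patients,
                    heterogeneity_sd = heterogeneity_sd)
  catalog <- make_catalog(cfg, seed = 1000 + run_seed)
  ch <- suppressMessages(apply_followup_exclusion(
    suppressMessages(simulate_cohort(catalog, seed = 2000 + run_seed))
  ))
  if (full_comparison) {
    cmp <- suppressWarnings(suppressMessages(
      compare_strategies(ch, catalog$map, seed = 3000 + run_seed)
    ))
    or_tab <- suppressWarnings(odds_ratio_table(
      comparison_fits(cmp, "death", "count"),
      comparison_fits(cmp, "death", "diseases"),
      catalog$map
    ))
  } else {
    cc <- cluster_counts(ch, catalog$map)
    d_cl <- suppressWarnings(build_design(ch, assign_count(cc)))
    d_di <- suppressWarnings(build_design(ch, "diseases", map = catalog$map))
    cmp <- NULL
    or_tab <- suppressWarnings(odds_ratio_table(
      suppressWarnings(fit_logistic(d_cl, "death")),
      suppressWarnings(fit_logistic(d_di, "death")),
      catalog$map
    ))
  }
  list(
    verdicts = if (!is.null(cmp)) glance(cmp),
    dispersion = dplyr::bind_rows(
      suppressWarnings(glance(dispersion_summary(or_tab, "all_diseases"))),
      suppressWarnings(glance(dispersion_summary(or_tab, "significant_only")))
    )
  )
}

study_runs <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- lapply(1:10, run_study)
  }
  .fixture_cache$study
}
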