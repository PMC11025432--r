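#' Configuration for the synthetic EHR cohort generator
#'
#' Bundles every tunable of the generator. Defaults emulate the population
#' structure of a large English primary-care MLTC cohort: adults (age drawn
#' from a normal with mean 53, SD 18, truncated at 18), 53.1% female, a
#' right-skewed long-term-condition count with median 8 (IQR 5-11) obtained
#' as 2 plus a negative binomial, 212 diseases partitioned into 15 clusters,
#' and 4.9% de-registration during follow-up.
#'
#' Disease co-occurrence is cluster-correlated: each patient draws a
#' cluster-propensity vector from a symmetric Dirichlet with concentration
#' `dirichlet_alpha`; small values concentrate a patient's diseases in few
#' clusters, large values spread them evenly.
#'
#' Outcome generation is disease-driven: each disease d carries a log-odds
#' contribution gamma_d per outcome, drawn as the mean effect mu_c of its
#' cluster plus Normal(0, `heterogeneity_sd`) noise. `heterogeneity_sd` is
#' therefore the within-cluster effect-heterogeneity knob: at 0 every disease
#' in a cluster has an identical outcome association; at the default 0.5 the
#' within-cluster spread of effects is substantial relative to the
#' between-cluster spread (`cluster_effect_sd` = 0.3).
#'
#' @param n_patients Number of patients to simulate.
#' @param n_clusters,n_diseases Partition dimensions (defaults 15 and 212).
#' @param ltc_size,ltc_mu Negative-binomial size and mean for the LTC count
#'   law `L = 2 + NB(size, mu)`; the defaults give quartiles 5/8/11.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the
#'   per-patient cluster propensity (default 0.5).
#' @param baseline_logit Named numeric, per-outcome intercept on the log-odds
#'   scale at reference covariates and no disease effects. Defaults
#'   correspond to prevalences of 3% (death), 25% (ED attendance) and 15%
#'   (emergency admission).
#' @param heterogeneity_sd Within-cluster SD of disease log-odds effects
#'   around the cluster mean (same for every outcome).
#' @param cluster_effect_sd Between-cluster SD of the cluster mean effects.
#' @param covariate_effects Named list of log-odds effects shared across
#'   outcomes: `age` (per year, centred at 53), `male`, `ethnicity` (named
#'   vector per non-reference level), `imd` (per decile, centred at 5.5).
#' @param onset_median_range,onset_spread_range Ranges (years) from which
#'   per-disease onset medians and spreads are drawn uniformly.
#' @param prevalence_log10_range Range of log10 relative disease prevalence
#'   weights (default spans two orders of magnitude).
#' @param female_prob,age_mean,age_sd,ethnicity_probs Demographic knobs;
#'   `ethnicity_probs` must be a named probability vector whose first element
#'   is the reference (most frequent) level.
#' @param dereg_prob Probability of de-registration during follow-up.
#' @param seed Default integer seed used when none is passed to the
#'   generator functions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       n_clusters = 15,
                       n_diseases = 212,
                       ltc_size = 3,
                       ltc_mu = 6.5,
                       dirichlet_alpha = 0.5,
                       baseline_logit = c(
                         death = qlogis(0.03),
                         ed_attendance = qlogis(0.25),
                         emergency_admission = qlogis(0.15)
                       ),
                       heterogeneity_sd = 0.5,
                       cluster_effect_sd = 0.3,
                       covariate_effects = list(
                         age = 0.05,
                         male = 0.15,
                         ethnicity = c(south_asian = 0.10, black = 0.05,
                                       mixed_other = 0.00),
                         imd = 0.03
                       ),
                       onset_median_range = c(25, 80),
                       onset_spread_range = c(8, 15),
                       prevalence_log10_range = c(-2, 0),
                       female_prob = 0.531,
                       age_mean = 53,
                       age_sd = 18,
                       ethnicity_probs = c(white = 0.862, south_asian = 0.060,
                                           black = 0.040, mixed_other = 0.038),
                       dereg_prob = 0.049,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_clusters < 1 || cfg$n_diseases < cfg$n_clusters) {
    abort("need n_diseases >= n_clusters >= 1", class = "mltc_config_error")
  }
  if (cfg$dereg_prob < 0 || cfg$dereg_prob > 1) {
    abort("dereg_prob must be in [0, 1]", class = "mltc_config_error")
  }
  if (cfg$heterogeneity_sd < 0 || cfg$cluster_effect_sd < 0) {
    abort("effect SDs must be nonnegative", class = "mltc_config_error")
  }
  miss <- setdiff(outcome_names(), names(cfg$baseline_logit))
  if (length(miss) > 0) {
    abort(paste0("baseline_logit missing outcome(s): ",
                 paste(miss, collapse = ", ")), class = "mltc_config_error")
  }
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-8) {
    abort("ethnicity_probs must sum to 1", class = "mltc_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read config files")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "mltc_config_error")
  }
  if (!is.null(raw$baseline_logit)) raw$baseline_logit <- unlist(raw$baseline_logit)
  if (!is.null(raw$ethnicity_probs)) raw$ethnicity_probs <- unlist(raw$ethnicity_probs)
  if (!is.null(raw$covariate_effects)) {
    raw$covariate_effects$ethnicity <- unlist(raw$covariate_effects$ethnicity)
  }
  do.call(sim_config, raw)
}

#' Build a synthetic disease catalog
#'
#' Creates the fixed structure a simulated cohort is drawn from: a
#' disease-to-cluster partition (round-robin over a randomly permuted disease
#' order, so cluster sizes differ by at most one and every cluster is
#' non-empty), per-disease relative prevalence weights (log-uniform across
#' `prevalence_log10_range`), per-disease onset-age medians and spreads, and
#' per-outcome disease effects gamma_d = mu_c(d) + Normal(0, heterogeneity_sd)
#' where the cluster means mu_c are Normal(0, cluster_effect_sd). The true
#' gamma_d are retained so downstream model fits can be checked against the
#' generating values.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `disease_catalog` with elements `map` (a
#'   [cluster_map()]), `diseases` (tibble: disease_id, cluster_id,
#'   base_prevalence, onset_median, onset_spread, gamma_<outcome>),
#'   `clusters` (tibble: cluster_id, mu_<outcome>) and `config`.
#' @export
make_catalog <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  D <- config$n_diseases
  K <- config$n_clusters
  withr::with_seed(seed, {
    disease_id <- sprintf("d%03d", seq_len(D))
    cluster_id <- sprintf("c%02d", seq_len(K))
    # round-robin over a random permutation: sizes differ by <= 1, none empty
    assignment <- cluster_id[(seq_len(D) - 1L) %% K + 1L][order(runif(D))]

    clusters <- tibble(cluster_id = cluster_id)
    for (oc in outcome_names()) {
      clusters[[paste0("mu_", oc)]] <- rnorm(K, 0, config$cluster_effect_sd)
    }

    diseases <- tibble(
      disease_id = disease_id,
      cluster_id = assignment,
      base_prevalence = 10^runif(D, config$prevalence_log10_range[1],
                                 config$prevalence_log10_range[2]),
      onset_median = runif(D, config$onset_median_range[1],
                           config$onset_median_range[2]),
      onset_spread = runif(D, config$onset_spread_range[1],
                           config$onset_spread_range[2])
    )
    mu_of <- function(oc) {
      clusters[[paste0("mu_", oc)]][match(diseases$cluster_id,
                                          clusters$cluster_id)]
    }
    for (oc in outcome_names()) {
      diseases[[paste0("gamma_", oc)]] <-
        mu_of(oc) + rnorm(D, 0, config$heterogeneity_sd)
    }

    map <- cluster_map(tibble(
      disease_id = diseases$disease_id,
      disease_name = paste("disease", diseases$disease_id),
      cluster_id = diseases$cluster_id,
      cluster_name = paste("cluster", diseases$cluster_id)
    ))
    structure(
      list(map = map, diseases = diseases, clusters = clusters,
           config = config, seed = seed),
      class = "disease_catalog"
    )
  })
}

#' Simulate a synthetic MLTC cohort
#'
#' Draws `config$n_patients` patients from a [make_catalog()] structure:
#' demographics as documented in [sim_config()]; a per-patient long-term
#' condition count `L = 2 + NB(ltc_size, ltc_mu)` (capped at the number of
#' diseases with a warning if ever exceeded); a cluster-propensity vector
#' from `Dirichlet(alpha)`; `L` distinct diseases sampled without replacement
#' with weight `base_prevalence(d) * propensity(cluster(d))`; per-event age
#' at diagnosis from a normal with the disease's onset median and spread,
#' truncated to (0, age at index] by exact inverse-CDF sampling; each outcome
#' Bernoulli on the logistic scale from the baseline logit, covariate effects
#' and the sum of the patient's disease effects; and an independent
#' de-registration flag.
#'
#' @param catalog A `disease_catalog`.
#' @param config A [sim_config()]; defaults to the one stored in the catalog.
#' @param seed Integer seed; defaults to `config$seed + 1` so catalog and
#'   cohort draws are decoupled but jointly reproducible.
#' @return A validated [cohort()].
#' @export
simulate_cohort <- function(catalog, config = catalog$config,
                            seed = config$seed + 1L) {
  stopifnot(inherits(catalog, "disease_catalog"))
  n <- config$n_patients
  D <- config$n_diseases
  K <- config$n_clusters
  dis <- catalog$diseases

  withr::with_seed(seed, {
    patient_id <- sprintf("p%07d", seq_len(n))
    # truncated-at-18 normal age via inverse CDF
    lo <- pnorm(18, config$age_mean, config$age_sd)
    age <- qnorm(runif(n, lo, 1), config$age_mean, config$age_sd)
    gender <- ifelse(runif(n) < config$female_prob, "female", "male")
    ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                        prob = config$ethnicity_probs)
    # slight gradient towards less deprived areas: 52.3% in deciles 1-5
    imd_probs <- c(rep(0.523 / 5, 5), rep(0.477 / 5, 5))
    imd <- sample(1:10, n, replace = TRUE, prob = imd_probs)

    L <- 2L + rnbinom(n, size = config$ltc_size, mu = config$ltc_mu)
    if (any(L > D)) {
      warn(sprintf("capped %d LTC count(s) at the number of diseases (%d)",
                   sum(L > D), D))
      L <- pmin(L, D)
    }

    # per-patient cluster propensity: symmetric Dirichlet via gamma draws
    g <- matrix(rgamma(n * K, shape = config$dirichlet_alpha), nrow = n)
    degen <- rowSums(g) == 0 # possible at tiny alpha
    if (any(degen)) g[degen, ] <- 1
    pi_mat <- g / rowSums(g)

    cl_index <- match(dis$cluster_id, catalog$clusters$cluster_id)
    base_w <- dis$base_prevalence
    picks <- lapply(seq_len(n), function(i) {
      sample.int(D, L[i], prob = base_w * pi_mat[i, cl_index])
    })
    ev_patient <- rep(seq_len(n), L)
    ev_disease <- unlist(picks, use.names = FALSE)

    # onset age: exact truncated normal on (0, age_at_index]
    m <- dis$onset_median[ev_disease]
    s <- dis$onset_spread[ev_disease]
    a <- age[ev_patient]
    p_lo <- pnorm(0, m, s)
    p_hi <- pnorm(a, m, s)
    onset <- qnorm(runif(length(m), p_lo, pmax(p_hi, p_lo)), m, s)
    # clamp where the window has numerically zero mass
    onset <- pmin(pmax(onset, 1e-3), a)

    # outcomes
    eth_eff <- c(setNames(0, names(config$ethnicity_probs)[1]),
                 config$covariate_effects$ethnicity)
    lp_cov <- config$covariate_effects$age * (age - config$age_mean) +
      config$covariate_effects$male * (gender == "male") +
      eth_eff[ethnicity] +
      config$covariate_effects$imd * (imd - 5.5)

    pat <- tibble(
      patient_id = patient_id,
      age_at_index = age,
      gender = gender,
      ethnicity = ethnicity,
      imd_decile = imd,
      deregistered = runif(n) < config$dereg_prob
    )
    for (oc in outcome_names()) {
      gam <- dis[[paste0("gamma_", oc)]][ev_disease]
      burden <- rowsum(gam, ev_patient)[, 1]
      lp <- config$baseline_logit[[oc]] + lp_cov + burden
      pat[[oc]] <- as.integer(runif(n) < plogis(lp))
    }

    events <- tibble(
      patient_id = patient_id[ev_patient],
      disease_id = dis$disease_id[ev_disease],
      age_at_diagnosis = round(onset, 4)
    )
    pat$age_at_index <- round(pat$age_at_index, 4)
    events$age_at_diagnosis <- pmin(events$age_at_diagnosis,
                                    pat$age_at_index[match(events$patient_id,
                                                           pat$patient_id)])
    cohort(pat, events, map = catalog$map,
           index_date_label = sprintf("synthetic (seed %d)", seed))
  })
}

#' Write the generator's ground-truth disease effects
#'
#' Emits `disease_id, cluster_id, gamma_death, gamma_ed_attendance,
#' gamma_emergency_admission` so that coefficient-recovery checks can compare
#' fitted disease-level estimates against the generating values.
#'
#' @param catalog A `disease_catalog`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog_truth <- function(catalog, path) {
  stopifnot(inherits(catalog, "disease_catalog"))
  truth <- select(catalog$diseases, all_of(c(
    "disease_id", "cluster_id", paste0("gamma_", outcome_names())
  )))
  readr::write_csv(truth, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n=%d, D=%d diseases, K=%d clusters, alpha=%.3g, tau=%.3g\n",
    x$n_patients, x$n_diseases, x$n_clusters, x$dirichlet_alpha,
    x$heterogeneity_sd
  ))
  invisible(x)
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat(sprintf("<disease_catalog> %d diseases in %d clusters (seed %d)\n",
              n_diseases(x$map), n_clusters(x$map), x$seed))
  invisible(x)
}
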