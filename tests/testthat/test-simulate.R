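test_that("catalog partition covers all diseases with no empty cluster", {
  cfg <- sim_config(n_patients = 10, n_diseases = 6, n_clusters = 3)
  catalog <- make_catalog(cfg, seed = 1)
  sizes <- table(catalog$diseases$cluster_id)
  expect_length(sizes, 3)
  expect_true(all(sizes >= 1))
  expect_equal(length(unique(catalog$diseases$disease_id)), 6)
  expect_error(
    make_catalog(sim_config(n_patients = 10, n_diseases = 2, n_clusters = 3)),
    class = "mltc_config_error"
  )
})

test_that("zero heterogeneity collapses disease effects onto cluster means", {
  cfg <- sim_config(n_patients = 10, n_diseases = 30, n_clusters = 5,
                    heterogeneity_sd = 0)
  catalog <- make_catalog(cfg, seed = 2)
  for (oc in c("death", "ed_attendance", "emergency_admission")) {
    mu <- catalog$clusters[[paste0("mu_", oc)]][
      match(catalog$diseases$cluster_id, catalog$clusters$cluster_id)]
    expect_equal(catalog$diseases[[paste0("gamma_", oc)]], mu)
  }
})

test_that("generation is reproducible from the seed and varies across seeds", {
  cfg <- sim_config(n_patients = 150, n_diseases = 30, n_clusters = 5)
  c1 <- make_catalog(cfg, seed = 7)
  c2 <- make_catalog(cfg, seed = 7)
  c3 <- make_catalog(cfg, seed = 8)
  expect_equal(c1$diseases, c2$diseases)
  expect_false(isTRUE(all.equal(c1$diseases$gamma_death,
                                c3$diseases$gamma_death)))

  s1 <- suppressMessages(simulate_cohort(c1, seed = 20))
  s2 <- suppressMessages(simulate_cohort(c1, seed = 20))
  s3 <- suppressMessages(simulate_cohort(c1, seed = 21))
  expect_equal(as.data.frame(s1$patients), as.data.frame(s2$patients))
  expect_equal(as.data.frame(s1$events), as.data.frame(s2$events))
  expect_false(identical(s1$events$disease_id, s3$events$disease_id))

  # byte-identical CSVs from identical (config, seed)
  d <- withr::local_tempdir()
  write_cohort(s1, file.path(d, "p1.csv"), file.path(d, "e1.csv"))
  write_cohort(s2, file.path(d, "p2.csv"), file.path(d, "e2.csv"))
  expect_identical(readLines(file.path(d, "p1.csv")),
                   readLines(file.path(d, "p2.csv")))
  expect_identical(readLines(file.path(d, "e1.csv")),
                   readLines(file.path(d, "e2.csv")))
})

test_that("every simulated patient is an MLTC adult with valid onset ages", {
  fx <- small_sim()
  ch <- fx$cohort
  expect_true(all(ch$patients$age_at_index >= 18))
  expect_true(all(table(ch$events$patient_id) >= 2))
  idx <- setNames(ch$patients$age_at_index, ch$patients$patient_id)
  expect_true(all(ch$events$age_at_diagnosis > 0))
  expect_true(all(ch$events$age_at_diagnosis <= idx[ch$events$patient_id]))
  # no duplicate patient-disease pair
  expect_equal(anyDuplicated(ch$events[c("patient_id", "disease_id")]), 0)
})

test_that("the LTC count law hits median 8 with IQR 5-11", {
  cfg <- sim_config(n_patients = 20000, n_diseases = 100, n_clusters = 10)
  ch <- suppressMessages(simulate_cohort(make_catalog(cfg, seed = 31),
                                         seed = 32))
  counts <- as.integer(table(ch$events$patient_id))
  expect_equal(unname(quantile(counts, c(0.25, 0.5, 0.75))), c(5, 8, 11))
})

test_that("outcome prevalence matches an independent Monte-Carlo oracle", {
  # tau = 0, no covariate effects, baseline 10%: the only signal is the
  # cluster-mean effects of the sampled diseases.
  cfg <- sim_config(
    n_patients = 50000, n_diseases = 40, n_clusters = 6,
    heterogeneity_sd = 0,
    baseline_logit = c(death = qlogis(0.1), ed_attendance = qlogis(0.1),
                       emergency_admission = qlogis(0.1)),
    covariate_effects = list(age = 0, male = 0,
                             ethnicity = c(south_asian = 0, black = 0,
                                           mixed_other = 0),
                             imd = 0)
  )
  catalog <- make_catalog(cfg, seed = 41)
  ch <- suppressMessages(simulate_cohort(catalog, seed = 42))
  observed <- mean(ch$patients$death)

  # Oracle: re-implement the disease-mixture draw independently and average
  # the exact Bernoulli probabilities (no outcome sampling noise).
  oracle <- withr::with_seed(43, {
    D <- cfg$n_diseases; K <- cfg$n_clusters; R <- 50000
    gam <- catalog$diseases$gamma_death
    w0 <- catalog$diseases$base_prevalence
    cl <- match(catalog$diseases$cluster_id, catalog$clusters$cluster_id)
    probs <- vapply(seq_len(R), function(i) {
      L <- min(2 + rnbinom(1, size = cfg$ltc_size, mu = cfg$ltc_mu), D)
      g <- rgamma(K, cfg$dirichlet_alpha)
      if (sum(g) == 0) g[] <- 1
      pi_k <- g / sum(g)
      picked <- sample.int(D, L, prob = w0 * pi_k[cl])
      plogis(qlogis(0.1) + sum(gam[picked]))
    }, numeric(1))
    mean(probs)
  })
  expect_lt(abs(observed - oracle), 0.015)
})

test_that("large Dirichlet concentration spreads diseases across more clusters", {
  span <- function(alpha, seed) {
    cfg <- sim_config(n_patients = 2000, n_diseases = 60, n_clusters = 10,
                      dirichlet_alpha = alpha)
    ch <- suppressMessages(simulate_cohort(make_catalog(cfg, seed = 50),
                                           seed = seed))
    cc <- cluster_counts(ch, make_catalog(cfg, seed = 50)$map)
    mean(rowSums(attr(cc, "count_matrix") > 0))
  }
  spans <- vapply(c(0.1, 0.5, 2, 1000), span, numeric(1), seed = 51)
  expect_true(all(diff(spans) > 0)) # monotone increasing in alpha
  expect_gt(spans[4], spans[1])
})

test_that("infeasible LTC counts are capped at the number of diseases", {
  cfg <- sim_config(n_patients = 50, n_diseases = 5, n_clusters = 2,
                    ltc_mu = 30)
  expect_warning(
    ch <- suppressMessages(simulate_cohort(make_catalog(cfg, seed = 61),
                                           seed = 62)),
    "capped"
  )
  expect_true(all(table(ch$events$patient_id) <= 5))
})

test_that("YAML config round-trips into a sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 500",
    "n_diseases: 30",
    "n_clusters: 5",
    "dirichlet_alpha: 0.2",
    "dereg_prob: 0.02",
    "seed: 9"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_patients, 500)
  expect_equal(cfg$dirichlet_alpha, 0.2)
  expect_equal(cfg$heterogeneity_sd, 0.5) # untouched default

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_knob: 1", bad)
  expect_error(read_sim_config(bad), class = "mltc_config_error")
})

test_that("catalog truth export carries one effect row per disease", {
  fx <- small_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog_truth(fx$catalog, path)
  truth <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(truth), n_diseases(fx$catalog$map))
  expect_setequal(names(truth), c("disease_id", "cluster_id", "gamma_death",
                                  "gamma_ed_attendance",
                                  "gamma_emergency_admission"))
  expect_equal(truth$gamma_death, fx$catalog$diseases$gamma_death)
})
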