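# Shared fixtures, built in code.

# A small map: enough diseases per cluster to realise any count vector used
# in the tests. Cluster ids sort in the order given.
make_map <- function(sizes, cluster_ids = sprintf("c%02d", seq_along(sizes))) {
  cluster_map(tibble::tibble(
    disease_id = unlist(lapply(seq_along(sizes), function(k) {
      sprintf("%s_d%02d", cluster_ids[k], seq_len(sizes[k]))
    })),
    disease_name = "dn",
    cluster_id = rep(cluster_ids, sizes),
    cluster_name = rep(cluster_ids, sizes)
  ))
}

# Build a cluster_counts object realising the given per-patient count
# vectors (a named list of integer vectors, one entry per cluster).
counts_from <- function(count_vectors, map = NULL) {
  K <- length(count_vectors[[1]])
  if (is.null(map)) {
    map <- make_map(rep(max(unlist(count_vectors)), K))
  }
  cluster_ids <- sort(unique(map$cluster_id))
  events <- purrr::imap_dfr(count_vectors, function(cv, pid) {
    tibble::tibble(
      patient_id = pid,
      disease_id = unlist(lapply(seq_len(K), function(k) {
        map$disease_id[map$cluster_id == cluster_ids[k]][seq_len(cv[k])]
      }))
    )
  })
  cluster_counts(events, map)
}

# The worked seven-LTC example: four diseases in a metabolic cluster, two in
# a respiratory-and-vascular cluster, one in an alcohol-and-liver cluster.
fig_map <- function() {
  make_map(c(4, 2, 1),
           cluster_ids = c("c1_metabolic", "c2_resp_vasc", "c3_alcohol_liver"))
}

fig_counts <- function() {
  counts_from(list(personA = c(4L, 2L, 1L)), map = fig_map())
}

# Random multi-patient counts for property sweeps: each patient gets 2-12
# diseases spread over K clusters with a random concentration.
random_counts <- function(n_patients, K = 5, seed = 1) {
  withr::with_seed(seed, {
    map <- make_map(rep(13, K))
    cvs <- lapply(seq_len(n_patients), function(i) {
      L <- sample(2:12, 1)
      w <- rgamma(K, shape = runif(1, 0.2, 3))
      as.integer(tabulate(sample.int(K, L, replace = TRUE, prob = w / sum(w)),
                          nbins = K))
    })
    names(cvs) <- sprintf("p%04d", seq_len(n_patients))
    counts_from(cvs, map = map)
  })
}

# A small simulated cohort shared by several tests (lazily cached).
.fixture_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(n_patients = 800, n_diseases = 40, n_clusters = 6)
    catalog <- make_catalog(cfg, seed = 11)
    cohort <- suppressMessages(simulate_cohort(catalog, seed = 12))
    .fixture_cache$small <- list(config = cfg, catalog = catalog,
                                 cohort = cohort)
  }
  .fixture_cache$small
}

# Hand-construct a design_matrix for closed-form model oracles.
manual_design <- function(X, outcomes = NULL, exposure_cols = colnames(X)) {
  structure(
    list(
      x = X,
      patient_id = sprintf("p%03d", seq_len(nrow(X))),
      outcomes = outcomes,
      exposure_cols = exposure_cols,
      dropped_columns = character(0),
      representation = "manual"
    ),
    class = "design_matrix"
  )
}

# Hand-construct an mltc_logit carrying given exposure coefficients, for
# odds-ratio arithmetic checks.
manual_fit <- function(terms, estimates, std_errors, outcome = "death",
                       n = 100L) {
  structure(
    list(
      coefficients = tibble::tibble(term = terms, estimate = estimates,
                                    std.error = std_errors),
      loglik = -1, k = length(terms), aic = 2 * length(terms) + 2, n = n,
      converged = TRUE, n_iterations = 5L, separation = character(0),
      dropped_columns = character(0), exposure_cols = terms,
      representation = "manual", outcome = outcome
    ),
    class = "mltc_logit"
  )
}
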