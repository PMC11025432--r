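test_that("intercept-only fit recovers the logit of the prevalence", {
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(1, 0), c(25, 75))
  fit <- fit_logistic(manual_design(X, exposure_cols = character(0)), y)
  expect_equal(fit$coefficients$estimate, log(25 / 75), tolerance = 1e-4)
  expect_equal(fit$k, 1)
  expect_true(fit$converged)
})

test_that("single-binary-exposure fit matches the 2x2 log odds ratio", {
  X <- cbind(`(Intercept)` = 1, exposed = rep(c(1, 0), each = 100))
  y <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(10, 90)))
  fit <- fit_logistic(manual_design(X, exposure_cols = "exposed"), y)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(beta["exposed"]), log((30 * 90) / (70 * 10)),
               tolerance = 1e-4)
  expect_equal(unname(beta["(Intercept)"]), log(10 / 90), tolerance = 1e-4)
  # Wald SE from the 2x2 table: sqrt(sum of reciprocal cell counts)
  se <- fit$coefficients$std.error[fit$coefficients$term == "exposed"]
  expect_equal(se, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90), tolerance = 1e-4)
})

test_that("one-parameter MLE agrees with a brute-force likelihood grid", {
  withr::with_seed(88, {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(0.8 * x))
  })
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_logistic(manual_design(X, exposure_cols = "x"), y)
  grid <- seq(-5, 5, by = 1e-3)
  lnl <- vapply(grid, function(b) sum(dbinom(y, 1, plogis(b * x), log = TRUE)),
                numeric(1))
  expect_equal(fit$coefficients$estimate, grid[which.max(lnl)],
               tolerance = 2e-3)
  expect_equal(fit$loglik, max(lnl), tolerance = 1e-6)
})

test_that("AIC is exactly 2k minus twice the log-likelihood", {
  fake <- manual_fit("a", 0, 1)
  fake$loglik <- -10; fake$k <- 1
  expect_equal(aic(fake), 22)

  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(1, 0), 50)
  fit <- fit_logistic(manual_design(X, exposure_cols = character(0)), y)
  expect_equal(fit$loglik, 100 * log(0.5), tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * 100 * log(0.5), tolerance = 1e-3)
  expect_identical(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(AIC(fit), fit$aic) # via the logLik method
})

test_that("design matrices pass counts through and drop empty columns", {
  map <- make_map(c(3, 3, 1))
  pat <- tibble::tibble(
    patient_id = c("pa", "pb", "pc", "pd"),
    age_at_index = c(40, 50, 60, 70),
    gender = c("female", "male", "female", "male"),
    ethnicity = "white", imd_decile = c(2L, 2L, 3L, 4L), deregistered = FALSE,
    death = c(0L, 1L, 0L, 1L), ed_attendance = 0L, emergency_admission = 0L
  )
  events <- tibble::tibble(
    patient_id = c("pa", "pa", "pb", "pb",
                   "pc", "pc", "pc", "pc", "pc", "pc", "pd", "pd"),
    disease_id = c("c01_d01", "c01_d02", "c01_d01", "c02_d01",
                   "c01_d01", "c01_d02", "c01_d03", "c02_d01", "c02_d02",
                   "c03_d01", "c02_d01", "c02_d02"),
    age_at_diagnosis = 30
  )
  ch <- cohort(pat, events)
  cc <- cluster_counts(ch, map)
  cl_cols <- c("c01", "c02", "c03")

  d_count <- build_design(ch, assign_count(cc), imd = "continuous")
  expect_equal(unname(d_count$x[, cl_cols]),
               unname(attr(cc, "count_matrix") + 0))

  # majority: pa holds one in c01, pd in c02, nobody in c03 -> c03 all-zero
  expect_warning(
    d_maj <- build_design(ch, assign_majority(cc), imd = "continuous"),
    "zero-variance"
  )
  expect_true("c03" %in% d_maj$dropped_columns)
  expect_false("c03" %in% colnames(d_maj$x))

  # support equivalence of exposure blocks: ge1 vs count
  d_ge1 <- build_design(ch, assign_threshold(cc, 1), imd = "continuous")
  expect_identical(d_ge1$x[, cl_cols] > 0, d_count$x[, cl_cols] > 0)
  # identical patient ordering across representations
  expect_identical(d_ge1$patient_id, d_count$patient_id)
})

test_that("disease design uses one indicator per mapped disease", {
  fx <- small_sim()
  ch <- suppressMessages(apply_followup_exclusion(fx$cohort))
  d <- suppressWarnings(build_design(ch, "diseases", map = fx$catalog$map))
  present <- intersect(sort(fx$catalog$map$disease_id), colnames(d$x))
  # indicators agree with the event table
  ev <- dplyr::distinct(ch$events, patient_id, disease_id)
  for (dis in withr::with_seed(91, sample(present, 5))) {
    carriers <- sort(ev$patient_id[ev$disease_id == dis])
    expect_identical(sort(d$patient_id[d$x[, dis] == 1]), carriers)
  }
  expect_error(fit_logistic(d, rep(0, nrow(d$x))),
               class = "mltc_validation_error")
})

test_that("adding a predictor never decreases the log-likelihood", {
  withr::with_seed(90, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.7 * x1))
  })
  X1 <- cbind(`(Intercept)` = 1, x1 = x1)
  X2 <- cbind(X1, x2 = x2)
  f1 <- fit_logistic(manual_design(X1, exposure_cols = "x1"), y)
  f2 <- fit_logistic(manual_design(X2, exposure_cols = c("x1", "x2")), y)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_equal(f2$k, f1$k + 1)
})

test_that("strategy comparison shares one patient set and flags the best", {
  fx <- small_sim()
  cmp <- suppressWarnings(suppressMessages(
    compare_strategies(fx$cohort, fx$catalog$map, seed = 14)
  ))
  tab <- tibble::as_tibble(cmp)
  expect_equal(nrow(tab), 8 * 3)
  expect_equal(length(unique(tab$n)), 1) # equal-n guarantee
  # AIC identity holds in every cell
  expect_identical(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  g <- glance(cmp)
  expect_setequal(g$outcome, c("death", "ed_attendance",
                               "emergency_admission"))
  expect_true(all(g$best_cluster_strategy %in%
                    c("ge1", "ge2", "ge3", "modal", "majority", "count",
                      "proportion")))
  fit <- comparison_fits(cmp, "death", "count")
  expect_s3_class(fit, "mltc_logit")
  expect_equal(fit$representation, "count")
})

test_that("when no patient has two diseases in one cluster, ge1 and count coincide", {
  # every patient has at most one disease per cluster: the count design
  # equals the ge1 design, so the fits match cell for cell
  pat <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:40),
    age_at_index = seq(30, 69), gender = rep(c("female", "male"), 20),
    ethnicity = "white", imd_decile = rep(1:10, 4), deregistered = FALSE,
    death = rep(c(0L, 1L), 20), ed_attendance = rep(c(1L, 0L), 20),
    emergency_admission = 0L
  )
  map <- make_map(c(1, 1, 1))
  events <- tibble::tibble(
    patient_id = rep(pat$patient_id, each = 2),
    disease_id = rep(c("c01_d01", "c02_d01"), 40),
    age_at_diagnosis = 25
  )
  events$disease_id[seq(2, 80, by = 4)] <- "c03_d01"
  ch <- cohort(pat, events)
  cmp <- suppressWarnings(suppressMessages(compare_strategies(
    ch, map, strategies = c("ge1", "count"),
    outcomes = c("death", "ed_attendance"), include_diseases = FALSE
  )))
  tab <- tibble::as_tibble(cmp)
  aic_wide <- tidyr::pivot_wider(tab[c("outcome", "representation", "AIC")],
                                 names_from = "representation",
                                 values_from = "AIC")
  expect_equal(aic_wide$ge1, aic_wide$count)
})
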