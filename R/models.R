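#' Build a regression design matrix for one exposure representation
#'
#' Assembles the model matrix for the outcome regressions: an intercept, an
#' exposure block, and the shared covariate block (age in years, continuous;
#' a male indicator; ethnicity dummies with the most frequent level as
#' reference; IMD-decile dummies with decile 1 as reference, or a single
#' continuous IMD term if requested).
#'
#' The exposure block is either an [assign_clusters()] result — binary
#' columns for the threshold/modal/majority strategies, integer counts for
#' the count strategy, proportions for the proportion strategy — or, with
#' `representation = "diseases"`, one 0/1 indicator per disease in the map
#' (the disease-level reference model).
#'
#' Zero-variance columns (e.g. a cluster no patient has a majority in, or a
#' disease absent from the cohort) are dropped and recorded, so the AIC
#' parameter count reflects estimated coefficients only. Patient ordering is
#' by patient id, identical across representations, so fits on different
#' representations use the same patients in the same order.
#'
#' @param x A [cohort()] (after [apply_followup_exclusion()] for outcome
#'   analyses).
#' @param representation An `assignment_result`, or `"diseases"`.
#' @param map A [cluster_map()]; required when `representation =
#'   "diseases"`.
#' @param imd `"categorical"` (default) or `"continuous"`.
#' @return A list of class `design_matrix`: `x` (numeric matrix with named
#'   columns), `patient_id`, `outcomes` (matrix of the three 0/1 outcomes,
#'   same row order), `exposure_cols`, `dropped_columns`, `representation`.
#' @export
build_design <- function(x, representation, map = NULL,
                         imd = c("categorical", "continuous")) {
  stopifnot(inherits(x, "cohort"))
  imd <- match.arg(imd)
  pat <- arrange(x$patients, .data$patient_id)

  if (identical(representation, "diseases")) {
    if (is.null(map)) abort("map is required for the disease representation")
    diseases <- sort(map$disease_id)
    ev <- distinct(x$events, .data$patient_id, .data$disease_id)
    i <- match(ev$patient_id, pat$patient_id)
    j <- match(ev$disease_id, diseases)
    if (anyNA(j)) {
      abort("cohort contains diseases absent from the map",
            class = "mltc_referential_error")
    }
    expo <- matrix(0, nrow(pat), length(diseases),
                   dimnames = list(NULL, diseases))
    expo[cbind(i, j)] <- 1
    rep_label <- "diseases"
  } else if (inherits(representation, "assignment_result")) {
    vm <- value_matrix(representation)
    ord <- match(pat$patient_id, rownames(vm))
    if (anyNA(ord)) {
      abort("assignment does not cover every cohort patient",
            class = "mltc_alignment_error")
    }
    expo <- vm[ord, , drop = FALSE]
    rownames(expo) <- NULL
    rep_label <- assignment_strategy(representation)
  } else {
    abort("representation must be an assignment_result or \"diseases\"")
  }

  cov_block <- covariate_block(pat, imd)
  X <- cbind(`(Intercept)` = 1, expo, cov_block$x)
  exposure_cols <- colnames(expo)

  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  keep["(Intercept)"] <- TRUE
  dropped <- colnames(X)[!keep]
  if (length(dropped) > 0) {
    warn(paste0("dropped zero-variance column(s): ",
                paste(utils::head(dropped, 10), collapse = ", ")))
  }
  X <- X[, keep, drop = FALSE]

  structure(
    list(
      x = X,
      patient_id = pat$patient_id,
      outcomes = as.matrix(pat[outcome_names()]),
      exposure_cols = intersect(exposure_cols, colnames(X)),
      dropped_columns = c(cov_block$dropped, dropped),
      representation = rep_label
    ),
    class = "design_matrix"
  )
}

covariate_block <- function(pat, imd) {
  dropped <- character(0)
  out <- list(age = pat$age_at_index, gender_male = as.numeric(pat$gender == "male"))

  eth_tab <- sort(table(pat$ethnicity), decreasing = TRUE)
  eth_levels <- names(eth_tab)[-1] # reference = most frequent
  for (lv in eth_levels) {
    out[[paste0("ethnicity_", lv)]] <- as.numeric(pat$ethnicity == lv)
  }

  if (imd == "continuous") {
    out$imd_decile <- as.numeric(pat$imd_decile)
  } else {
    present <- sort(unique(pat$imd_decile))
    for (d in setdiff(present, present[1])) { # reference = lowest present decile
      out[[paste0("imd_", d)]] <- as.numeric(pat$imd_decile == d)
    }
    absent <- setdiff(1:10, present)
    if (length(absent) > 0) {
      dropped <- paste0("imd_", absent)
      warn(paste0("IMD decile(s) with no observations dropped: ",
                  paste(absent, collapse = ", ")))
    }
  }
  list(x = do.call(cbind, out), dropped = dropped)
}

#' Fit a logistic regression on a design matrix
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (`stats::glm.fit`), with convergence tolerance tightened so the
#' log-likelihood is stable to well below 1e-8 and an iteration cap of 100.
#' Standard errors come from the inverse observed information at the
#' optimum. Coefficients with `|beta| > 15` are flagged as probable
#' separation; non-convergence yields a warning and `converged = FALSE`, not
#' an error, so strategy comparisons can still report the cell.
#'
#' @param design A [build_design()] result.
#' @param outcome One of `"death"`, `"ed_attendance"`,
#'   `"emergency_admission"`, or a 0/1 vector aligned with the design rows.
#' @return An object of class `mltc_logit`: coefficients tibble (`term,
#'   estimate, std.error`), `loglik`, `k` (estimated parameters, including
#'   the intercept), `aic` (= 2k - 2 loglik), `n`, `converged`,
#'   `n_iterations`, `separation` (flagged terms), `exposure_cols`,
#'   `representation`, `outcome`.
#' @export
fit_logistic <- function(design, outcome) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.character(outcome) && length(outcome) == 1) {
    oc_name <- outcome
    if (!oc_name %in% colnames(design$outcomes)) {
      abort(paste0("unknown outcome: ", oc_name))
    }
    y <- design$outcomes[, oc_name]
  } else {
    oc_name <- "custom"
    y <- as.numeric(outcome)
  }
  X <- design$x
  if (length(y) != nrow(X)) {
    abort("outcome length does not match design rows",
          class = "mltc_alignment_error")
  }
  if (length(unique(y)) < 2) {
    abort("outcome is constant; cannot fit", class = "mltc_validation_error")
  }

  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-12, maxit = 100))
  )
  beta <- fit$coefficients
  aliased <- is.na(beta)
  if (any(aliased)) {
    warn(paste0("aliased (collinear) column(s) excluded: ",
                paste(names(beta)[aliased], collapse = ", ")))
  }
  est <- beta[!aliased]

  # observed information from the weighted QR at the optimum (cf. summary.glm)
  p <- fit$rank
  Qr <- fit$qr
  cov_unscaled <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(cov_unscaled))
  names(se) <- colnames(Qr$qr)[seq_len(p)]
  se <- se[names(est)]

  mu <- fit$fitted.values
  loglik <- sum(dbinom(y, 1, mu, log = TRUE))
  k <- length(est)
  if (!fit$converged) {
    warn(sprintf("IRLS did not converge in %d iterations", fit$iter))
  }
  sep <- names(est)[abs(est) > 15]
  if (length(sep) > 0) {
    warn(paste0("possible separation (|beta| > 15): ",
                paste(sep, collapse = ", ")))
  }

  structure(
    list(
      coefficients = tibble(term = names(est), estimate = unname(est),
                            std.error = unname(se)),
      loglik = loglik,
      k = k,
      aic = 2 * k - 2 * loglik,
      n = length(y),
      converged = fit$converged,
      n_iterations = fit$iter,
      separation = sep,
      dropped_columns = c(design$dropped_columns, names(beta)[aliased]),
      exposure_cols = setdiff(design$exposure_cols, names(beta)[aliased]),
      representation = design$representation,
      outcome = oc_name
    ),
    class = "mltc_logit"
  )
}

#' Akaike information criterion of a fitted model
#'
#' `2k - 2 lnL`, where `k` counts every estimated coefficient including the
#' intercept (dropped or aliased columns excluded); lower values indicate a
#' better fit at equal data.
#'
#' @param fit An `mltc_logit`.
#' @return The AIC as a single number.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "mltc_logit"))
  2 * fit$k - 2 * fit$loglik
}

#' @export
logLik.mltc_logit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.mltc_logit <- function(x, ...) {
  cat(sprintf(
    "<mltc_logit> outcome '%s', representation '%s': n=%d, k=%d, AIC=%.1f%s\n",
    x$outcome, x$representation, x$n, x$k, x$aic,
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' Tidy a fitted logistic regression
#'
#' @param x An `mltc_logit`.
#' @param exponentiate Return odds ratios and exponentiated confidence
#'   limits instead of log-odds.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble: `term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high`.
#' @export
tidy.mltc_logit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- x$coefficients |>
    mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      conf.low = .data$estimate - z * .data$std.error,
      conf.high = .data$estimate + z * .data$std.error
    )
  if (exponentiate) {
    out <- mutate(out, across(all_of(c("estimate", "conf.low", "conf.high")),
                              exp))
  }
  out
}

#' Glance at a fitted logistic regression
#'
#' @param x An `mltc_logit`.
#' @param ... Unused.
#' @return A one-row tibble: `representation, outcome, n, k, logLik, AIC,
#'   converged, n_iterations`.
#' @export
glance.mltc_logit <- function(x, ...) {
  tibble(
    representation = x$representation, outcome = x$outcome,
    n = x$n, k = x$k, logLik = x$loglik, AIC = x$aic,
    converged = x$converged, n_iterations = x$n_iterations
  )
}
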