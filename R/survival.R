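# TIN-stratified survival analysis: Kaplan-Meier estimation, log-rank
# testing and Cox proportional-hazards regression (fitted via the survival
# package, Efron tie handling by default).

#' Build a survival table stratified by TIN status
#'
#' Joins TIN profiles with clinical data and derives a two-level grouping:
#' the scheme's positive class ("sTIN", "oTIN", "either" = sTIN or oTIN,
#' "both" = sTIN and oTIN) versus the rest. Categorical covariates are
#' coded against conventional reference levels: stage II, MSS, female sex,
#' right-sided location.
#'
#' @param profiles A `tin_profiles` tibble.
#' @param clinical A `clinical_table` tibble.
#' @param scheme One of "sTIN", "oTIN", "either", "both".
#' @param allow_subset Drop profiled samples without a clinical record
#'   (with a logged count) instead of erroring.
#' @return A `survival_table` tibble: `sample_id`, `time_years`, `event`,
#'   `group` (factor, reference = "rest"), `stage`, `msi`, `age`, `sex`,
#'   `location`.
#' @export
build_survival_groups <- function(profiles, clinical,
                                  scheme = c("sTIN", "oTIN", "either", "both"),
                                  allow_subset = FALSE) {
  scheme <- match.arg(scheme)
  if (!all(c("sample_id", "is_sTIN", "is_oTIN") %in% names(profiles))) {
    abort("profiles must contain sample_id, is_sTIN and is_oTIN")
  }
  prof <- tibble::as_tibble(profiles)
  missing <- setdiff(prof$sample_id, clinical$sample_id)
  if (length(missing)) {
    if (!allow_subset) {
      abort(sprintf("no clinical record for sample(s): %s (use allow_subset = TRUE to drop)",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    tin_log("dropping %d profiled sample(s) without clinical records", length(missing))
    prof <- prof[!prof$sample_id %in% missing, ]
  }
  positive <- switch(scheme,
                     sTIN = prof$is_sTIN,
                     oTIN = prof$is_oTIN,
                     either = prof$is_sTIN | prof$is_oTIN,
                     both = prof$is_sTIN & prof$is_oTIN)
  if (!any(positive) || all(positive)) {
    abort(sprintf("scheme \"%s\" yields a degenerate grouping (%d of %d positive)",
                  scheme, sum(positive), length(positive)))
  }
  grouping <- tibble::tibble(sample_id = prof$sample_id,
                             group = factor(ifelse(positive, scheme, "rest"),
                                            levels = c("rest", scheme)))
  out <- dplyr::inner_join(grouping, tibble::as_tibble(unclass(clinical)),
                           by = "sample_id")
  out$stage <- factor(out$stage, levels = c("II", "III"))
  out$sex <- factor(out$sex, levels = c("F", "M"))
  out$location <- factor(out$location, levels = c("right", "left", "rectum"))
  out$msi <- as.integer(out$msi)
  out <- out[c("sample_id", "time_years", "event", "group", "stage", "msi",
               "age", "sex", "location")]
  tin_log("survival groups (%s): %d positive, %d rest", scheme,
          sum(positive), sum(!positive))
  structure(out, class = c("survival_table", class(out)), scheme = scheme)
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimate per group, with a helper to read t-year survival
#' rates off the right-continuous step function.
#'
#' @param table A `survival_table` (or any data frame with `time_years`,
#'   `event` and a grouping column).
#' @param group Name of the grouping column (default "group").
#' @return Object of class `tin_km` wrapping the [survival::survfit()]
#'   fit.
#' @export
kaplan_meier <- function(table, group = "group") {
  check_survival_cols(table, group)
  if (any(table(table[[group]]) == 0)) abort("every group needs at least one patient")
  f <- as.formula(sprintf("survival::Surv(time_years, event) ~ %s", group))
  fit <- survival::survfit(f, data = table)
  structure(list(fit = fit, group = group, data = table), class = "tin_km")
}

check_survival_cols <- function(table, group) {
  need <- c("time_years", "event", group)
  if (!all(need %in% names(table))) {
    abort(sprintf("survival table must contain %s", paste(need, collapse = ", ")))
  }
  if (any(table$time_years <= 0)) abort("follow-up times must be positive")
  if (!all(table$event %in% c(0, 1))) abort("event must be 0/1")
  invisible(TRUE)
}

#' Survival rates at a given time
#'
#' @param km A `tin_km` object.
#' @param time Time point (years).
#' @return Tibble with `group` and `survival` (right-continuous value of
#'   the step function at `time`).
#' @export
survival_at <- function(km, time) {
  if (!inherits(km, "tin_km")) abort("`km` must be a tin_km object")
  s <- summary(km$fit, times = time, extend = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^.*=", "", as.character(s$strata))
  tibble::tibble(group = grp, survival = s$surv)
}

#' Tidy Kaplan-Meier curves
#' @param x A `tin_km` object.
#' @param ... Unused.
#' @return Tibble of step-function points: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
tidy.tin_km <- function(x, ...) {
  f <- x$fit
  grp <- if (is.null(f$strata)) "all" else {
    rep(sub("^.*=", "", names(f$strata)), f$strata)
  }
  tibble::tibble(group = grp, time = f$time, n_risk = f$n.risk,
                 n_event = f$n.event, survival = f$surv)
}

#' Log-rank (Mantel-Cox) test for equality of survival distributions
#'
#' @param table A survival table with exactly two groups.
#' @param group Name of the grouping column.
#' @return One-row tibble: `statistic` (chi-square, 1 df), `df`,
#'   `p.value`, per-group observed and expected event counts.
#' @export
logrank_test <- function(table, group = "group") {
  check_survival_cols(table, group)
  g <- factor(table[[group]])
  if (nlevels(droplevels(g)) != 2) abort("log-rank test requires exactly 2 non-empty groups")
  if (sum(table$event) < 1) abort("at least one event is required")
  f <- as.formula(sprintf("survival::Surv(time_years, event) ~ %s", group))
  d <- survival::survdiff(f, data = table)
  tibble::tibble(statistic = d$chisq, df = 1,
                 p.value = stats::pchisq(d$chisq, df = 1, lower.tail = FALSE),
                 observed_1 = d$obs[1], expected_1 = d$exp[1],
                 observed_2 = d$obs[2], expected_2 = d$exp[2])
}

#' Cox proportional-hazards regression
#'
#' Fits the partial likelihood with the survival package (Newton-Raphson,
#' Efron tie correction by default) and reports hazard ratios with Wald
#' 95% confidence intervals (exp(beta +/- 1.96 SE)) and p-values. The
#' design matrix is checked for rank deficiency and constant covariates
#' before fitting, and monotone-likelihood (perfect separation) fits are
#' turned into explicit errors naming the covariate.
#'
#' @param table A `survival_table`.
#' @param covariates Character vector of additional covariate column
#'   names (e.g. `c("stage", "msi", "age", "sex", "location")`); the
#'   `group` term is always included first.
#' @param group Name of the grouping column.
#' @param ties Tie-handling method: "efron" (default) or "breslow".
#' @return A `cox_result` tibble: `term`, `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p`, with the maximized log partial likelihood and
#'   concordance as attributes.
#' @export
cox_ph <- function(table, covariates = character(), group = "group",
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival_cols(table, group)
  if (length(unique(table$time_years[table$event == 1])) < 2) {
    abort("at least 2 distinct event times are required")
  }
  terms <- c(group, covariates)
  bad <- setdiff(terms, names(table))
  if (length(bad)) abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
  for (v in terms) {
    if (length(unique(table[[v]])) < 2) {
      abort(sprintf("covariate `%s` is constant", v))
    }
  }
  f <- as.formula(sprintf("survival::Surv(time_years, event) ~ %s",
                          paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                            data = table)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    abort("design matrix is rank deficient (aliased covariates); drop the redundant term")
  }
  fit <- withCallingHandlers(
    survival::coxph(f, data = table, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        abort(sprintf("Cox fit failed (monotone likelihood or non-convergence): %s",
                      conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble::tibble(
    term = rownames(co), beta = co[, "coef"], se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"]
  )
  structure(out, class = c("cox_result", class(out)),
            loglik = fit$loglik[2], concordance = unname(sm$concordance[1]),
            ties = ties, n = fit$n, n_events = fit$nevent)
}

#' One-line summary of a Cox fit
#' @param x A `cox_result`.
#' @param ... Unused.
#' @return One-row tibble with sample size, events and log partial
#'   likelihood.
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
                 loglik = attr(x, "loglik"),
                 concordance = attr(x, "concordance"), ties = attr(x, "ties"))
}

#' TIN survival analysis in one call
#'
#' Builds the groups for a scheme, then runs Kaplan-Meier, log-rank and
#' Cox analyses (univariate, plus multivariate when covariates are given).
#'
#' @inheritParams build_survival_groups
#' @param covariates Covariates for the multivariate Cox model (default
#'   none).
#' @param ties Tie handling for the Cox fits.
#' @return List of class `tin_survival` with `table`, `km`, `logrank`,
#'   `cox_univariate` and (optionally) `cox_multivariate`.
#' @export
tin_survival <- function(profiles, clinical, scheme = "sTIN",
                         covariates = character(), ties = "efron",
                         allow_subset = FALSE) {
  tab <- build_survival_groups(profiles, clinical, scheme = scheme,
                               allow_subset = allow_subset)
  km <- kaplan_meier(tab)
  lr <- logrank_test(tab)
  cox_uni <- cox_ph(tab, ties = ties)
  cox_multi <- if (length(covariates)) cox_ph(tab, covariates, ties = ties) else NULL
  structure(list(table = tab, km = km, logrank = lr,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi,
                 scheme = scheme),
            class = "tin_survival")
}

#' @export
print.tin_survival <- function(x, ...) {
  cat(sprintf("TIN survival analysis (scheme: %s)\n", x$scheme))
  n <- table(x$table$group)
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s n=%d", names(n), n), collapse = ", ")))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank$statistic, x$logrank$p.value))
  u <- x$cox_univariate[1, ]
  cat(sprintf("  univariate HR = %.2f (95%% CI %.2f to %.2f), p = %.4g\n",
              u$hr, u$ci_low, u$ci_high, u$p))
  if (!is.null(x$cox_multivariate)) {
    m <- x$cox_multivariate[1, ]
    cat(sprintf("  multivariate HR = %.2f (95%% CI %.2f to %.2f), p = %.4g\n",
                m$hr, m$ci_low, m$ci_high, m$p))
  }
  invisible(x)
}
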