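make_surv <- function(time, event, group) {
  tibble::tibble(sample_id = sprintf("p%02d", seq_along(time)),
                 time_years = time, event = as.integer(event),
                 group = factor(group))
}

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # times {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
  tab <- make_surv(c(1, 2, 3), c(1, 0, 1), rep("a", 3))
  km <- kaplan_meier(tab)
  s <- survival_at(km, c(1))
  expect_equal(s$survival, 2 / 3, tolerance = 1e-12)
  expect_equal(survival_at(km, 3)$survival, 0, tolerance = 1e-12)
  expect_equal(survival_at(km, 2.5)$survival, 2 / 3, tolerance = 1e-12)

  # no events: S(t) = 1 everywhere
  tab0 <- make_surv(1:4, rep(0, 4), rep("a", 4))
  expect_equal(survival_at(kaplan_meier(tab0), 4)$survival, 1)

  # no censoring: reduces to the empirical survivor function
  set.seed(70)
  t_all <- sort(runif(9, 1, 10))
  tab1 <- make_surv(t_all, rep(1, 9), rep("a", 9))
  km1 <- kaplan_meier(tab1)
  for (q in c(t_all[3], t_all[7], 5)) {
    expect_equal(survival_at(km1, q)$survival, mean(t_all > q), tolerance = 1e-12)
  }
})

test_that("log-rank test matches the O/E/V tabulation oracle", {
  # identical groups: statistic 0, p 1
  tab_eq <- make_surv(c(1, 2, 3, 4, 1, 2, 3, 4), c(1, 0, 1, 0, 1, 0, 1, 0),
                      rep(c("a", "b"), each = 4))
  res_eq <- logrank_test(tab_eq)
  expect_equal(res_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(res_eq$p.value, 1, tolerance = 1e-12)

  # small worked table with distinct times
  tab <- make_surv(c(1, 3, 5, 7, 2, 4, 6, 8), c(1, 1, 0, 1, 1, 1, 1, 0),
                   rep(c("a", "b"), each = 4))
  res <- logrank_test(tab)
  expect_equal(res$statistic,
               oracle_logrank(tab$time_years, tab$event, tab$group),
               tolerance = 1e-9)
  # chi-square upper-tail identity
  expect_equal(res$p.value, pchisq(res$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # invariance under label swap
  swapped <- tab
  swapped$group <- factor(ifelse(tab$group == "a", "b", "a"))
  expect_equal(logrank_test(swapped)$statistic, res$statistic, tolerance = 1e-12)

  expect_error(logrank_test(make_surv(1:3, c(1, 1, 1), rep("a", 3))),
               "2 non-empty groups")
})

test_that("Cox regression matches a grid-search maximizer of the partial likelihood", {
  tab <- make_surv(c(1, 2, 3, 4, 5), c(1, 1, 1, 1, 0), c(1, 0, 1, 0, 1))
  tab$x <- c(1, 0, 1, 0, 1)
  fit <- cox_ph(tab, group = "x")
  beta_ref <- oracle_cox_grid(tab$time_years, tab$event, tab$x)
  expect_equal(fit$beta[1], beta_ref, tolerance = 1e-4)
  # CI identity
  expect_equal(fit$ci_low, exp(fit$beta - 1.96 * fit$se), tolerance = 1e-12)
  expect_equal(fit$ci_high, exp(fit$beta + 1.96 * fit$se), tolerance = 1e-12)
  expect_true(all(fit$hr > 0))
})

test_that("degenerate Cox designs are rejected with informative errors", {
  set.seed(71)
  n <- 40
  tab <- make_surv(rexp(n, 0.2), rbinom(n, 1, 0.7),
                   rep(c("rest", "TIN"), each = n / 2))
  tab$dup <- as.integer(tab$group == "TIN")
  tab$dup2 <- tab$dup
  expect_error(quiet(cox_ph(tab, covariates = c("dup", "dup2"), group = "group")),
               "rank deficient")
  tab$flat <- 1
  expect_error(cox_ph(tab, covariates = "flat", group = "group"), "constant")
  one_event <- make_surv(1:5, c(1, 0, 0, 0, 0), c(0, 1, 0, 1, 0))
  expect_error(cox_ph(one_event), "2 distinct event times")
})

test_that("Cox coverage: CI contains the true hazard ratio in simulated cohorts", {
  # exponential survival, true HR 3 between groups
  n <- 200
  covered <- logical(40)
  for (i in seq_len(40)) {
    set.seed(600 + i)
    grp <- rep(c(0, 1), each = n / 2)
    time <- rexp(n, rate = 0.1 * exp(log(3) * grp))
    event <- as.integer(time <= 8)
    tab <- make_surv(pmin(time, 8), event,
                     factor(ifelse(grp == 1, "TIN", "rest"),
                            levels = c("rest", "TIN")))
    fit <- cox_ph(tab)
    covered[i] <- fit$ci_low[1] <= 3 && 3 <= fit$ci_high[1]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("survival groups are built per scheme with reference coding", {
  prof <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         is_sTIN = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                         is_oTIN = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  clin <- new_clinical(tibble::tibble(
    sample_id = sprintf("s%d", 1:6), time_years = c(2, 3, 1, 5, 4, 6),
    event = c(1L, 0L, 1L, 0L, 1L, 0L), stage = c("II", "III", "II", "III", "II", "III"),
    msi = c(0L, 1L, 0L, 0L, 1L, 0L), age = c(60, 70, 65, 55, 80, 75),
    sex = c("M", "F", "F", "M", "F", "M"),
    location = c("right", "left", "rectum", "right", "left", "rectum")))
  tab_e <- quiet(build_survival_groups(prof, clin, scheme = "either"))
  expect_equal(sum(tab_e$group == "either"), sum(prof$is_sTIN | prof$is_oTIN))
  expect_equal(levels(tab_e$group), c("rest", "either"))
  expect_equal(levels(tab_e$stage), c("II", "III"))
  tab_b <- quiet(build_survival_groups(prof, clin, scheme = "both"))
  expect_equal(sum(tab_b$group == "both"), 1)
  # no double positives in a subset: degenerate grouping errors
  expect_error(quiet(build_survival_groups(prof[2:6, ], clin, scheme = "both")),
               "degenerate")
  # missing clinical record
  prof2 <- rbind(prof, tibble::tibble(sample_id = "s9", is_sTIN = TRUE, is_oTIN = TRUE))
  expect_error(build_survival_groups(prof2, clin, "sTIN"), "s9")
  tab_d <- quiet(build_survival_groups(prof2, clin, "sTIN", allow_subset = TRUE))
  expect_equal(nrow(tab_d), 6)
  # group sizes equal flag counts on simulated profiles
  expect_equal(sum(quiet(build_survival_groups(prof, clin, "sTIN"))$group == "sTIN"),
               sum(prof$is_sTIN))
})
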