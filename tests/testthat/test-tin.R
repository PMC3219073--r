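test_that("percentile thresholds follow the linear-interpolation definition", {
  m <- matrix(1:100, 10, 10, dimnames = list(paste0("e", 1:10), paste0("s", 1:10)))
  thr <- compute_thresholds(m)
  expect_equal(unname(thr), c(1.99, 99.01), tolerance = 1e-12)

  # all scores equal: lower == upper, downstream counts all zero
  eq <- matrix(2, 5, 4, dimnames = list(paste0("e", 1:5), paste0("s", 1:4)))
  thr_eq <- compute_thresholds(eq)
  expect_equal(unname(thr_eq), c(2, 2))
  cnt <- count_deviations(eq, thr_eq)
  expect_true(all(cnt$n_skip == 0) && all(cnt$n_incl == 0))

  # standard normal scores approach the analytic quantiles
  set.seed(20)
  big <- matrix(rnorm(1e6), 1000, 1000,
                dimnames = list(NULL, paste0("s", 1:1000)))
  thr_n <- compute_thresholds(big)
  expect_equal(unname(thr_n), c(-2.326348, 2.326348), tolerance = 0.01)

  expect_error(compute_thresholds(matrix(numeric(0), 0, 0)), "empty")
})

test_that("deviation counting uses strict comparisons and matches a brute-force scan", {
  set.seed(21)
  m <- matrix(rnorm(1000), 100, 10, dimnames = list(NULL, paste0("s", 1:10)))
  # plant the 10 most extreme negative scores in sample 4
  m[1:10, 4] <- -10 - (1:10)
  thr <- compute_thresholds(m)
  cnt <- count_deviations(m, thr)
  expect_equal(which.max(cnt$n_skip), 4L)

  # brute-force scan oracle
  skip_ref <- incl_ref <- integer(10)
  for (j in 1:10) {
    for (i in 1:100) {
      if (m[i, j] < thr[["lower"]]) skip_ref[j] <- skip_ref[j] + 1L
      if (m[i, j] > thr[["upper"]]) incl_ref[j] <- incl_ref[j] + 1L
    }
  }
  expect_identical(cnt$n_skip, skip_ref)
  expect_identical(cnt$n_incl, incl_ref)

  # flagged fraction is (lower_pct + 100 - upper_pct) / 100 on continuous scores
  expect_equal(sum(cnt$n_skip + cnt$n_incl) / length(m), 0.02, tolerance = 1e-12)
})

test_that("relative amounts are log2 ratios to the arithmetic mean count", {
  counts <- tibble::tibble(sample_id = c("a", "b", "c"),
                           n_skip = c(2L, 2L, 4L), n_incl = c(2L, 2L, 4L))
  rel <- relative_amounts(counts)
  expect_equal(rel$rel_total, c(-0.415, -0.415, 0.585), tolerance = 1e-3)
  # mean-count consistency: sum of 2^rel * mean equals the total count sum
  totals <- counts$n_skip + counts$n_incl
  expect_equal(sum(2^rel$rel_total * mean(totals)), sum(totals), tolerance = 1e-6)
  # equal counts give all-zero relative amounts
  eqc <- tibble::tibble(sample_id = c("a", "b"), n_skip = c(3L, 3L), n_incl = c(5L, 5L))
  rel_eq <- relative_amounts(eqc)
  expect_true(all(abs(c(rel_eq$rel_skip, rel_eq$rel_incl, rel_eq$rel_total,
                        rel_eq$skew)) < 1e-12))
  # log-ratio identity: skew equals the within-sample log2 skip:incl odds
  # minus a constant shared across samples (the log2 ratio of mean counts)
  c1 <- tibble::tibble(sample_id = c("a", "b", "c"),
                       n_skip = c(8L, 2L, 5L), n_incl = c(2L, 4L, 5L))
  r1 <- relative_amounts(c1)
  offset <- log2(mean(c1$n_skip) / mean(c1$n_incl))
  expect_equal(r1$skew, log2(c1$n_skip / c1$n_incl) - offset, tolerance = 1e-12)
  # zero counts error with pseudocount advice
  zc <- tibble::tibble(sample_id = c("a", "b"), n_skip = c(0L, 3L), n_incl = c(2L, 2L))
  expect_error(relative_amounts(zc), "pseudocount")
  expect_silent(relative_amounts(zc, pseudocount = 0.5))
})

test_that("subtype calls use strict thresholds and independent flags", {
  prof <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         rel_total = c(0.2, 0.0, -1.2, 1.1),
                         skew = c(0.8, 0.7, 0.0, 0.9))
  out <- call_subtypes(prof)
  expect_equal(out$is_sTIN, c(TRUE, FALSE, FALSE, TRUE))  # 0.7 exactly is not sTIN
  expect_equal(out$is_oTIN, c(FALSE, FALSE, TRUE, TRUE))  # low side counts; both flags may co-occur
  # invariance under sample permutation
  perm <- sample(nrow(prof))
  out_p <- call_subtypes(prof[perm, ])
  expect_equal(out_p$is_sTIN, out$is_sTIN[perm])
  expect_equal(out_p$is_oTIN, out$is_oTIN[perm])
})

test_that("paired tumor-normal comparison is antisymmetric and detects elevated deviation", {
  # identical tumor/normal columns: no-variation outcome
  set.seed(30)
  m <- matrix(rnorm(200 * 5), 200, 5)
  scores <- cbind(m, m)
  colnames(scores) <- c(paste0("T", 1:5), paste0("N", 1:5))
  rownames(scores) <- paste0("e", 1:200)
  pairs <- tibble::tibble(tumor = paste0("T", 1:5), normal = paste0("N", 1:5))
  res <- paired_tumor_normal(scores, pairs, pseudocount = 0.5)
  expect_true(all(abs(res$pairs$difference) < 1e-12))
  expect_true(is.na(res$statistic))
  expect_match(res$note, "no variation")

  # swapping tumor/normal labels flips every difference
  set.seed(31)
  scores2 <- matrix(rnorm(200 * 10), 200, 10,
                    dimnames = list(paste0("e", 1:200),
                                    c(paste0("T", 1:5), paste0("N", 1:5))))
  res_fwd <- paired_tumor_normal(scores2, pairs, pseudocount = 0.5)
  res_rev <- paired_tumor_normal(scores2, tibble::tibble(tumor = pairs$normal,
                                                         normal = pairs$tumor),
                                 pseudocount = 0.5)
  expect_equal(res_rev$pairs$difference, -res_fwd$pairs$difference)

  expect_error(paired_tumor_normal(scores2,
                                   tibble::tibble(tumor = "T9", normal = "N1")),
               "unpaired|unknown")
})

test_that("tumors with doubled deviation rates show higher relative deviation than paired normals", {
  # 13 pairs, tumor deviation rate twice the normal rate
  cfg <- sim_config(n_genes = 120, probe_sets_per_gene = c(6, 10),
                    n_samples = 26, tin_sample_fraction = 0.5,
                    tin_rate_multiplier = 2, skew_ratio = 1,
                    deviation_delta = 1.5, noise_sigma = 0.25)
  sim <- simulate_tin_study(cfg, seed = 33)
  ff <- quiet(firma(sim$intensities, sim$chipdef, bg_correct = FALSE))
  tumors <- sim$truth$tin_samples
  normals <- setdiff(colnames(sim$intensities), tumors)
  pairs <- tibble::tibble(tumor = tumors, normal = normals)
  res <- paired_tumor_normal(ff$scores, pairs)
  expect_equal(nrow(res$pairs), 13)
  expect_gt(res$mean_difference, 0)
  expect_lt(res$p.value, 0.05)
})
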