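# TIN classification: per-sample counts of deviating exon usage, relative
# amounts on the log2 scale, skew between deviating skipping and
# inclusion, and the oTIN / sTIN subtype calls.

#' Percentile thresholds for deviating exon usage
#'
#' Lower and upper percentiles of the flattened FIRMA score matrix (by
#' default the 1st and 99th), computed with the linear-interpolation
#' percentile definition.
#'
#' @param scores FIRMA score matrix (probe sets x samples) or `firma_fit`.
#' @param lower_pct,upper_pct Percentiles in [0, 100].
#' @return Named numeric `c(lower, upper)`.
#' @export
compute_thresholds <- function(scores, lower_pct = 1, upper_pct = 99) {
  if (inherits(scores, "firma_fit")) scores <- scores$scores
  assert_scalar_number(lower_pct, "lower_pct", 0, 100)
  assert_scalar_number(upper_pct, "upper_pct", 0, 100)
  if (lower_pct > upper_pct) abort("lower_pct must not exceed upper_pct")
  v <- as.vector(scores)
  v <- v[is.finite(v)]
  if (!length(v)) abort("score matrix is empty")
  q <- stats::quantile(v, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Count deviating exon usage per sample
#'
#' Strict comparisons: a score below the lower threshold counts as a
#' deviating skipping event, a score above the upper threshold as a
#' deviating inclusion event; ties at a threshold are not flagged.
#'
#' @param scores FIRMA score matrix or `firma_fit`.
#' @param thresholds Named numeric `c(lower, upper)` from
#'   [compute_thresholds()].
#' @return Tibble with columns `sample_id`, `n_skip`, `n_incl`.
#' @export
count_deviations <- function(scores, thresholds) {
  if (inherits(scores, "firma_fit")) scores <- scores$scores
  if (is.null(colnames(scores))) abort("score matrix must carry sample identifiers")
  lower <- thresholds[["lower"]]; upper <- thresholds[["upper"]]
  if (lower > upper) abort("invalid thresholds: lower > upper")
  tibble::tibble(
    sample_id = colnames(scores),
    n_skip = as.integer(colSums(scores < lower, na.rm = TRUE)),
    n_incl = as.integer(colSums(scores > upper, na.rm = TRUE))
  )
}

#' Relative amounts of deviating exon usage
#'
#' For each sample, the log2 ratio of its deviation count to the
#' arithmetic mean count across samples, computed separately for skipping,
#' inclusion and their total; skew is the difference between the relative
#' skipping and inclusion amounts.
#'
#' @param counts Tibble with `sample_id`, `n_skip`, `n_incl` (from
#'   [count_deviations()]).
#' @param pseudocount Added to every count before taking ratios; the
#'   default 0 errors on zero counts rather than silently shifting them.
#' @return Input tibble extended with `rel_skip`, `rel_incl`, `rel_total`,
#'   `skew`.
#' @export
relative_amounts <- function(counts, pseudocount = 0) {
  need <- c("sample_id", "n_skip", "n_incl")
  if (!all(need %in% names(counts))) abort("counts must have sample_id, n_skip, n_incl")
  assert_scalar_number(pseudocount, "pseudocount", 0)
  skip <- counts$n_skip + pseudocount
  incl <- counts$n_incl + pseudocount
  total <- counts$n_skip + counts$n_incl + pseudocount
  if (any(skip == 0) || any(incl == 0) || any(total == 0)) {
    abort(paste0("zero deviation count for sample(s) ",
                 paste(utils::head(counts$sample_id[skip == 0 | incl == 0 | total == 0], 5),
                       collapse = ", "),
                 "; rerun with pseudocount = 0.5 to regularize"))
  }
  rel_skip <- log2(skip / mean(skip))
  rel_incl <- log2(incl / mean(incl))
  rel_total <- log2(total / mean(total))
  dplyr::mutate(tibble::as_tibble(counts),
                rel_skip = rel_skip, rel_incl = rel_incl,
                rel_total = rel_total, skew = rel_skip - rel_incl)
}

#' Call TIN subtypes
#'
#' A sample is sTIN (skewed transcriptome instability) when the absolute
#' difference between its relative amounts of deviating skipping and
#' inclusion exceeds `skew_threshold`, and oTIN (overall transcriptome
#' instability) when the absolute relative total amount exceeds
#' `overall_threshold`. Both comparisons are strict, and the flags are
#' independent (a sample may carry both subtypes).
#'
#' @param profiles Tibble with `rel_total` and `skew` columns.
#' @param skew_threshold,overall_threshold Positive cut-offs on the log2
#'   scale (defaults 0.7 and 1.0).
#' @return Input tibble extended with `is_sTIN`, `is_oTIN`.
#' @export
call_subtypes <- function(profiles, skew_threshold = 0.7, overall_threshold = 1.0) {
  if (!all(c("rel_total", "skew") %in% names(profiles))) {
    abort("profiles must have rel_total and skew columns")
  }
  assert_scalar_number(skew_threshold, "skew_threshold", 0)
  assert_scalar_number(overall_threshold, "overall_threshold", 0)
  dplyr::mutate(tibble::as_tibble(profiles),
                is_sTIN = abs(.data$skew) > skew_threshold,
                is_oTIN = abs(.data$rel_total) > overall_threshold)
}

#' Per-sample TIN profiles from FIRMA scores
#'
#' Convenience wrapper chaining [compute_thresholds()],
#' [count_deviations()], [relative_amounts()] and [call_subtypes()].
#'
#' @param scores FIRMA score matrix or `firma_fit`.
#' @inheritParams compute_thresholds
#' @inheritParams relative_amounts
#' @inheritParams call_subtypes
#' @return A `tin_profiles` tibble (sample_id, counts, relative amounts,
#'   skew, subtype flags) with the thresholds stored as attributes.
#' @export
tin_profiles <- function(scores, lower_pct = 1, upper_pct = 99,
                         skew_threshold = 0.7, overall_threshold = 1.0,
                         pseudocount = 0) {
  thr <- compute_thresholds(scores, lower_pct, upper_pct)
  counts <- count_deviations(scores, thr)
  prof <- relative_amounts(counts, pseudocount = pseudocount)
  prof <- call_subtypes(prof, skew_threshold, overall_threshold)
  tin_log("TIN profiles: thresholds [%.4g, %.4g]; flagged %d scores; %d sTIN, %d oTIN of %d samples",
          thr[["lower"]], thr[["upper"]], sum(prof$n_skip) + sum(prof$n_incl),
          sum(prof$is_sTIN), sum(prof$is_oTIN), nrow(prof))
  structure(prof,
            class = c("tin_profiles", class(prof)),
            thresholds = thr,
            lower_pct = lower_pct, upper_pct = upper_pct,
            skew_threshold = skew_threshold,
            overall_threshold = overall_threshold)
}

#' One-line summary of TIN profiles
#' @param x A `tin_profiles` tibble.
#' @param ... Unused.
#' @return One-row tibble of cohort-level counts and thresholds.
#' @export
glance.tin_profiles <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble::tibble(
    n_samples = nrow(x),
    mean_total_count = mean(x$n_skip + x$n_incl),
    lower_threshold = if (is.null(thr)) NA_real_ else thr[["lower"]],
    upper_threshold = if (is.null(thr)) NA_real_ else thr[["upper"]],
    n_sTIN = sum(x$is_sTIN), n_oTIN = sum(x$is_oTIN),
    n_both = sum(x$is_sTIN & x$is_oTIN),
    n_either = sum(x$is_sTIN | x$is_oTIN)
  )
}

#' Paired tumor-normal comparison of deviating exon usage
#'
#' Scores tumors and their matched normal samples jointly, computes joint
#' relative amounts, and contrasts each tumor with its own normal partner:
#' the per-pair difference in total relative deviating exon usage,
#' summarized by a paired t-test. This normalizes each tumor against the
#' background level of deviating exon usage in normal mucosa.
#'
#' @param scores FIRMA score matrix over tumors and normals jointly, or a
#'   `firma_fit` on the joint series.
#' @param pairs Tibble with columns `tumor` and `normal`; every listed
#'   sample must be a column of `scores` and each tumor has exactly one
#'   partner.
#' @inheritParams tin_profiles
#' @return Object of class `tin_paired`: per-pair tibble (`tumor`,
#'   `normal`, `rel_total_tumor`, `rel_total_normal`, `difference`), mean
#'   difference, paired t statistic and two-sided p-value. When all
#'   differences are identical the t-test is undefined and is reported as
#'   a "no variation" outcome (`statistic = NA`).
#' @export
paired_tumor_normal <- function(scores, pairs, lower_pct = 1, upper_pct = 99,
                                pseudocount = 0) {
  if (inherits(scores, "firma_fit")) scores <- scores$scores
  if (!all(c("tumor", "normal") %in% names(pairs))) {
    abort("pairs must have columns `tumor` and `normal`")
  }
  ids <- c(pairs$tumor, pairs$normal)
  if (anyDuplicated(ids)) abort("each sample may appear in exactly one pair")
  missing <- setdiff(ids, colnames(scores))
  if (length(missing)) {
    abort(sprintf("unpaired or unknown sample(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  thr <- compute_thresholds(scores, lower_pct, upper_pct)
  prof <- relative_amounts(count_deviations(scores, thr), pseudocount = pseudocount)
  rel <- setNames(prof$rel_total, prof$sample_id)
  per_pair <- tibble::tibble(
    tumor = pairs$tumor, normal = pairs$normal,
    rel_total_tumor = unname(rel[pairs$tumor]),
    rel_total_normal = unname(rel[pairs$normal]),
    difference = unname(rel[pairs$tumor] - rel[pairs$normal])
  )
  d <- per_pair$difference
  if (length(d) < 2 || stats::sd(d) == 0) {
    res <- list(statistic = NA_real_, p.value = NA_real_,
                note = "no variation among paired differences")
  } else {
    tt <- stats::t.test(d)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                note = NULL)
  }
  structure(list(pairs = per_pair, mean_difference = mean(d),
                 statistic = res$statistic, p.value = res$p.value,
                 note = res$note, thresholds = thr),
            class = "tin_paired")
}

#' @export
print.tin_paired <- function(x, ...) {
  cat(sprintf("Paired tumor-normal deviation comparison (%d pairs)\n",
              nrow(x$pairs)))
  cat(sprintf("  mean difference (tumor - normal): %.4f\n", x$mean_difference))
  if (is.null(x$note)) {
    cat(sprintf("  paired t = %.3f, two-sided p = %.3g\n", x$statistic, x$p.value))
  } else {
    cat(sprintf("  %s\n", x$note))
  }
  invisible(x)
}

#' Tidy a paired tumor-normal comparison
#' @param x A `tin_paired` object.
#' @param ... Unused.
#' @return The per-pair tibble.
#' @export
tidy.tin_paired <- function(x, ...) x$pairs

#' One-line summary of a paired comparison
#' @param x A `tin_paired` object.
#' @param ... Unused.
#' @return One-row tibble with the mean difference, t statistic and p.
#' @export
glance.tin_paired <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), mean_difference = x$mean_difference,
                 statistic = x$statistic, p.value = x$p.value)
}
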