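# Association between splicing-factor expression and deviation burden:
# per-gene Pearson correlations with the total relative amounts of
# deviating exon usage, benchmarked against random gene sets of equal
# size and against permutations of the deviation amounts across samples.

# Per-gene Pearson r and two-sided p (t distribution, n - 2 df) of each
# row of `expr` against the vector `v`. Zero-variance genes are excluded.
gene_correlations_ <- function(expr, v, alpha) {
  n <- length(v)
  keep <- apply(expr, 1, stats::sd) > 0
  excluded <- rownames(expr)[!keep]
  expr <- expr[keep, , drop = FALSE]
  r <- as.vector(stats::cor(t(expr), v))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) == 1] <- 0
  list(table = tibble::tibble(gene_id = rownames(expr), r = r, p = p,
                              significant = p < alpha),
       excluded = excluded)
}

summarize_correlations_ <- function(tab) {
  sig <- tab[tab$significant, , drop = FALSE]
  list(n_significant = nrow(sig),
       n_neg_significant = sum(sig$r < 0),
       n_pos_significant = sum(sig$r > 0),
       mean_r_significant = if (nrow(sig)) mean(sig$r) else NA_real_,
       neg_pos_ratio = if (any(sig$r > 0)) sum(sig$r < 0) / sum(sig$r > 0) else Inf)
}

#' Correlate gene expression with deviation burden
#'
#' Pearson correlation of each gene's expression with the per-sample total
#' relative amount of deviating exon usage; two-sided p-values from the t
#' distribution with n - 2 degrees of freedom. Significance is raw
#' p < `alpha` (no multiple-testing correction, by design); pass the
#' result through [stats::p.adjust()] externally if adjusted calls are
#' wanted.
#'
#' @param expr Gene-expression matrix (genes x samples, log2).
#' @param rel_total A `tin_profiles` tibble or named per-sample numeric
#'   vector of total relative deviation amounts.
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_table` tibble (`gene_id`, `r`, `p`,
#'   `significant`) with a `summary` attribute holding the counts of
#'   significant, negatively and positively correlated genes and the mean
#'   r among significant genes. Constant genes are excluded with a logged
#'   count.
#' @export
correlate_genes <- function(expr, rel_total, alpha = 0.05) {
  expr <- as_id_matrix(expr, "expression matrix")
  if (ncol(expr) < 3) abort("at least 3 samples are required for correlation")
  v <- rel_total_vector(rel_total, colnames(expr))
  res <- gene_correlations_(expr, v, alpha)
  if (length(res$excluded)) {
    tin_log("excluded %d constant gene(s) from correlation", length(res$excluded))
  }
  smry <- summarize_correlations_(res$table)
  smry$alpha <- alpha
  smry$n_excluded <- length(res$excluded)
  structure(res$table, class = c("correlation_table", class(res$table)),
            summary = smry, excluded = res$excluded)
}

#' One-line summary of a correlation table
#' @param x A `correlation_table`.
#' @param ... Unused.
#' @return One-row tibble with significance counts and the mean r among
#'   significant genes.
#' @export
glance.correlation_table <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n_genes = nrow(x), n_significant = s$n_significant,
                 n_neg_significant = s$n_neg_significant,
                 n_pos_significant = s$n_pos_significant,
                 mean_r_significant = s$mean_r_significant,
                 neg_pos_ratio = s$neg_pos_ratio,
                 n_excluded = s$n_excluded, alpha = s$alpha)
}

#' Random-gene-set null for the splicing-factor association
#'
#' Draws `n_sets` gene sets of `set_size` genes without replacement from
#' all genes of the expression matrix and summarizes each set's
#' correlation with the deviation amounts exactly as for the
#' splicing-factor set.
#'
#' @inheritParams correlate_genes
#' @param n_sets Number of random sets (default 100).
#' @param set_size Genes per set (default 280, the size of the
#'   splicing-factor list).
#' @param seed Optional integer seed making the draw reproducible.
#' @return A `random_set_null` tibble, one row per set: `n_significant`,
#'   `pct_significant`, `mean_r_significant`, `neg_pos_ratio`.
#' @export
random_geneset_null <- function(expr, rel_total, n_sets = 100, set_size = 280,
                                alpha = 0.05, seed = NULL) {
  expr <- as_id_matrix(expr, "expression matrix")
  if (set_size >= nrow(expr)) {
    if (set_size > nrow(expr)) abort("set_size exceeds the number of genes")
  }
  v <- rel_total_vector(rel_total, colnames(expr))
  # per-gene correlations computed once; random sets index into them
  res <- gene_correlations_(expr, v, alpha)
  tab <- res$table
  draws <- with_seed_(seed, replicate(n_sets, sample.int(nrow(tab), set_size),
                                      simplify = FALSE))
  rows <- purrr::map_dfr(draws, function(idx) {
    s <- summarize_correlations_(tab[idx, , drop = FALSE])
    tibble::tibble(n_significant = s$n_significant,
                   pct_significant = 100 * s$n_significant / set_size,
                   mean_r_significant = s$mean_r_significant,
                   n_neg_significant = s$n_neg_significant,
                   n_pos_significant = s$n_pos_significant,
                   neg_pos_ratio = s$neg_pos_ratio)
  })
  structure(rows, class = c("random_set_null", class(rows)),
            set_size = set_size, alpha = alpha)
}

#' Two-sample t-test for mean correlation strength
#'
#' Equal-variance two-sample t-test comparing the significant correlation
#' coefficients of the splicing-factor set with those of the random sets,
#' probing whether the splicing-factor correlations are shifted towards
#' stronger negative values.
#'
#' @param x,y Numeric vectors of correlation coefficients (each of length
#'   at least 2).
#' @return One-row tibble: `statistic`, `df`, `p.value`, `mean_x`,
#'   `mean_y`.
#' @export
compare_mean_r <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need at least 2 values")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' Permutation null for the splicing-factor correlation
#'
#' Recomputes the per-gene correlations for `n_perm` uniform random
#' shuffles of the deviation amounts across samples. For each permutation
#' the median correlation over all splicing-factor genes and the numbers
#' of significantly negative/positive genes are recorded. The empirical
#' p-value for the observed median correlation uses the add-one rule,
#' one-sided on the magnitude:
#' p = (1 + #\{perm: |median r| >= |observed|\}) / (n_perm + 1).
#' The excess of negatively over positively correlated genes is compared
#' as the fraction of permutations reaching at least the observed excess.
#'
#' @inheritParams correlate_genes
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `permutation_null` with the observed summaries,
#'   the per-permutation tibble, `p_median_r` and `p_neg_excess`.
#' @export
permutation_null <- function(expr, rel_total, n_perm = 1000, alpha = 0.05,
                             seed = NULL) {
  expr <- as_id_matrix(expr, "expression matrix")
  if (n_perm < 1) abort("n_perm must be at least 1")
  v <- rel_total_vector(rel_total, colnames(expr))
  n <- length(v)
  keep <- apply(expr, 1, stats::sd) > 0
  expr <- expr[keep, , drop = FALSE]
  obs <- gene_correlations_(expr, v, alpha)$table
  obs_median <- stats::median(obs$r)
  obs_excess <- sum(obs$significant & obs$r < 0) - sum(obs$significant & obs$r > 0)

  perm_mat <- with_seed_(seed, vapply(seq_len(n_perm), function(i) sample(v),
                                      numeric(n)))
  r_all <- stats::cor(t(expr), perm_mat)   # genes x n_perm
  tt <- r_all * sqrt((n - 2) / pmax(1 - r_all^2, .Machine$double.eps))
  p_all <- 2 * stats::pt(-abs(tt), df = n - 2)
  sig <- p_all < alpha
  perms <- tibble::tibble(
    median_r = apply(r_all, 2, stats::median),
    n_neg_significant = colSums(sig & r_all < 0),
    n_pos_significant = colSums(sig & r_all > 0)
  )
  perms$neg_excess <- perms$n_neg_significant - perms$n_pos_significant
  p_median <- (1 + sum(abs(perms$median_r) >= abs(obs_median))) / (n_perm + 1)
  p_excess <- mean(perms$neg_excess >= obs_excess)
  structure(list(observed_median_r = obs_median,
                 observed_neg_excess = obs_excess,
                 permutations = perms,
                 p_median_r = p_median, p_neg_excess = p_excess,
                 n_perm = n_perm, alpha = alpha),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null (%d permutations)\n", x$n_perm))
  cat(sprintf("  observed median r = %.3f (permuted range %.3f to %.3f)\n",
              x$observed_median_r, min(x$permutations$median_r),
              max(x$permutations$median_r)))
  cat(sprintf("  p(|median r|) = %.4g; p(neg excess) = %.4g\n",
              x$p_median_r, x$p_neg_excess))
  invisible(x)
}

#' Full splicing-factor association analysis
#'
#' Correlates the splicing-factor genes with the deviation amounts, builds
#' the random-gene-set and permutation nulls, and compares the mean
#' significant correlation of the splicing factors against the pooled
#' significant correlations of the random sets.
#'
#' @param expr Gene-expression matrix over all genes (genes x samples).
#' @param sf_genes Character vector of splicing-factor gene identifiers;
#'   all must be rows of `expr` (missing ones are reported, not dropped).
#' @inheritParams correlate_genes
#' @param n_sets,set_size Random-set null controls; `set_size` defaults to
#'   the size of the splicing-factor list.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed covering both nulls.
#' @return Object of class `sf_association` bundling the observed
#'   `correlation_table`, the `random_set_null`, the `permutation_null`,
#'   the mean-r comparison and the random-set comparison p-values
#'   (`p_n_significant`, `p_neg_pos_ratio`; 0 is reported as
#'   "< 1/n_sets" when printing).
#' @export
sf_association <- function(expr, sf_genes, rel_total, n_sets = 100,
                           set_size = NULL, n_perm = 1000, alpha = 0.05,
                           seed = NULL) {
  expr <- as_id_matrix(expr, "expression matrix")
  sf_genes <- unique(as.character(sf_genes))
  missing <- setdiff(sf_genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("%d splicing-factor gene(s) absent from the expression matrix: %s",
                  length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (is.null(set_size)) set_size <- length(sf_genes)
  v <- rel_total_vector(rel_total, colnames(expr))

  observed <- correlate_genes(expr[sf_genes, , drop = FALSE], v, alpha = alpha)
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(seed + 0:1)
  random_null <- random_geneset_null(expr, v, n_sets = n_sets,
                                     set_size = set_size, alpha = alpha,
                                     seed = seeds[[1]])
  perm_null <- permutation_null(expr[sf_genes, , drop = FALSE], v,
                                n_perm = n_perm, alpha = alpha,
                                seed = seeds[[2]])
  s <- attr(observed, "summary")
  p_n_sig <- mean(random_null$n_significant >= s$n_significant)
  obs_ratio <- s$neg_pos_ratio
  p_ratio <- mean(random_null$neg_pos_ratio >= obs_ratio)
  mean_cmp <- {
    sf_r <- observed$r[observed$significant]
    rnd_r <- random_null$mean_r_significant[!is.na(random_null$mean_r_significant)]
    if (length(sf_r) >= 2 && length(rnd_r) >= 2) compare_mean_r(sf_r, rnd_r) else NULL
  }
  tin_log("SF association: %d/%d significant (%d neg, %d pos); random-set p(n_sig) %s",
          s$n_significant, nrow(observed), s$n_neg_significant,
          s$n_pos_significant,
          if (p_n_sig == 0) sprintf("< %g", 1 / n_sets) else format(p_n_sig))
  structure(list(observed = observed, random_null = random_null,
                 permutation = perm_null, mean_r_comparison = mean_cmp,
                 p_n_significant = p_n_sig, p_neg_pos_ratio = p_ratio,
                 n_sets = n_sets, set_size = set_size, alpha = alpha),
            class = "sf_association")
}

#' @export
print.sf_association <- function(x, ...) {
  s <- attr(x$observed, "summary")
  fmt_p <- function(p) if (p == 0) sprintf("< %g", 1 / x$n_sets) else sprintf("%.4g", p)
  cat(sprintf("Splicing-factor association (%d genes, alpha = %g)\n",
              nrow(x$observed), x$alpha))
  cat(sprintf("  significant: %d (%.1f%%), of which %d negative / %d positive\n",
              s$n_significant, 100 * s$n_significant / nrow(x$observed),
              s$n_neg_significant, s$n_pos_significant))
  cat(sprintf("  mean r among significant: %.3f\n", s$mean_r_significant))
  cat(sprintf("  random-set null: p(n significant) %s, p(neg:pos ratio) %s\n",
              fmt_p(x$p_n_significant), fmt_p(x$p_neg_pos_ratio)))
  cat(sprintf("  permutation null: p(|median r|) = %.4g, p(neg excess) = %.4g\n",
              x$permutation$p_median_r, x$permutation$p_neg_excess))
  invisible(x)
}

#' Tidy a splicing-factor association
#' @param x An `sf_association`.
#' @param ... Unused.
#' @return The per-gene correlation tibble.
#' @export
tidy.sf_association <- function(x, ...) tibble::as_tibble(unclass(x$observed))

#' One-line summary of a splicing-factor association
#' @param x An `sf_association`.
#' @param ... Unused.
#' @return One-row tibble of the headline quantities.
#' @export
glance.sf_association <- function(x, ...) {
  s <- attr(x$observed, "summary")
  tibble::tibble(
    n_sf_genes = nrow(x$observed),
    n_significant = s$n_significant,
    pct_significant = 100 * s$n_significant / nrow(x$observed),
    n_neg_significant = s$n_neg_significant,
    n_pos_significant = s$n_pos_significant,
    mean_r_significant = s$mean_r_significant,
    random_mean_n_significant = mean(x$random_null$n_significant),
    p_n_significant = x$p_n_significant,
    p_neg_pos_ratio = x$p_neg_pos_ratio,
    observed_median_r = x$permutation$observed_median_r,
    p_median_r = x$permutation$p_median_r,
    p_neg_excess = x$permutation$p_neg_excess
  )
}
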