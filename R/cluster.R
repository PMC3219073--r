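# Hierarchical clustering of samples by splicing-factor expression and its
# association with the direction of overall transcriptome instability.

#' Hierarchically cluster samples by splicing-factor expression
#'
#' Samples are clustered on the (by default median-centered) expression of
#' the splicing-factor genes with Euclidean distance and complete linkage,
#' then cut at the dendrogram root into two groups. The partition is
#' compared against the direction of deviation burden: among oTIN samples
#' (when `otin_only = TRUE`) the sign of `rel_total`, otherwise
#' above-versus-below-average burden. The association is quantified with
#' Fisher's exact test on the 2x2 contingency table and a majority-label
#' agreement fraction. Samples are ordered lexicographically before
#' clustering so the result is deterministic.
#'
#' @param expr Expression matrix restricted to the splicing-factor genes
#'   (genes x samples).
#' @param profiles A `tin_profiles` tibble (needs `rel_total`, `is_oTIN`).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param center Median-center each gene before computing distances.
#' @param otin_only Restrict the clustering to oTIN samples.
#' @return Object of class `tin_cluster`: the `hclust` tree, a per-sample
#'   tibble (`sample_id`, `cluster`, `direction`), the contingency table,
#'   Fisher p-value and agreement fraction.
#' @export
hierarchical_cluster <- function(expr, profiles, metric = "euclidean",
                                 linkage = "complete", center = TRUE,
                                 otin_only = FALSE) {
  expr <- as_id_matrix(expr, "expression matrix")
  if (!all(c("sample_id", "rel_total") %in% names(profiles))) {
    abort("profiles must contain sample_id and rel_total")
  }
  prof <- tibble::as_tibble(profiles)
  if (otin_only) {
    if (!"is_oTIN" %in% names(prof)) abort("profiles must contain is_oTIN for otin_only")
    prof <- prof[prof$is_oTIN, ]
  }
  samples <- sort(intersect(colnames(expr), prof$sample_id))
  if (length(samples) < 2) abort("at least 2 samples are required for clustering")
  m <- expr[, samples, drop = FALSE]
  if (center) m <- m - apply(m, 1, stats::median)
  h <- stats::hclust(stats::dist(t(m), method = metric), method = linkage)
  cl <- stats::cutree(h, k = 2)

  rel <- rel_total_vector(prof, samples)
  direction <- if (otin_only) {
    ifelse(rel > 0, "high", "low")
  } else {
    ifelse(rel > mean(rel), "high", "low")
  }
  labels <- tibble::tibble(sample_id = samples,
                           cluster = unname(cl[samples]),
                           direction = unname(direction))
  tab <- table(cluster = labels$cluster, direction = labels$direction)
  fisher_p <- if (all(dim(tab) == c(2, 2))) stats::fisher.test(tab)$p.value else NA_real_
  agreement <- max(mean((labels$cluster == 1) == (labels$direction == "high")),
                   mean((labels$cluster == 2) == (labels$direction == "high")))
  tin_log("clustering: %d samples, agreement with %s split %.1f%% (Fisher p %s)",
          length(samples), if (otin_only) "oTIN high/low" else "above/below-average",
          100 * agreement, format(fisher_p, digits = 3))
  structure(list(hclust = h, labels = labels, contingency = tab,
                 fisher_p = fisher_p, agreement = agreement,
                 metric = metric, linkage = linkage, otin_only = otin_only),
            class = "tin_cluster")
}

#' @export
print.tin_cluster <- function(x, ...) {
  cat(sprintf("Two-group clustering (%s distance, %s linkage%s) of %d samples\n",
              x$metric, x$linkage, if (x$otin_only) ", oTIN samples only" else "",
              nrow(x$labels)))
  print(x$contingency)
  cat(sprintf("  agreement: %.1f%%; Fisher exact p: %s\n",
              100 * x$agreement, format(x$fisher_p, digits = 3)))
  invisible(x)
}

#' Tidy a clustering result
#' @param x A `tin_cluster`.
#' @param ... Unused.
#' @return Per-sample tibble with cluster and burden direction.
#' @export
tidy.tin_cluster <- function(x, ...) x$labels

#' One-line summary of a clustering result
#' @param x A `tin_cluster`.
#' @param ... Unused.
#' @return One-row tibble with agreement and Fisher p.
#' @export
glance.tin_cluster <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$labels), agreement = x$agreement,
                 fisher_p = x$fisher_p, otin_only = x$otin_only)
}
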