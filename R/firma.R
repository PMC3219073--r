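# Gene-level probe model and FIRMA alternative-splicing scores.
#
# For each gene, log2 probe intensities are modelled additively as
#   log2(I[k, s]) = c[s] + p[k] + r[k, s]
# (chip/sample effect + probe effect + residual), fitted robustly by
# median polish across ALL probes of the gene -- deliberately without an
# exon term, so that exon-level departures remain in the residuals. The
# FIRMA score of probe set j in sample s is the median residual of its
# probes divided by a robust per-gene scale (1.4826 * median |r|).

#' Fit the additive gene-level probe model by median polish
#'
#' @param x Numeric matrix, probes of one gene x samples, log2 scale.
#' @param tol Convergence tolerance on the largest sweep adjustment.
#' @param max_iter Maximum number of full row+column sweeps.
#' @return An object of class `gene_fit`: `chip_effects` (per sample,
#'   carries the overall expression level), `probe_effects` (per probe,
#'   median-centered), `residuals` (probes x samples), `iterations`,
#'   `converged`. The three components reconstruct `x` exactly.
#' @export
fit_gene_model <- function(x, tol = 1e-6, max_iter = 10L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) abort("gene submatrix must be numeric with no missing values")
  if (nrow(x) < 1L || ncol(x) < 1L) abort("gene submatrix must have at least one probe and one sample")
  fit <- median_polish_cpp(x, tol, as.integer(max_iter))
  names(fit$chip_effects) <- colnames(x)
  names(fit$probe_effects) <- rownames(x)
  dimnames(fit$residuals) <- dimnames(x)
  structure(fit, class = "gene_fit")
}

#' FIRMA scores for one fitted gene
#'
#' @param fit A `gene_fit` for the gene.
#' @param probe_sets Character vector assigning each probe (row of the
#'   fit's residual matrix) to its probe set, in row order.
#' @param mad_floor Lower bound on the robust scale, guarding against
#'   division by zero for degenerate genes.
#' @return Numeric matrix, probe sets x samples. Negative scores indicate
#'   candidate exon skipping, positive scores candidate inclusion.
#' @export
firma_score <- function(fit, probe_sets, mad_floor = 1e-6) {
  if (!inherits(fit, "gene_fit")) abort("`fit` must be a gene_fit")
  r <- fit$residuals
  probe_sets <- as.character(probe_sets)
  if (length(probe_sets) != nrow(r)) {
    abort("`probe_sets` must assign every probe of the fit")
  }
  s <- 1.4826 * stats::median(abs(r))
  if (s < mad_floor) {
    if (any(r != 0)) {
      warn("gene has (near-)zero residual MAD; FIRMA scale floored")
    }
    s <- mad_floor
  }
  sets <- unique(probe_sets)
  out <- matrix(0, nrow = length(sets), ncol = ncol(r),
                dimnames = list(sets, colnames(r)))
  for (i in seq_along(sets)) {
    idx <- which(probe_sets == sets[i])
    out[i, ] <- colwise_median_cpp(r[idx, , drop = FALSE])
  }
  out / s
}

#' Compute FIRMA scores and gene-level expression for a whole series
#'
#' Runs preprocessing (optional background correction, quantile
#' normalization, log2), fits the gene-level median-polish model per gene,
#' and derives per-exon FIRMA scores plus the gene-expression matrix (the
#' fitted chip effects, i.e. RMA-style summarized expression).
#'
#' @param intensities Raw intensity matrix (probes x samples, linear scale).
#' @param chipdef A `chipdef` mapping probes to probe sets and genes.
#' @param bg_correct,quantile_norm Preprocessing switches (see
#'   [preprocess_intensities()]).
#' @param tol,max_iter Median-polish controls (see [fit_gene_model()]).
#' @param mad_floor Robust-scale floor (see [firma_score()]).
#' @param allow_subset Permit probes in the chip definition that are absent
#'   from the matrix (they are dropped with a logged count). By default any
#'   identifier mismatch is an error.
#' @return Object of class `firma_fit` with elements `scores` (probe sets x
#'   samples), `expression` (genes x samples), `single_set_genes`
#'   (genes with only one probe set, whose scores reflect probe-level noise
#'   only and are flagged rather than excluded), and preprocessing
#'   provenance.
#' @export
firma <- function(intensities, chipdef, bg_correct = TRUE, quantile_norm = TRUE,
                  tol = 1e-6, max_iter = 10L, mad_floor = 1e-6,
                  allow_subset = FALSE) {
  if (!inherits(chipdef, "chipdef")) chipdef <- new_chipdef(chipdef)
  x <- as_id_matrix(intensities, "intensity matrix")

  missing_probes <- setdiff(chipdef$probe_id, rownames(x))
  if (length(missing_probes)) {
    if (!allow_subset) {
      abort(sprintf("%d chip-definition probe(s) absent from the intensity matrix (e.g. %s); use allow_subset = TRUE to intersect",
                    length(missing_probes), missing_probes[1]))
    }
    tin_log("dropping %d chip-definition probes absent from the matrix",
            length(missing_probes))
    chipdef <- chipdef[!chipdef$probe_id %in% missing_probes, ]
  }
  extra <- setdiff(rownames(x), chipdef$probe_id)
  if (length(extra)) {
    if (!allow_subset) {
      abort(sprintf("%d matrix probe(s) absent from the chip definition (e.g. %s); use allow_subset = TRUE to intersect",
                    length(extra), extra[1]))
    }
    tin_log("ignoring %d matrix probes absent from the chip definition",
            length(extra))
  }

  lognorm <- preprocess_intensities(x, bg_correct = bg_correct,
                                    quantile_norm = quantile_norm)

  genes <- unique(chipdef$gene_id)
  row_of <- match(chipdef$probe_id, rownames(lognorm))
  gene_rows <- split(seq_len(nrow(chipdef)), factor(chipdef$gene_id, levels = genes))

  n_samples <- ncol(lognorm)
  expression <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
                       dimnames = list(genes, colnames(lognorm)))
  score_blocks <- vector("list", length(genes))
  single_set <- character(0)
  for (i in seq_along(genes)) {
    idx <- gene_rows[[i]]
    sub <- lognorm[row_of[idx], , drop = FALSE]
    fit <- fit_gene_model(sub, tol = tol, max_iter = max_iter)
    expression[i, ] <- fit$chip_effects
    sets <- chipdef$probe_set_id[idx]
    if (length(unique(sets)) == 1L) single_set <- c(single_set, genes[i])
    score_blocks[[i]] <- firma_score(fit, sets, mad_floor = mad_floor)
  }
  scores <- do.call(rbind, score_blocks)
  tin_log("FIRMA: %d genes, %d probe sets, %d samples; %d single-probe-set gene(s)",
          length(genes), nrow(scores), n_samples, length(single_set))
  structure(list(scores = scores, expression = expression,
                 single_set_genes = single_set,
                 background_corrected = isTRUE(attr(lognorm, "background_corrected")),
                 tol = tol, max_iter = max_iter),
            class = "firma_fit")
}

#' Summarize gene-level expression by median polish
#'
#' RMA-style summarization: chip effects of the gene-level median-polish
#' fit, one row per gene of the chip definition.
#'
#' @param lognorm Background-corrected, quantile-normalized log2 matrix
#'   (probes x samples), e.g. from [preprocess_intensities()].
#' @param chipdef A `chipdef`.
#' @param tol,max_iter Median-polish controls.
#' @return Numeric matrix, genes x samples.
#' @export
summarize_gene_expression <- function(lognorm, chipdef, tol = 1e-6,
                                      max_iter = 10L) {
  if (!inherits(chipdef, "chipdef")) chipdef <- new_chipdef(chipdef)
  m <- as_id_matrix(lognorm, "log2 matrix")
  present <- chipdef$probe_id %in% rownames(m)
  dropped_genes <- setdiff(chipdef$gene_id, chipdef$gene_id[present])
  if (length(dropped_genes)) {
    warn(sprintf("%d gene(s) have no probes in the matrix and are excluded (e.g. %s)",
                 length(dropped_genes), dropped_genes[1]))
    chipdef <- chipdef[chipdef$gene_id %in% setdiff(chipdef$gene_id, dropped_genes), ]
    present <- chipdef$probe_id %in% rownames(m)
  }
  if (!all(present)) {
    abort(sprintf("%d probe(s) of retained genes absent from the matrix",
                  sum(!present)))
  }
  genes <- unique(chipdef$gene_id)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  rows <- split(match(chipdef$probe_id, rownames(m)),
                factor(chipdef$gene_id, levels = genes))
  for (i in seq_along(genes)) {
    fit <- fit_gene_model(m[rows[[i]], , drop = FALSE], tol = tol,
                          max_iter = max_iter)
    out[i, ] <- fit$chip_effects
  }
  out
}

#' @export
print.firma_fit <- function(x, ...) {
  cat(sprintf("FIRMA fit: %d probe sets x %d samples (%d genes, %d single-set)\n",
              nrow(x$scores), ncol(x$scores), nrow(x$expression),
              length(x$single_set_genes)))
  invisible(x)
}

#' Tidy a FIRMA fit into a long tibble of scores
#'
#' @param x A `firma_fit`.
#' @param ... Unused.
#' @return Tibble with columns `probe_set_id`, `sample_id`, `score`.
#' @export
tidy.firma_fit <- function(x, ...) {
  tibble::tibble(
    probe_set_id = rep(rownames(x$scores), times = ncol(x$scores)),
    sample_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}

#' One-line summary of a FIRMA fit
#' @param x A `firma_fit`.
#' @param ... Unused.
#' @return One-row tibble with dimensions and score quantiles.
#' @export
glance.firma_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$expression), n_probe_sets = nrow(x$scores),
    n_samples = ncol(x$scores),
    n_single_set_genes = length(x$single_set_genes),
    score_q01 = unname(stats::quantile(x$scores, 0.01)),
    score_q99 = unname(stats::quantile(x$scores, 0.99))
  )
}
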