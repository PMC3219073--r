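# Probe-level preprocessing: normal+exponential background correction and
# inter-chip quantile normalization, following the first two steps of the
# RMA pipeline. Both operate on raw linear-scale intensities; log2
# transformation happens afterwards in `preprocess_intensities()`.

#' Background-correct probe intensities
#'
#' Fits the RMA convolution model (observed = signal + background, with
#' exponentially distributed signal and normal background) independently to
#' each sample and replaces each intensity with the posterior expected
#' signal. The correction is strictly positive and monotone within a
#' sample. Model fitting uses the saddle-point approximation from the limma
#' package.
#'
#' @param x Numeric matrix of strictly positive intensities
#'   (probes x samples).
#' @return Matrix of corrected intensities, same dimnames.
#' @export
background_correct <- function(x) {
  x <- as_id_matrix(x, "intensity matrix")
  if (any(x <= 0)) abort("intensities must be strictly positive")
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (stats::sd(col) == 0) {
      abort(sprintf("sample %s has constant intensities; cannot fit background model",
                    colnames(x)[j]))
    }
    par <- limma::normexp.fit(col, method = "saddle")$par
    out[, j] <- limma::normexp.signal(par, col)
  }
  out
}

#' Quantile-normalize a matrix across columns
#'
#' After normalization every column shares the same sorted set of values:
#' the across-column mean of the order statistics. Within-column rank order
#' is preserved and ties receive the mean of their target quantiles.
#'
#' @param m Numeric matrix (rows x samples), no missing values.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) abort("matrix must be numeric with no missing values")
  if (ncol(m) == 1L) return(m)
  if (nrow(m) == 1L) {
    out <- m
    out[] <- mean(m)
    return(out)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Preprocess raw intensities to normalized log2 scale
#'
#' Optional background correction, inter-chip quantile normalization on the
#' linear scale, then log2 transformation.
#'
#' @param x Raw intensity matrix (probes x samples, strictly positive).
#' @param bg_correct Apply background correction first? Disable for data
#'   simulated without an additive background.
#' @param quantile_norm Apply inter-chip quantile normalization? Disable
#'   only for data whose columns are already on a common scale (e.g.
#'   noiseless simulations).
#' @return log2-scale matrix with attributes `background_corrected` and
#'   `quantile_normalized`.
#' @export
preprocess_intensities <- function(x, bg_correct = TRUE, quantile_norm = TRUE) {
  x <- as_id_matrix(x, "intensity matrix")
  if (any(x <= 0)) abort("intensities must be strictly positive")
  tin_log("preprocessing %d probes x %d samples (background correction: %s)",
          nrow(x), ncol(x), if (bg_correct) "on" else "off")
  if (bg_correct) x <- background_correct(x)
  if (quantile_norm) x <- quantile_normalize(x)
  out <- log2(x)
  attr(out, "background_corrected") <- bg_correct
  attr(out, "quantile_normalized") <- quantile_norm
  out
}
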