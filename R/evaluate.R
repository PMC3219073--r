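# Ground-truth evaluation helpers for simulated studies.

#' Detection AUC of FIRMA scores against injected deviations
#'
#' Treats every (probe set, sample) cell as a binary detection problem --
#' injected deviation versus not -- and computes the area under the ROC
#' curve of the absolute FIRMA score, via the rank (Mann-Whitney) formula
#' with ties shared.
#'
#' @param scores FIRMA score matrix (probe sets x samples) or `firma_fit`.
#' @param events Tibble of injected events with `probe_set_id` and
#'   `sample_id` (e.g. `truth$events` from a simulation).
#' @return AUC in [0, 1].
#' @export
score_detection_auc <- function(scores, events) {
  if (inherits(scores, "firma_fit")) scores <- scores$scores
  scores <- as_id_matrix(scores, "score matrix")
  ri <- match(events$probe_set_id, rownames(scores))
  ci <- match(events$sample_id, colnames(scores))
  ok <- !is.na(ri) & !is.na(ci)
  if (!all(ok)) {
    abort(sprintf("%d injected event(s) refer to unknown probe sets or samples",
                  sum(!ok)))
  }
  pos <- matrix(FALSE, nrow(scores), ncol(scores))
  pos[cbind(ri, ci)] <- TRUE
  x <- abs(as.vector(scores))
  y <- as.vector(pos)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) abort("need both injected and uninjected cells")
  r <- rank(x)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Recovery of simulated TIN status by subtype calls
#'
#' @param profiles A `tin_profiles` tibble.
#' @param truth Simulation ground truth (with `is_tin`).
#' @param flag Which call to score: "oTIN" or "sTIN".
#' @return One-row tibble with sensitivity and specificity.
#' @export
tin_recovery <- function(profiles, truth, flag = c("oTIN", "sTIN")) {
  flag <- match.arg(flag)
  called <- if (flag == "oTIN") profiles$is_oTIN else profiles$is_sTIN
  truth_pos <- unname(truth$is_tin[profiles$sample_id])
  tibble::tibble(
    flag = flag,
    n_true_positive = sum(truth_pos),
    sensitivity = if (any(truth_pos)) mean(called[truth_pos]) else NA_real_,
    specificity = if (any(!truth_pos)) mean(!called[!truth_pos]) else NA_real_
  )
}
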