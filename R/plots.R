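# ggplot2 displays for the main result types.

#' Plot per-sample TIN profiles
#'
#' Relative deviating skipping versus inclusion per sample, with the
#' subtype calls indicated; the diagonal band marks the sTIN skew
#' threshold.
#'
#' @param object A `tin_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tin_profiles <- function(object, ...) {
  st <- attr(object, "skew_threshold")
  if (is.null(st)) st <- 0.7
  df <- tibble::as_tibble(object)
  df$subtype <- dplyr::case_when(
    df$is_sTIN & df$is_oTIN ~ "both",
    df$is_sTIN ~ "sTIN",
    df$is_oTIN ~ "oTIN",
    TRUE ~ "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_incl, y = .data$rel_skip,
                                   colour = .data$subtype)) +
    ggplot2::geom_abline(intercept = c(-st, st), slope = 1, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "relative deviating inclusion (log2)",
                  y = "relative deviating skipping (log2)",
                  colour = "TIN subtype") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `tin_km` object.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @export
autoplot.tin_km <- function(object, ...) {
  df <- tidy(object)
  start <- dplyr::distinct(df, .data$group)
  start$time <- 0; start$survival <- 1
  df <- dplyr::bind_rows(start[c("group", "time", "survival")],
                         df[c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot a splicing-factor association against its random-set null
#'
#' Left: correlation coefficients of the significantly correlated
#' splicing-factor genes, ordered. Right: the number of significant genes
#' per random set with the splicing-factor count marked.
#'
#' @param object An `sf_association` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sf_association <- function(object, ...) {
  null_df <- tibble::as_tibble(object$random_null)
  obs_n <- attr(object$observed, "summary")$n_significant
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs_n, colour = "red") +
    ggplot2::labs(x = "significantly correlated genes per random set",
                  y = "random sets",
                  title = sprintf("splicing-factor set: %d significant", obs_n)) +
    ggplot2::theme_minimal()
}
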