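# broom-style accessors and ggplot2 visualizations for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Delta-TE fit
#'
#' @param x A `uorf_te_fit` from [delta_te_test()].
#' @param ... Unused.
#' @return The per-feature results tibble with the contrast attached.
#' @method tidy uorf_te_fit
#' @export
tidy.uorf_te_fit <- function(x, ...) {
  dplyr::mutate(x$results, contrast = paste0(x$test, "_vs_", x$reference),
                .before = 1)
}

#' One-row summary of a Delta-TE fit
#'
#' @param x A `uorf_te_fit`.
#' @param fdr Significance cutoff on q (default 0.1).
#' @param ... Unused.
#' @return Tibble with feature counts and the median dispersion.
#' @method glance uorf_te_fit
#' @export
glance.uorf_te_fit <- function(x, fdr = 0.1, ...) {
  r <- x$results
  tibble::tibble(
    contrast = paste0(x$test, "_vs_", x$reference),
    n_features = nrow(r),
    n_tested = sum(r$status == "ok"),
    n_low_count = sum(r$status == "low_count"),
    n_outlier = sum(r$status == "outlier"),
    n_significant = sum(r$q <= fdr, na.rm = TRUE),
    median_dispersion = stats::median(x$dispersion$alpha, na.rm = TRUE)
  )
}

#' Volcano plot of a Delta-TE fit
#'
#' log2 TE fold change against -log10 Wald p, colored by significance at
#' `q <= fdr` combined with the fold criterion.
#'
#' @param object A `uorf_te_fit`.
#' @param fdr,fold Call thresholds to highlight (defaults 0.1 and 2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uorf_te_fit
#' @export
autoplot.uorf_te_fit <- function(object, fdr = 0.1, fold = 2, ...) {
  d <- dplyr::filter(object$results, .data$status == "ok") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$q <= fdr & .data$log2_dte >= log2(fold) ~ "up",
      .data$q <= fdr & .data$log2_dte <= -log2(fold) ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_dte, -log10(.data$wald_p),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fold), log2(fold)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c23b22", down = "#2b6ca3",
                                            ns = "grey60")) +
    ggplot2::labs(
      x = expression(log[2] ~ Delta * TE),
      y = expression(-log[10] ~ p),
      title = sprintf("Delta-TE: %s vs %s", object$test, object$reference)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of uORF versus mORF TE changes with regulation calls
#'
#' @param calls Tibble from [classify_regulation()].
#' @return A ggplot (log2 axes; activated red, repressed blue).
#' @export
plot_regulation <- function(calls) {
  d <- dplyr::filter(calls, .data$class != "low_count")
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$dte_morf), log2(.data$dte_uorf),
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(activated = "#c23b22",
                                            repressed = "#2b6ca3",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ Delta * TE[mORF]),
                  y = expression(log[2] ~ Delta * TE[uORF])) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of TE changes at two conditions
#'
#' @param data Tibble with fold-change columns for the two contrasts.
#' @param dte_low,dte_high Columns (tidy-eval) holding positive fold changes.
#' @return A ggplot with quadrant shading counts in the subtitle.
#' @export
plot_quadrants <- function(data, dte_low, dte_high) {
  lo <- dplyr::pull(data, {{ dte_low }})
  hi <- dplyr::pull(data, {{ dte_high }})
  q <- quadrant(lo, hi)
  d <- tibble::tibble(x = log2(lo), y = log2(hi), quadrant = q$quadrant)
  counts <- table(factor(q$quadrant, levels = c("Q1", "Q2", "Q3", "Q4")))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = expression(log[2] ~ Delta * TE ~ "(low T)"),
      y = expression(log[2] ~ Delta * TE ~ "(high T)"),
      subtitle = paste(sprintf("%s: %d", names(counts), counts),
                       collapse = "  ")
    ) +
    ggplot2::theme_minimal()
}

#' Periodicity-feature plane of discovery candidates
#'
#' f0 against uniformity for scored candidates, colored by the translated
#' call, with the P = threshold decision boundary of the logistic.
#'
#' @param discovery Tibble from [validate_uorfs()]/[discover_uorfs()].
#' @param coeffs,threshold The logistic parameters used.
#' @return A ggplot.
#' @export
plot_discovery <- function(discovery, coeffs = c(-6, 9, 3),
                           threshold = 0.5) {
  # boundary: b0 + b1 f0 + b2 U = logit(threshold)
  b <- coeffs
  lt <- stats::qlogis(threshold)
  boundary <- tibble::tibble(f0 = seq(0, 1, length.out = 101)) |>
    dplyr::mutate(uniformity = (lt - b[1] - b[2] * .data$f0) / b[3]) |>
    dplyr::filter(.data$uniformity >= 0, .data$uniformity <= 1)
  ggplot2::ggplot(discovery,
                  ggplot2::aes(.data$f0, .data$uniformity,
                               colour = .data$translated)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = boundary, ggplot2::aes(colour = NULL),
                       linetype = "dashed") +
    ggplot2::labs(x = "frame-0 fraction", y = "uniformity") +
    ggplot2::theme_minimal()
}
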