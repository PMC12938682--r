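# ggplot2 figures for the three diagnostic analyses and the RSCU heatmap.

#' Neutrality plot (GC12 against GC3) with the fitted regression line
#'
#' @param fit A [neutrality_regression()] result.
#' @return A ggplot object.
#' @export
plot_neutrality <- function(fit) {
  stopifnot(inherits(fit, "neutrality_fit"))
  lab <- sprintf("slope = %.3f, r = %.3f, p = %.2g, n = %d",
                 fit$slope, fit$r, fit$p, fit$n)
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$x, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = toupper(fit$x_choice), y = "GC12", subtitle = lab) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_classic()
}

#' ENC-GC3 plot with the expected-ENC curve
#'
#' @param analysis An [enc_gc3_analysis()] result.
#' @return A ggplot object.
#' @export
plot_enc_gc3 <- function(analysis) {
  curve <- data.frame(gc3s = seq(0.01, 0.99, by = 0.01))
  curve$enc <- enc_expected(curve$gc3s)
  ggplot2::ggplot(analysis$genes,
                  ggplot2::aes(x = .data$gc3s, y = .data$enc_obs)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$gc3s, y = .data$enc),
                       colour = "firebrick") +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 62)) +
    ggplot2::theme_classic()
}

#' Histogram of the ENC deviation ratio
#'
#' @param analysis An [enc_gc3_analysis()] result.
#' @return A ggplot object.
#' @export
plot_enc_ratio_hist <- function(analysis) {
  h <- analysis$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = if (nrow(h)) h$bin_right[1] - h$bin_left[1] else 1,
                      fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "(ENCexp - ENCobs) / ENCobs", y = "genes") +
    ggplot2::theme_classic()
}

#' PR2 parity plot with 0.5 crosshairs
#'
#' @param pr2 A [pr2_table()] result.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(pr2) {
  ggplot2::ggplot(pr2, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_classic()
}

#' RSCU heatmap over genes or datasets
#'
#' Tile fill follows the conventional thresholds: RSCU < 1 white (avoided),
#' 1-2 light blue (preferred), > 2 dark blue (strongly preferred).
#'
#' @param m A matrix of RSCU values (rows = genes or datasets, columns =
#'   codons), e.g. from [rscu_matrix()].
#' @return A ggplot object.
#' @export
plot_rscu_heatmap <- function(m) {
  df <- data.frame(
    row = rep(rownames(m), ncol(m)),
    codon = rep(colnames(m), each = nrow(m)),
    rscu = as.vector(m),
    stringsAsFactors = FALSE
  )
  df$band <- cut(df$rscu, breaks = c(-Inf, 1, 2, Inf),
                 labels = c("< 1", "1-2", "> 2"), right = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$row,
                                   fill = .data$band)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c("< 1" = "white",
                                          "1-2" = "lightblue",
                                          "> 2" = "steelblue4"),
                               name = "RSCU") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
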