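#' Plot percentage RNA-signal distributions across fractions
#'
#' Line-and-point plot of the percentage signal per fraction, coloured by
#' treatment, facetted by gene and (when present) quantification mode and
#' arm. The canonical figure for reading a polysome shift: a rightward move
#' of the treated curve means redistribution toward heavier polysomes.
#'
#' @param data Output of [percent_signal()].
#' @param replicate_lines Plot each replicate (thin lines) instead of the
#'   replicate mean.
#' @return A ggplot object.
#' @export
plot_fraction_distribution <- function(data, replicate_lines = FALSE) {
  req_cols(data, c("fraction", "percent", "treatment"),
           "plot_fraction_distribution")
  grp <- intersect(c("gene", "mode", "sample_id"), names(data))
  if (!replicate_lines && "replicate" %in% names(data)) {
    data <- data |>
      group_by(across(all_of(c(grp, "treatment", "fraction")))) |>
      summarise(percent = mean(percent), .groups = "drop")
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = fraction, y = percent, colour = treatment,
    group = if (replicate_lines && "replicate" %in% names(data)) {
      interaction(treatment, replicate)
    } else {
      treatment
    }
  )) +
    ggplot2::geom_line(linewidth = if (replicate_lines) 0.3 else 0.7) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "Fraction", y = "RNA signal (%)", colour = NULL) +
    ggplot2::theme_bw()
  facet_vars <- intersect(c("gene", "mode", "sample_id"), names(data))
  if (length(facet_vars) > 0) {
    p <- p + ggplot2::facet_wrap(facet_vars, labeller = ggplot2::label_both)
  }
  p
}

#' Plot per-replicate translational shifts
#'
#' Dot plot of dF_W per replicate, by arm and quantification mode, with the
#' arm mean marked. Visual counterpart of the mode comparison: tighter,
#' better-separated points under spike-in normalization indicate the
#' variance removed by the spike-in.
#'
#' @param shifts Output of [delta_fw()].
#' @return A ggplot object.
#' @export
plot_delta_fw <- function(shifts) {
  req_cols(shifts, c("sample_id", "delta_fw"), "plot_delta_fw")
  p <- ggplot2::ggplot(shifts, ggplot2::aes(x = sample_id, y = delta_fw)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05,
                                                            height = 0),
                        alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3, colour = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = expression(Delta * F[W])) +
    ggplot2::theme_bw()
  facet_vars <- intersect(c("gene", "mode"), names(shifts))
  if (length(facet_vars) > 0) p <- p + ggplot2::facet_wrap(facet_vars)
  p
}

#' Plot per-fraction spike-in recovery
#'
#' Bar plot of spike-in relative quantity per fraction and sample. Because
#' equal spike-in was added to every fraction, deviations from a flat profile
#' expose uneven RNA isolation; flagged fractions are highlighted.
#'
#' @param recovery Output of [fraction_recovery_report()].
#' @return A ggplot object.
#' @export
plot_fraction_recovery <- function(recovery) {
  req_cols(recovery, c("fraction", "rq", "flagged"), "plot_fraction_recovery")
  ggplot2::ggplot(recovery, ggplot2::aes(x = fraction, y = rq,
                                         fill = flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35",
                                          `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(c("sample_id", "treatment", "replicate"),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Fraction", y = "Spike-in relative quantity",
                  fill = "> fold threshold") +
    ggplot2::theme_bw()
}
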