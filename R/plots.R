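## Figures: PheWAS volcano plot and MR forest plot.

#' Volcano plot of a PheWAS scan
#'
#' Odds ratio against -log10 p, one point per phenotype, FDR-significant
#' phenotypes highlighted.
#'
#' @param scan data.frame from [phewasScan()] (after [addFdr()]).
#' @param qSig q-value significance threshold for highlighting (default 0.05).
#' @return a ggplot object.
#' @export
plotVolcano <- function(scan, qSig = 0.05) {
  d <- scan[!is.na(scan$p), , drop = FALSE]
  d$significant <- !is.na(d$q) & d$q < qSig
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "forestgreen"),
                                 name = sprintf("q < %.2g", qSig)) +
    ggplot2::labs(x = "Odds ratio", y = expression(-log[10](p))) +
    ggplot2::theme_bw()
}

#' Forest plot of per-variant ratio estimates with method summaries
#'
#' @param input an [MRInput2S-class].
#' @param results data.frame from [mrAllMethods()].
#' @return a ggplot object.
#' @importFrom rlang .data
#' @export
plotForest <- function(input, results) {
  per <- data.frame(label = input@variantId,
                    estimate = input@by / input@bx,
                    se = input@sy / abs(input@bx),
                    kind = "variant", stringsAsFactors = FALSE)
  overall <- data.frame(label = results$method, estimate = results$estimate,
                        se = results$se, kind = "method",
                        stringsAsFactors = FALSE)
  d <- rbind(per, overall)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label,
                                  colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                                         xmax = .data$estimate + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Causal estimate (per SD exposure)", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}
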