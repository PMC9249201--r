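# ggplot2 displays for the main result types.

#' Plot an imputation result
#'
#' Candidate bins by rank against imputed probability, colored by reference
#' frequency; a vertical line marks the default output cutoff (average
#' reference bin count minus the input size).
#'
#' @param object An `imputation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imputation_result <- function(object, ...) {
  cand <- object[!object$is_input, ]
  cand$rank <- seq_len(nrow(cand))
  cutoff <- attr(object, "avg_bin_count") - sum(object$is_input)
  p <- ggplot2::ggplot(cand, ggplot2::aes(x = .data$rank,
                                          y = .data$imputed_probability,
                                          colour = .data$reference_frequency)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "candidate rank", y = "imputed probability",
                  colour = "reference\nfrequency") +
    ggplot2::theme_minimal()
  if (cutoff > 0 && cutoff <= nrow(cand)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot per-bin cross-validation results
#'
#' AUROC and average precision per candidate bin against class balance, with
#' the random baselines (0.5 for AUROC, the class balance itself for average
#' precision) as dashed references.
#'
#' @param object A `cv_result` from [crossvalidate_reference()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("auroc", "auprc"),
                              names_to = "metric", values_to = "value")
  baseline <- tibble(metric = c("auroc", "auprc"),
                     intercept = c(0.5, NA), slope = c(0, 1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class_balance, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(data = baseline[1, ],
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         linetype = "dashed") +
    ggplot2::geom_abline(data = tibble(metric = "auprc"),
                         intercept = 0, slope = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "class balance (fraction of 1s)", y = "cross-validated value") +
    ggplot2::theme_minimal()
}

#' Plot specificity simulations
#'
#' Single-cell specificity against origin-consensus similarity; points above
#' zero are imputations closer to their origin than to the peer consensus.
#'
#' @param object A `specificity_result` from [simulate_specificity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.specificity_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$origin_consensus_similarity,
                               y = .data$specificity,
                               colour = factor(.data$input_size))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Jaccard(origin, consensus)", y = "single-cell specificity",
                  colour = "input bins") +
    ggplot2::theme_minimal()
}

#' Plot an interpretation result
#'
#' Feature importances of the cell's observed bins for the query-position
#' model, labelled by nearest gene when annotated.
#'
#' @param object An `interpretation_result`.
#' @param top Number of features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interpretation_result <- function(object, top = 20, ...) {
  feats <- head(object$features, top)
  lab <- if ("gene" %in% names(feats)) {
    ifelse(is.na(feats$gene), paste0(feats$chrom, ":", feats$bin_index),
           feats$gene)
  } else {
    paste0(feats$chrom, ":", feats$bin_index)
  }
  feats$label <- factor(lab, levels = rev(unique(lab)))
  ggplot2::ggplot(feats, ggplot2::aes(x = .data$importance, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "feature importance", y = NULL,
                  title = sprintf("%s:%s-%s  probability %.3f",
                                  object$query$chrom,
                                  format(object$query$start, scientific = FALSE),
                                  format(object$query$end, scientific = FALSE),
                                  object$probability)) +
    ggplot2::theme_minimal()
}
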