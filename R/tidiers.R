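# broom-style tidiers for the package's result objects.

#' Tidy a reference matrix
#'
#' One row per reference bin with its presence frequency across experiments.
#'
#' @param x A `reference_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reference_matrix <- function(x, ...) {
  bin_frequency(x)
}

#' One-row summary of a reference matrix
#'
#' @param x A `reference_matrix`.
#' @param ... Unused.
#' @return A tibble with target, dimensions, density and average bin count.
#' @export
glance.reference_matrix <- function(x, ...) {
  tibble(target = x$target,
         n_experiments = nrow(x$values),
         n_bins = ncol(x$values),
         bin_size = x$bin_size,
         assembly = x$assembly,
         density = mean(x$values),
         avg_bin_count = average_bin_count(x))
}

#' @export
tidy.imputation_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an imputation result
#'
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @return A tibble with input/candidate counts and probability summaries.
#' @export
glance.imputation_result <- function(x, ...) {
  cand <- x$imputed_probability[!x$is_input]
  tibble(n_input = sum(x$is_input),
         n_candidates = length(cand),
         mean_probability = mean(cand),
         max_probability = if (length(cand)) max(cand) else NA_real_,
         avg_bin_count = attr(x, "avg_bin_count"),
         target = attr(x, "target"),
         seed = attr(x, "seed"))
}

#' @export
tidy.interpretation_result <- function(x, ...) {
  x$features
}

#' @export
glance.interpretation_result <- function(x, ...) {
  tibble(chrom = x$query$chrom, start = x$query$start, end = x$query$end,
         probability = x$probability, observed = x$observed,
         n_features = x$n_features,
         max_tss_distance = x$max_tss_distance %||% NA_real_)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(n_bins = nrow(x),
         mean_auroc = mean(x$auroc),
         mean_auprc = mean(x$auprc),
         mean_balance = mean(x$class_balance),
         mean_auprc_minus_balance = mean(x$auprc - x$class_balance))
}

#' @export
glance.specificity_result <- function(x, ...) {
  tibble(n_runs = nrow(x),
         fraction_specific = mean(x$specificity > 0),
         mean_specificity = mean(x$specificity),
         mean_j_origin = mean(x$j_origin),
         mean_j_consensus = mean(x$j_consensus))
}
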