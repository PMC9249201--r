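# The imputation engine. For one sparse single cell, the reference columns
# split into training features (bins the cell observed) and candidate bins
# (bins it did not). One random-forest classifier is trained per candidate
# bin — features: the reference experiments' presence patterns over the
# cell's bins; labels: the candidate bin's reference column — and then
# evaluated on an all-ones probe vector. The resulting probability is the
# model's belief that the candidate bin is present given that every observed
# bin is present, which makes the ranking specific to the individual cell.

#' Partition reference columns into training features and candidates
#'
#' @param rs A `reference_matrix`.
#' @param sc A [bin_set()]: the single cell's observed bins. Bins the
#'   reference does not cover carry no reference signal; they are excluded
#'   from the feature matrix (and reported) but are never discarded from the
#'   cell's output profile.
#' @return A list with `tf` (binary n-by-s feature matrix, columns keyed by
#'   bin), `features` (tibble of the s feature bins), `candidates` (tibble of
#'   candidate bins with `frequency` and matrix column index), and
#'   `unmatched` (tibble of cell bins absent from the reference).
#' @export
make_training <- function(rs, sc) {
  stopifnot(inherits(rs, "reference_matrix"), inherits(sc, "bin_set"))
  if (nrow(sc) == 0) stop_input("single-cell profile is empty")
  if (!isTRUE(all.equal(rs$bin_size, bin_size_of(sc)))) {
    stop_input("single-cell bin size does not match the reference",
               class = "chipimpute_bin_size_error")
  }
  keys <- bin_key(rs$bins)
  sc_keys <- bin_key(sc)
  col <- match(sc_keys, keys)
  unmatched <- as_tibble(sc)[is.na(col), , drop = FALSE]
  if (nrow(unmatched) > 0) {
    inform(sprintf(
      "%d single-cell bin(s) absent from the reference; excluded from training, kept in output",
      nrow(unmatched)))
  }
  feat_col <- sort(col[!is.na(col)])
  if (length(feat_col) == 0) {
    stop_input("no usable features: the cell shares no bin with the reference",
               class = "chipimpute_no_features_error")
  }
  cand_col <- setdiff(seq_along(keys), feat_col)
  if (length(cand_col) == 0) {
    warn("the cell already covers every reference bin; no candidates to impute")
  }
  freq <- colMeans(rs$values)
  list(
    tf = rs$values[, feat_col, drop = FALSE],
    features = dplyr::mutate(rs$bins[feat_col, ], frequency = freq[feat_col]),
    candidates = dplyr::mutate(rs$bins[cand_col, ],
                               frequency = freq[cand_col], .col = cand_col),
    unmatched = unmatched)
}

# Forest contract shared by imputation and interpretation: probability
# forest, bootstrap samples, ceiling(sqrt(s)) features per split, nodes grown
# to purity. `importance` optionally requests impurity or permutation
# importances.
fit_forest <- function(tf, class_vector, seed, trees, importance = "none") {
  if (is.null(colnames(tf))) colnames(tf) <- paste0("f", seq_len(ncol(tf)))
  y <- factor(class_vector, levels = c(0L, 1L))
  s <- ncol(tf)
  ranger::ranger(
    x = tf, y = y,
    num.trees = trees,
    mtry = min(s, ceiling(sqrt(s))),
    min.node.size = 1,
    probability = TRUE,
    importance = importance,
    seed = seed,
    num.threads = 1)
}

probe_predict <- function(model, s, feature_names = NULL) {
  feature_names <- feature_names %||% model$forest$independent.variable.names
  probe <- matrix(1, 1, s, dimnames = list(NULL, feature_names))
  unname(stats::predict(model, data = probe, num.threads = 1)$predictions[1, "1"])
}

#' Imputed probability for one candidate bin
#'
#' Trains the per-bin classifier and evaluates it on the all-ones probe
#' vector. The returned probability is the unweighted mean over trees of the
#' class-1 fraction in the leaf the probe reaches. A constant class vector
#' short-circuits to exactly 0 or 1 without training.
#'
#' @param tf Binary feature matrix (experiments x observed bins).
#' @param class_vector Binary vector of length `nrow(tf)`: the candidate
#'   bin's reference column.
#' @param seed Integer seed (forest construction is deterministic given it).
#' @param trees Number of trees (default 100).
#' @return A probability in `[0, 1]`.
#' @export
impute_bin <- function(tf, class_vector, seed = 1L, trees = 100L) {
  if (length(class_vector) != nrow(tf)) {
    stop_input("class vector length must equal the number of reference experiments")
  }
  if (ncol(tf) < 1) stop_input("feature matrix has no columns")
  if (!all(class_vector %in% 0:1)) stop_input("class vector must be binary")
  if (all(class_vector == 1L)) return(1.0)
  if (all(class_vector == 0L)) return(0.0)
  model <- fit_forest(tf, class_vector, seed, trees)
  probe_predict(model, ncol(tf))
}

#' Impute a single cell
#'
#' Runs [impute_bin()] for every candidate bin and returns the full ranked
#' result: the cell's observed bins first (probability sentinel -1), then
#' candidates sorted by imputed probability (ties broken by reference
#' frequency, then genome position). Each candidate model is seeded by a
#' pure function of the master seed and the bin's identity, so results are
#' identical regardless of evaluation order.
#'
#' @param rs A `reference_matrix`.
#' @param sc A [bin_set()] for the cell.
#' @param seed Master seed.
#' @param trees Trees per candidate forest (default 100).
#' @return An `imputation_result` tibble with columns `bin_id`, `chrom`,
#'   `start`, `end`, `bin_index`, `reference_frequency`,
#'   `imputed_probability`, `is_input`.
#' @export
impute_cell <- function(rs, sc, seed = 1L, trees = 100L) {
  parts <- make_training(rs, sc)
  tf <- parts$tf
  cand <- parts$candidates
  rho <- vapply(seq_len(nrow(cand)), function(g) {
    impute_bin(tf, rs$values[, cand$.col[g]],
               seed = derive_seed(seed, cand$chrom[g], cand$bin_index[g]),
               trees = trees)
  }, 0.0)
  cand <- dplyr::mutate(cand, imputed_probability = rho, is_input = FALSE)
  cand <- cand[order(-cand$imputed_probability, -cand$frequency,
                     chrom_rank(cand$chrom), cand$bin_index), ]
  # observed bins: matched ones carry their reference frequency; bins outside
  # the reference are retained with frequency NA
  obs <- bind_rows(
    dplyr::mutate(parts$features, is_input = TRUE),
    dplyr::mutate(parts$unmatched, frequency = NA_real_, is_input = TRUE))
  obs <- obs[order(chrom_rank(obs$chrom), obs$bin_index), ]
  obs$imputed_probability <- -1
  out <- bind_rows(obs, cand)[, c("chrom", "bin_index", "start", "end",
                                  "frequency", "imputed_probability", "is_input")]
  out <- dplyr::mutate(out,
                       bin_id = paste0(.data$chrom, "_", .data$bin_index),
                       .before = 1)
  names(out)[names(out) == "frequency"] <- "reference_frequency"
  structure(as_tibble(out),
            class = c("imputation_result", class(tibble())),
            bin_size = rs$bin_size, assembly = rs$assembly,
            target = rs$target, seed = seed,
            n_input = nrow(obs), avg_bin_count = average_bin_count(rs))
}

#' Select the final imputed profile
#'
#' The completed profile keeps every observed bin and adds the top-ranked
#' candidates until `total_size` bins are reached. The default size is the
#' average bin count of the reference experiments, so the completed cell has
#' the footprint of a typical bulk profile of the same target.
#'
#' @param result An `imputation_result` from [impute_cell()].
#' @param total_size Total number of bins in the output (default: the
#'   reference's average bin count, recorded on the result).
#' @return A [bin_set()] of the completed profile.
#' @export
select_output <- function(result, total_size = NULL) {
  stopifnot(inherits(result, "imputation_result"))
  total_size <- total_size %||% attr(result, "avg_bin_count")
  if (!is.numeric(total_size) || total_size <= 0) {
    stop_input("`total_size` must be a positive number")
  }
  obs <- result[result$is_input, ]
  n_add <- total_size - nrow(obs)
  if (n_add < 0) {
    warn(sprintf("cell already has %d bins (>= total_size %d); output is the input unchanged",
                 nrow(obs), as.integer(total_size)))
    n_add <- 0
  }
  cand <- result[!result$is_input, ]  # already in ranked order
  keep <- bind_rows(obs, head(cand, n_add))
  bin_set(keep[, c("chrom", "bin_index")], attr(result, "bin_size"),
          attr(result, "assembly"))
}

#' Write / read the ranked imputation table
#'
#' TSV with columns `bin_id`, `chrom`, `start`, `end`,
#' `reference_frequency`, `imputed_probability`: observed bins first with
#' probability -1, then candidates by descending probability.
#'
#' @param result An `imputation_result`.
#' @param path Output path.
#' @return `path` invisibly; `read_imputation_table()` returns the tibble in
#'   file order.
#' @export
write_imputation_table <- function(result, path) {
  stopifnot(inherits(result, "imputation_result"))
  out <- result[, c("bin_id", "chrom", "start", "end",
                    "reference_frequency", "imputed_probability")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_imputation_table
#' @export
read_imputation_table <- function(path) {
  readr::read_tsv(path, col_types = "ccdddd", progress = FALSE)
}

#' Frequency-only imputation baseline
#'
#' Scores every reference bin by its reference frequency alone, ignoring the
#' single cell entirely. This is the no-learning comparator for the model:
#' any cell-type specificity the forest achieves must exceed what plain
#' reference frequencies provide.
#'
#' @param rs A `reference_matrix`.
#' @return A tibble of all reference bins with a `probability` column equal
#'   to the bin frequency (identical for every cell by construction).
#' @export
average_interaction <- function(rs) {
  stopifnot(inherits(rs, "reference_matrix"))
  dplyr::mutate(bin_frequency(rs), probability = .data$frequency)
}
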