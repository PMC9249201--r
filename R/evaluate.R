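# Validation machinery: per-bin cross-validation, down-sampling simulations
# with leave-out ablations, Jaccard-based single-cell specificity against a
# peer consensus, randomization baselines, and clustering quality.

#' Jaccard index between two bin sets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty.
#'
#' @param a,b [bin_set()] objects at the same bin size.
#' @return A value in `[0, 1]`.
#' @examples
#' a <- bin_set(data.frame(chrom = "chr1", bin_index = 1:3), 5000)
#' b <- bin_set(data.frame(chrom = "chr1", bin_index = 2:4), 5000)
#' jaccard(a, b)  # 2 shared of 4 total -> 0.5
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "bin_set"), inherits(b, "bin_set"))
  check_same_bin_size(a, b)
  ka <- bin_key(a); kb <- bin_key(b)
  u <- length(union(ka, kb))
  if (u == 0) return(1.0)
  length(intersect(ka, kb)) / u
}

# Set difference on bin sets, preserving attributes.
bin_setdiff <- function(a, b) {
  keep <- !(bin_key(a) %in% bin_key(b))
  bin_set(as_tibble(a)[keep, c("chrom", "bin_index")],
          bin_size_of(a), assembly_of(a))
}

# Rank-based AUROC via pROC with fixed direction (no auto-direction bias).
auroc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("0", "1"), direction = "<", quiet = TRUE)))
}

# Average precision: step-wise integral of the precision-recall curve,
# i.e. the mean of precision at the rank of each positive. Conservative for
# imbalanced classes; ties broken by stable order.
average_precision <- function(labels, scores) {
  labels <- as.integer(as.character(labels))
  if (sum(labels) == 0 || sum(labels) == length(labels)) return(NA_real_)
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- cumsum(lab)
  prec <- hits / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab)
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled and dealt round-robin over folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_rng(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified cross-validation of one candidate-bin classifier
#'
#' Evaluates whether the reference carries predictive signal for a candidate
#' bin: stratified k-fold CV over the reference experiments, per-fold AUROC
#' and average precision on the held-out rows, reported as means together
#' with the bin's class balance. When the minority class has fewer members
#' than `folds`, the fold count is reduced to the minority count; bins with
#' fewer than 2 minority members (or a constant class vector) are not
#' evaluable and return `NULL`.
#'
#' @param tf Binary feature matrix (experiments x observed bins).
#' @param class_vector Binary candidate-bin column.
#' @param folds Maximum number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param trees Trees per fold model.
#' @return A one-row tibble (`class_balance`, `auroc`, `auprc`,
#'   `folds_used`), or `NULL` for a non-evaluable bin.
#' @export
crossvalidate_bin <- function(tf, class_vector, folds = 10L, seed = 1L,
                              trees = 100L) {
  if (length(class_vector) != nrow(tf)) {
    stop_input("class vector length must equal the number of reference experiments")
  }
  if (is.null(colnames(tf))) colnames(tf) <- paste0("f", seq_len(ncol(tf)))
  minority <- min(sum(class_vector == 1), sum(class_vector == 0))
  if (minority < 2) return(NULL)
  k <- min(folds, minority)
  fold <- stratified_folds(class_vector, k, seed)
  metrics <- purrr::map(seq_len(k), function(f) {
    test <- fold == f
    model <- fit_forest(tf[!test, , drop = FALSE], class_vector[!test],
                        seed = seed + f, trees = trees)
    pred <- stats::predict(model, data = tf[test, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
    lab <- factor(class_vector[test], levels = c(0, 1))
    c(auroc = auroc(lab, pred), auprc = average_precision(lab, pred))
  })
  m <- do.call(rbind, metrics)
  tibble(class_balance = mean(class_vector),
         auroc = mean(m[, "auroc"], na.rm = TRUE),
         auprc = mean(m[, "auprc"], na.rm = TRUE),
         folds_used = k)
}

#' Cross-validate candidate bins for one cell
#'
#' Builds the cell's feature matrix, then runs [crossvalidate_bin()] on a
#' (possibly subsampled) set of evaluable candidate bins. On an intact
#' reference this verifies that candidate-bin presence is predictable from
#' the cell's bins; on a shuffled reference ([shuffle_reference()]) it
#' calibrates the random baseline: AUROC concentrates at 0.5 and average
#' precision at the class balance.
#'
#' @param rs A `reference_matrix`.
#' @param sc A [bin_set()] for the cell.
#' @param n_bins Optional number of candidate bins to sample (uniformly,
#'   seeded) from the evaluable candidates; default all.
#' @param folds,seed,trees As in [crossvalidate_bin()].
#' @return A `cv_result` tibble: one row per evaluated bin with its
#'   coordinates, `class_balance`, `auroc`, `auprc`, `folds_used`.
#' @export
crossvalidate_reference <- function(rs, sc, n_bins = NULL, folds = 10L,
                                    seed = 1L, trees = 100L) {
  parts <- make_training(rs, sc)
  cand <- parts$candidates
  balance <- colMeans(rs$values[, cand$.col, drop = FALSE])
  nref <- nrow(rs$values)
  minority <- pmin(balance, 1 - balance) * nref
  evaluable <- which(minority >= 2)
  if (length(evaluable) == 0) stop_input("no evaluable candidate bins")
  if (!is.null(n_bins) && n_bins < length(evaluable)) {
    evaluable <- with_rng(seed, sort(sample(evaluable, n_bins)))
  }
  rows <- purrr::map(evaluable, function(g) {
    rec <- crossvalidate_bin(parts$tf, rs$values[, cand$.col[g]],
                             folds = folds,
                             seed = derive_seed(seed, cand$chrom[g], cand$bin_index[g]),
                             trees = trees)
    if (is.null(rec)) return(NULL)
    dplyr::bind_cols(cand[g, c("chrom", "bin_index", "start", "end")], rec)
  })
  out <- bind_rows(rows)
  structure(out, class = c("cv_result", class(tibble())))
}

#' Down-sample a full profile to a sparse one
#'
#' Uniform random subset without replacement — the simulation of a sparse
#' single-cell capture from a full (bulk-derived) profile.
#'
#' @param origin A [bin_set()].
#' @param size Number of bins to keep (must not exceed `nrow(origin)`).
#' @param seed Integer seed.
#' @return A [bin_set()] subset of `origin`.
#' @export
downsample_profile <- function(origin, size, seed) {
  stopifnot(inherits(origin, "bin_set"))
  if (size > nrow(origin)) {
    stop_input(sprintf("cannot sample %d bins from a profile of %d",
                       size, nrow(origin)),
               class = "chipimpute_size_error")
  }
  keep <- with_rng(seed, sort(sample.int(nrow(origin), size)))
  bin_set(as_tibble(origin)[keep, c("chrom", "bin_index")],
          bin_size_of(origin), assembly_of(origin))
}

#' Random sparse input (randomization baseline)
#'
#' Samples `s` bins uniformly from the reference columns, ignoring any real
#' cell — the "randomized sparse input" control.
#'
#' @param rs A `reference_matrix`.
#' @param s Number of bins.
#' @param seed Integer seed.
#' @return A [bin_set()].
#' @export
randomized_input <- function(rs, s, seed) {
  stopifnot(inherits(rs, "reference_matrix"))
  if (s > nrow(rs$bins)) {
    stop_input("cannot sample more bins than the reference has columns",
               class = "chipimpute_size_error")
  }
  keep <- with_rng(seed, sort(sample.int(nrow(rs$bins), s)))
  bin_set(rs$bins[keep, c("chrom", "bin_index")], rs$bin_size, rs$assembly)
}

# Origin row of a reference as a bin set.
row_profile <- function(rs, accession) {
  i <- match(accession, rs$experiments$accession)
  if (is.na(i)) stop_input(sprintf("'%s' is not a reference experiment", accession))
  bin_set(rs$bins[rs$values[i, ] == 1, c("chrom", "bin_index")],
          rs$bin_size, rs$assembly)
}

#' Down-sampling simulation for one origin experiment
#'
#' Treats one bulk experiment as a full single-cell profile, down-samples it
#' to each requested sparse size, imputes with the origin (or its whole
#' biosample) held out of the training reference, and scores the imputed
#' probabilities against origin membership. The sampled input bins are known
#' before imputation and are excluded from the evaluation universe; the
#' negatives are the training reference's columns not in the input and not
#' in the origin.
#'
#' @param rs A `reference_matrix`.
#' @param origin Accession of the origin experiment.
#' @param sizes Sparse input sizes (bins), e.g. `c(100, 200, 400)`.
#' @param mode `"leave_out_origin"` or `"leave_out_cell_type"`.
#' @param seed Master seed.
#' @param trees Trees per candidate forest.
#' @return A tibble: one row per size with `auroc`, `auprc`,
#'   `class_balance` (positive fraction of the evaluation universe),
#'   `n_positive`, `n_evaluated`.
#' @export
run_simulation <- function(rs, origin, sizes,
                           mode = c("leave_out_origin", "leave_out_cell_type"),
                           seed = 1L, trees = 100L) {
  mode <- match.arg(mode)
  origin_bins <- row_profile(rs, origin)
  train_rs <- drop_rows(rs, mode, origin)
  rows <- purrr::map(sizes, function(sz) {
    sc <- downsample_profile(origin_bins, sz, seed = seed + sz)
    result <- impute_cell(train_rs, sc, seed = seed, trees = trees)
    eval_rows <- result[!result$is_input, ]
    labels <- factor(as.integer(bin_key(eval_rows) %in% bin_key(origin_bins)),
                     levels = c(0, 1))
    tibble(size = sz,
           auroc = auroc(labels, eval_rows$imputed_probability),
           auprc = average_precision(labels, eval_rows$imputed_probability),
           class_balance = mean(labels == "1"),
           n_positive = sum(labels == "1"),
           n_evaluated = nrow(eval_rows))
  })
  dplyr::mutate(bind_rows(rows), origin = origin, mode = mode, .before = 1)
}

#' Consensus profile of an origin's peer experiments
#'
#' The aggregate profile of the other experiments sharing the origin's
#' biosample (and target, which all rows of a reference share): a bin is
#' included when present in more than half of those peers.
#'
#' @param rs A `reference_matrix`.
#' @param origin Accession of the origin experiment.
#' @return A [bin_set()].
#' @export
consensus_profile <- function(rs, origin) {
  stopifnot(inherits(rs, "reference_matrix"))
  i <- match(origin, rs$experiments$accession)
  if (is.na(i)) stop_input(sprintf("'%s' is not a reference experiment", origin))
  peers <- which(rs$experiments$biosample == rs$experiments$biosample[i])
  peers <- setdiff(peers, i)
  if (length(peers) == 0) {
    stop_input("origin has no peer experiment with the same biosample",
               class = "chipimpute_no_peers_error")
  }
  share <- colMeans(rs$values[peers, , drop = FALSE])
  bin_set(rs$bins[share > 0.5, c("chrom", "bin_index")],
          rs$bin_size, rs$assembly)
}

#' Single-cell specificity of an imputed profile
#'
#' Measures whether an imputed profile is closer to the specific origin it
#' was simulated from than to the consensus of the origin's peers. The
#' sampled input bins are known before imputation, so they are removed from
#' all three sets first; specificity is
#' `Jaccard(imputed, origin) - Jaccard(imputed, consensus)`, positive when
#' the imputation recovered origin-specific structure beyond the biosample
#' consensus.
#'
#' @param imputed,origin,consensus,input_bins [bin_set()] objects at one
#'   bin size.
#' @return A one-row tibble: `j_origin`, `j_consensus`, `specificity`,
#'   `origin_consensus_similarity`, `input_size`.
#' @export
specificity <- function(imputed, origin, consensus, input_bins) {
  for (x in list(origin, consensus, input_bins)) check_same_bin_size(imputed, x)
  i2 <- bin_setdiff(imputed, input_bins)
  o2 <- bin_setdiff(origin, input_bins)
  c2 <- bin_setdiff(consensus, input_bins)
  jo <- jaccard(i2, o2); jc <- jaccard(i2, c2)
  tibble(j_origin = jo, j_consensus = jc, specificity = jo - jc,
         origin_consensus_similarity = jaccard(o2, c2),
         input_size = nrow(input_bins))
}

#' Specificity simulation for one origin experiment
#'
#' End-to-end single-cell-specificity run: down-sample the origin, impute
#' with the origin left out, select the completed profile at the reference's
#' average bin count, and score it against the origin and the peer
#' consensus via [specificity()].
#'
#' @inheritParams run_simulation
#' @param total_size Completed-profile size (default: average bin count of
#'   the training reference).
#' @return A `specificity_result` tibble, one row per size.
#' @export
simulate_specificity <- function(rs, origin, sizes, seed = 1L, trees = 100L,
                                 total_size = NULL) {
  origin_bins <- row_profile(rs, origin)
  consensus <- consensus_profile(rs, origin)
  train_rs <- drop_rows(rs, "leave_out_origin", origin)
  rows <- purrr::map(sizes, function(sz) {
    sc <- downsample_profile(origin_bins, sz, seed = seed + sz)
    result <- impute_cell(train_rs, sc, seed = seed, trees = trees)
    imputed <- select_output(result, total_size)
    specificity(imputed, origin_bins, consensus, sc)
  })
  out <- dplyr::mutate(bind_rows(rows), origin = origin,
                       size = sizes, .before = 1)
  structure(out, class = c("specificity_result", class(tibble())))
}

#' Davies-Bouldin clustering quality index
#'
#' Mean over clusters of the worst-case ratio
#' `(scatter_i + scatter_j) / centroid_distance_ij` (lower is better).
#' Scatter is the mean Euclidean distance of a cluster's points to its
#' centroid. Coincident centroids of distinct clusters yield `Inf`.
#'
#' @param points Numeric matrix or data frame, one row per cell (e.g. an
#'   embedding of imputed profiles).
#' @param labels Cluster/cell-type labels, one per row.
#' @return A nonnegative score.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) {
    stop_input("`labels` must have one entry per row of `points`")
  }
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) {
    stop_input("need at least 2 clusters", class = "chipimpute_cluster_error")
  }
  centroid <- do.call(rbind, lapply(cl, function(g) {
    colMeans(points[labels == g, , drop = FALSE])
  }))
  scatter <- vapply(seq_along(cl), function(i) {
    p <- points[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums((p - matrix(centroid[i, ], nrow(p), ncol(p), byrow = TRUE))^2)))
  }, 0.0)
  r <- vapply(seq_along(cl), function(i) {
    max(vapply(setdiff(seq_along(cl), i), function(j) {
      d <- sqrt(sum((centroid[i, ] - centroid[j, ])^2))
      if (d == 0) Inf else (scatter[i] + scatter[j]) / d
    }, 0.0))
  }, 0.0)
  mean(r)
}

#' Recall of bins removed from a profile
#'
#' Removes a random fraction of a cell's reference-covered bins, imputes
#' from the remainder, and reports the fraction of removed bins ranked
#' within the top-k candidates, k being the number of removed bins. With
#' `removal_fraction = 0` nothing is removed and recall is vacuously 1.
#'
#' @param rs A `reference_matrix`.
#' @param cell A [bin_set()].
#' @param removal_fraction Fraction of the cell's reference-covered bins to
#'   remove (in `[0, 1)`).
#' @param seed Master seed.
#' @param trees Trees per candidate forest.
#' @return A one-row tibble: `recall`, `n_removed`, `n_kept`.
#' @export
recall_of_removed_bins <- function(rs, cell, removal_fraction, seed = 1L,
                                   trees = 100L) {
  stopifnot(inherits(rs, "reference_matrix"), inherits(cell, "bin_set"))
  in_rs <- bin_key(cell) %in% bin_key(rs$bins)
  covered <- bin_set(as_tibble(cell)[in_rs, c("chrom", "bin_index")],
                     bin_size_of(cell), assembly_of(cell))
  n_remove <- floor(removal_fraction * nrow(covered))
  if (n_remove == 0) {
    return(tibble(recall = 1.0, n_removed = 0L, n_kept = nrow(covered)))
  }
  if (n_remove >= nrow(covered)) {
    stop_input("removal would leave no bins", class = "chipimpute_size_error")
  }
  removed_idx <- with_rng(seed, sort(sample.int(nrow(covered), n_remove)))
  removed <- bin_set(as_tibble(covered)[removed_idx, c("chrom", "bin_index")],
                     bin_size_of(cell), assembly_of(cell))
  kept <- bin_setdiff(covered, removed)
  result <- impute_cell(rs, kept, seed = seed, trees = trees)
  top <- head(result[!result$is_input, ], n_remove)
  tibble(recall = mean(bin_key(removed) %in% bin_key(top)),
         n_removed = n_remove, n_kept = nrow(kept))
}
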