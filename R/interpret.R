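# Interpretable single-locus mode: instead of scoring every candidate bin,
# train the per-bin classifier for one user-chosen genomic position and
# report which of the cell's observed bins drive the prediction (random
# forest feature importances), annotated with the nearest gene. High
# importance of a promoter-proximal bin for another promoter's model is a
# model-derived hint of a regulatory relationship, which co-expression data
# can corroborate.

#' Read a gene annotation table
#'
#' TSV with columns `symbol`, `chrom`, `tss`, `strand` (one transcription
#' start site per gene symbol).
#'
#' @param path File path.
#' @return A tibble, chromosome names normalized.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    symbol = "c", chrom = "c", tss = "d", strand = "c"), progress = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  required <- c("symbol", "chrom", "tss", "strand")
  if (!all(required %in% names(ann))) {
    stop_input(paste("annotation needs columns:", paste(required, collapse = ", ")))
  }
  if (anyDuplicated(ann$symbol)) stop_input("duplicate gene symbols in annotation")
  dplyr::mutate(ann, chrom = normalize_chrom(.data$chrom))
}

#' Read a gene-gene co-expression table
#'
#' TSV with columns `gene_a`, `gene_b`, `score` (nonnegative). Lookup is
#' symmetric; a missing pair scores 0 (absence of evidence).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_coexpression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", score = "d"), progress = FALSE)
}

coexpression_score <- function(coex, a, b) {
  hit <- (coex$gene_a == a & coex$gene_b == b) |
         (coex$gene_a == b & coex$gene_b == a)
  if (any(hit)) coex$score[which(hit)[1]] else 0
}

#' Annotate bins with their nearest gene
#'
#' Nearest gene by absolute distance between the bin midpoint and the gene's
#' TSS; equidistant genes are resolved to the lexicographically first symbol.
#' The reported distance is signed on the gene's strand: negative when the
#' bin lies upstream of the TSS.
#'
#' @param bins A [bin_set()] or tibble with `chrom`, `start`, `end`.
#' @param annotation A gene annotation tibble (see [read_gene_annotation()]).
#' @return The bins with `gene` and `tss_distance` columns; bins on
#'   chromosomes without any annotated gene get `gene = NA`.
#' @export
annotate_nearest_gene <- function(bins, annotation) {
  annotation <- validate_annotation(annotation)
  bins <- as_tibble(bins)
  mid <- (bins$start + bins$end) / 2
  res <- purrr::map(seq_len(nrow(bins)), function(i) {
    cand <- annotation[annotation$chrom == bins$chrom[i], ]
    if (nrow(cand) == 0) {
      return(tibble(gene = NA_character_, tss_distance = NA_real_))
    }
    d <- abs(mid[i] - cand$tss)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(cand$symbol[best])][1]
    raw <- mid[i] - cand$tss[best]               # + means bin right of TSS
    signed <- if (cand$strand[best] == "-") -raw else raw
    tibble(gene = cand$symbol[best], tss_distance = signed)
  })
  dplyr::bind_cols(bins, bind_rows(res))
}

#' Interpret the model for one genomic position
#'
#' Trains exactly the per-candidate-bin classifier of [impute_bin()] for the
#' bin containing `position`, and reports the imputed probability together
#' with the cell's observed bins ranked by normalized impurity-decrease
#' importance. When `max_tss_distance` is set, the feature set is restricted
#' before training to observed bins whose midpoint lies within that distance
#' of an annotated TSS, focusing the model on promoter-proximal context.
#'
#' @param rs A `reference_matrix`.
#' @param sc A [bin_set()] for the cell.
#' @param chrom,position Chromosome and 0-based bp coordinate of interest.
#' @param annotation Optional gene annotation; required for nearest-gene
#'   reporting and for `max_tss_distance`.
#' @param seed,trees As in [impute_bin()].
#' @param max_tss_distance Optional bp radius for the TSS restriction.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An `interpretation_result`: list with `query` (the bin), and
#'   `probability`, `observed` (was the bin already in the cell), `features`
#'   (tibble ranked by importance, with gene annotation when available).
#' @export
interpret_position <- function(rs, sc, chrom, position, annotation = NULL,
                               seed = 1L, trees = 100L,
                               max_tss_distance = NULL,
                               importance = c("impurity", "permutation")) {
  stopifnot(inherits(rs, "reference_matrix"))
  importance <- match.arg(importance)
  chrom <- normalize_chrom(chrom)
  if (!is.numeric(position) || position < 0) {
    stop_input("`position` must be a nonnegative bp coordinate")
  }
  qidx <- floor(position / rs$bin_size)
  query <- tibble(chrom = chrom, bin_index = qidx,
                  start = qidx * rs$bin_size, end = (qidx + 1) * rs$bin_size)
  qcol <- match(bin_key(query), bin_key(rs$bins))
  if (is.na(qcol)) {
    stop_input(sprintf(
      "bin %s:%d-%d is outside the reference universe (present in no reference experiment), so its class vector would be all zero",
      chrom, query$start, query$end),
      class = "chipimpute_unknown_bin_error")
  }
  parts <- make_training(rs, sc)
  observed <- bin_key(query) %in% bin_key(parts$features)
  feats <- parts$features
  tf <- parts$tf
  if (!is.null(max_tss_distance)) {
    if (is.null(annotation)) {
      stop_input("`max_tss_distance` requires a gene annotation")
    }
    ann <- validate_annotation(annotation)
    mid <- (feats$start + feats$end) / 2
    near <- vapply(seq_len(nrow(feats)), function(i) {
      cand <- ann[ann$chrom == feats$chrom[i], ]
      nrow(cand) > 0 && min(abs(mid[i] - cand$tss)) <= max_tss_distance
    }, TRUE)
    if (!any(near)) {
      stop_input("TSS-distance restriction removes every feature",
                 class = "chipimpute_no_features_error")
    }
    feats <- feats[near, ]
    tf <- tf[, near, drop = FALSE]
  }
  class_vector <- rs$values[, qcol]
  bin_seed <- derive_seed(seed, chrom, qidx)
  if (observed) {
    rho <- 1.0
    imp <- rep(0, nrow(feats))
    inform("query bin is already observed in the cell; probability 1 by definition")
  } else if (all(class_vector == 1L) || all(class_vector == 0L)) {
    rho <- as.numeric(class_vector[1])
    imp <- rep(0, nrow(feats))
  } else {
    model <- fit_forest(tf, class_vector, bin_seed, trees,
                        importance = importance)
    rho <- probe_predict(model, ncol(tf), colnames(tf))
    imp <- ranger::importance(model)
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  feats <- dplyr::mutate(feats, importance = unname(imp))
  if (!is.null(annotation)) {
    feats <- annotate_nearest_gene(feats, annotation)
  }
  feats <- feats[order(-feats$importance, chrom_rank(feats$chrom),
                       feats$bin_index), ]
  structure(list(query = query, probability = rho, observed = observed,
                 features = as_tibble(feats),
                 n_features = nrow(feats), seed = seed, trees = trees,
                 max_tss_distance = max_tss_distance),
            class = "interpretation_result")
}

#' @export
print.interpretation_result <- function(x, ...) {
  cat(sprintf("<interpretation_result> %s:%s-%s  probability %.3f%s\n",
              x$query$chrom, format(x$query$start, scientific = FALSE),
              format(x$query$end, scientific = FALSE), x$probability,
              if (x$observed) " (already observed)" else ""))
  cat(sprintf("  %d features; top importances:\n", x$n_features))
  print(head(x$features, 5))
  invisible(x)
}

#' Correlate feature importances with co-expression
#'
#' For an interpreted promoter, compares the model's feature importances
#' with co-expression scores between each feature's nearest gene and the
#' query gene. Duplicate feature genes are aggregated by summed importance
#' before correlating. A high Pearson correlation indicates the model leans
#' on bins near genes that are co-expressed with the query gene, supporting
#' a regulatory reading of the importances.
#'
#' @param result An `interpretation_result` with gene-annotated features.
#' @param query_gene Symbol of the gene whose promoter was interpreted.
#' @param coexpression Co-expression tibble (see [read_coexpression()]).
#' @return Pearson correlation coefficient, or `NA` when either vector has
#'   zero variance.
#' @export
correlate_importance_coexpression <- function(result, query_gene, coexpression) {
  stopifnot(inherits(result, "interpretation_result"))
  feats <- result$features
  if (!"gene" %in% names(feats)) {
    stop_input("features carry no gene annotation; rerun interpret_position() with `annotation`")
  }
  feats <- feats[!is.na(feats$gene), ]
  agg <- feats |>
    group_by(.data$gene) |>
    summarise(importance = sum(.data$importance), .groups = "drop")
  if (nrow(agg) < 3) {
    stop_input("need at least 3 annotated features to correlate")
  }
  coex_scores <- vapply(agg$gene, function(g) {
    coexpression_score(coexpression, g, query_gene)
  }, 0.0)
  if (sd(agg$importance) == 0 || sd(coex_scores) == 0) return(NA_real_)
  cor(agg$importance, coex_scores)
}

#' Promoter coverage and imputed probability across cells
#'
#' For each gene, the promoter bin is the bin containing its TSS. Reports
#' (i) the fraction of cells whose sparse profile already covers the
#' promoter bin and (ii) the mean and sd of the imputed probability across
#' cells (cells that already observe the bin contribute probability 1). A
#' `max_frequency` filter selects genes whose promoter is rarely present in
#' the bulk reference — the regime where imputation is informative rather
#' than a frequency lookup.
#'
#' @param rs A `reference_matrix`.
#' @param cells List of [bin_set()] profiles.
#' @param genes Character vector of gene symbols.
#' @param annotation Gene annotation tibble.
#' @param seed,trees As in [impute_bin()].
#' @param max_frequency Optional cutoff; genes whose promoter-bin reference
#'   frequency is >= this value are dropped.
#' @return A tibble: one row per gene with `coverage`, `mean_probability`,
#'   `sd_probability`, `reference_frequency`, `n_cells`.
#' @export
promoter_scan <- function(rs, cells, genes, annotation, seed = 1L,
                          trees = 100L, max_frequency = NULL) {
  annotation <- validate_annotation(annotation)
  rows <- purrr::map(genes, function(g) {
    ann <- annotation[annotation$symbol == g, ]
    if (nrow(ann) == 0) {
      warn(sprintf("gene '%s' absent from annotation; skipped", g))
      return(NULL)
    }
    qidx <- floor(ann$tss / rs$bin_size)
    key <- paste(ann$chrom, qidx, sep = ":")
    col <- match(key, bin_key(rs$bins))
    if (is.na(col)) {
      warn(sprintf("promoter bin of '%s' outside the reference universe; skipped", g))
      return(NULL)
    }
    freq <- mean(rs$values[, col])
    if (!is.null(max_frequency) && freq >= max_frequency) return(NULL)
    covered <- vapply(cells, function(sc) key %in% bin_key(sc), TRUE)
    rho <- vapply(seq_along(cells), function(i) {
      res <- suppressMessages(
        interpret_position(rs, cells[[i]], ann$chrom, ann$tss,
                           seed = seed + i - 1L, trees = trees))
      res$probability
    }, 0.0)
    tibble(gene = g, chrom = ann$chrom, promoter_bin = qidx,
           reference_frequency = freq,
           coverage = mean(covered),
           mean_probability = mean(rho),
           sd_probability = if (length(rho) > 1) sd(rho) else NA_real_,
           n_cells = length(cells))
  })
  bind_rows(rows)
}
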