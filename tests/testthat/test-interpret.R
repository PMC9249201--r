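test_that("interpretation shares the imputation engine's probability", {
  bench <- local_bench()
  rs <- bench$reference
  cell <- generate_cell(bench, 1, 80, seed = 3)
  parts <- make_training(rs, cell$sc)
  cand <- parts$candidates[5, ]
  res <- interpret_position(rs, cell$sc, cand$chrom, cand$start + 1,
                            seed = 17, trees = 40)
  rho <- impute_bin(parts$tf, rs$values[, cand$.col],
                    seed = chipimpute:::derive_seed(17, cand$chrom, cand$bin_index),
                    trees = 40)
  expect_equal(res$probability, rho)
})

test_that("importances are normalized and degenerate cases are exact", {
  bench <- local_bench()
  rs <- bench$reference
  cell <- generate_cell(bench, 2, 60, seed = 4)
  parts <- make_training(rs, cell$sc)
  cand <- parts$candidates[10, ]
  res <- interpret_position(rs, cell$sc, cand$chrom, cand$start, seed = 5, trees = 30)
  expect_equal(sum(res$features$importance), 1)
  expect_true(all(res$features$importance >= 0))
  expect_true(!is.unsorted(rev(res$features$importance)))
  # query bin already observed in the cell: probability 1, all-zero importances
  obs <- as.data.frame(cell$sc)[1, ]
  expect_message(
    res_obs <- interpret_position(rs, cell$sc, obs$chrom, obs$start, seed = 5),
    "already observed")
  expect_identical(res_obs$probability, 1.0)
  expect_true(res_obs$observed)
  expect_equal(sum(res_obs$features$importance), 0)
})

test_that("positions outside the reference universe are rejected", {
  rs <- tiny_rs()
  expect_error(interpret_position(rs, bins_of(1), "chr9", 1),
               class = "chipimpute_unknown_bin_error")
})

test_that("a planted perfectly co-occurring feature dominates the importances", {
  bench <- local_bench()
  rs <- bench$reference
  cell <- generate_cell(bench, 1, 150, seed = 2)
  tb <- bench$truth$bins
  bg <- tb$bin_index[tb$role == "background" & tb$kept]
  feat_idx <- intersect(cell$sc$bin_index, bg)[1]
  query_idx <- setdiff(bg, cell$sc$bin_index)[1]
  planted <- plant_cooccurrence(rs, list(chrom = "chrS", bin_index = query_idx),
                                list(chrom = "chrS", bin_index = feat_idx))
  wins <- vapply(1:20, function(sd) {
    res <- interpret_position(planted, cell$sc, "chrS", query_idx * 5000 + 1,
                              seed = sd)
    res$features$bin_index[1] == feat_idx
  }, TRUE)
  # oracle: the planted feature has per-column association 1 with the class
  # vector, strictly above every other feature, so it must rank first
  assoc <- abs(suppressWarnings(
    cor(planted$values[, paste0("chrS:", query_idx)],
        chipimpute:::make_training(planted, cell$sc)$tf)))
  expect_equal(colnames(assoc)[which.max(assoc)], paste0("chrS:", feat_idx))
  expect_gte(mean(wins), 0.95)
})

test_that("TSS-distance restriction shrinks the feature set before training", {
  bench <- local_bench()
  rs <- bench$reference
  ann <- synthetic_annotation(bench)
  cell <- generate_cell(bench, 1, 100, seed = 6)
  parts <- make_training(rs, cell$sc)
  cand <- parts$candidates[3, ]
  free <- interpret_position(rs, cell$sc, cand$chrom, cand$start, seed = 7,
                             trees = 30, annotation = ann)
  tight <- interpret_position(rs, cell$sc, cand$chrom, cand$start, seed = 7,
                              trees = 30, annotation = ann, max_tss_distance = 2500)
  expect_lte(nrow(tight$features), nrow(free$features))
  # with TSS at signature-bin midpoints, only signature bins survive a 2.5 kb radius
  sig <- bench$truth$bins$bin_index[grepl("signature", bench$truth$bins$role)]
  expect_true(all(tight$features$bin_index %in% sig))
  # annotation on a different chromosome: no feature is near any TSS
  far_ann <- tibble::tibble(symbol = "FAR", chrom = "chr1", tss = 0, strand = "+")
  expect_error(
    interpret_position(rs, cell$sc, cand$chrom, cand$start, annotation = far_ann,
                       max_tss_distance = 1000),
    class = "chipimpute_no_features_error")
})

test_that("nearest-gene annotation uses midpoint distance with documented tie-breaks", {
  ann <- tibble::tibble(symbol = c("B", "A", "C"),
                        chrom = c("chr1", "chr1", "chr1"),
                        tss = c(2500, 12500, 2500 + 30000),
                        strand = c("+", "-", "+"))
  bins <- bins_of(c(0, 2))
  out <- annotate_nearest_gene(bins, ann)
  # bin 0 midpoint 2500 == TSS of B (distance 0)
  expect_equal(out$gene[1], "B")
  expect_equal(out$tss_distance[1], 0)
  # bin 2 midpoint 12500: gene A at distance 0 but on '-' strand -> signed flip of 0
  expect_equal(out$gene[2], "A")
  # equidistant genes resolve lexicographically
  ann2 <- tibble::tibble(symbol = c("ZZ", "AA"), chrom = "chr1",
                         tss = c(2000, 3000), strand = "+")
  expect_equal(annotate_nearest_gene(bins_of(0), ann2)$gene, "AA")
  # signed upstream distance on the minus strand
  ann3 <- tibble::tibble(symbol = "G", chrom = "chr1", tss = 1000, strand = "-")
  d <- annotate_nearest_gene(bins_of(0), ann3)$tss_distance
  expect_equal(d, -(2500 - 1000))
  # unannotated chromosome
  expect_true(is.na(annotate_nearest_gene(bins_of(0, chrom = "chr7"), ann3)$gene))
})

test_that("importance-coexpression correlation matches hand-built cases", {
  res <- structure(list(features = tibble::tibble(
    chrom = "chr1", bin_index = 1:3, start = 0, end = 1,
    importance = c(0.5, 0.3, 0.2), gene = c("G1", "G2", "G3"))),
    class = "interpretation_result")
  coex <- tibble::tibble(gene_a = c("G1", "G2", "G3"), gene_b = "Q",
                         score = c(0.5, 0.3, 0.2))
  expect_equal(correlate_importance_coexpression(res, "Q", coex), 1.0)
  # affine decreasing scores (0.6 - importance): exactly anti-correlated
  anti <- tibble::tibble(gene_a = c("G1", "G2", "G3"), gene_b = "Q",
                         score = c(0.1, 0.3, 0.4))
  expect_equal(correlate_importance_coexpression(res, "Q", anti), -1.0)
  # duplicate feature genes aggregate by summed importance; missing pairs score 0
  res2 <- res
  res2$features$gene <- c("G1", "G1", "G3")
  res2$features <- rbind(res2$features,
                         tibble::tibble(chrom = "chr1", bin_index = 4, start = 0,
                                        end = 1, importance = 0.1, gene = "G9"))
  coex2 <- tibble::tibble(gene_a = c("G1", "G3"), gene_b = "Q", score = c(0.8, 0.2))
  r <- correlate_importance_coexpression(res2, "Q", coex2)
  expect_equal(r, cor(c(0.8, 0.2, 0.1), c(0.8, 0.2, 0)))
  # zero variance -> NA
  flat <- tibble::tibble(gene_a = c("G1", "G2", "G3"), gene_b = "Q", score = 0)
  expect_true(is.na(correlate_importance_coexpression(res, "Q", flat)))
  expect_error(correlate_importance_coexpression(
    structure(list(features = res$features[1:2, ]), class = "interpretation_result"),
    "Q", coex), "at least 3")
})

test_that("promoter scan reports coverage and imputed probability per gene", {
  bench <- local_bench()
  rs <- bench$reference
  ann <- synthetic_annotation(bench)
  cells <- lapply(1:3, function(i) generate_cell(bench, 1, 60, seed = 20 + i)$sc)
  genes <- head(ann$symbol[startsWith(ann$symbol, "G1_")], 2)
  out <- suppressMessages(promoter_scan(rs, cells, genes, ann, seed = 9, trees = 20))
  expect_equal(out$gene, genes)
  expect_true(all(out$coverage >= 0 & out$coverage <= 1))
  expect_true(all(out$mean_probability >= 0 & out$mean_probability <= 1))
  expect_equal(out$n_cells, c(3, 3))
  # coverage counts exactly the cells whose profile holds the promoter bin
  key <- paste0(out$chrom[1], ":", out$promoter_bin[1])
  manual <- mean(vapply(cells, function(sc) key %in% chipimpute:::bin_key(sc), TRUE))
  expect_equal(out$coverage[1], manual)
  expect_warning(suppressMessages(promoter_scan(rs, cells, "NOPE", ann)), "absent")
  # the low-frequency filter drops common promoters
  freqs <- bin_frequency(rs)
  common <- promoter_scan(rs, cells, genes, ann, max_frequency = 0)
  expect_equal(nrow(common), 0)
})
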