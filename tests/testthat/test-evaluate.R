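test_that("Jaccard identities hold", {
  a <- bins_of(1:3); b <- bins_of(2:4); d <- bins_of(7:9)
  e <- bins_of(integer(0))
  expect_equal(jaccard(a, a), 1.0)
  expect_equal(jaccard(a, d), 0.0)
  expect_equal(jaccard(a, b), 0.5)  # {1,2,3} vs {2,3,4}: 2 shared of 4
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_equal(jaccard(a, e), 0.0)
  expect_equal(jaccard(e, e), 1.0)
  expect_error(jaccard(a, bins_of(1:3, bin_size = 1000)),
               class = "chipimpute_bin_size_error")
})

test_that("average precision and AUROC match hand-computed rankings", {
  ap <- chipimpute:::average_precision
  # ranking (by score desc): 1,0,1,0 -> precisions at positives 1/1 and 2/3
  expect_equal(ap(c(1, 0, 1, 0), c(4, 3, 2, 1)), mean(c(1, 2/3)))
  expect_equal(ap(c(0, 0, 1), c(3, 2, 1)), 1/3)
  expect_true(is.na(ap(c(1, 1), c(1, 2))))
  roc <- chipimpute:::auroc
  expect_equal(roc(factor(c(0, 0, 1, 1), levels = 0:1), c(1, 2, 3, 4)), 1.0)
  expect_equal(roc(factor(c(1, 1, 0, 0), levels = 0:1), c(1, 2, 3, 4)), 0.0)
  expect_equal(roc(factor(c(0, 1, 0, 1), levels = 0:1), c(1, 1, 1, 1)), 0.5)
})

test_that("per-bin cross-validation recovers separable signal and skips degenerate bins", {
  bench <- local_bench()
  rs <- bench$reference
  cell <- generate_cell(bench, 1, 100, seed = 12)
  parts <- make_training(rs, cell$sc)
  # a class vector equal to one feature column is (near) perfectly separable
  rec <- crossvalidate_bin(parts$tf, parts$tf[, 10], seed = 31)
  expect_gt(rec$auroc, 0.9)
  expect_gt(rec$auprc, 0.85)
  expect_equal(rec$class_balance, mean(parts$tf[, 10]))
  # constant and near-constant class vectors are not evaluable
  expect_null(crossvalidate_bin(parts$tf, rep(1L, 30)))
  expect_null(crossvalidate_bin(parts$tf, c(1L, rep(0L, 29))))
  # folds reduce to the minority count
  y <- c(rep(1L, 3), rep(0L, 27))
  expect_equal(crossvalidate_bin(parts$tf, y, folds = 10, seed = 1, trees = 10)$folds_used, 3)
})

test_that("down-sampling is a deterministic uniform subset", {
  origin <- bins_of(1:50)
  sub1 <- downsample_profile(origin, 10, seed = 4)
  sub2 <- downsample_profile(origin, 10, seed = 4)
  sub3 <- downsample_profile(origin, 10, seed = 5)
  expect_identical(as.data.frame(sub1), as.data.frame(sub2))
  expect_false(identical(as.data.frame(sub1), as.data.frame(sub3)))
  expect_true(all(bin_key(sub1) %in% bin_key(origin)))
  expect_equal(nrow(sub1), 10)
  expect_equal(as.data.frame(downsample_profile(origin, 50, seed = 1)),
               as.data.frame(origin))
  expect_error(downsample_profile(origin, 51, seed = 1),
               class = "chipimpute_size_error")
})

test_that("randomized input samples reference columns with the same guarantees", {
  rs <- tiny_rs()
  r1 <- randomized_input(rs, 3, seed = 2)
  expect_equal(nrow(r1), 3)
  expect_true(all(bin_key(r1) %in% bin_key(rs$bins)))
  expect_identical(as.data.frame(r1), as.data.frame(randomized_input(rs, 3, seed = 2)))
  expect_error(randomized_input(rs, 6, seed = 1), class = "chipimpute_size_error")
})

test_that("consensus profiles apply the strict-majority rule over peers", {
  # 4 peers of 'x' biosample minus origin -> 3 peers; bin kept iff in >1.5 peers
  exps <- tibble::tibble(
    accession = c("O", "P1", "P2", "P3"), target = "T", biosample = "x",
    assembly = "y",
    bins = list(bins_of(0:1), bins_of(c(0, 2)), bins_of(c(0, 2)), bins_of(c(1, 2))))
  rs <- build_reference(exps, "T")
  cons <- consensus_profile(rs, "O")
  expect_bin_indices(cons, c(0, 2))  # bin0 in 2/3 peers, bin2 in 3/3, bin1 in 1/3
  # two peers: presence in 1 of 2 is not a strict majority
  rs2 <- build_reference(exps[c(1, 2, 4), ], "T")  # peers {0,2} and {1,2}
  expect_bin_indices(consensus_profile(rs2, "O"), 2)
  # single peer: consensus equals that peer
  rs3 <- build_reference(exps[1:2, ], "T")
  expect_bin_indices(consensus_profile(rs3, "O"), c(0, 2))
  expect_error(consensus_profile(build_reference(tiny_experiments(), "TGT"), "E4"),
               class = "chipimpute_no_peers_error")
})

test_that("specificity algebra behaves under the input-bin removal", {
  origin <- bins_of(1:10); consensus <- bins_of(6:15); input <- bins_of(1:3)
  # imputed == origin -> specificity = 1 - J(origin', consensus') >= 0
  rec <- specificity(origin, origin, consensus, input)
  expect_equal(rec$j_origin, 1.0)
  expect_equal(rec$specificity, 1 - rec$j_consensus)
  expect_gte(rec$specificity, 0)
  # imputed == consensus -> specificity <= 0
  rec2 <- specificity(consensus, origin, consensus, input)
  expect_lte(rec2$specificity, 0)
  # all equal -> 0
  rec3 <- specificity(origin, origin, origin, input)
  expect_equal(rec3$specificity, 0)
  # antisymmetry under swapping origin and consensus
  imp <- bins_of(4:12)
  fwd <- specificity(imp, origin, consensus, input)
  rev <- specificity(imp, consensus, origin, input)
  expect_equal(fwd$specificity, -rev$specificity)
  expect_equal(rec$input_size, 3)
})

test_that("simulations exclude input bins from evaluation and respect the ablation", {
  bench <- local_bench()
  rs <- bench$reference
  sim <- suppressMessages(
    run_simulation(rs, "SYN11", sizes = 100, seed = 5, trees = 25))
  origin_bins <- chipimpute:::row_profile(rs, "SYN11")
  # reconstruct the run's training reference and sparse input, and verify the
  # evaluation universe is exactly (training columns) minus (input bins)
  train <- suppressMessages(drop_rows(rs, "leave_out_origin", "SYN11"))
  sc <- downsample_profile(origin_bins, 100, seed = 5 + 100)
  in_cols <- sum(bin_key(sc) %in% chipimpute:::bin_key(train$bins))
  expect_equal(sim$n_evaluated, ncol(train$values) - in_cols)
  expect_equal(sim$n_positive,
               sum(chipimpute:::bin_key(train$bins) %in% bin_key(origin_bins)) -
                 in_cols)
  expect_true(sim$auroc > 0.5 && sim$auroc <= 1)
  loct <- suppressMessages(
    run_simulation(rs, "SYN11", sizes = 100, mode = "leave_out_cell_type",
                   seed = 5, trees = 25))
  # harder ablation: never better than a clairvoyant ceiling, still informative
  expect_true(loct$auroc > 0.5)
})

test_that("Davies-Bouldin matches manual arithmetic and guards degenerate geometry", {
  # two clusters on a line: A = {0, 2}, B = {10, 12}
  pts <- matrix(c(0, 2, 10, 12), ncol = 1)
  labels <- c("A", "A", "B", "B")
  # scatter_A = scatter_B = 1, centroid distance 10 -> DB = (1+1)/10 = 0.2
  expect_equal(davies_bouldin(pts, labels), 0.2)
  # well-separated tight clusters -> near 0
  tight <- rbind(matrix(rnorm(20, 0, 1e-3), ncol = 2),
                 matrix(rnorm(20, 50, 1e-3), ncol = 2))
  expect_lt(davies_bouldin(tight, rep(c("a", "b"), each = 10)), 1e-3)
  # coincident centroids of distinct clusters -> Inf
  dup <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(davies_bouldin(dup, c("a", "a", "b", "b")), Inf)
  expect_error(davies_bouldin(pts, rep("A", 4)), class = "chipimpute_cluster_error")
})

test_that("recall of removed bins counts removed bins in the top-k candidates", {
  bench <- local_bench()
  rs <- bench$reference
  cell <- generate_cell(bench, 3, 200, seed = 14)
  none <- recall_of_removed_bins(rs, cell$origin, 0, seed = 1)
  expect_equal(none$recall, 1.0)
  expect_equal(none$n_removed, 0L)
  rec <- suppressMessages(
    recall_of_removed_bins(rs, cell$origin, 0.25, seed = 14, trees = 50))
  expect_equal(rec$n_removed, floor(0.25 * nrow(cell$origin)))
  expect_true(rec$recall >= 0 && rec$recall <= 1)
  expect_error(recall_of_removed_bins(rs, cell$origin, 1, seed = 1),
               class = "chipimpute_size_error")
})
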