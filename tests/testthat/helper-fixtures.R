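# Fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdir().

bins_of <- function(idx, bin_size = 5000, chrom = "chr1") {
  bin_set(tibble::tibble(chrom = rep_len(chrom, length(idx)), bin_index = idx),
          bin_size)
}

# A tiny hand-specified reference: 4 experiments over chr1 bins, two
# biosamples. Bin 0 present everywhere, bin 4 only in E4.
tiny_experiments <- function() {
  tibble::tibble(
    accession = c("E1", "E2", "E3", "E4"),
    target = "TGT",
    biosample = c("liver", "liver", "liver", "brain"),
    assembly = "hg38",
    bins = list(bins_of(c(0, 1, 2)),
                bins_of(c(0, 1, 3)),
                bins_of(c(0, 2, 3)),
                bins_of(c(0, 4))))
}

tiny_rs <- function() build_reference(tiny_experiments(), "TGT")

# The default synthetic benchmark is moderately expensive to exercise, so
# it is generated once per test run and shared.
local_bench <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- default_benchmark()
    memo
  }
})

# Independent brute-force oracle for the imputed probability: walk each tree
# of a fitted forest with the all-ones probe via the exported tree structure
# and average the leaf class-1 fractions. Shares no code with predict().
traverse_probe <- function(model, feature_names) {
  probe <- stats::setNames(rep(1, length(feature_names)), feature_names)
  per_tree <- vapply(seq_len(model$num.trees), function(t) {
    ti <- ranger::treeInfo(model, t)
    ti <- ti[order(ti$nodeID), ]
    node <- 1L
    repeat {
      r <- ti[node, ]
      if (r$terminal) return(r$pred.1)
      node <- if (probe[[r$splitvarName]] <= r$splitval) {
        r$leftChild + 1L
      } else {
        r$rightChild + 1L
      }
    }
  }, 0.0)
  mean(per_tree)
}

expect_bin_indices <- function(bs, idx) {
  expect_equal(bs$bin_index, as.numeric(idx))
}
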