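test_that("build_reference assembles the union-of-bins presence matrix", {
  rs <- tiny_rs()
  expect_equal(dim(rs), c(4L, 5L))
  expect_bin_indices(ref_bins <- rs$bins, 0:4)
  expect_equal(unname(colSums(rs$values)), c(4, 2, 2, 2, 1))
  # two experiments sharing one bin
  small <- tibble::tibble(
    accession = c("A", "B"), target = "T", biosample = "x", assembly = "y",
    bins = list(bins_of(c(1, 2)), bins_of(c(2, 3))))
  rs2 <- build_reference(small, "T")
  expect_equal(unname(colSums(rs2$values)), c(1, 2, 1))
})

test_that("build_reference errors on missing targets and mixed bin sizes", {
  expect_error(build_reference(tiny_experiments(), "NOPE"),
               class = "chipimpute_target_error")
  mixed <- tiny_experiments()
  mixed$bins[[2]] <- bins_of(0:1, bin_size = 1000)
  expect_error(build_reference(mixed, "TGT"), class = "chipimpute_bin_size_error")
})

test_that("build_reference is invariant to experiment order and supports target groups", {
  exps <- tiny_experiments()
  shuffled <- exps[c(3, 1, 4, 2), ]
  expect_equal(build_reference(shuffled, "TGT")$values, tiny_rs()$values)
  grouped <- exps
  grouped$target <- c("A", "A", "B", "B")
  rs <- build_reference(grouped, c("A", "B"))
  expect_equal(nrow(rs$values), 4)
  expect_equal(rs$target, "A+B")
})

test_that("average bin count rounds the mean row sum half-up", {
  rs <- tiny_rs()  # row sums 3,3,3,2 -> mean 2.75 -> 3
  expect_equal(average_bin_count(rs), 3)
  # mean 1.5 rounds up to 2 (checked by direct arithmetic: floor(1.5+0.5))
  small <- tibble::tibble(
    accession = c("A", "B"), target = "T", biosample = "x", assembly = "y",
    bins = list(bins_of(1), bins_of(c(1, 2))))
  expect_equal(average_bin_count(build_reference(small, "T")), 2)
})

test_that("bin frequencies are column means and unknown bins error", {
  rs <- tiny_rs()
  expect_equal(bin_frequency(rs)$frequency, c(1, 0.5, 0.5, 0.5, 0.25))
  expect_equal(bin_frequency(rs, bins_of(4))$frequency, 0.25)
  expect_error(bin_frequency(rs, bins_of(99)),
               class = "chipimpute_unknown_bin_error")
})

test_that("shuffling preserves shape and column sums and is seed-deterministic", {
  bench <- local_bench()
  rs <- bench$reference
  sh1 <- shuffle_reference(rs, seed = 5)
  sh2 <- shuffle_reference(rs, seed = 5)
  sh3 <- shuffle_reference(rs, seed = 6)
  expect_identical(sh1$values, sh2$values)
  expect_false(identical(sh1$values, sh3$values))
  expect_equal(colSums(sh1$values), colSums(rs$values))
  expect_equal(dim(sh1), dim(rs))
  # single-row matrix cannot change
  one <- tiny_rs()
  one$values <- one$values[1, , drop = FALSE]
  one$experiments <- one$experiments[1, ]
  expect_identical(shuffle_reference(one, 3)$values, one$values)
})

test_that("leave-out ablations drop the right rows and prune empty columns", {
  rs <- tiny_rs()
  loo <- drop_rows(rs, "leave_out_origin", "E4")
  expect_equal(loo$experiments$accession, c("E1", "E2", "E3"))
  # bin 4 was present only in E4 -> column pruned
  expect_bin_indices(loo$bins, 0:3)
  expect_true(all(colSums(loo$values) >= 1))
  loct <- suppressMessages(drop_rows(rs, "leave_out_cell_type", "E4"))
  expect_equal(unique(loct$experiments$biosample), "liver")
  # removing the 3 liver rows would leave 1 < 2 -> error
  expect_error(suppressMessages(drop_rows(rs, "leave_out_cell_type", "E1")),
               class = "chipimpute_too_few_rows_error")
  expect_error(drop_rows(rs, "leave_out_origin", "missing"), "not a reference")
})

test_that("leave-out cell type never trains on the origin's biosample", {
  bench <- local_bench()
  rs <- bench$reference
  origin <- "SYN01"
  bio <- rs$experiments$biosample[rs$experiments$accession == origin]
  loct <- suppressMessages(drop_rows(rs, "leave_out_cell_type", origin))
  expect_false(bio %in% loct$experiments$biosample)
  expect_equal(nrow(loct$values), 20)
})

test_that("reference serialization round-trips losslessly and validates headers", {
  rs <- tiny_rs()
  path <- withr::local_tempfile(fileext = ".txt")
  write_reference(rs, path)
  back <- read_reference(path)
  expect_equal(back$values, rs$values)
  expect_equal(back$experiments, rs$experiments)
  expect_equal(as.data.frame(back$bins), as.data.frame(rs$bins))
  expect_equal(back$bin_size, rs$bin_size)
  expect_equal(back$target, rs$target)

  corrupt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("NOT_A_REFERENCE 1", "junk"), corrupt)
  expect_error(read_reference(corrupt), class = "chipimpute_format_error")
  truncated <- withr::local_tempfile(fileext = ".txt")
  writeLines(head(readLines(path), 8), truncated)
  expect_error(read_reference(truncated), class = "chipimpute_format_error")
  expect_error(read_reference(file.path(tempdir(), "absent.ref")), "no such file")
})

test_that("experiments load from a metadata table with relative BED paths", {
  dir <- withr::local_tempdir()
  writeLines("chr1\t0\t5000\nchr1\t9000\t9100", file.path(dir, "a.bed"))
  writeLines("chr1\t0\t4000", file.path(dir, "b.bed"))
  readr::write_tsv(tibble::tibble(
    accession = c("A1", "B1"), target = "T", biosample = c("x", "y"),
    assembly = "hg38", path = c("a.bed", "b.bed")),
    file.path(dir, "meta.tsv"))
  exps <- read_experiments(file.path(dir, "meta.tsv"), bin_size = 5000)
  rs <- build_reference(exps, "T")
  expect_equal(dim(rs), c(2L, 2L))
  expect_equal(unname(rs$values["A1", ]), c(1L, 1L))
  expect_equal(unname(rs$values["B1", ]), c(1L, 0L))
})
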