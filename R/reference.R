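# The target-specific reference matrix: a binary experiments-by-bins matrix
# built from bulk ChIP-seq experiments sharing one protein target. Rows are
# experiments, columns are bins present in at least one of them.

#' Build a reference matrix
#'
#' Collects all experiments matching the requested protein target (or target
#' group) and assembles the binary presence matrix: entry (i, j) is 1 when
#' bin j is present in experiment i. Columns are the union of the matching
#' experiments' bins, sorted by genome position, so every column has at least
#' one presence by construction.
#'
#' @param experiments A tibble with columns `accession`, `target`,
#'   `biosample`, `assembly` and a list-column `bins` of [bin_set()] objects
#'   (see [read_experiments()]).
#' @param target Character vector of one or more target names; multiple names
#'   are merged into one reference (e.g. functionally similar histone marks
#'   pooled to enlarge the training set).
#' @return A `reference_matrix` object.
#' @examples
#' exps <- tibble::tibble(
#'   accession = c("E1", "E2"), target = "X", biosample = c("a", "b"),
#'   assembly = "hg38",
#'   bins = list(bin_set(data.frame(chrom = "chr1", bin_index = 0:1), 5000),
#'               bin_set(data.frame(chrom = "chr1", bin_index = 1:2), 5000)))
#' build_reference(exps, "X")
#' @export
build_reference <- function(experiments, target) {
  experiments <- as_tibble(experiments)
  required <- c("accession", "target", "biosample", "assembly", "bins")
  if (!all(required %in% names(experiments))) {
    stop_input(paste("experiments need columns:", paste(required, collapse = ", ")))
  }
  hit <- experiments$target %in% target
  if (!any(hit)) {
    stop_input(sprintf("no experiment matches target(s) %s",
                       paste(target, collapse = ", ")),
               class = "chipimpute_target_error")
  }
  experiments <- experiments[hit, ]
  if (anyDuplicated(experiments$accession)) {
    stop_input("duplicate experiment accessions")
  }
  # deterministic row order regardless of input order
  experiments <- experiments[order(experiments$accession), ]
  sizes <- unique(vapply(experiments$bins, bin_size_of, 0))
  if (length(sizes) != 1) {
    stop_input("experiments have mixed bin sizes",
               class = "chipimpute_bin_size_error")
  }
  assemblies <- unique(experiments$assembly)
  if (length(assemblies) != 1) {
    stop_input("experiments have mixed assemblies")
  }
  all_bins <- bind_rows(purrr::map(experiments$bins, ~ .x[, c("chrom", "bin_index")]))
  cols <- bin_set(all_bins, sizes, assemblies)
  cols <- tibble(chrom = cols$chrom, bin_index = cols$bin_index,
                 start = cols$start, end = cols$end)
  keys <- paste(cols$chrom, cols$bin_index, sep = ":")
  values <- matrix(0L, nrow(experiments), nrow(cols),
                   dimnames = list(experiments$accession, keys))
  for (i in seq_len(nrow(experiments))) {
    values[i, match(bin_key(experiments$bins[[i]]), keys)] <- 1L
  }
  new_reference_matrix(
    target = paste(sort(unique(experiments$target)), collapse = "+"),
    experiments = experiments[, c("accession", "target", "biosample", "assembly")],
    bins = cols, values = values, bin_size = sizes, assembly = assemblies)
}

new_reference_matrix <- function(target, experiments, bins, values, bin_size,
                                 assembly) {
  structure(list(target = target, experiments = experiments, bins = bins,
                 values = values, bin_size = as.numeric(bin_size),
                 assembly = assembly),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf(
    "<reference_matrix> target %s: %d experiments x %d bins (%s bp, %s)\n",
    x$target, nrow(x$values), ncol(x$values),
    format(x$bin_size, big.mark = ","), x$assembly))
  cat(sprintf("  biosamples: %s\n",
              paste(head(unique(x$experiments$biosample), 6), collapse = ", ")))
  invisible(x)
}

#' @export
dim.reference_matrix <- function(x) dim(x$values)

ref_bins <- function(rs) {
  new_bin_set(rs$bins, rs$bin_size, rs$assembly)
}

#' Average bin count of the reference experiments
#'
#' The mean number of present bins per experiment, rounded half-up. This is
#' the default size of an imputed profile: the completed single cell should
#' look like a typical bulk profile of the same target.
#'
#' @param rs A `reference_matrix`.
#' @return An integer count.
#' @export
average_bin_count <- function(rs) {
  stopifnot(inherits(rs, "reference_matrix"))
  floor(mean(rowSums(rs$values)) + 0.5)
}

#' Per-bin reference frequency
#'
#' Fraction of reference experiments in which each bin is present (column
#' mean of the binary matrix).
#'
#' @param rs A `reference_matrix`.
#' @param bins Optional [bin_set()] or tibble with `chrom` and `bin_index`;
#'   if given, frequencies are returned for exactly these bins and a bin
#'   absent from the reference is an error (reference columns always have at
#'   least one presence, so an absent bin has no defined column).
#' @return A tibble with `chrom`, `bin_index`, `frequency`.
#' @export
bin_frequency <- function(rs, bins = NULL) {
  stopifnot(inherits(rs, "reference_matrix"))
  freq <- colMeans(rs$values)
  out <- dplyr::mutate(rs$bins, frequency = unname(freq))
  if (is.null(bins)) return(out)
  idx <- match(bin_key(bins), bin_key(rs$bins))
  if (anyNA(idx)) {
    stop_input("bin not present in the reference matrix",
               class = "chipimpute_unknown_bin_error")
  }
  out[idx, ]
}

#' Shuffle a reference matrix (randomization baseline)
#'
#' Permutes each column's entries independently across experiments. Per-bin
#' frequencies (column sums) are preserved while all cross-experiment
#' co-occurrence structure — the signal the imputation model learns from —
#' is destroyed. Imputation on a shuffled reference is the negative control:
#' cross-validated AUROC collapses to 0.5.
#'
#' @param rs A `reference_matrix`.
#' @param seed Integer seed; the same seed reproduces the same shuffle.
#' @return A `reference_matrix` of identical shape and column sums.
#' @export
shuffle_reference <- function(rs, seed) {
  stopifnot(inherits(rs, "reference_matrix"))
  n <- nrow(rs$values)
  values <- rs$values
  with_rng(seed, {
    for (j in seq_len(ncol(values))) {
      values[, j] <- values[sample.int(n), j]
    }
  })
  new_reference_matrix(rs$target, rs$experiments, rs$bins, values,
                       rs$bin_size, rs$assembly)
}

#' Remove reference rows for ablation experiments
#'
#' Supports the two simulation ablations: `"leave_out_origin"` removes the
#' single origin experiment before training, and `"leave_out_cell_type"`
#' removes every experiment sharing the origin's biosample. Columns left with
#' no presence are dropped to preserve the invariant that every reference
#' column is present in at least one experiment.
#'
#' @param rs A `reference_matrix`.
#' @param mode `"leave_out_origin"` or `"leave_out_cell_type"`.
#' @param origin Accession of the origin experiment (a row of `rs`).
#' @return A `reference_matrix` with fewer rows (and possibly fewer columns).
#' @export
drop_rows <- function(rs, mode = c("leave_out_origin", "leave_out_cell_type"),
                      origin) {
  stopifnot(inherits(rs, "reference_matrix"))
  mode <- match.arg(mode)
  i <- match(origin, rs$experiments$accession)
  if (is.na(i)) {
    stop_input(sprintf("origin '%s' is not a reference experiment", origin))
  }
  drop <- if (mode == "leave_out_origin") {
    i
  } else {
    which(rs$experiments$biosample == rs$experiments$biosample[i])
  }
  keep <- setdiff(seq_len(nrow(rs$values)), drop)
  if (length(keep) < 2) {
    stop_input("row removal leaves fewer than 2 reference experiments",
               class = "chipimpute_too_few_rows_error")
  }
  values <- rs$values[keep, , drop = FALSE]
  nonzero <- colSums(values) > 0
  if (any(!nonzero)) {
    inform(sprintf("dropping %d all-zero column(s) after row removal",
                   sum(!nonzero)))
  }
  new_reference_matrix(rs$target, rs$experiments[keep, ],
                       rs$bins[nonzero, ], values[, nonzero, drop = FALSE],
                       rs$bin_size, rs$assembly)
}

REF_MAGIC <- "CHIPIMPUTE_REFERENCE"
REF_VERSION <- 1L

#' Serialize / deserialize a reference matrix
#'
#' Versioned plain-text container: a magic line, header key/value pairs
#' (target, assembly, bin size, n, m), an experiment-metadata block, a
#' bin-coordinate block, and one 0/1 presence string per experiment. The
#' round trip is lossless and the header is validated on read.
#'
#' @param rs A `reference_matrix`.
#' @param path File path.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   returns the `reference_matrix`.
#' @export
write_reference <- function(rs, path) {
  stopifnot(inherits(rs, "reference_matrix"))
  e <- rs$experiments
  lines <- c(
    paste(REF_MAGIC, REF_VERSION),
    paste0("target\t", rs$target),
    paste0("assembly\t", rs$assembly),
    paste0("bin_size\t", format(rs$bin_size, scientific = FALSE)),
    paste0("n\t", nrow(rs$values)),
    paste0("m\t", ncol(rs$values)),
    sprintf("E\t%s\t%s\t%s\t%s", e$accession, e$target, e$biosample, e$assembly),
    sprintf("B\t%s\t%s", rs$bins$chrom,
            format(rs$bins$bin_index, scientific = FALSE, trim = TRUE)),
    sprintf("R\t%s\t%s", e$accession,
            apply(rs$values, 1, paste, collapse = "")))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) < 6 || !identical(strsplit(lines[1], " ")[[1]][1], REF_MAGIC)) {
    stop_input("not a reference file (bad magic line)",
               class = "chipimpute_format_error")
  }
  version <- suppressWarnings(as.integer(strsplit(lines[1], " ")[[1]][2]))
  if (is.na(version) || version != REF_VERSION) {
    stop_input("unsupported reference file version",
               class = "chipimpute_format_error")
  }
  header <- strsplit(lines[2:6], "\t", fixed = TRUE)
  hv <- setNames(vapply(header, `[[`, "", 2), vapply(header, `[[`, "", 1))
  n <- as.integer(hv[["n"]]); m <- as.integer(hv[["m"]])
  body <- lines[-(1:6)]
  parse_block <- function(tag, k) {
    block <- body[startsWith(body, paste0(tag, "\t"))]
    if (length(block) != k) {
      stop_input(sprintf("corrupt reference file: expected %d '%s' lines, found %d",
                         k, tag, length(block)),
                 class = "chipimpute_format_error")
    }
    strsplit(block, "\t", fixed = TRUE)
  }
  eb <- parse_block("E", n)
  experiments <- tibble(accession = vapply(eb, `[[`, "", 2),
                        target = vapply(eb, `[[`, "", 3),
                        biosample = vapply(eb, `[[`, "", 4),
                        assembly = vapply(eb, `[[`, "", 5))
  bb <- parse_block("B", m)
  bin_size <- as.numeric(hv[["bin_size"]])
  idx <- as.numeric(vapply(bb, `[[`, "", 3))
  bins <- tibble(chrom = vapply(bb, `[[`, "", 2), bin_index = idx,
                 start = idx * bin_size, end = (idx + 1) * bin_size)
  rb <- parse_block("R", n)
  values <- matrix(0L, n, m,
                   dimnames = list(experiments$accession, paste(bins$chrom, bins$bin_index, sep = ":")))
  for (i in seq_len(n)) {
    bits <- as.integer(strsplit(rb[[i]][3], "")[[1]])
    if (length(bits) != m || anyNA(bits) || !all(bits %in% 0:1)) {
      stop_input("corrupt reference file: bad presence string",
                 class = "chipimpute_format_error")
    }
    values[match(rb[[i]][2], experiments$accession), ] <- bits
  }
  new_reference_matrix(hv[["target"]], experiments, bins, values,
                       bin_size, hv[["assembly"]])
}

#' Read bulk experiments from a metadata table
#'
#' The metadata table is TSV with columns `accession`, `target`, `biosample`,
#' `assembly`, `path` (BED file of peak calls, relative paths resolved
#' against the table's directory). Each BED file is binned with
#' [read_bed()].
#'
#' @param path Metadata TSV path.
#' @param bin_size Bin width in bp.
#' @param chrom_filter,chrom_sizes Passed to [read_bed()].
#' @param exclude_chroms Chromosomes dropped from every experiment (default
#'   none for reference construction; pass `c("chrX","chrY","chrM")` to match
#'   single-cell inputs that exclude them).
#' @return A tibble suitable for [build_reference()].
#' @export
read_experiments <- function(path, bin_size, chrom_filter = NULL,
                             chrom_sizes = NULL, exclude_chroms = NULL) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  required <- c("accession", "target", "biosample", "assembly", "path")
  if (!all(required %in% names(meta))) {
    stop_input(paste("metadata needs columns:", paste(required, collapse = ", ")))
  }
  base <- dirname(path)
  beds <- ifelse(grepl("^(/|[A-Za-z]:)", meta$path), meta$path,
                 file.path(base, meta$path))
  meta$bins <- purrr::map2(beds, meta$assembly, function(p, asm) {
    b <- read_bed(p, bin_size, chrom_filter = chrom_filter,
                  chrom_sizes = chrom_sizes, assembly = asm)
    if (!is.null(exclude_chroms)) {
      b <- bin_set(b[!(b$chrom %in% normalize_chrom(exclude_chroms)),
                     c("chrom", "bin_index")], bin_size, asm)
    }
    b
  })
  meta[, c("accession", "target", "biosample", "assembly", "bins")]
}
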