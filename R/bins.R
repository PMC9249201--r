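# Genomic bin model: fixed-size, non-overlapping windows tiling the genome.
# All coordinates are BED-style 0-based half-open; bin k on a chromosome
# covers [k * bin_size, (k + 1) * bin_size).

#' Construct a bin set
#'
#' A bin set is the package's representation of any binary genomic profile at
#' a fixed bin size: a single cell's observed bins, a binned bulk peak file,
#' or an imputed profile. It is a tibble with columns `chrom`, `bin_index`,
#' `start`, `end`, sorted by genome position and duplicate-free, carrying the
#' bin size and assembly label as attributes.
#'
#' @param bins A data frame with a `chrom` column and either `bin_index` or
#'   `start` (interpreted as an exact bin start; must be a multiple of
#'   `bin_size`).
#' @param bin_size Bin width in bp (positive integer).
#' @param assembly Genome assembly label (free text, default `"unknown"`).
#' @return A `bin_set` tibble.
#' @examples
#' bin_set(data.frame(chrom = "chr1", bin_index = c(2, 0)), bin_size = 5000)
#' @export
bin_set <- function(bins, bin_size, assembly = "unknown") {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || is.na(bin_size) || bin_size <= 0) {
    stop_input("`bin_size` must be a single positive number")
  }
  bin_size <- as.numeric(bin_size)
  bins <- as_tibble(bins)
  if (nrow(bins) == 0) {
    out <- tibble(chrom = character(), bin_index = numeric(),
                  start = numeric(), end = numeric())
    return(new_bin_set(out, bin_size, assembly))
  }
  if (!"chrom" %in% names(bins)) stop_input("bins need a `chrom` column")
  chrom <- normalize_chrom(bins$chrom)
  if ("bin_index" %in% names(bins)) {
    idx <- as.numeric(bins$bin_index)
  } else if ("start" %in% names(bins)) {
    start <- as.numeric(bins$start)
    if (any(start %% bin_size != 0)) {
      stop_input("`start` values must be multiples of `bin_size`; use peaks_to_bins() for arbitrary intervals")
    }
    idx <- start / bin_size
  } else {
    stop_input("bins need a `bin_index` or `start` column")
  }
  if (any(is.na(idx)) || any(idx < 0)) stop_input("bin indices must be nonnegative")
  out <- tibble(chrom = chrom, bin_index = idx,
                start = idx * bin_size, end = (idx + 1) * bin_size) |>
    distinct(.data$chrom, .data$bin_index, .keep_all = TRUE)
  out <- out[order(chrom_rank(out$chrom), out$bin_index), ]
  new_bin_set(out, bin_size, assembly)
}

new_bin_set <- function(df, bin_size, assembly) {
  structure(df,
            class = c("bin_set", class(tibble())),
            bin_size = as.numeric(bin_size),
            assembly = assembly)
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("# A bin set: %d bins of %s bp (%s)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              attr(x, "assembly")))
  NextMethod()
}

bin_size_of <- function(x) attr(x, "bin_size")
assembly_of <- function(x) attr(x, "assembly") %||% "unknown"

# Stable string key identifying a bin; used for set operations and column
# matching against the reference matrix.
bin_key <- function(x) paste(x$chrom, x$bin_index, sep = ":")

check_same_bin_size <- function(a, b) {
  if (!isTRUE(all.equal(bin_size_of(a), bin_size_of(b)))) {
    stop_input(sprintf("bin sizes differ (%s vs %s)",
                       bin_size_of(a), bin_size_of(b)),
               class = "chipimpute_bin_size_error")
  }
}

#' Map peak intervals to genomic bins
#'
#' A bin is marked present when at least one peak overlaps it by at least
#' 1 bp — the presence rule used to binarize bulk ChIP-seq peak calls.
#'
#' @param peaks A data frame with `chrom`, `start`, `end` (0-based half-open
#'   intervals, BED convention).
#' @param bin_size Bin width in bp.
#' @param chrom_filter Optional character vector; peaks on chromosomes outside
#'   this set are dropped.
#' @param chrom_sizes Optional named chromosome-length vector (see
#'   [read_chrom_sizes()]); peaks on chromosomes absent from it are dropped
#'   with a warning, and bins are truncated to the chromosome end.
#' @param assembly Assembly label stored on the result.
#' @return A [bin_set()].
#' @examples
#' peaks_to_bins(data.frame(chrom = "chr1", start = 4999, end = 5001), 5000)
#' @export
peaks_to_bins <- function(peaks, bin_size, chrom_filter = NULL,
                          chrom_sizes = NULL, assembly = "unknown") {
  peaks <- as_tibble(peaks)
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(peaks))) {
    stop_input("peaks need `chrom`, `start`, `end` columns")
  }
  if (nrow(peaks) == 0) {
    return(bin_set(tibble(chrom = character(), bin_index = numeric()),
                   bin_size, assembly))
  }
  start <- as.numeric(peaks$start); end <- as.numeric(peaks$end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0)) {
    stop_input("peak coordinates must be nonnegative numbers")
  }
  if (any(end <= start)) {
    stop_input("peaks must satisfy start < end (0-based half-open)",
               class = "chipimpute_interval_error")
  }
  chrom <- normalize_chrom(peaks$chrom)
  if (!is.null(chrom_filter)) {
    keep <- chrom %in% normalize_chrom(chrom_filter)
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  }
  if (!is.null(chrom_sizes)) {
    known <- chrom %in% names(chrom_sizes)
    if (any(!known)) {
      warn(sprintf("dropping %d peak(s) on chromosomes absent from chrom_sizes: %s",
                   sum(!known), paste(unique(chrom[!known]), collapse = ", ")))
      chrom <- chrom[known]; start <- start[known]; end <- end[known]
    }
  }
  if (length(chrom) == 0) {
    return(bin_set(tibble(chrom = character(), bin_index = numeric()),
                   bin_size, assembly))
  }
  first <- floor(start / bin_size)
  last <- floor((end - 1) / bin_size)  # end exclusive: last covered base is end - 1
  idx <- purrr::map2(first, last, seq)
  out <- tibble(chrom = rep(chrom, lengths(idx)), bin_index = unlist(idx))
  if (!is.null(chrom_sizes)) {
    maxidx <- ceiling(as.numeric(chrom_sizes[out$chrom]) / bin_size) - 1
    out <- out[out$bin_index <= maxidx, ]
  }
  bs <- bin_set(out, bin_size, assembly)
  if (!is.null(chrom_sizes)) {
    # last bin of a chromosome may be truncated to the chromosome length
    len <- as.numeric(chrom_sizes[bs$chrom])
    bs$end <- pmin(bs$end, len)
  }
  bs
}

#' Count genome-wide bins
#'
#' Number of fixed-size bins needed to tile every chromosome: the sum over
#' chromosomes of `ceiling(length / bin_size)`. At 5 kb this exceeds 600,000
#' for the human primary assembly, which is the size of the imputation search
#' space before restricting to a target-specific reference.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @return A single count.
#' @examples
#' count_genome_bins(c(chr1 = 10001), 5000)
#' @export
count_genome_bins <- function(chrom_sizes, bin_size) {
  if (length(chrom_sizes) == 0) stop_input("empty chromosome size table")
  if (!is.numeric(chrom_sizes) || any(chrom_sizes <= 0)) {
    stop_input("chromosome lengths must be positive numbers")
  }
  if (bin_size <= 0) stop_input("`bin_size` must be positive")
  sum(ceiling(as.numeric(chrom_sizes) / bin_size))
}

#' Read a chromosome-sizes table
#'
#' Two-column whitespace-separated text (`name length`), as distributed with
#' UCSC assemblies. Tables for the hg38 and mm10 primary chromosomes are
#' bundled with the package.
#'
#' @param path File path, or one of `"hg38"`, `"mm10"` for the bundled tables.
#' @return Named numeric vector of lengths, names normalized.
#' @examples
#' hg38 <- read_chrom_sizes("hg38")
#' count_genome_bins(hg38, 5000)
#' @export
read_chrom_sizes <- function(path) {
  if (path %in% c("hg38", "mm10")) {
    path <- system.file("extdata", paste0(path, ".chrom.sizes"),
                        package = "chipimpute", mustWork = TRUE)
  }
  df <- readr::read_table(path, col_names = c("chrom", "length"),
                          col_types = "cd", progress = FALSE)
  if (nrow(df) == 0) stop_input("empty chromosome size table")
  if (any(df$length <= 0)) stop_input("chromosome lengths must be positive")
  nm <- normalize_chrom(df$chrom)
  if (anyDuplicated(nm)) stop_input("duplicate chromosome names")
  setNames(df$length, nm)
}

#' Read a BED file as a bin set
#'
#' Reads BED3+ (tab-separated, 0-based half-open, no header) and maps each
#' region to the bins it overlaps. A region spanning a bin boundary therefore
#' contributes all bins it touches.
#'
#' @param path BED file path.
#' @inheritParams peaks_to_bins
#' @return A [bin_set()].
#' @export
read_bed <- function(path, bin_size, chrom_filter = NULL, chrom_sizes = NULL,
                     assembly = "unknown") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(bin_set(tibble(chrom = character(), bin_index = numeric()),
                   bin_size, assembly))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_input(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                       which(nf < 3)[1], path),
               class = "chipimpute_bed_error")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_input(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                       bad[1], path),
               class = "chipimpute_bed_error")
  }
  peaks_to_bins(tibble(chrom = chrom, start = start, end = end),
                bin_size = bin_size, chrom_filter = chrom_filter,
                chrom_sizes = chrom_sizes, assembly = assembly)
}

#' Write a bin set as BED3
#'
#' Tab-separated `chrom start end`, sorted by genome position. Reading the
#' file back with [read_bed()] at the same bin size reproduces the bin set.
#'
#' @param bins A [bin_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bins, path) {
  stopifnot(inherits(bins, "bin_set"))
  lines <- sprintf("%s\t%s\t%s", bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE))
  readr::write_lines(lines, path)
  invisible(path)
}

# Parse region labels of a binned count matrix: "chr1:0-5000" or
# "chr1_0_5000" (both in the wild for single-cell count matrices).
parse_region_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([^:_]+)[:_]([0-9]+)[-_]([0-9]+)$", labels))
  bad <- which(lengths(m) != 4)
  if (length(bad)) {
    stop_input(sprintf("unparseable region label: '%s'", labels[bad[1]]),
               class = "chipimpute_region_error")
  }
  tibble(chrom = normalize_chrom(vapply(m, `[[`, "", 2)),
         start = as.numeric(vapply(m, `[[`, "", 3)),
         end = as.numeric(vapply(m, `[[`, "", 4)))
}

#' Extract per-cell bin sets from a binned count matrix
#'
#' Single-cell ChIP-seq datasets are distributed as regions-by-cells count
#' matrices. Each cell's profile is binarized: a bin is present when its
#' count is positive. Sex chromosomes (and chrM) are excluded by default, the
#' convention for single-cell input; apply the same exclusion when building
#' the reference so feature spaces match.
#'
#' @param counts A data frame of nonnegative counts whose first column (or
#'   row names) holds region labels `chrom:start-end` or `chrom_start_end`;
#'   remaining columns are cells.
#' @param bin_size Bin width in bp.
#' @param exclude_chroms Chromosomes to drop (default chrX, chrY, chrM).
#' @param assembly Assembly label.
#' @return A named list of [bin_set()], one per cell column.
#' @export
matrix_to_cell_beds <- function(counts, bin_size,
                                exclude_chroms = c("chrX", "chrY", "chrM"),
                                assembly = "unknown") {
  counts <- as.data.frame(counts)
  if (ncol(counts) >= 1 && (is.character(counts[[1]]) || is.factor(counts[[1]]))) {
    labels <- as.character(counts[[1]])
    counts <- counts[, -1, drop = FALSE]
  } else if (!is.null(rownames(counts))) {
    labels <- rownames(counts)
  } else {
    stop_input("count matrix needs region labels in the first column or row names")
  }
  if (ncol(counts) == 0) stop_input("count matrix has no cell columns")
  regions <- parse_region_labels(labels)
  keep <- !(regions$chrom %in% normalize_chrom(exclude_chroms))
  regions <- regions[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  purrr::map(setNames(seq_along(counts), names(counts)), function(j) {
    present <- which(as.numeric(counts[[j]]) > 0)
    peaks_to_bins(regions[present, , drop = FALSE], bin_size,
                  assembly = assembly)
  })
}
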