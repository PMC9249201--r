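# Synthetic reference generator with planted, known structure. Experiments
# belong to cell types; each type owns a block of signature bins present
# with high probability in its own experiments and with background
# probability elsewhere; shared bins emulate housekeeping regions present
# everywhere; background bins are noise. Everything is seeded, so fixtures
# are reproducible and every downstream claim can be checked against the
# planted truth.

#' Describe a synthetic reference
#'
#' The default values define the package's standard benchmark: 3 cell types
#' with 10 experiments each over 1600 bins (300 signature bins per type,
#' 200 shared, 500 background) on one synthetic chromosome `chrS`, presence
#' probability 0.9 for a type's own signature (and shared) bins and 0.05
#' elsewhere, at 5 kb bins.
#'
#' @param n_cell_types Number of planted cell types.
#' @param experiments_per_type Experiments per cell type.
#' @param n_signature Signature bins per cell type.
#' @param n_shared Shared (housekeeping-like) bins.
#' @param n_background Background-noise bins.
#' @param p_signature Presence probability of a type's signature bins in that
#'   type's experiments (also of shared bins everywhere).
#' @param p_background Presence probability everywhere else.
#' @param bin_size Bin width in bp.
#' @param seed Generator seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cell_types = 3, experiments_per_type = 10,
                           n_signature = 300, n_shared = 200,
                           n_background = 500, p_signature = 0.9,
                           p_background = 0.05, bin_size = 5000, seed = 1L) {
  if (!(p_background >= 0 && p_background < p_signature && p_signature <= 1)) {
    stop_input("need 0 <= p_background < p_signature <= 1")
  }
  counts <- c(n_cell_types, experiments_per_type, n_signature, n_shared,
              n_background)
  if (any(counts < 0) || n_cell_types < 1 || experiments_per_type < 1) {
    stop_input("counts must be nonnegative (>= 1 type and experiment)")
  }
  structure(list(n_cell_types = n_cell_types,
                 experiments_per_type = experiments_per_type,
                 n_signature = n_signature, n_shared = n_shared,
                 n_background = n_background, p_signature = p_signature,
                 p_background = p_background, bin_size = bin_size,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic reference matrix with planted truth
#'
#' Entries are independent Bernoulli draws according to each bin's role
#' (see [synthetic_spec()]). Columns that come out all-zero are dropped so
#' the reference-column invariant (every bin present somewhere) holds; the
#' truth table records which planted bins survived.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `reference` (a `reference_matrix`), `truth` (list with
#'   `bins` — role and owning type per planted bin, plus `kept` — and
#'   `experiments` — accession and cell type), and `spec`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_cell_types; E <- spec$experiments_per_type
  total <- C * spec$n_signature + spec$n_shared + spec$n_background
  if (total < 1) stop_input("spec yields an empty bin universe")
  role <- c(rep(paste0("signature_type", seq_len(C)), each = spec$n_signature),
            rep("shared", spec$n_shared),
            rep("background", spec$n_background))
  owner <- c(rep(seq_len(C), each = spec$n_signature),
             rep(NA_integer_, spec$n_shared + spec$n_background))
  exp_type <- rep(seq_len(C), each = E)
  accession <- sprintf("SYN%02d", seq_len(C * E))
  # presence probability matrix (experiments x bins)
  p <- matrix(spec$p_background, C * E, total)
  for (t in seq_len(C)) {
    p[exp_type == t, which(!is.na(owner) & owner == t)] <- spec$p_signature
  }
  p[, role == "shared"] <- spec$p_signature
  values <- with_rng(spec$seed,
                     matrix(as.integer(stats::runif(length(p)) < p),
                            nrow(p), ncol(p)))
  kept <- colSums(values) > 0
  if (!any(kept)) stop_input("generated matrix is empty; raise presence probabilities")
  bins <- tibble(chrom = "chrS", bin_index = as.numeric(seq_len(total) - 1),
                 start = (seq_len(total) - 1) * spec$bin_size,
                 end = seq_len(total) * spec$bin_size)
  values <- values[, kept, drop = FALSE]
  dimnames(values) <- list(accession,
                           paste(bins$chrom[kept], bins$bin_index[kept], sep = ":"))
  experiments <- tibble(accession = accession, target = "SYNTARGET",
                        biosample = paste0("type", exp_type),
                        assembly = "synthetic")
  rs <- new_reference_matrix("SYNTARGET", experiments, bins[kept, ], values,
                             spec$bin_size, "synthetic")
  truth <- list(
    bins = dplyr::mutate(bins, role = role, cell_type = owner, kept = kept),
    experiments = tibble(accession = accession, cell_type = exp_type))
  list(reference = rs, truth = truth, spec = spec)
}

#' Generate a synthetic cell with its full origin profile
#'
#' The origin is either one synthetic experiment's row (default; carries the
#' generator's Bernoulli noise like a real bulk profile) or the clean
#' signature-plus-shared bin set of the cell type. The sparse cell is a
#' uniform subset of the origin.
#'
#' @param bundle Output of [generate_reference()].
#' @param cell_type Integer cell type (1-based).
#' @param s Sparse profile size in bins.
#' @param seed Integer seed for the down-sampling.
#' @param accession Origin experiment accession; default the type's first
#'   experiment. Ignored for `origin = "signature"`.
#' @param origin `"experiment"` (default) or `"signature"`.
#' @return A list: `sc` (sparse [bin_set()]), `origin` ([bin_set()]),
#'   `accession` (or `NA` for the clean origin).
#' @export
generate_cell <- function(bundle, cell_type, s, seed = 1L, accession = NULL,
                          origin = c("experiment", "signature")) {
  origin <- match.arg(origin)
  rs <- bundle$reference; truth <- bundle$truth
  if (!cell_type %in% truth$experiments$cell_type) {
    stop_input(sprintf("no such cell type: %s", cell_type))
  }
  if (origin == "experiment") {
    accession <- accession %||%
      truth$experiments$accession[truth$experiments$cell_type == cell_type][1]
    full <- row_profile(rs, accession)
  } else {
    accession <- NA_character_
    tb <- truth$bins
    own <- tb$kept & (tb$role == "shared" |
                      (!is.na(tb$cell_type) & tb$cell_type == cell_type))
    full <- bin_set(tb[own, c("chrom", "bin_index")], rs$bin_size, rs$assembly)
  }
  sc <- downsample_profile(full, s, seed)
  list(sc = sc, origin = full, accession = accession)
}

#' Plant an exactly co-occurring bin pair
#'
#' Copies one reference column onto another (optionally flipping entries
#' with probability `noise`), creating a candidate bin whose presence is
#' perfectly (or near-perfectly) predictable from one specific feature bin.
#' Ground truth for importance-ranking tests: when the query bin's model is
#' interpreted, the planted feature must dominate the importances.
#'
#' @param rs A `reference_matrix`.
#' @param query_bin,feature_bin Tibbles/lists with `chrom` and `bin_index`
#'   identifying reference columns.
#' @param noise Per-entry flip probability (default 0).
#' @param seed Seed for the noise flips.
#' @return The modified `reference_matrix`.
#' @export
plant_cooccurrence <- function(rs, query_bin, feature_bin, noise = 0,
                               seed = 1L) {
  stopifnot(inherits(rs, "reference_matrix"))
  keys <- bin_key(rs$bins)
  qi <- match(paste(normalize_chrom(query_bin$chrom), query_bin$bin_index, sep = ":"), keys)
  fi <- match(paste(normalize_chrom(feature_bin$chrom), feature_bin$bin_index, sep = ":"), keys)
  if (is.na(qi) || is.na(fi)) stop_input("bin not present in the reference matrix",
                                         class = "chipimpute_unknown_bin_error")
  col <- rs$values[, fi]
  if (noise > 0) {
    flip <- with_rng(seed, stats::runif(length(col)) < noise)
    col[flip] <- 1L - col[flip]
  }
  if (all(col == 0)) col[1] <- 1L  # preserve the column invariant
  rs$values[, qi] <- col
  rs
}

#' Synthetic gene annotation for the planted reference
#'
#' Places one gene TSS at the midpoint of every signature bin (symbols
#' `G<type>_<index>`, strand alternating), so the interpretation pathway is
#' exercisable end to end on synthetic data.
#'
#' @param bundle Output of [generate_reference()].
#' @return An annotation tibble (see [read_gene_annotation()]).
#' @export
synthetic_annotation <- function(bundle) {
  tb <- bundle$truth$bins
  sig <- tb[grepl("^signature", tb$role) & tb$kept, ]
  tibble(symbol = sprintf("G%d_%04d", sig$cell_type, sig$bin_index),
         chrom = sig$chrom,
         tss = (sig$start + sig$end) / 2,
         strand = rep_len(c("+", "-"), nrow(sig)))
}

#' The default synthetic benchmark
#'
#' Generates the documented default reference ([synthetic_spec()] with seed
#' 1) and, when `dir` is given, writes the complete fixture bundle to disk:
#' one BED file per synthetic experiment, the experiment metadata TSV, the
#' serialized reference, and the planted truth as JSON. Regenerating with
#' the same spec reproduces byte-identical files.
#'
#' @param dir Optional output directory (created if missing).
#' @param spec A [synthetic_spec()]; default the documented benchmark spec.
#' @return The [generate_reference()] bundle, with `files` added when `dir`
#'   was given.
#' @export
default_benchmark <- function(dir = NULL, spec = synthetic_spec()) {
  bundle <- generate_reference(spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rs <- bundle$reference
    bed_paths <- file.path(dir, paste0(rs$experiments$accession, ".bed"))
    for (i in seq_len(nrow(rs$experiments))) {
      write_bed(row_profile(rs, rs$experiments$accession[i]), bed_paths[i])
    }
    meta_path <- file.path(dir, "experiments.tsv")
    readr::write_tsv(
      dplyr::mutate(rs$experiments, path = basename(bed_paths)),
      meta_path, progress = FALSE)
    ref_path <- file.path(dir, "reference.txt")
    write_reference(rs, ref_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(spec = unclass(spec),
           bins = bundle$truth$bins,
           experiments = bundle$truth$experiments),
      truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$files <- c(metadata = meta_path, reference = ref_path,
                      truth = truth_path)
  }
  bundle
}
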