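# Internal helpers shared across modules.

# Deterministic RNG scope: all base-R sampling in the package goes through
# this so a caller's RNG state is never touched.
with_rng <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Per-bin seed derivation: imputation results must not depend on the order in
# which candidate bins are evaluated, so every candidate model gets a seed
# that is a pure function of (master seed, bin identity). Kept < 2^31 - 1.
derive_seed <- function(master, chrom, bin_index) {
  h <- 0
  for (ch in utf8ToInt(as.character(chrom))) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 %% 2147483647
  s <- (s + h * 69621) %% 2147483647
  s <- (s + (as.numeric(bin_index) %% 2147483647) * 16807) %% 2147483647
  as.integer(s %% 2147483646 + 1)
}

stop_input <- function(msg, class = "chipimpute_input_error", ...) {
  abort(msg, class = class, ...)
}

# Chromosome sort rank: chr1..chr22 numerically, then chrX, chrY, chrM, then
# anything else alphabetically. Gives a deterministic genome-position order
# without requiring a chrom-sizes table.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
          ifelse(core == "X", 1e6 + 1,
          ifelse(core == "Y", 1e6 + 2,
          ifelse(core %in% c("M", "MT"), 1e6 + 3, NA))))
  other <- is.na(rank)
  if (any(other)) {
    lv <- sort(unique(core[other]))
    rank[other] <- 2e6 + match(core[other], lv)
  }
  rank
}

#' Normalize chromosome names
#'
#' Accepts both UCSC-style (`chr1`) and Ensembl-style (`1`, `MT`) names and
#' returns the `chr`-prefixed form used throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_chrom(c("1", "chr2", "MT", "X"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  bad <- is.na(chrom) | chrom == ""
  if (any(bad)) stop_input("empty chromosome name")
  core <- sub("^chr", "", chrom)
  core[core == "MT"] <- "M"
  paste0("chr", core)
}
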