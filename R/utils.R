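#' @import data.table
#' @importFrom stats p.adjust rmultinom rnorm runif t.test wilcox.test
#'   fisher.test rlnorm setNames median quantile sd
#' @importFrom utils read.table write.table packageVersion
NULL

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Count-weighted mode; ties broken toward the smallest value.
weighted_mode <- function(values, weights = rep(1, length(values))) {
  if (length(values) == 0L) return(NA_real_)
  tab <- tapply(weights, values, sum)
  keys <- as.numeric(names(tab))
  keys[order(-tab, keys)][1L]
}

# Derive a stage sub-seed from the top-level seed, kept inside 32-bit range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 100 + k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Strand-aware slice in transcription orientation. `five0` is the 0-based
# genomic coordinate of the mature 5' base; the returned string covers
# [5' - upstream, 5' + downstream - 1] in the sense direction of `strand`.
# Returns NA if the slice runs off the chromosome.
extract_sense <- function(genome, chrom, five0, strand, upstream, downstream) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop_fmt("unknown chromosome '%s'", chrom)
  len <- nchar(seq)
  if (strand == "+") {
    from <- five0 - upstream
    to <- five0 + downstream - 1L
    if (from < 0L || to >= len) return(NA_character_)
    substr(seq, from + 1L, to + 1L)
  } else {
    from <- five0 - downstream + 1L
    to <- five0 + upstream
    if (from < 0L || to >= len) return(NA_character_)
    revcomp(substr(seq, from + 1L, to + 1L))
  }
}

# Vectorised over loci rows; returns NA where the slice is out of bounds.
extract_sense_many <- function(genome, loci, upstream, downstream) {
  vapply(seq_len(nrow(loci)), function(i) {
    extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                  upstream, downstream)
  }, character(1))
}
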