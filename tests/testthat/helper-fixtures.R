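# Shared fixtures and independent oracles for the test suite.

# Small simulation for unit tests: 1/10 of the default locus counts and a
# 40 kb cluster chromosome, so brute-force oracles stay cheap.
tiny_config <- function(seed = 11L) {
  sim_config(seed = seed, chrom_len = 40000L, n_motif_loci = 30L,
             n_nonmotif_loci = 10L, library_depth = 20000L,
             n_target_genes = 15L)
}

# Default-condition simulation, built once per test run.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- generate_genome(sim_config(seed = 7L))
  .sim_cache$sim
}
tiny_sim <- function() {
  if (is.null(.sim_cache$tiny))
    .sim_cache$tiny <- generate_genome(tiny_config())
  .sim_cache$tiny
}

# Plain-R reverse complement, independent of the package's Biostrings path.
rc_oracle <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# Brute-force read-to-locus assignment: test every read against every locus
# by direct string comparison over the genome, with no indexing.
brute_assign <- function(library, genome, loci) {
  rows <- list()
  for (r in seq_len(nrow(library$reads))) {
    seq <- library$reads$sequence[r]
    len <- nchar(seq)
    matched <- FALSE
    for (i in seq_len(nrow(loci))) {
      chrom <- genome[[loci$chrom[i]]]
      five0 <- loci$start[i]
      ml <- loci$mature_length[i]
      for (ext5 in 0:10) {
        if (ext5 + 1L > len) next            # must cover the 5' U
        if (loci$strand[i] == "+") {
          from <- five0 - ext5
          if (from < 0L || from + len > nchar(chrom)) next
          gseq <- substr(chrom, from + 1L, from + len)
        } else {
          to <- five0 + ext5
          if (to - len + 1L < 0L || to >= nchar(chrom)) next
          gseq <- rc_oracle(substr(chrom, to - len + 2L, to + 1L))
        }
        # read must lie inside the locus window (<= mature + 20 downstream)
        if (len - ext5 > ml + 20L) next
        if (identical(gseq, seq)) {
          call <- if (ext5 > 10L || len > 45L) "other_locus_overlap"
                  else if (ext5 == 0L && len == ml) "mature"
                  else if (len > ml) "precursor_candidate"
                  else "other_locus_overlap"
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = seq, locus_id = loci$locus_id[i],
            five_prime_ext = ext5, species_call = call,
            stringsAsFactors = FALSE)
          matched <- TRUE
          break  # smallest ext5 for this locus
        }
      }
    }
    if (!matched)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq, locus_id = NA_character_, five_prime_ext = NA_integer_,
        species_call = "unassigned", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Exhaustive all-window target enumeration oracle.
brute_targets <- function(pirna, transcript, max_mm = 3L) {
  site <- rc_oracle(pirna)
  k <- nchar(site)
  n <- nchar(transcript)
  if (k > n) return(data.frame(position = integer(0), mismatches = integer(0)))
  sv <- strsplit(site, "")[[1L]]
  tv <- strsplit(transcript, "")[[1L]]
  hits <- lapply(seq_len(n - k + 1L), function(p) {
    mm <- sum(tv[p:(p + k - 1L)] != sv)
    if (mm <= max_mm) data.frame(position = p, mismatches = mm) else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(position = integer(0), mismatches = integer(0))
  else out
}

# Random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Build a single-locus genome with a given upstream context; the mature
# 21-mer begins with T at 0-based position `five0`.
plant_locus <- function(five0 = 100L, strand = "+", upstream_core = NULL,
                        core_offset = 40L, chrom_len = 300L, seed = 1L) {
  set.seed(seed)
  ch <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  put <- function(up_from, up_to, bases) {
    if (strand == "+") ch[(five0 - up_from):(five0 - up_to) + 1L] <<- bases
    else ch[(five0 + up_from):(five0 + up_to) + 1L] <<- chartr("ACGT", "TGCA", bases)
  }
  put(0L, 0L, "T")
  if (!is.null(upstream_core))
    put(core_offset + 7L, core_offset, strsplit(upstream_core, "")[[1L]])
  genome <- c(chrI = paste(ch, collapse = ""))
  loci <- data.frame(locus_id = "L1", chrom = "chrI", start = five0,
                     strand = strand, mature_length = 21L,
                     stringsAsFactors = FALSE)
  loci$mature_seq <- pirnaforge:::extract_sense(genome, "chrI", five0, strand, 0L, 21L)
  loci$motif_score <- NA_real_
  loci$class_label <- "unscored"
  list(genome = genome, loci = loci)
}
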