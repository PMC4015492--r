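# Assignment window around a locus: 10 nt upstream of the mature 5' base to
# 20 nt past the mature 3' end, in sense orientation. A read is assigned iff
# it matches this window exactly, covers the mature 5' base, and starts at or
# upstream of it (5' extension >= 0).
WINDOW_UP <- 10L
WINDOW_DOWN_EXTRA <- 20L
MAX_EXT5 <- 10L
MAX_READ_LEN <- 45L

locus_windows <- function(genome, loci) {
  vapply(seq_len(nrow(loci)), function(i) {
    w <- extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                       WINDOW_UP, loci$mature_length[i] + WINDOW_DOWN_EXTRA)
    if (is.na(w)) {  # truncate at chromosome ends
      up <- WINDOW_UP; down <- loci$mature_length[i] + WINDOW_DOWN_EXTRA
      len <- nchar(genome[[loci$chrom[i]]])
      if (loci$strand[i] == "+") {
        up <- min(up, loci$start[i])
        down <- min(down, len - loci$start[i])
      } else {
        up <- min(up, len - loci$start[i] - 1L)
        down <- min(down, loci$start[i] + 1L)
      }
      w <- extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                         up, down)
      attr(w, "up") <- up
      return(paste0(strrep("N", WINDOW_UP - up), w))  # pad so 5' U is at index up+1
    }
    w
  }, character(1))
}

#' Assign library reads to piRNA loci by exact match
#'
#' A read is assigned to a locus when it matches the genome exactly on the
#' locus strand within a locus-anchored window, covers the mature 5' base,
#' and begins at or upstream of it. Species calls: `mature` (no 5'
#' extension, read length equals the mature length), `precursor_candidate`
#' (read longer than the mature length, hence 5'- and/or 3'-extended),
#' `other_locus_overlap` (covers the 5' base but is shorter than mature, or
#' exceeds the extension guards). Reads matching no locus are `unassigned`.
#' Reads matching several loci get one row per locus with `multi = TRUE`;
#' exactly one row per read is marked `primary` (smallest 5' extension, then
#' lexicographic locus id) so that global profiles count each read once.
#'
#' @param library An `srna_library`.
#' @param genome Named character vector of chromosome sequences.
#' @param loci Loci data.frame.
#' @return data.frame with one row per (read, locus) pair plus one row per
#'   unassigned read: `sequence`, `count`, `locus_id`, `five_prime_ext`,
#'   `three_prime_ext`, `read_length`, `species_call`, `multi`, `primary`.
#' @export
assign_reads <- function(library, genome, loci) {
  reads <- library$reads
  wins <- locus_windows(genome, loci)
  hasN <- grepl("N", wins, fixed = TRUE) & !startsWith(wins, "N")
  if (any(hasN))
    warn_fmt("%d locus window(s) overlap N bases; exact matching there will fail",
             sum(hasN))

  # enumerate all admissible window substrings: start q (0-based) in
  # 0..WINDOW_UP, lengths 15..min(window), read must cover the 5' U
  idx_list <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    wlen <- nchar(wins[i])
    max_len <- wlen            # longest read the window can hold
    q <- rep(0:WINDOW_UP, each = max_len - 15L + 1L)
    len <- rep(15:max_len, times = WINDOW_UP + 1L)
    ok <- q + len <= wlen & q + len > WINDOW_UP
    q <- q[ok]; len <- len[ok]
    if (!length(q)) next
    key <- substring(wins[i], q + 1L, q + len)
    keep <- !grepl("N", key, fixed = TRUE)
    idx_list[[i]] <- data.table::data.table(
      seqkey = key[keep], locus_i = i, ext5 = WINDOW_UP - q[keep])
  }
  index <- data.table::rbindlist(idx_list)

  rd <- data.table::data.table(seqkey = reads$sequence, count = reads$count,
                               read_length = nchar(reads$sequence))
  hits <- if (nrow(index)) index[rd, on = "seqkey", allow.cartesian = TRUE]
          else data.table::data.table(seqkey = rd$seqkey, locus_i = NA_integer_,
                                      ext5 = NA_integer_, count = rd$count,
                                      read_length = rd$read_length)
  data.table::setnames(hits, "seqkey", "sequence")
  # a read matching one locus window at several positions counts once for
  # that locus, at the smallest 5' extension
  data.table::setorder(hits, sequence, ext5, na.last = TRUE)
  hits <- hits[!duplicated(paste(hits$sequence, hits$locus_i)), ]

  out <- data.frame(
    sequence = hits$sequence,
    count = hits$count,
    locus_id = ifelse(is.na(hits$locus_i), NA_character_,
                      loci$locus_id[hits$locus_i]),
    five_prime_ext = hits$ext5,
    read_length = hits$read_length,
    stringsAsFactors = FALSE
  )
  ml <- ifelse(is.na(hits$locus_i), NA_integer_,
               loci$mature_length[hits$locus_i])
  out$three_prime_ext <- out$read_length - ml - out$five_prime_ext
  out$species_call <- ifelse(
    is.na(out$locus_id), "unassigned",
    ifelse(out$five_prime_ext > MAX_EXT5 | out$read_length > MAX_READ_LEN,
           "other_locus_overlap",
    ifelse(out$five_prime_ext == 0L & out$read_length == ml, "mature",
    ifelse(out$read_length > ml, "precursor_candidate", "other_locus_overlap"))))

  # multiplicity and primary flags
  nmatch <- stats::ave(as.integer(!is.na(out$locus_id)), out$sequence, FUN = sum)
  out$multi <- !is.na(out$locus_id) & nmatch > 1L
  ord <- order(out$sequence, out$five_prime_ext, out$locus_id,
               method = "radix")
  first <- !duplicated(out$sequence[ord])
  out$primary <- FALSE
  out$primary[ord[first]] <- TRUE
  attr(out, "total_count") <- library$total_count
  attr(out, "sample_id") <- library$sample_id
  attr(out, "genotype") <- library$genotype
  attr(out, "protocol") <- library$protocol
  out
}

#' Count-weighted 5'-extension and length profiles
#'
#' Builds histograms of the 5' extension and read length over the primary
#' alignment rows whose species call is in `species`, weighted by read
#' count, alongside unique-sequence counts. Modal values break ties toward
#' the smaller value.
#'
#' @param alignments Output of [assign_reads()] (one library).
#' @param species Species calls to keep (default
#'   `c("mature", "precursor_candidate")`).
#' @return An `extension_profile`: list with `ext` and `length` data.frames
#'   (`value`, `reads`, `sequences`), `modal_ext`, `modal_length`,
#'   `n_reads`, and the library labels.
#' @export
extension_profile <- function(alignments,
                              species = c("mature", "precursor_candidate")) {
  keep <- alignments$primary & alignments$species_call %in% species
  a <- alignments[keep, , drop = FALSE]
  histo <- function(v, w) {
    if (!length(v)) return(data.frame(value = integer(0), reads = numeric(0),
                                      sequences = integer(0)))
    reads <- tapply(w, v, sum)
    seqs <- tapply(w, v, length)
    data.frame(value = as.integer(names(reads)), reads = as.numeric(reads),
               sequences = as.integer(seqs))
  }
  structure(list(
    ext = histo(a$five_prime_ext, a$count),
    length = histo(a$read_length, a$count),
    modal_ext = weighted_mode(a$five_prime_ext, a$count),
    modal_length = weighted_mode(a$read_length, a$count),
    n_reads = sum(a$count),
    species = species,
    sample_id = attr(alignments, "sample_id"),
    genotype = attr(alignments, "genotype"),
    protocol = attr(alignments, "protocol")
  ), class = "extension_profile")
}

#' @export
print.extension_profile <- function(x, ...) {
  cat(sprintf("extension_profile %s (%s/%s): %s reads; modal ext %s nt, modal length %s nt\n",
              x$sample_id %||% "?", x$genotype %||% "?", x$protocol %||% "?",
              format(x$n_reads, big.mark = ","), x$modal_ext, x$modal_length))
  invisible(x)
}

#' Compare mature/precursor composition across cloning protocols
#'
#' Summarises, per protocol, the mature and precursor-candidate read
#' fractions (of the total library) and the modal assigned read length, and
#' checks the qualitative protocol contract: cap-selected (capRNA)
#' libraries should be depleted of mature 21-mers, untreated
#' (5'-monophosphate-dependent) libraries should lack precursors, and
#' cap-removed (TAP) libraries should contain both.
#'
#' @param alignments_by_protocol Named list (names = protocols) of
#'   [assign_reads()] outputs over the same locus set.
#' @return data.frame with one row per protocol: `protocol`,
#'   `mature_fraction`, `precursor_fraction`, `modal_length`, `modal_ext`,
#'   `contract_ok`. A warning is raised when a protocol violates its
#'   expectation.
#' @export
compare_protocols <- function(alignments_by_protocol) {
  rows <- lapply(names(alignments_by_protocol), function(pr) {
    a <- alignments_by_protocol[[pr]]
    total <- attr(a, "total_count")
    p <- a$primary
    mat <- sum(a$count[p & a$species_call == "mature"])
    pre <- sum(a$count[p & a$species_call == "precursor_candidate"])
    prof <- extension_profile(a)
    data.frame(protocol = pr,
               mature_fraction = mat / total,
               precursor_fraction = pre / total,
               modal_length = prof$modal_length,
               modal_ext = prof$modal_ext,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$contract_ok <- TRUE
  for (i in seq_len(nrow(out))) {
    pr <- out$protocol[i]
    ok <- switch(pr,
      capRNA = out$mature_fraction[i] < 0.05 && out$precursor_fraction[i] > 0,
      untreated = out$precursor_fraction[i] < 0.05,
      TAP = out$mature_fraction[i] > 0 && out$precursor_fraction[i] > 0,
      TRUE)
    out$contract_ok[i] <- ok
    if (!ok) warn_fmt("protocol contract violated for '%s'", pr)
  }
  out
}

#' Per-locus mature and precursor counts
#'
#' Counts, per locus, the reads called mature and precursor-candidate.
#' Multi-locus reads contribute to every matching locus and are flagged by
#' the `any_multi` column (global profiles use primary rows only; see
#' [assign_reads()]).
#'
#' @param alignments Output of [assign_reads()].
#' @return data.frame `locus_id`, `mature_count`, `precursor_count`,
#'   `any_multi`.
#' @export
per_locus_counts <- function(alignments) {
  a <- alignments[!is.na(alignments$locus_id), , drop = FALSE]
  ids <- sort(unique(a$locus_id))
  agg <- function(sp) {
    x <- a[a$species_call == sp, , drop = FALSE]
    v <- tapply(x$count, x$locus_id, sum)
    out <- setNames(rep(0, length(ids)), ids)
    out[names(v)] <- v
    out
  }
  mult <- tapply(a$multi, a$locus_id, any)
  data.frame(locus_id = ids,
             mature_count = as.numeric(agg("mature")),
             precursor_count = as.numeric(agg("precursor_candidate")),
             any_multi = as.logical(mult[ids]),
             stringsAsFactors = FALSE)
}
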