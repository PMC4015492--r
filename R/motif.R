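#' Build a position weight matrix from aligned core sequences
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' Scores derived from the PWM are log2-odds against the background, so a
#' uniform background and pseudocount 0 give the consensus of a degenerate
#' alignment a score of `width * 2` bits.
#'
#' @param upstream_cores Character vector of equal-length training strings
#'   (the motif cores extracted upstream of high-confidence loci).
#' @param pseudocount Added per cell; 0 is allowed only if every column
#'   contains all four bases.
#' @param background Named probabilities for A, C, G, T (default uniform).
#' @return A `pwm` object: list with `width`, `probs` (4 x width matrix,
#'   rows A,C,G,T), `background`, `pseudocount`.
#' @export
build_pwm <- function(upstream_cores, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(upstream_cores) == 0L) stop_fmt("no training sequences")
  width <- nchar(upstream_cores[1L])
  if (any(nchar(upstream_cores) != width))
    stop_fmt("training strings must all have length %d", width)
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  if (abs(sum(background) - 1) > 1e-9) stop_fmt("background must sum to 1")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(upstream_cores, "")), nrow = length(upstream_cores),
                byrow = TRUE)
  counts <- vapply(seq_len(width), function(j)
    vapply(bases, function(b) sum(mat[, j] == b), numeric(1)), numeric(4))
  probs <- (counts + pseudocount) / (length(upstream_cores) + 4 * pseudocount)
  if (any(probs == 0))
    stop_fmt("zero probability with pseudocount 0; supply a pseudocount")
  rownames(probs) <- bases
  structure(list(width = width, probs = probs,
                 background = background[bases], pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, pseudocount %g, consensus %s\n", x$width,
              x$pseudocount,
              paste(rownames(x$probs)[apply(x$probs, 2, which.max)],
                    collapse = "")))
  invisible(x)
}

# log2-odds score of every `width`-window of `s` (a sense-oriented string);
# returns numeric vector over start positions 1..(nchar(s)-width+1)
pwm_scan <- function(pwm, s) {
  n <- nchar(s) - pwm$width + 1L
  if (n < 1L) return(numeric(0))
  lo <- log2(pwm$probs / pwm$background)
  ch <- strsplit(s, "")[[1L]]
  idx <- match(ch, rownames(lo))          # NA for N
  vapply(seq_len(n), function(p) {
    cols <- idx[p:(p + pwm$width - 1L)]
    if (anyNA(cols)) return(-Inf)
    sum(lo[cbind(cols, seq_len(pwm$width))])
  }, numeric(1))
}

#' Score the upstream region of one locus against a PWM
#'
#' The strand-aware upstream region of the locus is scanned over a window of
#' offsets, where the offset is the distance (bp) from the motif core's 3'
#' end to the mature 5' base. The best (maximal) log2-odds placement is
#' reported; ties break toward offset 40, then toward the smaller offset.
#' Loci too close to a chromosome end are scored over the available part of
#' the window with a warning; if no placement fits, an error is raised.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param locus One row of a loci data.frame.
#' @param pwm A [build_pwm()] object.
#' @param window Integer range of offsets to search (default 30:50).
#' @return List (`motif_score`) with `score` (bits), `offset` (bp) and
#'   `window`.
#' @export
score_locus <- function(genome, locus, pwm, window = 30:50) {
  offs <- sort(window)
  max_up <- max(offs) + pwm$width - 1L
  up <- extract_sense(genome, locus$chrom, locus$start, locus$strand,
                      max_up, 0L)
  truncated <- FALSE
  while (is.na(up) && length(offs) > 1L) {
    truncated <- TRUE
    offs <- offs[-length(offs)]
    max_up <- max(offs) + pwm$width - 1L
    up <- extract_sense(genome, locus$chrom, locus$start, locus$strand,
                        max_up, 0L)
  }
  if (is.na(up))
    stop_fmt("locus %s: upstream window entirely outside chromosome",
             locus$locus_id %||% "?")
  if (truncated)
    warn_fmt("locus %s: upstream window truncated at chromosome end; searching offsets %d..%d",
             locus$locus_id %||% "?", min(offs), max(offs))
  # `up` ends at the base immediately 5' of the mature 5' U; a core whose
  # 3' end lies `o` bp upstream starts at string index length(up) - o - width + 2
  scores <- pwm_scan(pwm, up)
  starts <- nchar(up) - offs - pwm$width + 2L
  ok <- starts >= 1L
  offs <- offs[ok]; starts <- starts[ok]
  sc <- scores[starts]
  best <- max(sc)
  cand <- offs[sc >= best - 1e-12]
  offset <- if (40L %in% cand) 40L else min(cand)
  structure(list(score = best, offset = offset,
                 window = c(min(window), max(window))),
            class = "motif_score")
}

#' Score every locus and attach class labels
#'
#' Convenience wrapper: runs [score_locus()] over a loci table and
#' classifies at the cutoff.
#'
#' @inheritParams score_locus
#' @param loci Loci data.frame.
#' @param cutoff Classification cutoff in bits (strictly greater =>
#'   motif-dependent).
#' @return The loci data.frame with `motif_score`, `motif_offset` and
#'   `class_label` filled in.
#' @export
score_loci <- function(genome, loci, pwm, window = 30:50, cutoff = 7) {
  ms <- lapply(seq_len(nrow(loci)), function(i)
    score_locus(genome, loci[i, ], pwm, window))
  loci$motif_score <- vapply(ms, `[[`, numeric(1), "score")
  loci$motif_offset <- vapply(ms, `[[`, numeric(1), "offset")
  loci$class_label <- vapply(loci$motif_score, classify_locus, character(1),
                             cutoff = cutoff)
  loci
}

#' Classify a locus from its motif score
#'
#' Scores strictly greater than the cutoff are `motif_dependent`; everything
#' else (including the cutoff itself) is `motif_independent`.
#'
#' @param score Motif score in bits (or a `motif_score` object).
#' @param cutoff Cutoff in bits (default 7).
#' @return `"motif_dependent"` or `"motif_independent"`.
#' @export
classify_locus <- function(score, cutoff = 7) {
  if (inherits(score, "motif_score")) score <- score$score
  if (!is.finite(score)) stop_fmt("motif score must be finite")
  if (score > cutoff) "motif_dependent" else "motif_independent"
}

#' Histogram of motif scores in fixed-width windows
#'
#' Bins scores into windows of width `binwidth` and reports each bin by its
#' midpoint, as in score-distribution plots (counts are intended to be of
#' unique sequences; pass one score per unique sequence).
#'
#' @param scores Numeric scores (one per unique sequence).
#' @param binwidth Window width (default 5 bits).
#' @return data.frame with `midpoint` and `count`; empty input gives an
#'   empty histogram.
#' @export
score_histogram <- function(scores, binwidth = 5) {
  if (binwidth <= 0) stop_fmt("binwidth must be positive")
  if (length(scores) == 0L)
    return(data.frame(midpoint = numeric(0), count = integer(0)))
  bin <- floor(scores / binwidth)
  tab <- table(bin)
  data.frame(midpoint = (as.numeric(names(tab)) + 0.5) * binwidth,
             count = as.integer(tab))
}

#' Modes of a score histogram
#'
#' Local maxima of the binned counts (strictly greater than the left
#' neighbour and at least the right neighbour, over occupied bins padded
#' with zeros), used to summarise bimodality of a score distribution.
#'
#' @param hist data.frame from [score_histogram()].
#' @return Numeric vector of midpoints that are local maxima.
#' @export
histogram_modes <- function(hist) {
  if (nrow(hist) == 0L) return(numeric(0))
  # place counts on a full grid so gaps count as zeros
  bw <- if (nrow(hist) > 1L) min(diff(sort(hist$midpoint))) else 1
  grid <- seq(min(hist$midpoint), max(hist$midpoint), by = bw)
  counts <- rep(0L, length(grid))
  counts[match(floor(hist$midpoint / bw + 1e-9), floor(grid / bw + 1e-9))] <- hist$count
  n <- length(counts)
  left <- c(-1, counts[-n]); right <- c(counts[-1], -1)
  grid[counts > left & counts >= right & counts > 0]
}

#' Train a core PWM from motif-aligned upstream regions
#'
#' Emulates building a scoring matrix from the upstream regions of
#' high-confidence piRNA loci: each locus's upstream search window is
#' scanned for the placement closest to a seed consensus (the Ruby core
#' `CTGTTTCA` by default); loci within `max_seed_mm` mismatches contribute
#' their aligned core to the training alignment. Loci without a credible
#' core instance are left out, so the matrix is weighted by the motif-bearing
#' subset only.
#'
#' @param genome Named character vector.
#' @param loci Loci data.frame.
#' @param seed_core Consensus used to align training instances.
#' @param window Offset range searched (core 3' end to mature 5' base).
#' @param max_seed_mm Maximum mismatches to the seed for a training instance.
#' @param pseudocount Passed to [build_pwm()].
#' @return A `pwm`; the number of training loci is in attribute `n_train`.
#' @export
train_pwm <- function(genome, loci, seed_core = "CTGTTTCA", window = 30:50,
                      max_seed_mm = 1L, pseudocount = 1) {
  width <- nchar(seed_core)
  sv <- strsplit(seed_core, "")[[1L]]
  offs <- sort(window)
  cores <- character(0)
  for (i in seq_len(nrow(loci))) {
    up <- extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                        max(offs) + width - 1L, 0L)
    if (is.na(up)) next
    best_mm <- width + 1L; best_off <- NA_integer_; best_core <- NA_character_
    for (o in offs) {
      st <- nchar(up) - o - width + 2L
      core <- substr(up, st, st + width - 1L)
      mm <- sum(strsplit(core, "")[[1L]] != sv)
      closer <- mm < best_mm ||
        (mm == best_mm && abs(o - 40L) < abs(best_off - 40L))
      if (closer) { best_mm <- mm; best_off <- o; best_core <- core }
    }
    if (best_mm <= max_seed_mm) cores <- c(cores, best_core)
  }
  if (length(cores) < 10L)
    stop_fmt("only %d credible core instances; cannot train", length(cores))
  pwm <- build_pwm(cores, pseudocount = pseudocount)
  attr(pwm, "n_train") <- length(cores)
  pwm
}

#' Extract upstream core sequences for PWM training
#'
#' Pulls the `width`-long sequence whose 3' end sits `offset` bp upstream of
#' each locus's mature 5' base, strand-aware.
#'
#' @param genome Named character vector.
#' @param loci Loci data.frame.
#' @param offset Core 3'-end offset (default 40).
#' @param width Core width (default 8).
#' @return Character vector of cores (NA where out of bounds).
#' @export
extract_upstream_cores <- function(genome, loci, offset = 40L, width = 8L) {
  vapply(seq_len(nrow(loci)), function(i) {
    up <- extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                        offset + width - 1L, 0L)
    if (is.na(up)) return(NA_character_)
    substr(up, 1L, width)
  }, character(1))
}
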