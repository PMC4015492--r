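#' Find piRNA target sites by mismatch-bounded antisense complementarity
#'
#' Slides the reverse complement of a piRNA along each transcript and
#' reports every ungapped window within the mismatch budget (plain Hamming
#' distance over the full piRNA length; no G:U wobble).
#'
#' @param pirna_seq Named character vector of piRNA sequences (U may be
#'   written as T).
#' @param transcripts Named character vector of transcript sequences.
#' @param max_mm Maximum mismatches (default 3).
#' @return data.frame of hits: `pirna_id`, `gene_id`, `position` (1-based
#'   start of the site on the transcript), `mismatches`, `orientation`.
#' @export
find_targets <- function(pirna_seq, transcripts, max_mm = 3L) {
  pirna_seq <- toupper(chartr("U", "T", pirna_seq))
  if (is.null(names(pirna_seq)))
    names(pirna_seq) <- paste0("pirna-", seq_along(pirna_seq))
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("tx-", seq_along(transcripts))
  tx_set <- Biostrings::DNAStringSet(toupper(transcripts))
  rows <- list()
  for (p in names(pirna_seq)) {
    pat <- Biostrings::DNAString(revcomp(pirna_seq[[p]]))
    for (g in names(transcripts)) {
      if (length(pat) > nchar(transcripts[[g]])) next
      m <- Biostrings::matchPattern(pat, tx_set[[g]], max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m)
      mm <- vapply(st, function(s)
        Biostrings::neditStartingAt(pat, tx_set[[g]], starting.at = s),
        integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        pirna_id = p, gene_id = g, position = st, mismatches = mm,
        orientation = "antisense", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pirna_id = character(0), gene_id = character(0),
                      position = integer(0), mismatches = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Quantify antisense 22G-RNAs per gene
#'
#' Counts library reads of length 20-23 nt with a 5' G that match the
#' genome exactly in antisense orientation within a gene body (i.e. the
#' read's reverse complement occurs in the gene's sense sequence), and
#' normalizes to reads per million of total library size. Sense-matching
#' reads are not counted. A strict 22-nt-only definition is available.
#'
#' @param library An `srna_library`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param genome Named character vector.
#' @param lengths Admissible read lengths (default 20:23; set `22L` for the
#'   strict definition).
#' @return data.frame `gene_id`, `count`, `rpm`.
#' @export
antisense_22g <- function(library, genes, genome, lengths = 20:23) {
  if (!all(genes$strand %in% c("+", "-")))
    stop_fmt("gene annotation must be stranded")
  reads <- library$reads
  len <- nchar(reads$sequence)
  cand <- reads[len %in% lengths & startsWith(reads$sequence, "G"), ,
                drop = FALSE]
  gene_seq <- vapply(seq_len(nrow(genes)), function(g) {
    s <- substr(genome[[genes$chrom[g]]], genes$start[g] + 1L, genes$end[g])
    if (genes$strand[g] == "-") revcomp(s) else s
  }, character(1))
  rc <- if (nrow(cand)) revcomp(cand$sequence) else character(0)
  counts <- vapply(gene_seq, function(s)
    if (length(rc)) sum(cand$count[vapply(rc, function(r)
      grepl(r, s, fixed = TRUE), logical(1))]) else 0, numeric(1))
  data.frame(gene_id = genes$gene_id, count = unname(counts),
             rpm = unname(counts) / library$total_count * 1e6,
             stringsAsFactors = FALSE)
}

#' Per-position antisense 22G start profile for one gene
#'
#' Positions are 5'-end start coordinates of antisense reads on the
#' transcript (1-based, transcript orientation), RPM-normalized.
#'
#' @inheritParams antisense_22g
#' @param gene_id Gene to profile.
#' @return data.frame `position`, `rpm`.
#' @export
antisense_22g_profile <- function(library, genes, genome, gene_id,
                                  lengths = 20:23) {
  g <- which(genes$gene_id == gene_id)
  if (length(g) != 1L) stop_fmt("unknown gene '%s'", gene_id)
  s <- substr(genome[[genes$chrom[g]]], genes$start[g] + 1L, genes$end[g])
  if (genes$strand[g] == "-") s <- revcomp(s)
  reads <- library$reads
  len <- nchar(reads$sequence)
  cand <- reads[len %in% lengths & startsWith(reads$sequence, "G"), ,
                drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    site <- gregexpr(revcomp(cand$sequence[i]), s, fixed = TRUE)[[1L]]
    if (site[1L] == -1L) next
    # antisense read 5' end corresponds to the 3' end of the sense window
    pos <- site + nchar(cand$sequence[i]) - 1L
    rows[[length(rows) + 1L]] <- data.frame(position = pos,
                                            count = cand$count[i])
  }
  if (!length(rows)) return(data.frame(position = integer(0), rpm = numeric(0)))
  d <- do.call(rbind, rows)
  agg <- tapply(d$count, d$position, sum)
  data.frame(position = as.integer(names(agg)),
             rpm = as.numeric(agg) / library$total_count * 1e6)
}

#' Differential-expression gene sets across mutant genotypes
#'
#' For every mutant genotype versus wild type computes the mean log2 fold
#' change, a Welch two-sample t-test p-value, and Benjamini-Hochberg
#' q-values across genes. A gene passes a contrast iff its log2 fold change
#' strictly exceeds `log2(fold)`, `p < alpha` and `q < mt_alpha`. Genes are
#' then partitioned: `shared` (pass in prg1 and every prde1 allele),
#' `prg1_only` (prg1 but no prde1 allele), `prde1_only` (some prde1 allele
#' but not prg1).
#'
#' @param expr An `expression_matrix` (log2 values) with a `wild_type`
#'   genotype and at least two replicates per genotype.
#' @param fold Fold-change gate (default 4; strict `>`).
#' @param alpha Per-contrast p-value gate (default 0.05).
#' @param mt_alpha BH q-value gate (default 0.1).
#' @param pooled_var Use the pooled-variance (Student) t-test instead of
#'   Welch.
#' @return List of class `de_gene_sets`: `shared`, `prg1_only`,
#'   `prde1_only` (character vectors), `stats` (long data.frame of
#'   per-gene per-contrast `log2fc`, `p`, `q`, `pass`) and `thresholds`.
#' @export
de_gene_sets <- function(expr, fold = 4, alpha = 0.05, mt_alpha = 0.1,
                         pooled_var = FALSE) {
  gts <- expr$samples$genotype
  if (!"wild_type" %in% gts) stop_fmt("no wild_type samples")
  contrasts <- setdiff(unique(gts), "wild_type")
  if (any(table(gts) < 2L)) stop_fmt("need >= 2 replicates per genotype")
  wt <- expr$values[, gts == "wild_type", drop = FALSE]
  stats_list <- lapply(contrasts, function(ct) {
    mu <- expr$values[, gts == ct, drop = FALSE]
    lfc <- rowMeans(mu) - rowMeans(wt)
    p <- vapply(seq_len(nrow(mu)), function(i)
      t.test(mu[i, ], wt[i, ], var.equal = pooled_var)$p.value, numeric(1))
    q <- p.adjust(p, method = "BH")
    data.frame(gene_id = expr$genes, contrast = ct, log2fc = lfc, p = p,
               q = q,
               pass = lfc > log2(fold) & p < alpha & q < mt_alpha,
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, stats_list)
  pass_mat <- do.call(cbind, lapply(stats_list, `[[`, "pass"))
  colnames(pass_mat) <- contrasts
  prde_cols <- grep("^prde1", contrasts, value = TRUE)
  prg_col <- grep("^prg1", contrasts, value = TRUE)
  pass_prg <- if (length(prg_col)) rowSums(pass_mat[, prg_col, drop = FALSE]) > 0 else rep(FALSE, nrow(pass_mat))
  pass_all_prde <- if (length(prde_cols)) rowSums(pass_mat[, prde_cols, drop = FALSE]) == length(prde_cols) else rep(FALSE, nrow(pass_mat))
  pass_any_prde <- if (length(prde_cols)) rowSums(pass_mat[, prde_cols, drop = FALSE]) > 0 else rep(FALSE, nrow(pass_mat))
  genes <- expr$genes
  structure(list(
    shared = genes[pass_prg & pass_all_prde],
    prg1_only = genes[pass_prg & !pass_any_prde],
    prde1_only = genes[!pass_prg & pass_any_prde],
    stats = stats,
    thresholds = list(fold = fold, alpha = alpha, mt_alpha = mt_alpha,
                      test = if (pooled_var) "student" else "welch")),
    class = "de_gene_sets")
}

#' @export
print.de_gene_sets <- function(x, ...) {
  cat(sprintf("de_gene_sets (> %g-fold, p < %g, q < %g): shared %d, prg1_only %d, prde1_only %d\n",
              x$thresholds$fold, x$thresholds$alpha, x$thresholds$mt_alpha,
              length(x$shared), length(x$prg1_only), length(x$prde1_only)))
  invisible(x)
}

#' Fisher's exact test for set enrichment
#'
#' Two-sided exact test on the 2x2 table of hits inside/outside a gene set.
#'
#' @param hits_in_set Genes in the set with the property.
#' @param set_size Size of the set.
#' @param hits_in_universe Genes in the universe with the property
#'   (including the set).
#' @param universe_size Size of the universe (including the set).
#' @return List with `odds_ratio` (sample odds ratio; `NA` for zero-margin
#'   tables), `p`, and the `table`.
#' @export
fisher_enrichment <- function(hits_in_set, set_size, hits_in_universe,
                              universe_size) {
  if (hits_in_set > set_size || hits_in_universe > universe_size ||
      set_size > universe_size || hits_in_set > hits_in_universe)
    stop_fmt("inconsistent counts")
  a <- hits_in_set
  b <- set_size - hits_in_set
  c <- hits_in_universe - hits_in_set
  d <- (universe_size - set_size) - c
  tab <- matrix(c(a, b, c, d), 2L, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"), c("hit", "no_hit")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  p <- fisher.test(tab)$p.value
  # after the margin check this is never 0/0
  or <- (a * d) / (b * c)
  list(odds_ratio = or, p = p, table = tab)
}

#' Permutation test for gene-set score enrichment
#'
#' The statistic is the mean score of set members; the null distribution is
#' built from random same-size gene sets drawn without replacement. The
#' p-value uses the add-one estimator `(1 + #{null >= observed}) /
#' (n_perm + 1)`.
#'
#' @param gene_stat Named numeric vector of per-gene scores.
#' @param gene_set Character vector of gene ids (subset of the names).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed for the permutation stream.
#' @return List with `observed`, `p`, `n_perm`.
#' @export
permutation_set_test <- function(gene_stat, gene_set, n_perm = 1000L,
                                 seed = 1L) {
  if (n_perm < 100L) stop_fmt("n_perm must be >= 100")
  if (!all(gene_set %in% names(gene_stat)))
    stop_fmt("gene_set contains genes without scores")
  k <- length(gene_set)
  if (k > length(gene_stat)) stop_fmt("set larger than universe")
  obs <- mean(gene_stat[gene_set])
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mean(gene_stat[sample.int(length(gene_stat), k)]), numeric(1))
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Two-sided Mann-Whitney comparison of two score sets
#'
#' Unpaired two-sided Wilcoxon rank-sum test with tie correction (exact
#' when sample sizes permit and there are no ties).
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @return List with `statistic` (U for the first sample), `p_value`.
#' @export
rank_set_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop_fmt("empty input")
  if (length(unique(c(values_a, values_b))) == 1L) {
    warn_fmt("all values tied; p = 1")
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1))
  }
  res <- suppressWarnings(wilcox.test(values_a, values_b,
                                      alternative = "two.sided"))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
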