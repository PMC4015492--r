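#' Simulation configuration
#'
#' Defaults encode the structural facts the pipeline is built around:
#' a Ruby-motif core `CTGTTTCA` ending ~40 bp upstream of the mature 5' U
#' with an A/T-rich spacer, capped precursors beginning 2 nt upstream of
#' the mature 5' U with lengths peaking at 28-29 nt, and genotype effects
#' (prg-1: mature piRNAs lost, precursors kept; prde-1: motif-dependent
#' mature piRNAs and precursors lost, motif-independent retained with a
#' slight increase).
#'
#' @param seed Top-level seed; all stage randomness derives from it.
#' @param n_chrom Number of chromosomes (first carries the piRNA cluster,
#'   second the protein-coding genes used for 22G/DE analysis).
#' @param chrom_len Chromosome length in nt.
#' @param n_motif_loci,n_nonmotif_loci Counts of motif-dependent and
#'   motif-independent piRNA loci.
#' @param motif_offset_mean Modal distance (bp) from the motif core 3' end to
#'   the mature 5' U.
#' @param motif_offset_jitter Half-width of the offset jitter (bp); offsets
#'   are drawn from `mean +/- jitter` with the mode at `mean`.
#' @param spacer_at_fraction Probability that a spacer base is A or T.
#' @param precursor_ext5 5' extension of precursors relative to the mature
#'   5' U (nt, fixed at 2).
#' @param precursor_lengths,precursor_length_weights Support and weights of
#'   the precursor total-length distribution (mode shared between 28 and 29).
#' @param precursor_ratio Expected precursor:mature abundance ratio in
#'   cap-containing protocols.
#' @param library_depth Total reads per simulated library.
#' @param background_fraction Expected fraction of degradation background
#'   reads (random genomic slices, 15-35 nt).
#' @param genotype_effects Named list of per-class abundance multipliers;
#'   see defaults.
#' @param n_target_genes Number of genes placed for the 22G/expression stage,
#'   split equally between shared targets, prg-1-only targets and untargeted.
#' @param gene_length Gene body length (nt).
#' @param n_reps Expression replicates per genotype.
#' @param expr_effect Log2 up-regulation of de-silenced targets.
#' @param expr_sd Gaussian noise s.d. of log2 expression.
#' @param g22_shared_multiplier 22G multiplier applied to shared targets in
#'   both mutants and to prg-1-only targets in prg-1.
#' @param target_site_fraction,offtarget_site_fraction Fraction of target /
#'   untargeted genes carrying a planted antisense piRNA site (<=3 mismatches).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 7L,
                       n_chrom = 2L,
                       chrom_len = 200000L,
                       n_motif_loci = 300L,
                       n_nonmotif_loci = 60L,
                       motif_offset_mean = 40L,
                       motif_offset_jitter = 2L,
                       spacer_at_fraction = 0.75,
                       precursor_ext5 = 2L,
                       precursor_lengths = 26:36,
                       precursor_length_weights =
                         c(8, 12, 24, 24, 12, 7, 5, 3, 2, 1.5, 0.5),
                       precursor_ratio = 0.15,
                       library_depth = 200000L,
                       background_fraction = 0.05,
                       genotype_effects = list(
                         wild_type = c(mature_dep = 1, mature_indep = 1,
                                       prec_dep = 1, prec_indep = 1),
                         prg1 = c(mature_dep = 0, mature_indep = 0,
                                  prec_dep = 1, prec_indep = 1),
                         prde1 = c(mature_dep = 0, mature_indep = 1.25,
                                   prec_dep = 0, prec_indep = 1)),
                       n_target_genes = 60L,
                       gene_length = 1000L,
                       n_reps = 5L,
                       expr_effect = 2.5,
                       expr_sd = 0.4,
                       g22_shared_multiplier = 0.1,
                       target_site_fraction = 0.7,
                       offtarget_site_fraction = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$library_depth > 0, cfg$background_fraction >= 0,
            cfg$background_fraction <= 1, cfg$spacer_at_fraction >= 0,
            cfg$spacer_at_fraction <= 1,
            all(unlist(cfg$genotype_effects) >= 0),
            length(cfg$precursor_lengths) == length(cfg$precursor_length_weights))
  structure(cfg, class = "sim_config")
}

RUBY_CORE <- "CTGTTTCA"

offset_probs <- function(cfg) {
  # mode at motif_offset_mean, symmetric falloff over +/- jitter
  j <- cfg$motif_offset_jitter
  offs <- (cfg$motif_offset_mean - j):(cfg$motif_offset_mean + j)
  w <- c(0.05, 0.15, 0.60, 0.15, 0.05)
  if (j != 2L) w <- stats::dnorm(offs, cfg$motif_offset_mean, max(j / 2, 0.5))
  list(offsets = offs, probs = w / sum(w))
}

rand_bases <- function(n, at_fraction = 0.5) {
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic genome with piRNA loci and target genes
#'
#' Places non-overlapping piRNA loci on the first ("cluster") chromosome:
#' motif-dependent loci get the `CTGTTTCA` core planted with its 3' end at a
#' jittered offset upstream of the mature 5' U and an A/T-rich spacer in
#' between; motif-independent loci are guaranteed free of the core within
#' 60 bp upstream. All mature 5' bases are forced to T (5' U on the RNA).
#' Genes for the 22G/expression stage are placed on the second chromosome,
#' and a subset carries a planted antisense piRNA site with 0-3 mismatches.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `loci` (unscored
#'   locus data.frame as from [read_loci()]) and `truth` (list of `loci`
#'   with true classes/offsets/abundances, `genes` with intervals and true
#'   regulatory classes, and the config).
#' @export
generate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(substream_seed(cfg$seed, 1L))
  chrom_names <- paste0("chr", c("IVlike", "IIlike", as.roman(seq_len(max(0, cfg$n_chrom - 2L)) + 4L)))[seq_len(cfg$n_chrom)]
  chars <- lapply(seq_len(cfg$n_chrom), function(i)
    sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE))
  names(chars) <- chrom_names

  n_loci <- cfg$n_motif_loci + cfg$n_nonmotif_loci
  slot <- 150L
  margin <- 70L  # room for upstream window + mature + precursor tail
  n_slots <- (cfg$chrom_len - 2L * margin) %/% slot
  if (n_slots < n_loci)
    stop_fmt("genome too short for %d loci (have %d slots)", n_loci, n_slots)
  anchors <- margin + slot * (sort(sample(n_slots, n_loci)) - 1L) + margin
  strand <- sample(c("+", "-"), n_loci, replace = TRUE)
  is_motif <- c(rep(TRUE, cfg$n_motif_loci), rep(FALSE, cfg$n_nonmotif_loci))
  is_motif <- sample(is_motif)
  op <- offset_probs(cfg)
  offsets <- ifelse(is_motif,
                    sample(op$offsets, n_loci, replace = TRUE, prob = op$probs),
                    NA_integer_)
  cluster <- chars[[1L]]

  for (i in seq_len(n_loci)) {
    five0 <- anchors[i]
    st <- strand[i]
    put <- function(up_from, up_to, bases) {
      # write sense bases (5'->3') at sense positions [5'-up_from .. 5'-up_to]
      # (upstream distances from the mature 5' base)
      if (st == "+") {
        g <- (five0 - up_from):(five0 - up_to) + 1L
        cluster[g] <<- bases
      } else {
        # genomic coordinates run opposite to sense order on '-'
        g <- (five0 + up_from):(five0 + up_to) + 1L
        cluster[g] <<- chartr("ACGT", "TGCA", bases)
      }
    }
    # mature body: 5' U plus 20 downstream bases already random; force T at 5'
    put(0L, 0L, "T")
    if (is_motif[i]) {
      o <- offsets[i]
      put(o + 7L, o, strsplit(RUBY_CORE, "")[[1L]])
      if (o > 1L)
        put(o - 1L, 1L, rand_bases(o - 1L, cfg$spacer_at_fraction))
    } else {
      # scrub the 60-bp upstream window of any core occurrence
      repeat {
        up <- if (st == "+") cluster[(five0 - 67L):(five0 - 1L) + 1L]
              else rev(chartr("ACGT", "TGCA", cluster[(five0 + 1L):(five0 + 67L) + 1L]))
        if (!grepl(RUBY_CORE, paste(up, collapse = ""), fixed = TRUE)) break
        put(67L, 1L, rand_bases(67L))
      }
    }
  }
  chars[[1L]] <- cluster
  genome_pre <- vapply(chars, paste, character(1), collapse = "")

  loci <- data.frame(
    locus_id = sprintf("21ur-%04d", seq_len(n_loci)),
    chrom = chrom_names[1L],
    start = anchors,
    strand = strand,
    mature_length = 21L,
    stringsAsFactors = FALSE
  )
  loci$mature_seq <- extract_sense_many(as.list(genome_pre), loci, 0L, 21L)
  loci$motif_score <- NA_real_
  loci$class_label <- "unscored"

  # target genes on the second chromosome
  genes <- NULL
  if (cfg$n_chrom >= 2L && cfg$n_target_genes > 0L) {
    per <- cfg$n_target_genes %/% 3L
    classes <- c(rep("shared_target", per), rep("prg1_only_target", per),
                 rep("untargeted", cfg$n_target_genes - 2L * per))
    classes <- sample(classes)
    pitch <- cfg$gene_length + 500L
    if (cfg$n_target_genes * pitch + 1000L > cfg$chrom_len)
      stop_fmt("chromosome too short for %d genes", cfg$n_target_genes)
    gstart <- 500L + pitch * (seq_len(cfg$n_target_genes) - 1L)
    gstrand <- sample(c("+", "-"), cfg$n_target_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("gene-%03d", seq_len(cfg$n_target_genes)),
      chrom = chrom_names[2L],
      start = gstart, end = gstart + cfg$gene_length,
      strand = gstrand, class = classes, stringsAsFactors = FALSE)
    # plant antisense piRNA sites (reverse complement of a mature 21-mer with
    # 0-3 substitutions) into a fraction of gene bodies
    gchars <- strsplit(genome_pre[[2L]], "")[[1L]]
    site_frac <- ifelse(classes == "untargeted", cfg$offtarget_site_fraction,
                        cfg$target_site_fraction)
    has_site <- runif(cfg$n_target_genes) < site_frac
    motif_ids <- which(is_motif)
    for (g in which(has_site)) {
      pir <- loci$mature_seq[sample(motif_ids, 1L)]
      site <- strsplit(revcomp(pir), "")[[1L]]
      n_mm <- sample(0:3, 1L)
      if (n_mm > 0L) {
        at <- sample(21L, n_mm)
        site[at] <- vapply(site[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
      pos <- genes$start[g] + sample(cfg$gene_length - 21L, 1L)
      sl <- (pos + 1L):(pos + 21L)
      gchars[sl] <- if (genes$strand[g] == "+") site
                    else rev(chartr("ACGT", "TGCA", site))
      has_site[g] <- TRUE
    }
    genes$planted_site <- has_site
    genome_pre[[2L]] <- paste(gchars, collapse = "")
  }

  # per-locus baseline abundances are part of the truth: they make locus
  # abundances paired across genotype libraries
  abundance <- rlnorm(n_loci, meanlog = 0, sdlog = 1)

  truth_loci <- data.frame(
    locus_id = loci$locus_id,
    true_class = ifelse(is_motif, "motif_dependent", "motif_independent"),
    true_offset = offsets,
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  list(genome = genome_pre, loci = loci,
       truth = list(loci = truth_loci, genes = genes, config = cfg))
}

#' Simulate a collapsed small-RNA library for one genotype and protocol
#'
#' Mature reads are exact 21-mer locus sequences; precursor reads start
#' `precursor_ext5` nt upstream of the mature 5' U with total length drawn
#' from the precursor length distribution (same strand); background reads
#' are random genomic slices of 15-35 nt. Expected class abundances are
#' scaled by the genotype effects, then the protocol filter is applied:
#' `untreated` excludes capped species (precursors), `TAP` includes both,
#' `capRNA` keeps only capped species. Counts are multinomial at the
#' requested depth.
#'
#' @param sim Result of [generate_genome()].
#' @param genotype `wild_type`, `prg1` or `prde1`.
#' @param protocol `untreated`, `TAP` or `capRNA`.
#' @param depth Total read count (default from config).
#' @param seed Seed for this library (default derived from config seed).
#' @param sample_id Sample identifier.
#' @return List with `library` (an `srna_library`) and `origins`, a
#'   data.frame recording per-species truth: `origin` (`locus_id`,
#'   `background`), `species` (`mature`/`precursor`/`background`),
#'   `sequence`, `count`, `capped`.
#' @export
generate_library <- function(sim, genotype, protocol,
                             depth = sim$truth$config$library_depth,
                             seed = NULL,
                             sample_id = paste(genotype, protocol, sep = "_")) {
  cfg <- sim$truth$config
  genotype <- match.arg(genotype, c("wild_type", "prg1", "prde1"))
  protocol <- match.arg(protocol, c("untreated", "TAP", "capRNA"))
  if (depth <= 0L) stop_fmt("depth must be positive")
  if (is.null(seed))
    seed <- substream_seed(cfg$seed,
                           10L + match(genotype, c("wild_type", "prg1", "prde1")) * 3L +
                             match(protocol, c("untreated", "TAP", "capRNA")))
  set.seed(seed)

  loci <- sim$loci
  tr <- sim$truth$loci
  eff <- cfg$genotype_effects[[genotype]]
  dep <- tr$true_class == "motif_dependent"

  # mature species
  mat <- data.frame(origin = loci$locus_id, species = "mature",
                    sequence = loci$mature_seq,
                    weight = tr$abundance *
                      ifelse(dep, eff[["mature_dep"]], eff[["mature_indep"]]),
                    capped = FALSE, stringsAsFactors = FALSE)

  # precursor species: one per locus x length
  lens <- cfg$precursor_lengths
  lw <- cfg$precursor_length_weights / sum(cfg$precursor_length_weights)
  n_loci <- nrow(loci)
  pre_idx <- rep(seq_len(n_loci), each = length(lens))
  pre_len <- rep(lens, times = n_loci)
  e5 <- cfg$precursor_ext5
  chrom_seq <- sim$genome[loci$chrom[pre_idx]]
  five0 <- loci$start[pre_idx]
  plus <- loci$strand[pre_idx] == "+"
  pre_seq <- character(length(pre_idx))
  pre_seq[plus] <- substring(chrom_seq[plus], five0[plus] - e5 + 1L,
                             five0[plus] + (pre_len[plus] - e5))
  pre_seq[!plus] <- revcomp(substring(chrom_seq[!plus],
                                      five0[!plus] - (pre_len[!plus] - e5) + 2L,
                                      five0[!plus] + e5 + 1L))
  pre <- data.frame(origin = loci$locus_id[pre_idx], species = "precursor",
                    sequence = pre_seq,
                    weight = tr$abundance[pre_idx] * cfg$precursor_ratio *
                      rep(lw, times = n_loci) *
                      ifelse(dep[pre_idx], eff[["prec_dep"]], eff[["prec_indep"]]),
                    capped = TRUE, stringsAsFactors = FALSE)

  pool <- rbind(mat, pre)
  pool <- switch(protocol,
                 untreated = pool[!pool$capped, , drop = FALSE],
                 TAP = pool,
                 capRNA = pool[pool$capped, , drop = FALSE])
  pool <- pool[pool$weight > 0 & !is.na(pool$sequence), , drop = FALSE]

  # degradation background: random genomic slices, 15-35 nt, either strand
  n_bg <- 2000L
  bg_len <- sample(15:35, n_bg, replace = TRUE)
  bg_chrom <- sample(names(sim$genome), n_bg, replace = TRUE)
  bg_pos <- vapply(bg_chrom, function(ch)
    sample(nchar(sim$genome[[ch]]) - 40L, 1L), numeric(1))
  bg_seq <- substring(sim$genome[bg_chrom], bg_pos, bg_pos + bg_len - 1L)
  bg_rc <- runif(n_bg) < 0.5
  bg_seq[bg_rc] <- revcomp(bg_seq[bg_rc])
  bg <- data.frame(origin = "background", species = "background",
                   sequence = unname(bg_seq),
                   weight = NA_real_, capped = FALSE, stringsAsFactors = FALSE)

  sig_w <- pool$weight / sum(pool$weight) * (1 - cfg$background_fraction)
  bg_w <- rep(cfg$background_fraction / n_bg, n_bg)
  all_sp <- rbind(pool, bg)
  probs <- c(sig_w, bg_w)
  counts <- as.vector(rmultinom(1L, size = depth, prob = probs))
  keep <- counts > 0L
  origins <- data.frame(all_sp[keep, c("origin", "species", "sequence", "capped")],
                        count = counts[keep], stringsAsFactors = FALSE)
  lib <- srna_library(
    data.frame(sequence = origins$sequence, count = origins$count,
               stringsAsFactors = FALSE),
    sample_id = sample_id, genotype = genotype, protocol = protocol)
  list(library = lib, origins = origins, seed = seed)
}

#' Simulate 22G-RNA libraries and a matched expression matrix
#'
#' 22G reads are 22-nt slices antisense to gene bodies with a 5' G (start
#' positions are chosen so the genomic context yields a G at the read 5'
#' end, so every read matches the genome exactly). Per-gene 22G abundance
#' is reduced (default x0.1) in both mutants for shared targets and in
#' prg-1 only for prg-1-only targets. Log2 expression is up-shifted
#' (default +2.5) in exactly the genotypes where a gene's 22G-RNAs are
#' lost; untargeted genes stay flat.
#'
#' @param sim Result of [generate_genome()].
#' @param genotypes Genotypes to simulate (wild_type must be included).
#' @param n_reps Expression replicates per genotype.
#' @param depth 22G library depth per genotype.
#' @param seed Seed (default derived from config seed).
#' @return List with `g22_libraries` (named list of `srna_library`),
#'   `g22_origins` (per-genotype truth tables), and `expression`
#'   (an `expression_matrix`).
#' @export
generate_22g_and_expression <- function(sim,
                                        genotypes = c("wild_type", "prg1", "prde1"),
                                        n_reps = sim$truth$config$n_reps,
                                        depth = sim$truth$config$library_depth,
                                        seed = substream_seed(sim$truth$config$seed, 30L)) {
  cfg <- sim$truth$config
  genes <- sim$truth$genes
  if (is.null(genes)) stop_fmt("simulation has no target genes")
  if (n_reps < 2L) stop_fmt("n_reps must be >= 2")
  stopifnot("wild_type" %in% genotypes)
  set.seed(seed)

  # candidate antisense 22G start positions per gene (5' G guaranteed)
  gene_seq <- vapply(seq_len(nrow(genes)), function(g) {
    s <- substr(sim$genome[[genes$chrom[g]]], genes$start[g] + 1L, genes$end[g])
    if (genes$strand[g] == "-") revcomp(s) else s
  }, character(1))
  glen <- nchar(gene_seq[1L])
  cand <- lapply(gene_seq, function(s) {
    ch <- strsplit(s, "")[[1L]]
    t <- which(ch == "C")              # S[t] == C => antisense read 5' base G
    t <- t[t >= 22L & t <= glen]       # read covers S[t-21..t]
    t
  })
  n_sites <- pmin(lengths(cand), 30L)
  sites <- lapply(seq_along(cand), function(g)
    sort(cand[[g]][sample.int(length(cand[[g]]), n_sites[g])]))
  base_ab <- rlnorm(nrow(genes), 0, 0.7) *
    ifelse(genes$class == "prg1_only_target", 0.6, 1)

  multiplier <- function(class, genotype) {
    m <- cfg$g22_shared_multiplier
    switch(class,
           shared_target = if (genotype %in% c("prg1", "prde1")) m else 1,
           prg1_only_target = if (genotype == "prg1") m else 1,
           untargeted = 1)
  }

  g22_libraries <- list()
  g22_origins <- list()
  for (gt in genotypes) {
    sp_gene <- rep(seq_len(nrow(genes)), times = n_sites)
    sp_pos <- unlist(sites)
    sp_seq <- revcomp(substring(gene_seq[sp_gene], sp_pos - 21L, sp_pos))
    site_w <- unlist(lapply(seq_len(nrow(genes)), function(g)
      if (n_sites[g] > 0L) rep(1 / n_sites[g], n_sites[g]) else numeric(0)))
    w <- base_ab[sp_gene] * site_w *
      vapply(sp_gene, function(g) multiplier(genes$class[g], gt), numeric(1))
    probs <- w / sum(w)
    counts <- as.vector(rmultinom(1L, depth, probs))
    keep <- counts > 0L
    origins <- data.frame(origin = paste0("22G:", genes$gene_id[sp_gene[keep]]),
                          species = "22G", sequence = sp_seq[keep],
                          count = counts[keep], stringsAsFactors = FALSE)
    g22_origins[[gt]] <- origins
    g22_libraries[[gt]] <- srna_library(
      data.frame(sequence = origins$sequence, count = origins$count,
                 stringsAsFactors = FALSE),
      sample_id = paste0("g22_", gt), genotype = gt, protocol = "untreated")
  }

  # expression matrix: baseline per gene, up-shift where 22Gs are lost
  baseline <- rnorm(nrow(genes), 6, 1)
  samp_gt <- rep(genotypes, each = n_reps)
  vals <- matrix(NA_real_, nrow(genes), length(samp_gt))
  for (j in seq_along(samp_gt)) {
    up <- vapply(genes$class, function(cl)
      multiplier(cl, samp_gt[j]) < 1, logical(1))
    vals[, j] <- baseline + ifelse(up, cfg$expr_effect, 0) +
      rnorm(nrow(genes), 0, cfg$expr_sd)
  }
  rownames(vals) <- genes$gene_id
  colnames(vals) <- paste0(samp_gt, "_r", rep(seq_len(n_reps), length(genotypes)))
  expr <- expression_matrix(vals, samp_gt)

  list(g22_libraries = g22_libraries, g22_origins = g22_origins,
       expression = expr)
}
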