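test_that("generation is byte-identical under the same seed", {
  a <- generate_genome(tiny_config(seed = 21L))
  b <- generate_genome(tiny_config(seed = 21L))
  expect_identical(a$genome, b$genome)
  expect_identical(a$loci, b$loci)
  expect_identical(a$truth, b$truth)
  la <- generate_library(a, "wild_type", "TAP")
  lb <- generate_library(b, "wild_type", "TAP")
  expect_identical(la$library$reads, lb$library$reads)
  expect_identical(la$origins, lb$origins)
})

test_that("motif-dependent loci carry the core upstream; independent loci do not", {
  sim <- tiny_sim()
  tr <- sim$truth$loci
  upstream <- vapply(seq_len(nrow(sim$loci)), function(i)
    pirnaforge:::extract_sense(sim$genome, sim$loci$chrom[i],
                               sim$loci$start[i], sim$loci$strand[i], 60L, 0L),
    character(1))
  dep <- tr$true_class == "motif_dependent"
  expect_true(all(grepl("CTGTTTCA", upstream[dep], fixed = TRUE)))
  expect_false(any(grepl("CTGTTTCA", upstream[!dep], fixed = TRUE)))
  # all mature sequences start with the 5' U
  expect_true(all(startsWith(sim$loci$mature_seq, "T")))
})

test_that("spacer composition matches the configured A/T fraction", {
  sim <- default_sim()
  cfg <- sim$truth$config
  tr <- sim$truth$loci
  dep <- which(tr$true_class == "motif_dependent")
  spacers <- vapply(dep, function(i) {
    o <- tr$true_offset[i]
    up <- pirnaforge:::extract_sense(sim$genome, sim$loci$chrom[i],
                                     sim$loci$start[i], sim$loci$strand[i],
                                     o - 1L, 0L)
    up
  }, character(1))
  bases <- strsplit(paste(spacers, collapse = ""), "")[[1L]]
  n <- length(bases)
  p_hat <- mean(bases %in% c("A", "T"))
  se <- sqrt(cfg$spacer_at_fraction * (1 - cfg$spacer_at_fraction) / n)
  expect_lt(abs(p_hat - cfg$spacer_at_fraction), 3 * se)
})

test_that("every emitted read has exactly one origin and counts are conserved", {
  sim <- tiny_sim()
  for (combo in list(c("wild_type", "TAP"), c("prg1", "untreated"),
                     c("prde1", "capRNA"))) {
    l <- generate_library(sim, combo[1], combo[2])
    expect_equal(sum(l$origins$count), l$library$total_count)
    # origins account for every library sequence
    expect_setequal(unique(l$origins$sequence), l$library$reads$sequence)
  }
})

test_that("genotype effects silence the right species", {
  sim <- tiny_sim()
  tr <- sim$truth$loci
  dep_ids <- tr$locus_id[tr$true_class == "motif_dependent"]
  indep_ids <- tr$locus_id[tr$true_class == "motif_independent"]

  # prg-1: no mature reads of either class, precursors still present
  prg_unt <- generate_library(sim, "prg1", "untreated")
  expect_identical(sum(prg_unt$origins$species == "mature"), 0L)
  prg_tap <- generate_library(sim, "prg1", "TAP")
  wt_tap <- generate_library(sim, "wild_type", "TAP")
  prec <- function(l, ids) sum(l$origins$count[l$origins$species == "precursor" &
                                                 l$origins$origin %in% ids])
  expect_gt(prec(prg_tap, dep_ids), 0.5 * prec(wt_tap, dep_ids))

  # prde-1: motif-dependent mature and precursors gone, independent retained
  prde_tap <- generate_library(sim, "prde1", "TAP")
  expect_equal(prec(prde_tap, dep_ids), 0)
  expect_gt(prec(prde_tap, indep_ids), 0)
  mat <- function(l, ids) sum(l$origins$count[l$origins$species == "mature" &
                                                l$origins$origin %in% ids])
  expect_equal(mat(prde_tap, dep_ids), 0)
  expect_gt(mat(prde_tap, indep_ids), 0)
})

test_that("protocol filters include or exclude capped species", {
  sim <- tiny_sim()
  unt <- generate_library(sim, "wild_type", "untreated")
  expect_identical(sum(unt$origins$capped), 0L)
  cap <- generate_library(sim, "wild_type", "capRNA")
  expect_identical(sum(cap$origins$species == "mature"), 0L)
  tap <- generate_library(sim, "wild_type", "TAP")
  expect_gt(sum(tap$origins$species == "mature"), 0L)
  expect_gt(sum(tap$origins$species == "precursor"), 0L)
})

test_that("truth-side precursor geometry peaks at +2 nt and 28-29 nt", {
  sim <- default_sim()
  tap <- generate_library(sim, "wild_type", "TAP")
  pre <- tap$origins[tap$origins$species == "precursor", ]
  lens <- nchar(pre$sequence)
  modal_len <- pirnaforge:::weighted_mode(lens, pre$count)
  expect_true(modal_len %in% c(28, 29))
  # every generated precursor begins exactly 2 nt upstream: its 3rd base on
  # is the mature 5' U, so position 3 must align with the locus 21-mer start
  loci <- sim$loci
  m <- match(pre$origin, loci$locus_id)
  expect_true(all(substr(pre$sequence, 3, 3) == "T"))
  expect_true(all(substr(pre$sequence, 3, 23) == loci$mature_seq[m]))
})

test_that("22G reads are 22-nt, 5' G, antisense to gene bodies", {
  sim <- tiny_sim()
  g22 <- generate_22g_and_expression(sim, n_reps = 2L, depth = 5000L)
  for (gt in names(g22$g22_libraries)) {
    reads <- g22$g22_libraries[[gt]]$reads
    expect_true(all(nchar(reads$sequence) == 22L))
    expect_true(all(startsWith(reads$sequence, "G")))
  }
  # antisense: the reverse complement occurs in the gene sense sequence
  genes <- sim$truth$genes
  org <- g22$g22_origins$wild_type
  gid <- sub("^22G:", "", org$origin)
  i <- match(gid, genes$gene_id)
  sense <- vapply(seq_len(nrow(org)), function(k) {
    s <- substr(sim$genome[[genes$chrom[i[k]]]], genes$start[i[k]] + 1L,
                genes$end[i[k]])
    if (genes$strand[i[k]] == "-") rc_oracle(s) else s
  }, character(1))
  hit <- mapply(function(r, s) grepl(rc_oracle(r), s, fixed = TRUE),
                org$sequence, sense)
  expect_true(all(hit))
})

test_that("untargeted genes are expression-flat; targets shift where 22Gs are lost", {
  sim <- default_sim()
  g22 <- generate_22g_and_expression(sim)
  cfg <- sim$truth$config
  genes <- sim$truth$genes
  expr <- g22$expression
  gts <- expr$samples$genotype
  lfc <- function(gt) rowMeans(expr$values[, gts == gt, drop = FALSE]) -
    rowMeans(expr$values[, gts == "wild_type", drop = FALSE])
  for (gt in c("prg1", "prde1")) {
    fc <- lfc(gt)
    flat <- abs(fc[genes$class == "untargeted"])
    expect_lt(mean(flat), 3 * cfg$expr_sd / sqrt(cfg$n_reps))
    up_truth <- switch(gt,
                       prg1 = genes$class %in% c("shared_target", "prg1_only_target"),
                       prde1 = genes$class == "shared_target")
    expect_gt(min(fc[up_truth]), 1)
  }
})
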