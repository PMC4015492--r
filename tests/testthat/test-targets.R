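test_that("target search respects the mismatch budget", {
  set.seed(61)
  pir <- paste0("T", rand_dna(20))
  site <- rc_oracle(pir)
  tx_exact <- paste0(rand_dna(50), site, rand_dna(50))
  hits <- find_targets(c(p1 = pir), c(t1 = tx_exact), max_mm = 3)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 51L)
  expect_identical(hits$mismatches, 0L)

  # plant exactly 4 substitutions: no hit at budget 3, hit at 4
  s4 <- strsplit(site, "")[[1L]]
  at <- c(2, 7, 12, 18)
  s4[at] <- vapply(s4[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  tx4 <- paste0(rand_dna(30), paste(s4, collapse = ""), rand_dna(30))
  h0 <- brute_targets(pir, tx4, 3)            # confirm the construction
  expect_identical(nrow(find_targets(c(p1 = pir), c(t1 = tx4), 3)), nrow(h0))
  expect_identical(nrow(find_targets(c(p1 = pir), c(t1 = tx4), 4)), 1L)

  # piRNA longer than transcript: no hits, no error
  expect_identical(nrow(find_targets(c(p1 = pir), c(t1 = "ACGT"), 3)), 0L)
})

test_that("target search equals exhaustive enumeration on random transcripts", {
  set.seed(62)
  for (rep in 1:8) {
    pir <- paste0("T", rand_dna(20))
    # bias the transcript toward near-matches so hits actually occur
    site <- strsplit(rc_oracle(pir), "")[[1L]]
    n_mm <- sample(0:3, 1)
    if (n_mm > 0) {
      at <- sample(21, n_mm)
      site[at] <- vapply(site[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    tx <- paste0(rand_dna(80), paste(site, collapse = ""), rand_dna(99))
    got <- find_targets(c(p = pir), c(t = tx), 3)
    want <- brute_targets(pir, tx, 3)
    expect_identical(nrow(got), nrow(want))
    expect_identical(sort(got$position), sort(want$position))
    expect_identical(got$mismatches[order(got$position)],
                     want$mismatches[order(want$position)])
  }
})

test_that("antisense 22G counting is strand-specific", {
  set.seed(63)
  gene_sense <- paste0(rand_dna(200), "C", rand_dna(100))
  g <- c(chrI = gene_sense)
  genes <- data.frame(gene_id = "gA", chrom = "chrI", start = 0L,
                      end = nchar(gene_sense), strand = "+",
                      stringsAsFactors = FALSE)
  anti <- rc_oracle(substr(gene_sense, 180, 201))  # 22-mer ending at the C
  stopifnot(startsWith(anti, "G"))
  sense_read <- substr(gene_sense, 10, 31)
  lib <- srna_library(data.frame(sequence = c(anti, sense_read),
                                 count = c(6L, 3L)), "s", "wild_type")
  q <- antisense_22g(lib, genes, g)
  counted_sense <- startsWith(sense_read, "G") &&
    grepl(rc_oracle(sense_read), gene_sense, fixed = TRUE)
  expect_equal(q$count, 6 + if (counted_sense) 3 else 0)
  expect_equal(q$rpm, q$count / 9 * 1e6)
  # a gene on the minus strand sees the complementary population
  genes2 <- genes; genes2$strand <- "-"
  q2 <- antisense_22g(srna_library(data.frame(sequence = anti, count = 6L),
                                   "s", "wild_type"), genes2, g)
  expect_equal(q2$count, 0)
})

test_that("mutant 22G levels drop only for the right target classes", {
  sim <- default_sim()
  g22 <- generate_22g_and_expression(sim)
  genes <- sim$truth$genes
  q <- lapply(g22$g22_libraries, antisense_22g, genes = genes,
              genome = sim$genome)
  ratio <- function(gt, cl) {
    sel <- genes$class == cl
    (q[[gt]]$rpm[sel] + 1) / (q$wild_type$rpm[sel] + 1)
  }
  expect_lt(median(ratio("prde1", "shared_target")), 0.3)
  expect_gt(median(ratio("prde1", "prg1_only_target")), 0.7)
  expect_lt(median(ratio("prg1", "prg1_only_target")), 0.3)
  expect_lt(median(ratio("prg1", "shared_target")), 0.3)
})

test_that("DE gate is strict at the fold threshold", {
  # integer log2 values make the fold-change arithmetic exact: gExact sits
  # at a mean difference of exactly 2 (fourfold), gUp at 3
  vals <- rbind(c(0, 1, 1, 2, 2, 3, 3, 4),
                c(0, 1, 1, 2, 3, 4, 4, 5))
  rownames(vals) <- c("gExact", "gUp")
  colnames(vals) <- paste0("s", 1:8)
  expr <- expression_matrix(vals, rep(c("wild_type", "prg1"), each = 4))
  de <- de_gene_sets(expr, fold = 4, alpha = 0.05, mt_alpha = 0.1)
  # gExact clears the p and q gates but sits at exactly fourfold
  st <- de$stats[de$stats$gene_id == "gExact", ]
  expect_lt(st$p, 0.05)
  expect_equal(st$log2fc, 2)
  expect_false("gExact" %in% de$prg1_only)
  expect_true("gUp" %in% de$prg1_only)
})

test_that("permuting genotype labels empties the DE sets", {
  sim <- tiny_sim()
  g22 <- generate_22g_and_expression(sim, n_reps = 4L, depth = 5000L)
  expr <- g22$expression
  set.seed(64)
  for (rep in 1:3) {
    perm <- expr
    perm$samples$genotype <- sample(perm$samples$genotype)
    de <- de_gene_sets(perm)
    expect_lte(length(de$shared) + length(de$prg1_only) + length(de$prde1_only), 1L)
  }
})

test_that("BH q-values dominate p-values and preserve order", {
  set.seed(65)
  for (rep in 1:10) {
    p <- runif(200)^sample(1:3, 1)
    q <- p.adjust(p, method = "BH")
    expect_true(all(q >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("Fisher enrichment matches hand-enumerated hypergeometric tails", {
  r <- fisher_enrichment(10, 20, 20, 40)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  # table (5,0 / 0,5): enumerate the hypergeometric support directly
  r2 <- fisher_enrichment(5, 5, 5, 10)
  # P(X = k) for k hits among 5 draws from 5/5; two-sided p sums
  # probabilities <= P(observed)
  probs <- dhyper(0:5, 5, 5, 5)
  p_expected <- sum(probs[probs <= probs[6] + 1e-12])
  expect_equal(r2$p, p_expected)
  expect_identical(r2$odds_ratio, Inf)

  # proportional scaling leaves the odds ratio unchanged
  a <- fisher_enrichment(6, 10, 18, 40)
  b <- fisher_enrichment(12, 20, 36, 80)
  expect_equal(a$odds_ratio, b$odds_ratio)

  # zero-margin table
  z <- fisher_enrichment(0, 10, 0, 40)
  expect_identical(z$p, 1)
  expect_true(is.na(z$odds_ratio))
})

test_that("permutation set test hits the floor, stays calibrated, and is deterministic", {
  set.seed(66)
  stat <- setNames(rnorm(300), paste0("g", 1:300))
  top <- names(sort(stat, decreasing = TRUE))[1:20]
  r <- permutation_set_test(stat, top, n_perm = 999, seed = 5)
  expect_equal(r$p, 1 / 1000)
  r2 <- permutation_set_test(stat, top, n_perm = 999, seed = 5)
  expect_identical(r, r2)

  # random sets: p roughly uniform
  ps <- vapply(1:200, function(i)
    permutation_set_test(stat, sample(names(stat), 25), n_perm = 199,
                         seed = i)$p, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(mean(ps <= 0.25), 0.15)
  expect_lt(mean(ps <= 0.25), 0.35)
})

test_that("rank comparison handles ties, symmetry and exact enumeration", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_set_compare(x, x)$p_value, 1, tolerance = 0.05)
  expect_warning(r <- rank_set_compare(rep(2, 5), rep(2, 6)), "tied")
  expect_identical(r$p_value, 1)

  # disjoint support, n = m = 20: exact two-sided p is 2 / choose(40, 20)
  set.seed(67)
  a <- runif(20); b <- runif(20) + 10
  r2 <- rank_set_compare(a, b)
  expect_equal(r2$p_value, 2 / choose(40, 20))
  r3 <- rank_set_compare(b, a)
  expect_equal(r3$p_value, r2$p_value)
  expect_equal(r3$statistic, 400 - r2$statistic)
})
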