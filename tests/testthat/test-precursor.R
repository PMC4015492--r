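make_lib <- function(seqs, counts = rep(1L, length(seqs))) {
  srna_library(data.frame(sequence = seqs, count = counts,
                          stringsAsFactors = FALSE),
               sample_id = "t", genotype = "wild_type", protocol = "TAP")
}

test_that("mature, precursor and foreign reads get the expected calls", {
  pl <- plant_locus(five0 = 150L, strand = "+", seed = 12L)
  g <- pl$genome; loci <- pl$loci
  mature <- loci$mature_seq
  # 28-mer starting 2 nt upstream: ext5 2, ext3 5
  pre28 <- pirnaforge:::extract_sense(g, "chrI", 150L, "+", 2L, 26L)
  foreign <- strrep("ACGT", 7)  # not in this genome w.h.p.; verify
  stopifnot(!grepl(foreign, g[["chrI"]], fixed = TRUE))
  al <- assign_reads(make_lib(c(mature, pre28, foreign)), g, loci)
  al <- al[order(al$sequence), ]
  get <- function(s) al[al$sequence == s, ]
  expect_identical(get(mature)$species_call, "mature")
  expect_identical(get(mature)$five_prime_ext, 0L)
  expect_identical(get(pre28)$species_call, "precursor_candidate")
  expect_identical(get(pre28)$five_prime_ext, 2L)
  expect_identical(get(pre28)$three_prime_ext, 5L)
  expect_identical(get(foreign)$species_call, "unassigned")
})

test_that("assignment works identically on the minus strand", {
  pl <- plant_locus(five0 = 150L, strand = "-", seed = 13L)
  pre <- pirnaforge:::extract_sense(pl$genome, "chrI", 150L, "-", 2L, 27L)
  al <- assign_reads(make_lib(c(pl$loci$mature_seq, pre)), pl$genome, pl$loci)
  expect_setequal(al$species_call, c("mature", "precursor_candidate"))
  expect_identical(al$five_prime_ext[al$species_call == "precursor_candidate"], 2L)
})

test_that("indexed assignment agrees with the brute-force oracle", {
  sim <- tiny_sim()   # 40 kb cluster chromosome
  set.seed(41)
  # mix of true species, perturbed reads and random junk
  tap <- generate_library(sim, "wild_type", "TAP", depth = 3000L)
  pick <- sample(nrow(tap$library$reads), 120L)
  seqs <- tap$library$reads$sequence[pick]
  junk <- vapply(1:30, function(i) rand_dna(sample(15:45, 1)), "")
  lib <- make_lib(unique(c(seqs, junk)))
  al <- assign_reads(lib, sim$genome, sim$loci)
  oracle <- brute_assign(lib, sim$genome, sim$loci)
  for (s in lib$reads$sequence) {
    a <- al[al$sequence == s & !is.na(al$locus_id), ]
    o <- oracle[oracle$sequence == s & !is.na(oracle$locus_id), ]
    expect_setequal(paste(a$locus_id, a$five_prime_ext, a$species_call),
                    paste(o$locus_id, o$five_prime_ext, o$species_call))
  }
})

test_that("read counts are conserved across species classes", {
  sim <- tiny_sim()
  for (pr in c("untreated", "TAP", "capRNA")) {
    l <- generate_library(sim, "wild_type", pr)
    al <- assign_reads(l$library, sim$genome, sim$loci)
    expect_equal(sum(al$count[al$primary]), l$library$total_count)
    # primary marks exactly one row per unique sequence
    expect_identical(sum(al$primary), nrow(l$library$reads))
  }
})

test_that("profiles report modes with ties to the smaller value", {
  pl <- plant_locus(five0 = 150L, strand = "+", seed = 14L)
  al <- assign_reads(make_lib(pl$loci$mature_seq, 10L), pl$genome, pl$loci)
  prof <- extension_profile(al, "mature")
  expect_identical(prof$modal_ext, 0)
  expect_identical(prof$modal_length, 21)
  expect_identical(prof$ext$reads, 10)
  expect_identical(prof$ext$sequences, 1L)
  # tie between lengths 21 and 28 resolves to 21
  pre <- pirnaforge:::extract_sense(pl$genome, "chrI", 150L, "+", 2L, 26L)
  al2 <- assign_reads(make_lib(c(pl$loci$mature_seq, pre), c(5L, 5L)),
                      pl$genome, pl$loci)
  prof2 <- extension_profile(al2)
  expect_identical(prof2$modal_length, 21)
})

test_that("empty profiles are valid", {
  pl <- plant_locus(five0 = 150L, strand = "+", seed = 15L)
  foreign <- strrep("TGCA", 6)
  stopifnot(!grepl(foreign, pl$genome[["chrI"]], fixed = TRUE))
  al <- assign_reads(make_lib(foreign), pl$genome, pl$loci)
  prof <- extension_profile(al)
  expect_identical(nrow(prof$ext), 0L)
  expect_true(is.na(prof$modal_ext))
})

test_that("protocol comparison reproduces the cloning-chemistry contract", {
  sim <- tiny_sim()
  als <- lapply(c(untreated = "untreated", TAP = "TAP", capRNA = "capRNA"),
                function(pr) {
                  l <- generate_library(sim, "wild_type", pr)
                  assign_reads(l$library, sim$genome, sim$loci)
                })
  rep <- compare_protocols(als)
  expect_true(all(rep$contract_ok))
  expect_lt(rep$precursor_fraction[rep$protocol == "untreated"], 0.05)
  expect_lt(rep$mature_fraction[rep$protocol == "capRNA"], 0.05)
  expect_gt(rep$mature_fraction[rep$protocol == "TAP"], 0.1)
  expect_gt(rep$precursor_fraction[rep$protocol == "TAP"], 0.02)
  expect_identical(rep$modal_length[rep$protocol == "untreated"], 21)
  expect_true(rep$modal_length[rep$protocol == "capRNA"] %in% c(28, 29))
})

test_that("per-locus tables flag multi-locus reads and keep full counts", {
  # two identical loci -> their shared mature read maps to both
  set.seed(16)
  body <- paste0("T", rand_dna(20))
  ch <- paste0(rand_dna(100), body, rand_dna(60), body, rand_dna(100))
  g <- c(chrI = ch)
  loci <- data.frame(locus_id = c("La", "Lb"), chrom = "chrI",
                     start = c(100L, 181L), strand = "+", mature_length = 21L,
                     mature_seq = body, motif_score = NA_real_,
                     class_label = "unscored", stringsAsFactors = FALSE)
  al <- assign_reads(make_lib(body, 4L), g, loci)
  assigned <- al[!is.na(al$locus_id), ]
  expect_identical(nrow(assigned), 2L)
  expect_true(all(assigned$multi))
  expect_identical(sum(assigned$primary), 1L)
  pc <- per_locus_counts(al)
  expect_identical(pc$mature_count, c(4, 4))
  expect_true(all(pc$any_multi))
  # conservation ledger counts the read once
  expect_identical(sum(al$count[al$primary]), 4L)
})
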