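default_run_config <- function() {
  list(
    out_dir = "pirnaforge_run",
    seed = 7L,
    simulate = TRUE,
    genome = NULL, loci = NULL, libraries = NULL, expression = NULL,
    cutoff = 7,
    window_min = 30L, window_max = 50L,
    de_fold = 4, de_alpha = 0.05, de_mt_alpha = 0.1,
    max_mm = 3L,
    log_level = "info"
  )
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, then motif scoring and classification,
#' precursor calling per library, genotype abundance comparison, and the
#' target/DE/22G stage, writing each stage's tabular output plus a
#' provenance block (config, seed, package version) under `out_dir`.
#' Unknown config keys are rejected before any stage runs.
#'
#' @param config Named list overriding the defaults (see
#'   `pirnaforge:::default_run_config()`). With `simulate = TRUE` all inputs
#'   are generated; otherwise supply `genome` (FASTA path), `loci` (BED),
#'   `libraries` (data.frame `path`, `sample_id`, `genotype`, `protocol`)
#'   and optionally `expression` (TSV).
#' @return Invisibly, a list of in-memory stage results; artifacts are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (cfg$log_level != "quiet") message(sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  results <- list()
  if (isTRUE(cfg$simulate)) {
    say("[simulate] generating synthetic data (seed %d)", cfg$seed)
    sim <- stage("simulate", {
      s <- generate_genome(sim_config(seed = cfg$seed))
      write_genome_fasta(s$genome, file.path(cfg$out_dir, "genome.fa"))
      write_loci_bed(s$loci, file.path(cfg$out_dir, "loci.bed"))
      s
    })
    libs <- stage("simulate", {
      combos <- expand.grid(genotype = c("wild_type", "prg1", "prde1"),
                            protocol = c("untreated", "TAP", "capRNA"),
                            stringsAsFactors = FALSE)
      out <- lapply(seq_len(nrow(combos)), function(i)
        generate_library(sim, combos$genotype[i], combos$protocol[i]))
      for (l in out)
        write_library(l$library, file.path(cfg$out_dir,
                                           paste0(l$library$sample_id, ".tsv")))
      truth <- do.call(rbind, lapply(out, function(l)
        cbind(sample_id = l$library$sample_id, l$origins)))
      write.table(truth, file.path(cfg$out_dir, "truth_origins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(sim$truth$loci, file.path(cfg$out_dir, "truth_loci.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
    g22 <- stage("simulate", generate_22g_and_expression(sim))
    write_expression(g22$expression, file.path(cfg$out_dir, "expr.tsv"))
    genome <- sim$genome
    loci <- sim$loci
    genes <- sim$truth$genes
    expr <- g22$expression
    results$sim <- sim
    results$g22 <- g22
    libraries <- lapply(libs, `[[`, "library")
  } else {
    say("[load] reading inputs")
    genome <- stage("load", read_genome_fasta(cfg$genome))
    loci <- stage("load", read_loci(cfg$loci, genome))
    libraries <- stage("load", lapply(seq_len(nrow(cfg$libraries)), function(i)
      read_library(cfg$libraries$path[i], cfg$libraries$sample_id[i],
                   cfg$libraries$genotype[i], cfg$libraries$protocol[i])))
    expr <- if (!is.null(cfg$expression)) read_expression(cfg$expression) else NULL
    genes <- NULL
  }

  say("[score-motifs] training PWM and classifying %d loci", nrow(loci))
  scored <- stage("score-motifs", {
    pwm <- train_pwm(genome, loci, window = cfg$window_min:cfg$window_max)
    score_loci(genome, loci, pwm, cfg$window_min:cfg$window_max, cfg$cutoff)
  })
  write_loci_bed(scored, file.path(cfg$out_dir, "scored.bed"))
  results$scored <- scored

  say("[call-precursors] profiling %d libraries", length(libraries))
  profiles <- stage("call-precursors", lapply(libraries, function(lib) {
    al <- assign_reads(lib, genome, scored)
    prof <- extension_profile(al)
    pc <- per_locus_counts(al)
    write.table(pc, file.path(cfg$out_dir,
                              paste0(lib$sample_id, "_locus_counts.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ed <- prof$ext; names(ed)[1] <- "five_prime_ext"
    ld <- prof$length; names(ld)[1] <- "read_length"
    write.table(ed, file.path(cfg$out_dir, paste0(lib$sample_id, "_ext.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ld, file.path(cfg$out_dir, paste0(lib$sample_id, "_len.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(alignments = al, profile = prof)
  }))
  results$profiles <- profiles

  say("[compare] genotype abundance statistics")
  untreated <- vapply(libraries, function(l) l$protocol == "untreated", logical(1))
  if (sum(untreated) >= 2L) {
    tab <- stage("compare", normalize_rpm(
      locus_count_table(libraries[untreated], genome, scored)))
    summ <- stage("compare", class_summary(tab))
    write.table(summ, file.path(cfg$out_dir, "class_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$class_summary <- summ
  }

  if (!is.null(expr)) {
    say("[de] differential-expression gene sets")
    de <- stage("de", de_gene_sets(expr, cfg$de_fold, cfg$de_alpha,
                                   cfg$de_mt_alpha))
    write.table(de$stats, file.path(cfg$out_dir, "de_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sets <- data.frame(
      gene_id = c(de$shared, de$prg1_only, de$prde1_only),
      set = rep(c("shared", "prg1_only", "prde1_only"),
                c(length(de$shared), length(de$prg1_only),
                  length(de$prde1_only))))
    write.table(sets, file.path(cfg$out_dir, "de_sets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$de <- de
  }

  if (!is.null(genes) && isTRUE(cfg$simulate)) {
    say("[g22] antisense 22G quantification")
    g22q <- stage("g22", {
      qs <- lapply(names(results$g22$g22_libraries), function(gt) {
        q <- antisense_22g(results$g22$g22_libraries[[gt]], genes, genome)
        names(q)[2:3] <- paste0(c("count_", "rpm_"), gt)
        q
      })
      Reduce(function(a, b) merge(a, b, by = "gene_id"), qs)
    })
    write.table(g22q, file.path(cfg$out_dir, "g22.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$g22_quant <- g22q

    say("[targets] piRNA target prediction (up to %d mismatches)", cfg$max_mm)
    gene_seqs <- vapply(seq_len(nrow(genes)), function(g) {
      s <- substr(genome[[genes$chrom[g]]], genes$start[g] + 1L, genes$end[g])
      if (genes$strand[g] == "-") revcomp(s) else s
    }, character(1))
    names(gene_seqs) <- genes$gene_id
    dep <- scored$class_label == "motif_dependent"
    pirnas <- setNames(scored$mature_seq[dep], scored$locus_id[dep])
    hits <- stage("targets", find_targets(pirnas, gene_seqs, cfg$max_mm))
    write.table(hits, file.path(cfg$out_dir, "target_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$target_hits <- hits
  }

  provenance <- list(
    package = "pirnaforge",
    version = as.character(packageVersion("pirnaforge")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("libraries"))],
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  say("[done] artifacts in %s", cfg$out_dir)
  invisible(results)
}

#' One-shot end-to-end demo on synthetic data
#'
#' Runs the whole pipeline on generated data; no external inputs and no
#' network access are needed.
#'
#' @param out_dir Artifact directory.
#' @param seed Top-level seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
pirna_demo <- function(out_dir = tempfile("pirnaforge_demo_"), seed = 7L,
                       quiet = FALSE) {
  run_pipeline(list(out_dir = out_dir, seed = as.integer(seed),
                    simulate = TRUE,
                    log_level = if (quiet) "quiet" else "info"))
}
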