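#' Read a genome FASTA file
#'
#' Loads a (small) genome into a named character vector, one uppercase
#' sequence per chromosome. Sequences may contain `N`; any other character
#' is a format error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over `{A,C,G,T,N}`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_fmt("empty FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop_fmt("duplicate FASTA header: %s", dup[1L])
  seqs <- toupper(as.character(ss))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop_fmt("invalid character '%s' in record '%s' at position %d",
               substr(seqs[[i]], bad, bad), nm[i], bad)
    if (nchar(seqs[[i]]) == 0L) stop_fmt("empty sequence for record '%s'", nm[i])
  }
  setNames(seqs, nm)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by [read_genome_fasta()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read piRNA loci from a BED-like file
#'
#' Intervals are BED6 (0-based, half-open; column 6 is strand). Internally a
#' locus is stored by the genomic coordinate of its mature 5' base: the BED
#' start for `+` loci and `end - 1` for `-` loci, so that 5'-extension
#' arithmetic is strand-uniform. The mature sequence is extracted strand-aware
#' from the genome (reverse complement on `-`). Two optional extra columns
#' (motif score, class label) are read back if present.
#'
#' @param path BED6 or BED6+2 file.
#' @param genome Named character vector from [read_genome_fasta()].
#' @return `data.frame` with columns `locus_id`, `chrom`, `start` (0-based 5'
#'   base), `strand`, `mature_length`, `mature_seq`, `motif_score`,
#'   `class_label`.
#' @export
read_loci <- function(path, genome) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "bed_start", "bed_end", "name",
                                  "score", "strand", "motif_score",
                                  "class_label")[1:max(6, count_fields(path))],
                    fill = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop_fmt("expected at least 6 BED columns in %s", path)
  if (!all(bed$strand %in% c("+", "-")))
    stop_fmt("strand column must be '+' or '-'")
  loci <- data.frame(
    locus_id = as.character(bed$name),
    chrom = as.character(bed$chrom),
    start = ifelse(bed$strand == "+", bed$bed_start, bed$bed_end - 1L),
    strand = bed$strand,
    mature_length = bed$bed_end - bed$bed_start,
    stringsAsFactors = FALSE
  )
  if (any(loci$mature_length < 1L)) stop_fmt("interval of length < 1")
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    if (!chrom %in% names(genome)) stop_fmt("unknown chromosome '%s'", chrom)
    if (bed$bed_start[i] < 0L || bed$bed_end[i] > nchar(genome[[chrom]]))
      stop_fmt("interval %s exceeds chromosome '%s' bounds", loci$locus_id[i], chrom)
  }
  loci$mature_seq <- extract_sense_many(genome, loci, 0L, loci$mature_length[1L])
  # per-row downstream lengths (extract_sense_many uses scalar), redo mixed case
  if (length(unique(loci$mature_length)) > 1L) {
    loci$mature_seq <- vapply(seq_len(nrow(loci)), function(i) {
      extract_sense(genome, loci$chrom[i], loci$start[i], loci$strand[i],
                    0L, loci$mature_length[i])
    }, character(1))
  }
  nonU <- substr(loci$mature_seq, 1L, 1L) != "T"
  if (any(nonU))
    warn_fmt("%d locus/loci without a 5' U (first base not T): e.g. %s",
             sum(nonU), loci$locus_id[which(nonU)[1L]])
  nc <- loci$mature_length != 21L
  if (any(nc))
    warn_fmt("%d locus/loci with non-canonical mature length (not 21 nt)", sum(nc))
  withN <- grepl("N", loci$mature_seq, fixed = TRUE)
  if (any(withN)) {
    warn_fmt("dropping %d locus/loci overlapping N bases", sum(withN))
    loci <- loci[!withN, , drop = FALSE]
  }
  loci$motif_score <- if ("motif_score" %in% names(bed)) as.numeric(bed$motif_score[!withN]) else NA_real_
  loci$class_label <- if ("class_label" %in% names(bed)) as.character(bed$class_label[!withN]) else "unscored"
  rownames(loci) <- NULL
  loci
}

count_fields <- function(path) {
  first <- readLines(path, n = 1L)
  length(strsplit(first, "\t", fixed = TRUE)[[1L]])
}

#' Write loci to a BED-like file
#'
#' Emits BED6 plus two columns (motif score, class label) when scores are
#' present. The BED interval is reconstructed from the stored 5'-base
#' coordinate, strand-aware.
#'
#' @param loci Loci `data.frame` from [read_loci()] or the generator.
#' @param path Output path.
#' @param extra Write score/class columns (default: only when any score set).
#' @export
write_loci_bed <- function(loci, path, extra = any(!is.na(loci$motif_score))) {
  bed_start <- ifelse(loci$strand == "+", loci$start,
                      loci$start - loci$mature_length + 1L)
  bed_end <- bed_start + loci$mature_length
  out <- data.frame(loci$chrom, bed_start, bed_end, loci$locus_id, 0L,
                    loci$strand)
  if (extra) {
    out$score <- loci$motif_score
    out$class <- loci$class_label
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a collapsed small-RNA library
#'
#' A library file is a two-column TSV of `sequence<TAB>count`. Duplicate
#' sequences are merged by summing counts.
#'
#' @param path TSV path.
#' @param sample_id Sample identifier.
#' @param genotype One of `wild_type`, `prg1`, `prde1`, `other`.
#' @param protocol One of `untreated`, `TAP`, `capRNA`.
#' @return An object of class `srna_library`: list with `sample_id`,
#'   `genotype`, `protocol`, `reads` (data.frame `sequence`, `count`) and
#'   `total_count`.
#' @export
read_library <- function(path, sample_id = basename(path),
                         genotype = "other", protocol = "untreated") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (file.size(path) == 0L) stop_fmt("empty library: %s", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("sequence", "count"),
                    colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop_fmt("empty library: %s", path)
  srna_library(tab, sample_id = sample_id, genotype = genotype,
               protocol = protocol)
}

#' Construct a small-RNA library object
#'
#' @param reads data.frame with columns `sequence` and `count`.
#' @inheritParams read_library
#' @export
srna_library <- function(reads, sample_id, genotype = "other",
                         protocol = "untreated") {
  genotype <- match.arg(genotype, c("wild_type", "prg1", "prde1", "other"))
  protocol <- match.arg(protocol, c("untreated", "TAP", "capRNA"))
  if (any(reads$count <= 0) || any(reads$count != round(reads$count)))
    stop_fmt("counts must be positive integers")
  lens <- nchar(reads$sequence)
  if (any(lens < 15L | lens > 100L))
    stop_fmt("sequence lengths must be in [15, 100] nt")
  if (anyDuplicated(reads$sequence)) {
    agg <- tapply(reads$count, reads$sequence, sum)
    reads <- data.frame(sequence = names(agg), count = as.numeric(agg),
                        stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, genotype = genotype,
                 protocol = protocol,
                 reads = reads[order(reads$sequence), , drop = FALSE],
                 total_count = sum(reads$count)),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s' (%s, %s): %d unique sequences, %s reads\n",
              x$sample_id, x$genotype, x$protocol, nrow(x$reads),
              format(x$total_count, big.mark = ",")))
  invisible(x)
}

#' Write a library to sequence-count TSV
#' @param lib `srna_library`.
#' @param path Output path.
#' @export
write_library <- function(lib, path) {
  write.table(lib$reads, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' The format is a gene-by-sample TSV with a two-line header: line one holds
#' sample identifiers, line two the genotype of each sample.
#'
#' @param path TSV path.
#' @return An `expression_matrix`: list with `genes`, `samples` (data.frame
#'   `sample_id`, `genotype`, `replicate`) and `values` (numeric matrix).
#' @export
read_expression <- function(path) {
  hdr <- readLines(path, n = 2L)
  ids <- strsplit(hdr[1L], "\t", fixed = TRUE)[[1L]][-1L]
  gts <- strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]][-1L]
  if (length(ids) != length(gts)) stop_fmt("header lines disagree in length")
  tab <- read.table(path, sep = "\t", skip = 2L, header = FALSE,
                    row.names = 1L, stringsAsFactors = FALSE)
  values <- as.matrix(tab)
  colnames(values) <- ids
  if (anyNA(values)) stop_fmt("expression matrix contains missing values")
  expression_matrix(values, genotypes = gts)
}

#' Construct an expression matrix object
#' @param values Numeric genes-by-samples matrix of log2 expression, with
#'   gene row names and sample column names.
#' @param genotypes Character vector, one genotype per column.
#' @export
expression_matrix <- function(values, genotypes) {
  stopifnot(is.matrix(values), length(genotypes) == ncol(values))
  reps <- stats::ave(seq_along(genotypes), genotypes, FUN = seq_along)
  structure(list(genes = rownames(values),
                 samples = data.frame(sample_id = colnames(values),
                                      genotype = genotypes,
                                      replicate = reps,
                                      stringsAsFactors = FALSE),
                 values = values),
            class = "expression_matrix")
}

#' Write an expression matrix
#' @param expr `expression_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", expr$samples$sample_id), collapse = "\t"), con)
  writeLines(paste(c("genotype", expr$samples$genotype), collapse = "\t"), con)
  write.table(expr$values, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Runs the strict readers over a set of files, dispatching on extension
#' (`.fa`/`.fasta` genome, `.bed` loci, `.tsv` library), and reports
#' problems without stopping at the first.
#'
#' @param files Character vector of paths.
#' @param genome Optional genome (required to validate BED files).
#' @return Invisibly, a data.frame of `file`, `ok`, `message`.
#' @export
validate_files <- function(files, genome = NULL) {
  res <- lapply(files, function(f) {
    msg <- tryCatch({
      ext <- tolower(tools::file_ext(f))
      if (ext %in% c("fa", "fasta")) read_genome_fasta(f)
      else if (ext == "bed") {
        if (is.null(genome)) stop_fmt("genome required to validate %s", f)
        read_loci(f, genome)
      } else if (ext == "tsv") read_library(f)
      else stop_fmt("unrecognized extension: %s", f)
      "ok"
    }, error = conditionMessage, warning = conditionMessage)
    data.frame(file = f, ok = identical(msg, "ok"), message = msg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  invisible(out)
}
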