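#' Build a per-locus count table across libraries
#'
#' Assigns each library's reads to the loci and tabulates per-locus counts
#' of one species (mature by default). Multi-locus reads contribute to every
#' matching locus, as in [per_locus_counts()].
#'
#' @param libraries List of `srna_library` objects.
#' @param genome Named character vector.
#' @param loci Loci data.frame (ideally scored, so class labels are set).
#' @param species `"mature"` or `"precursor_candidate"`.
#' @return A `locus_count_table`: list with `counts` (loci x samples
#'   matrix), `samples` (data.frame `sample_id`, `genotype`, `total_count`),
#'   `loci` and `species`; `rpm` is added by [normalize_rpm()].
#' @export
locus_count_table <- function(libraries, genome, loci, species = "mature") {
  cols <- lapply(libraries, function(lib) {
    al <- assign_reads(lib, genome, loci)
    pc <- per_locus_counts(al)
    v <- setNames(if (species == "mature") pc$mature_count else pc$precursor_count,
                  pc$locus_id)
    out <- setNames(rep(0, nrow(loci)), loci$locus_id)
    out[names(v)] <- v
    out
  })
  counts <- do.call(cbind, cols)
  colnames(counts) <- vapply(libraries, `[[`, character(1), "sample_id")
  samples <- data.frame(
    sample_id = colnames(counts),
    genotype = vapply(libraries, `[[`, character(1), "genotype"),
    total_count = vapply(libraries, `[[`, numeric(1), "total_count"),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, loci = loci,
                 species = species),
            class = "locus_count_table")
}

#' Normalize a count table to reads per million
#'
#' RPM is `count / total_library_count * 1e6`, where the total is the whole
#' library (assigned or not), so the assigned RPM of a sample sums to
#' `1e6 * assigned_fraction`.
#'
#' @param table A `locus_count_table`.
#' @return The table with an `rpm` matrix added.
#' @export
normalize_rpm <- function(table) {
  if (any(table$samples$total_count <= 0)) stop_fmt("zero library total")
  table$rpm <- sweep(table$counts, 2L, table$samples$total_count, "/") * 1e6
  table
}

#' One-sided Wilcoxon test for per-locus depletion
#'
#' Tests whether mutant per-locus abundances are reduced relative to wild
#' type. Loci are natural pairs across genotypes, so the paired signed-rank
#' test is the default; an unpaired rank-sum variant is available. The
#' alternative is `mut < wt`. Exact p-values are used for n <= 25 (no
#' ties), the normal approximation with continuity correction otherwise.
#'
#' @param wt,mut Per-locus RPM (or count) vectors.
#' @param paired Use the signed-rank test on locus pairs (default TRUE).
#' @return List with `statistic`, `p_value`, `direction`
#'   (`"reduction"`/`"increase"`/`"none"`), `method`, `n`.
#' @export
reduction_test <- function(wt, mut, paired = TRUE) {
  if (paired && length(wt) != length(mut))
    stop_fmt("paired test requires equal-length vectors")
  if (paired) {
    d <- mut - wt
    if (all(d == 0)) {
      warn_fmt("all paired differences are zero; p = 1 by convention")
      return(list(statistic = NA_real_, p_value = 1,
                  direction = "none", method = "wilcoxon signed-rank",
                  n = 0L))
    }
    n_eff <- sum(d != 0)
    wt_res <- suppressWarnings(
      wilcox.test(mut, wt, paired = TRUE, alternative = "less",
                  exact = n_eff <= 25L, correct = TRUE))
  } else {
    n_eff <- min(length(wt), length(mut))
    wt_res <- suppressWarnings(
      wilcox.test(mut, wt, paired = FALSE, alternative = "less",
                  exact = n_eff <= 25L, correct = TRUE))
  }
  med_diff <- median(mut) - median(wt)
  list(statistic = unname(wt_res$statistic),
       p_value = wt_res$p.value,
       direction = if (med_diff < 0) "reduction" else if (med_diff > 0) "increase" else "none",
       method = wt_res$method,
       n = n_eff)
}

#' Class-wise abundance summary across genotypes
#'
#' For each locus class (motif-dependent / motif-independent) and each
#' mutant genotype, reports the median RPM, the median fold change relative
#' to wild type (with a 0.1 RPM pseudocount to avoid division by zero;
#' ranks in the test are computed on the raw values), and the one-sided
#' depletion p-value from [reduction_test()].
#'
#' @param table A `locus_count_table` with RPM (see [normalize_rpm()]).
#' @param wt_sample Sample id of the wild-type column (default: the sample
#'   whose genotype is `wild_type`).
#' @param pseudo RPM pseudocount for fold changes (default 0.1).
#' @return data.frame with one row per class x mutant sample: `class_label`,
#'   `sample_id`, `genotype`, `n_loci`, `median_rpm_wt`, `median_rpm`,
#'   `median_fold_change`, `p_reduction`.
#' @export
class_summary <- function(table, wt_sample = NULL, pseudo = 0.1) {
  if (is.null(table$rpm)) table <- normalize_rpm(table)
  if (is.null(wt_sample)) {
    wt_sample <- table$samples$sample_id[table$samples$genotype == "wild_type"]
    if (length(wt_sample) != 1L)
      stop_fmt("specify wt_sample (found %d wild_type samples)", length(wt_sample))
  }
  muts <- setdiff(table$samples$sample_id, wt_sample)
  classes <- unique(table$loci$class_label)
  rows <- list()
  for (cl in classes) {
    sel <- table$loci$class_label == cl
    if (sum(sel) < 10L)
      warn_fmt("class '%s' has %d loci; low power", cl, sum(sel))
    wt <- table$rpm[sel, wt_sample]
    for (s in muts) {
      mut <- table$rpm[sel, s]
      rt <- reduction_test(wt, mut, paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        class_label = cl, sample_id = s,
        genotype = table$samples$genotype[table$samples$sample_id == s],
        n_loci = sum(sel),
        median_rpm_wt = median(wt),
        median_rpm = median(mut),
        median_fold_change = median((mut + pseudo) / (wt + pseudo)),
        p_reduction = rt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
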