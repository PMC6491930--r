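#' Call per-gene ancestry genotypes
#'
#' Maps local-ancestry segments onto gene intervals to produce, for every
#' (gene, individual), an unordered pair of haplotype ancestry labels. A
#' haplotype receives a label at a gene iff the gene interval is fully
#' contained in a single segment of that haplotype whose certainty is at
#' least `min_certainty`; a gene straddling a segment boundary gets no
#' label on that haplotype (conservative containment rule). Individual
#' cells therefore carry 0, 1, or 2 ancestry assignments.
#'
#' @param segments Validated segment tibble from [read_ancestry_segments()].
#' @param genes Gene annotation tibble from [read_gene_annotations()].
#' @param min_certainty Minimum segment certainty for an assignment
#'   (default 0.99, matching high-confidence local-ancestry practice).
#' @param population Optional population id stored as an attribute and
#'   carried into downstream result tables.
#'
#' @return A tibble of ancestry genotype calls: one row per
#'   (gene, individual) with columns `gene_id`, `individual_id`, `anc1`,
#'   `anc2`. The pair is unordered and stored canonically: both labels
#'   sorted when two are assigned; a single label in `anc1` (with `anc2`
#'   `NA`) when one is assigned; both `NA` when none. The full
#'   gene-by-individual grid is present, so per-gene full-pair counts can
#'   be read off directly (see [apply_ancestry_threshold()]).
#' @export
call_gene_ancestry <- function(segments, genes, min_certainty = 0.99,
                               population = NULL) {
  if (min_certainty < 0) abort("min_certainty must be >= 0")
  segments <- as_tibble(segments)
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) abort("No genes supplied")
  individuals <- sort(unique(segments$individual_id))
  if (length(individuals) == 0) abort("No individuals in segment set")

  usable <- filter(segments, .data$certainty >= min_certainty)
  grid <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    individual_id = individuals
  )
  if (nrow(usable) > 0) {
    seg_gr <- GenomicRanges::GRanges(
      seqnames = usable$chrom,
      ranges = IRanges::IRanges(start = usable$start + 1, end = usable$end)
    )
    gene_gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end)
    )
    hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr, type = "within")
    assign_tbl <- tibble(
      gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
      individual_id = usable$individual_id[S4Vectors::subjectHits(hits)],
      haplotype = usable$haplotype[S4Vectors::subjectHits(hits)],
      ancestry = usable$ancestry[S4Vectors::subjectHits(hits)]
    )
    wide <- assign_tbl %>%
      mutate(haplotype = paste0("h", .data$haplotype)) %>%
      tidyr::pivot_wider(
        names_from = "haplotype", values_from = "ancestry"
      )
    if (!"h0" %in% names(wide)) wide$h0 <- NA_character_
    if (!"h1" %in% names(wide)) wide$h1 <- NA_character_
    calls <- left_join(grid, wide, by = c("gene_id", "individual_id"))
  } else {
    calls <- mutate(grid, h0 = NA_character_, h1 = NA_character_)
  }
  calls <- canonicalize_calls(calls)
  attr(calls, "population_id") <- population
  attr(calls, "min_certainty") <- min_certainty
  class(calls) <- c("ancestry_calls", class(calls))
  calls
}

# Store the unordered pair canonically: sorted when full, single in anc1.
canonicalize_calls <- function(calls) {
  h0 <- calls$h0
  h1 <- calls$h1
  anc1 <- ifelse(is.na(h0), h1, ifelse(is.na(h1), h0, pmin(h0, h1)))
  anc2 <- ifelse(is.na(h0) | is.na(h1), NA_character_, pmax(h0, h1))
  calls$h0 <- NULL
  calls$h1 <- NULL
  calls$anc1 <- anc1
  calls$anc2 <- anc2
  calls
}

#' Construct an ancestry-call table directly from labels
#'
#' Convenience constructor used by the simulator and in tests: takes
#' per-(gene, individual) haplotype labels and returns the same canonical
#' call tibble as [call_gene_ancestry()].
#'
#' @param gene_id,individual_id,hap1,hap2 Vectors of equal length;
#'   `hap1`/`hap2` are ancestry labels or `NA`.
#' @param population Optional population id attribute.
#' @return An `ancestry_calls` tibble.
#' @export
ancestry_calls <- function(gene_id, individual_id, hap1, hap2,
                           population = NULL) {
  assert_ancestry_labels(c(hap1, hap2))
  calls <- canonicalize_calls(tibble(
    gene_id = gene_id, individual_id = individual_id, h0 = hap1, h1 = hap2
  ))
  attr(calls, "population_id") <- population
  class(calls) <- c("ancestry_calls", class(calls))
  calls
}

#' Per-gene counts of fully assigned individuals
#'
#' @param calls An ancestry-call tibble.
#' @return A tibble with `gene_id` and `n_pairs`, the number of individuals
#'   with both haplotypes assigned at that gene.
#' @export
gene_pair_counts <- function(calls) {
  calls %>%
    group_by(.data$gene_id) %>%
    summarise(n_pairs = sum(!is.na(.data$anc2)), .groups = "drop")
}

#' Apply the ancestry-genotype inclusion threshold
#'
#' Computes, across genes, the mean and standard deviation of the number of
#' individuals with two ancestry assignments (`n_pairs`), and retains genes
#' whose count is strictly above `mean - sd`. When the standard deviation is
#' zero (all genes equally covered) the rule degenerates to `n_pairs >=
#' mean`, so uniformly covered gene sets are retained rather than dropped
#' wholesale.
#'
#' @param calls An ancestry-call tibble.
#' @return The filtered call tibble. The threshold and the summary
#'   statistics are attached as attributes `threshold`, `mean_pairs`,
#'   `sd_pairs`, and `n_genes_dropped`.
#' @export
apply_ancestry_threshold <- function(calls) {
  counts <- gene_pair_counts(calls)
  if (nrow(counts) == 0 || all(counts$n_pairs == 0)) {
    abort("no callable genes: every gene is all-missing")
  }
  mean_pairs <- mean(counts$n_pairs)
  sd_pairs <- sd(counts$n_pairs)
  if (length(counts$n_pairs) == 1 || sd_pairs == 0) {
    threshold <- mean_pairs
    keep <- counts$n_pairs >= threshold
  } else {
    threshold <- mean_pairs - sd_pairs
    keep <- counts$n_pairs > threshold
  }
  kept_genes <- counts$gene_id[keep]
  out <- filter(calls, .data$gene_id %in% kept_genes)
  for (a in c("population_id", "min_certainty")) {
    attr(out, a) <- attr(calls, a)
  }
  class(out) <- unique(c("ancestry_calls", class(out)))
  attr(out, "threshold") <- threshold
  attr(out, "mean_pairs") <- mean_pairs
  attr(out, "sd_pairs") <- sd_pairs
  attr(out, "n_genes_dropped") <- sum(!keep)
  out
}

#' Serialize an ancestry genotype matrix as TSV
#'
#' Writes a genes-by-individuals grid with cells like `"AFR/EUR"` (full
#' pair), `"EUR"` (single assignment) or `"."` (missing).
#'
#' @param calls An ancestry-call tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ancestry_matrix <- function(calls, path) {
  cell <- ifelse(is.na(calls$anc1), ".",
    ifelse(is.na(calls$anc2), calls$anc1,
      paste0(calls$anc1, "/", calls$anc2)
    )
  )
  wide <- calls %>%
    mutate(cell = cell) %>%
    select("gene_id", "individual_id", "cell") %>%
    tidyr::pivot_wider(names_from = "individual_id", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read an ancestry genotype matrix from TSV
#'
#' Inverse of [write_ancestry_matrix()].
#'
#' @param path TSV path written by [write_ancestry_matrix()].
#' @param population Optional population id attribute.
#' @return An `ancestry_calls` tibble.
#' @export
read_ancestry_matrix <- function(path, population = NULL) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene_id",
    names_to = "individual_id", values_to = "cell"
  )
  parts <- strsplit(ifelse(long$cell == ".", NA_character_, long$cell),
    "/",
    fixed = TRUE
  )
  hap1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, character(1))
  hap2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
  ancestry_calls(long$gene_id, long$individual_id, hap1, hap2,
    population = population
  )
}

#' Convert per-gene calls to ancestry segments
#'
#' Emits one segment per assigned (gene, individual, haplotype) covering the
#' gene's interval, with certainty 1. Useful for writing simulated data in
#' the segment exchange format; [call_gene_ancestry()] on the result
#' recovers the original calls when gene intervals do not overlap.
#'
#' @param calls An ancestry-call tibble (full pairs and singles included).
#' @param genes Gene annotations giving each gene's interval.
#' @return A segment tibble as returned by [read_ancestry_segments()].
#' @export
calls_to_segments <- function(calls, genes) {
  full <- calls %>%
    filter(!is.na(.data$anc1)) %>%
    left_join(select(genes, "gene_id", "chrom", "start", "end"), by = "gene_id")
  if (anyNA(full$chrom)) {
    abort("calls reference gene(s) absent from the annotation")
  }
  seg1 <- full %>%
    transmute_seg(anc_col = "anc1", hap = 0L)
  seg2 <- full %>%
    filter(!is.na(.data$anc2)) %>%
    transmute_seg(anc_col = "anc2", hap = 1L)
  arrange(
    bind_rows(seg1, seg2),
    .data$individual_id, .data$haplotype, .data$chrom, .data$start
  )
}

transmute_seg <- function(df, anc_col, hap) {
  tibble(
    individual_id = df$individual_id,
    haplotype = hap,
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    ancestry = df[[anc_col]],
    certainty = 1
  )
}
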