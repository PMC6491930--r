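#' Locus ancestry fractions
#'
#' For each gene, the fractions of African, European and Native American
#' labels among the haplotypes of fully assigned individuals (both copies
#' labelled). These fractions play the role of the three allele frequencies
#' in the triallelic Hardy-Weinberg null. Individuals with 0 or 1
#' assignments are excluded so that observed and expected counts refer to
#' the same cohort.
#'
#' @param calls An ancestry-call tibble (see [call_gene_ancestry()]).
#' @return A tibble with `gene_id`, `n_pairs`, and fraction columns
#'   `f_AFR`, `f_EUR`, `f_NAT` summing to 1 per gene. Genes with no full
#'   pairs are dropped; an error is raised if no gene has any.
#' @export
locus_ancestry_fractions <- function(calls) {
  full <- filter(calls, !is.na(.data$anc2))
  if (nrow(full) == 0) abort("no ancestry pairs at any locus")
  long <- tibble(
    gene_id = rep(full$gene_id, 2),
    ancestry = c(full$anc1, full$anc2)
  )
  counts <- long %>%
    count(.data$gene_id, .data$ancestry) %>%
    tidyr::pivot_wider(
      names_from = "ancestry", values_from = "n", values_fill = 0
    )
  for (a in .ANCESTRIES) if (!a %in% names(counts)) counts[[a]] <- 0
  total <- counts$AFR + counts$EUR + counts$NAT
  tibble(
    gene_id = counts$gene_id,
    n_pairs = total / 2,
    f_AFR = counts$AFR / total,
    f_EUR = counts$EUR / total,
    f_NAT = counts$NAT / total
  )
}

#' Hardy-Weinberg expected homozygote and heterozygote counts
#'
#' Under random mating with three ancestry "alleles" at frequencies
#' a, e, n (a + e + n = 1), genotype frequencies follow the trinomial
#' expansion (a + e + n)^2: expected ancestry homozygosity is
#' a^2 + e^2 + n^2 and heterozygosity is 2ae + 2an + 2en. Frequencies are
#' scaled by the number of fully assigned individuals to give expected
#' counts (real-valued; no rounding).
#'
#' @param f_AFR,f_EUR,f_NAT Ancestry fraction vectors (recycled together);
#'   each triple must be non-negative and sum to 1.
#' @param n_pairs Number of individuals with two assignments per locus.
#' @return A tibble with columns `exp_hom` and `exp_het`;
#'   `exp_hom + exp_het == n_pairs`.
#' @examples
#' hw_expected_counts(0.5, 0.3, 0.2, 100) # exp_hom 38, exp_het 62
#' @export
hw_expected_counts <- function(f_AFR, f_EUR, f_NAT, n_pairs) {
  s <- f_AFR + f_EUR + f_NAT
  if (any(abs(s - 1) > 1e-9)) abort("ancestry fractions must sum to 1")
  if (any(c(f_AFR, f_EUR, f_NAT) < 0)) abort("ancestry fractions must be >= 0")
  hom <- f_AFR^2 + f_EUR^2 + f_NAT^2
  tibble(
    exp_hom = hom * n_pairs,
    exp_het = (1 - hom) * n_pairs
  )
}

#' Observed ancestry homozygote and heterozygote counts
#'
#' Counts, per gene, individuals whose two haplotype labels agree
#' (ancestry homozygotes) or differ (heterozygotes). Cells with fewer than
#' two assignments are excluded.
#'
#' @param calls An ancestry-call tibble.
#' @return A tibble with `gene_id`, `obs_hom`, `obs_het`, `n_pairs`.
#' @export
observed_counts <- function(calls) {
  calls %>%
    group_by(.data$gene_id) %>%
    summarise(
      obs_hom = sum(!is.na(.data$anc2) & .data$anc1 == .data$anc2),
      obs_het = sum(!is.na(.data$anc2) & .data$anc1 != .data$anc2),
      n_pairs = sum(!is.na(.data$anc2)),
      .groups = "drop"
    )
}

#' Per-gene observed and expected count table
#'
#' Assembles the per-gene 2x2 underlying the assortative mating index:
#' observed vs Hardy-Weinberg-expected homozygote/heterozygote counts,
#' along with the locus ancestry fractions and per-ancestry homozygote
#' counts used by the driver decomposition.
#'
#' @param calls An ancestry-call tibble.
#' @return A tibble with one row per gene carrying `n_pairs`, fractions
#'   `f_AFR`/`f_EUR`/`f_NAT`, `obs_hom`, `obs_het`, `exp_hom`, `exp_het`,
#'   and per-ancestry homozygote counts `hom_AFR`, `hom_EUR`, `hom_NAT`.
#'   Genes with no full pairs are dropped.
#' @export
gene_count_table <- function(calls) {
  fr <- locus_ancestry_fractions(calls)
  obs <- observed_counts(calls)
  hom_anc <- calls %>%
    filter(!is.na(.data$anc2) & .data$anc1 == .data$anc2) %>%
    count(.data$gene_id, ancestry = .data$anc1) %>%
    mutate(ancestry = paste0("hom_", .data$ancestry)) %>%
    tidyr::pivot_wider(
      names_from = "ancestry", values_from = "n", values_fill = 0
    )
  ex <- hw_expected_counts(fr$f_AFR, fr$f_EUR, fr$f_NAT, fr$n_pairs)
  out <- fr %>%
    mutate(exp_hom = ex$exp_hom, exp_het = ex$exp_het) %>%
    left_join(select(obs, -"n_pairs"), by = "gene_id") %>%
    left_join(hom_anc, by = "gene_id")
  for (a in paste0("hom_", .ANCESTRIES)) {
    if (!a %in% names(out)) out[[a]] <- 0L
    out[[a]][is.na(out[[a]])] <- 0L
  }
  out
}

#' Gene-level assortative mating index
#'
#' Adds the AMI, `ln((obs_hom/exp_hom) / (obs_het/exp_het))`, to a per-gene
#' count table. Positive values indicate excess ancestry homozygosity
#' (assortative mating), negative values excess heterozygosity
#' (disassortative mating). When an observed cell is zero, the
#' Haldane-Anscombe continuity correction (+0.5 to all four cells) is
#' applied and the value flagged in `ami_corrected`. Genes where either
#' expected cell is zero (ancestry fixed at the locus) have no defined
#' index: `ami` is `NA` and `ami_excluded` records the reason.
#'
#' @param counts A per-gene count table from [gene_count_table()], or any
#'   tibble with `obs_hom`, `obs_het`, `exp_hom`, `exp_het`.
#' @return The input with columns `ami`, `ami_corrected`, `ami_excluded`
#'   appended.
#' @export
gene_ami <- function(counts) {
  obs_hom <- counts$obs_hom
  obs_het <- counts$obs_het
  exp_hom <- counts$exp_hom
  exp_het <- counts$exp_het
  excluded <- ifelse(exp_hom <= 0 | exp_het <= 0, "fixed locus", NA_character_)
  corrected <- !is.na(obs_hom) & (obs_hom == 0 | obs_het == 0) & is.na(excluded)
  k <- ifelse(corrected, 0.5, 0)
  ami <- log(((obs_hom + k) / (exp_hom + k)) / ((obs_het + k) / (exp_het + k)))
  ami[!is.na(excluded)] <- NA_real_
  counts$ami <- ami
  counts$ami_corrected <- corrected
  counts$ami_excluded <- excluded
  counts
}
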