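#' Ancestry-specific drivers of assortative mating (AH profile)
#'
#' Decomposes a gene set's homozygosity excess by ancestry. For ancestry
#' anc and gene g, let `obs` be the number of individuals homozygous for
#' anc at g and `exp = f_anc(g)^2 * n_pairs(g)` its triallelic
#' Hardy-Weinberg expectation. The driver statistic is the sum of relative
#' deviations over the set's genes:
#' \deqn{AH_{anc} = \sum_g \frac{obs_g^{anc} - exp_g^{anc}}{exp_g^{anc}}}
#' Positive values mean that ancestry contributes excess homozygosity
#' (drives assortative mating); negative values a deficit. Genes where the
#' ancestry is absent (`exp = 0`) are skipped for that ancestry and
#' counted in `n_genes_skipped`. A per-gene mean (`ah_mean`) and the
#' absolute deviation sum (`excess_hom`) are emitted alongside for
#' interpretability.
#'
#' @param counts Per-gene count table from [gene_count_table()], restricted
#'   to the gene set of interest.
#' @param phenotype_id,population_id Optional identifiers for the output.
#' @return A tibble with one row per ancestry: `ancestry`, `ah` (sum of
#'   relative deviations), `ah_mean` (per-gene mean), `excess_hom` (sum of
#'   `obs - exp`), `n_genes_used`, `n_genes_skipped`.
#' @export
ancestry_homozygosity <- function(counts, phenotype_id = NA_character_,
                                  population_id = NA_character_) {
  if (nrow(counts) == 0) abort("empty gene set")
  purrr::map_dfr(.ANCESTRIES, function(anc) {
    f <- counts[[paste0("f_", anc)]]
    obs <- counts[[paste0("hom_", anc)]]
    expd <- f^2 * counts$n_pairs
    use <- expd > 0
    rel <- (obs[use] - expd[use]) / expd[use]
    tibble(
      phenotype_id = phenotype_id,
      population_id = population_id,
      ancestry = anc,
      ah = sum(rel),
      ah_mean = if (any(use)) mean(rel) else NA_real_,
      excess_hom = sum(obs[use] - expd[use]),
      n_genes_used = sum(use),
      n_genes_skipped = sum(!use)
    )
  })
}

#' Global ancestry fractions from local-ancestry data
#'
#' Per-individual genome-wide ancestry proportions computed from local
#' assignments. Given an ancestry-call table, the fraction of each
#' individual's assigned gene-haplotypes per ancestry; given a segment
#' table, the fraction of assigned base pairs. Fractions sum to 1 over
#' the assigned material of each individual.
#'
#' @param x An ancestry-call tibble (columns `anc1`/`anc2`) or a segment
#'   tibble (columns `start`/`end`/`ancestry`).
#' @return A tibble with `individual_id`, `f_AFR`, `f_EUR`, `f_NAT`.
#'   Individuals with nothing assigned are excluded with a message.
#' @export
global_ancestry_fractions <- function(x) {
  if (all(c("anc1", "anc2") %in% names(x))) {
    long <- tibble(
      individual_id = rep(x$individual_id, 2),
      ancestry = c(x$anc1, x$anc2),
      weight = 1
    ) %>% filter(!is.na(.data$ancestry))
  } else if (all(c("start", "end", "ancestry") %in% names(x))) {
    long <- tibble(
      individual_id = x$individual_id,
      ancestry = x$ancestry,
      weight = x$end - x$start
    )
  } else {
    abort("x must be an ancestry-call or segment tibble")
  }
  all_ind <- unique(x$individual_id)
  fr <- long %>%
    group_by(.data$individual_id, .data$ancestry) %>%
    summarise(w = sum(.data$weight), .groups = "drop_last") %>%
    mutate(f = .data$w / sum(.data$w)) %>%
    ungroup() %>%
    select(-"w") %>%
    tidyr::pivot_wider(
      names_from = "ancestry", values_from = "f", values_fill = 0,
      names_prefix = "f_"
    )
  for (a in paste0("f_", .ANCESTRIES)) if (!a %in% names(fr)) fr[[a]] <- 0
  excluded <- setdiff(all_ind, fr$individual_id)
  if (length(excluded) > 0) {
    inform(sprintf(
      "global_ancestry_fractions: excluded %d individual(s) with no assignments",
      length(excluded)
    ))
  }
  select(fr, "individual_id", "f_AFR", "f_EUR", "f_NAT")
}

#' Inter-individual variation of ancestry components
#'
#' Coefficient of variation (sample sd / mean) of per-individual global
#' ancestry fractions, for each of the three continental components.
#' Ancestry components that drive assortative mating are expected to show
#' elevated inter-individual variance, hence elevated CV. Raw variance is
#' emitted alongside.
#'
#' @param fractions Tibble from [global_ancestry_fractions()] (>= 2
#'   individuals).
#' @param population_id Optional identifier for the output.
#' @return A tibble with one row per ancestry: `ancestry`, `mean`, `sd`,
#'   `variance`, `cv` (`NA` with `cv_undefined = TRUE` when the mean
#'   fraction is 0).
#' @export
ancestry_cv <- function(fractions, population_id = NA_character_) {
  if (nrow(fractions) < 2) abort("need >= 2 individuals for a CV")
  purrr::map_dfr(.ANCESTRIES, function(anc) {
    f <- fractions[[paste0("f_", anc)]]
    m <- mean(f)
    s <- sd(f)
    tibble(
      population_id = population_id,
      ancestry = anc,
      mean = m,
      sd = s,
      variance = s^2,
      cv = if (m > 0) s / m else NA_real_,
      cv_undefined = m == 0
    )
  })
}
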