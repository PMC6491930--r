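#' Fit the assortative-mating analysis for one population
#'
#' Runs the core analysis chain on one population's ancestry calls:
#' ancestry-genotype inclusion threshold, gene-set filtering to callable
#' genes, optional LD pruning, per-gene observed/expected counts and AMI,
#' Mantel-Haenszel meta-analysis per gene set, BH q-values over the
#' population's phenotype family, and per-ancestry driver (AH) profiles.
#'
#' @param calls An ancestry-call tibble (see [call_gene_ancestry()]).
#' @param sets Long gene-set tibble (see [read_gene_sets()]).
#' @param ld Optional LD table (see [read_ld_table()]).
#' @param r2_max Maximum tolerated within-set pairwise r² (default 0.1).
#' @param min_set_size Minimum genes per set after filtering (default 2).
#' @param population Population id for result tables (defaults to the
#'   calls attribute, else `"pop"`).
#' @param apply_threshold Apply the `mean - sd` inclusion threshold
#'   (default TRUE).
#'
#' @return An object of class `ami_fit`: a list with `gene_table` (per
#'   gene counts + AMI), `phenotype_results` (per set pooled log OR, CI,
#'   p, q), `ah_profiles`, `sets` (the filtered sets actually analysed),
#'   `threshold` (value and summary stats), `stage_counts`, and
#'   `population_id`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
ami_analysis <- function(calls, sets, ld = NULL, r2_max = 0.1,
                         min_set_size = 2, population = NULL,
                         apply_threshold = TRUE) {
  population <- population %||% attr(calls, "population_id") %||% "pop"
  n_sets_in <- length(unique(sets$phenotype_id))
  n_genes_in <- length(unique(calls$gene_id))
  if (apply_threshold) {
    kept <- apply_ancestry_threshold(calls)
  } else {
    kept <- calls
    attr(kept, "threshold") <- 0
    attr(kept, "mean_pairs") <- NA_real_
    attr(kept, "sd_pairs") <- NA_real_
  }
  callable <- unique(kept$gene_id)
  sets_f <- filter_gene_sets(sets, callable, min_size = min_set_size)
  if (!is.null(ld)) {
    sets_f <- ld_prune_gene_sets(sets_f, ld, r2_max = r2_max, min_size = min_set_size)
  }
  gene_table <- gene_ami(gene_count_table(kept))
  results <- purrr::map_dfr(unique(sets_f$phenotype_id), function(ph) {
    ids <- sets_f$gene_id[sets_f$phenotype_id == ph]
    meta_ami(
      filter(gene_table, .data$gene_id %in% ids),
      phenotype_id = ph, population_id = population
    )
  })
  results$category <- sets_f$category[match(results$phenotype_id, sets_f$phenotype_id)]
  results$q_value <- bh_qvalues(results$p_value)
  ah <- purrr::map_dfr(unique(sets_f$phenotype_id), function(ph) {
    ids <- sets_f$gene_id[sets_f$phenotype_id == ph]
    ancestry_homozygosity(
      filter(gene_table, .data$gene_id %in% ids),
      phenotype_id = ph, population_id = population
    )
  })
  structure(
    list(
      gene_table = mutate(gene_table, population_id = population),
      phenotype_results = results,
      ah_profiles = ah,
      sets = sets_f,
      threshold = list(
        value = attr(kept, "threshold"),
        mean_pairs = attr(kept, "mean_pairs"),
        sd_pairs = attr(kept, "sd_pairs")
      ),
      stage_counts = list(
        n_genes_input = n_genes_in,
        n_genes_callable = length(callable),
        n_sets_input = n_sets_in,
        n_sets_analyzed = length(unique(sets_f$phenotype_id))
      ),
      population_id = population
    ),
    class = "ami_fit"
  )
}

#' @export
print.ami_fit <- function(x, ...) {
  cat(sprintf(
    "AMI analysis for population '%s': %d callable genes, %d gene sets\n",
    x$population_id, x$stage_counts$n_genes_callable,
    x$stage_counts$n_sets_analyzed
  ))
  sig <- sum(x$phenotype_results$q_value < 0.05, na.rm = TRUE)
  cat(sprintf(
    "  mean gene AMI = %.3f; %d set(s) significant at q < 0.05\n",
    mean(x$gene_table$ami, na.rm = TRUE), sig
  ))
  invisible(x)
}

#' Tidy the per-phenotype results of an AMI fit
#'
#' @param x An `ami_fit` object.
#' @param ... Unused.
#' @return The per-phenotype results tibble (pooled log OR, CI, p, q).
#' @export
tidy.ami_fit <- function(x, ...) {
  as_tibble(x$phenotype_results)
}

#' One-row summary of an AMI fit
#'
#' @param x An `ami_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: population, callable genes, sets analysed,
#'   mean/sd of gene-level AMI, count of sets significant at q < 0.05.
#' @export
glance.ami_fit <- function(x, ...) {
  tibble(
    population_id = x$population_id,
    n_genes_callable = x$stage_counts$n_genes_callable,
    n_sets_analyzed = x$stage_counts$n_sets_analyzed,
    mean_gene_ami = mean(x$gene_table$ami, na.rm = TRUE),
    sd_gene_ami = sd(x$gene_table$ami, na.rm = TRUE),
    n_significant = sum(x$phenotype_results$q_value < 0.05, na.rm = TRUE),
    threshold = x$threshold$value
  )
}
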