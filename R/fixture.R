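#' Generate a self-consistent synthetic dataset on disk
#'
#' Simulates four admixed populations with distinct ancestry profiles
#' (one European-heavy three-way mixture, one balanced European/Native
#' American, one Native-American-heavy, one European-dominated) and writes
#' everything the analysis pipeline consumes: per-population segment TSVs,
#' a gene BED file, a GMT of polygenic gene sets, a pairwise gene-gene LD
#' table, and a YAML run configuration. Useful for documentation,
#' end-to-end tests and power studies.
#'
#' When `trait_assortment_strength > 0`, one population (`PopB`) mates
#' assortatively on a designated trait gene set of `trait_set_size` genes
#' (emitted as the first GMT entry, `TraitInjected`), while the others
#' keep their genome-wide settings — an injected trait-specific signal
#' with known truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param n_individuals,n_genes,n_generations Simulation dimensions per
#'   population (defaults 80 individuals, 300 genes, 5 mate-choice
#'   generations).
#' @param n_burnin Random-mating generations before mate choice (default 3:
#'   the fixture populations represent recently admixed cohorts that still
#'   carry broad inter-individual ancestry variation, as real Latin
#'   American populations do).
#' @param trait_set_size,trait_assortment_strength Injected trait-specific
#'   assortment (0 = none).
#' @return Invisibly, a list with the written `paths` and the parsed
#'   `config`.
#' @export
generate_fixture_dataset <- function(dir, seed = 1,
                                     n_individuals = 80, n_genes = 300,
                                     n_generations = 5, n_burnin = 3,
                                     trait_set_size = 0,
                                     trait_assortment_strength = 0) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) abort(sprintf("cannot create directory %s", dir))
  }
  profiles <- list(
    PopA = list(pi = c(AFR = 0.08, EUR = 0.65, NAT = 0.27), strength = 3),
    PopB = list(pi = c(AFR = 0.05, EUR = 0.45, NAT = 0.50), strength = 5),
    PopC = list(pi = c(AFR = 0.03, EUR = 0.20, NAT = 0.77), strength = 3),
    PopD = list(pi = c(AFR = 0.15, EUR = 0.70, NAT = 0.15), strength = 0)
  )
  genes <- synthetic_gene_annotations(n_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  with_seed_or_not(seed, {
    trait_genes <- NULL
    if (trait_assortment_strength > 0 && trait_set_size > 0) {
      trait_genes <- sort(sample(gene_ids, trait_set_size))
    }
    seg_paths <- character(0)
    for (pop in names(profiles)) {
      prof <- profiles[[pop]]
      if (pop == "PopB" && !is.null(trait_genes)) {
        sim <- simulate_admixed_population(
          n_individuals = n_individuals, n_genes = n_genes,
          n_generations = n_generations, n_burnin = n_burnin,
          founder_proportions = prof$pi,
          assortment_strength = trait_assortment_strength,
          assort_on = "gene_subset", trait_genes = trait_genes
        )
      } else {
        sim <- simulate_admixed_population(
          n_individuals = n_individuals, n_genes = n_genes,
          n_generations = n_generations, n_burnin = n_burnin,
          founder_proportions = prof$pi,
          assortment_strength = prof$strength
        )
      }
      p <- file.path(dir, sprintf("segments_%s.tsv", pop))
      write_ancestry_segments(calls_to_segments(sim$calls, genes), p)
      seg_paths[pop] <- p
    }

    bed_path <- file.path(dir, "genes.bed")
    readr::write_tsv(
      tibble(
        chrom = genes$chrom, start = genes$start, end = genes$end,
        name = genes$gene_id, score = 0L, strand = "."
      ),
      bed_path,
      col_names = FALSE, progress = FALSE
    )

    categories <- c("anthropometric", "neurological", "HLA", "other")
    set_sizes <- c(2, 3, 5, 8, 10, 12, 15, 20, 25, 30)
    sets <- purrr::map_dfr(seq_along(set_sizes), function(i) {
      tibble(
        phenotype_id = sprintf("Trait%02d", i),
        category = categories[((i - 1) %% 4) + 1],
        gene_id = sort(sample(gene_ids, set_sizes[i]))
      )
    })
    if (!is.null(trait_genes)) {
      sets <- bind_rows(
        tibble(
          phenotype_id = "TraitInjected", category = "anthropometric",
          gene_id = trait_genes
        ),
        sets
      )
    }
    gmt_path <- file.path(dir, "gene_sets.gmt")
    write_gene_sets(sets, gmt_path)

    # a sparse LD table among set genes, mostly independent pairs
    set_genes <- unique(sets$gene_id)
    n_ld <- min(20, choose(length(set_genes), 2))
    pair_a <- sample(set_genes, n_ld, replace = TRUE)
    pair_b <- sample(set_genes, n_ld, replace = TRUE)
    keep <- pair_a != pair_b
    ld <- tibble(
      gene_a = pair_a[keep], gene_b = pair_b[keep],
      r2 = round(stats::rbeta(sum(keep), 1, 8), 4)
    ) %>% distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
    ld_path <- file.path(dir, "ld_table.tsv")
    readr::write_tsv(ld, ld_path, progress = FALSE)

    config <- list(
      segments = as.list(seg_paths),
      genes_bed = bed_path,
      gene_sets_gmt = gmt_path,
      ld_table = ld_path,
      min_certainty = 0.99,
      r2_max = 0.1,
      min_set_size = 2,
      permutations = list(
        random_mating = FALSE, n_virtual = 10000,
        gene_set = FALSE, n_perms = 1000
      ),
      out_dir = file.path(dir, "results"),
      seed = seed
    )
    config_path <- file.path(dir, "config.yaml")
    yaml::write_yaml(config, config_path)

    invisible(list(
      paths = list(
        segments = seg_paths, genes_bed = bed_path, gene_sets_gmt = gmt_path,
        ld_table = ld_path, config = config_path
      ),
      config = config
    ))
  })
}
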