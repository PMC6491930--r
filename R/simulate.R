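#' Simulate an admixed population with tunable assortative mating
#'
#' Forward-in-time simulator of a diploid admixed population carrying
#' per-gene haplotype ancestry labels in \{AFR, EUR, NAT\}. Founders are
#' single-ancestry individuals (homozygous for one ancestry at every gene)
#' sampled from `founder_proportions`. Each subsequent generation:
#'
#' 1. every individual's ancestry vector is computed — global fractions
#'    over all genes, or over `trait_genes` only when
#'    `assort_on = "gene_subset"` (optionally restricted to the
#'    component(s) in `assort_ancestry`);
#' 2. monogamous mate pairs are drawn by weighted sequential sampling
#'    without self-mating, the weight of a candidate pair being
#'    `exp(-assortment_strength * d)` with `d` the Euclidean distance
#'    between the two ancestry vectors divided by the generation's mean
#'    pairwise distance (a scale-free preference, so a given strength
#'    discriminates equally whether ancestry variation is wide or already
#'    homogenized; `assortment_strength = 0` is random mating);
#' 3. each pair produces enough offspring to keep the population size
#'    constant; each offspring gene-haplotype is drawn uniformly from the
#'    corresponding parent's two gene copies, independently across genes
#'    (free recombination).
#'
#' The first `n_burnin` generations mate randomly regardless of
#' `assortment_strength`, modelling an admixture pulse followed by
#' admixture homogenization before mate choice acts — without it, strong
#' assortment from single-ancestry founders simply prevents admixture and
#' every locus stays homozygous. Mate-choice generations follow.
#'
#' Assortative mating in this model changes genotype frequencies (excess
#' ancestry homozygosity) but not expected ancestry fractions, which stay
#' at the founder proportions up to drift.
#'
#' @param n_individuals Diploid population size per generation (default
#'   200).
#' @param n_genes Number of unlinked gene loci (default 500).
#' @param n_generations Number of mate-choice generations after burn-in
#'   (default 5; with `n_burnin = 0` and `n_generations = 0` the founder
#'   population is returned).
#' @param n_burnin Random-mating generations between the founding
#'   admixture pulse and the mate-choice phase (default 10, roughly the
#'   post-admixture timescale over which individual admixture proportions
#'   homogenize).
#' @param founder_proportions Named fractions `c(AFR=, EUR=, NAT=)`
#'   summing to 1 (default `c(0.15, 0.55, 0.30)`, a typical three-way
#'   admixed profile).
#' @param assortment_strength Non-negative mate-matching strength (0 =
#'   random mating).
#' @param assort_on `"global_ancestry"` (default) or `"gene_subset"`
#'   (similarity computed over `trait_genes` only).
#' @param trait_genes Gene ids (of the form `g0001`, ...) defining the
#'   trait set when `assort_on = "gene_subset"`.
#' @param assort_ancestry Optional subset of `c("AFR","EUR","NAT")`;
#'   mate distance is computed on these components only (default all
#'   three), letting one ancestry drive mate choice.
#' @param seed Optional integer seed; identical seeds give identical
#'   simulations.
#'
#' @return An object of class `admix_sim`: a list with
#'   * `calls` — the final generation as an [ancestry_calls()] tibble,
#'   * `truth` — a list with `config` (echo of all parameters),
#'     `fractions` (final per-individual global ancestry fractions), and
#'     `per_generation` (tibble of generation, realized mate-pair
#'     ancestry correlation, and mean ancestry fractions),
#'   * `genes` — synthetic gene annotations for the simulated loci.
#' @export
simulate_admixed_population <- function(n_individuals = 200,
                                        n_genes = 500,
                                        n_generations = 5,
                                        n_burnin = 10,
                                        founder_proportions = c(
                                          AFR = 0.15, EUR = 0.55, NAT = 0.30
                                        ),
                                        assortment_strength = 0,
                                        assort_on = c(
                                          "global_ancestry", "gene_subset"
                                        ),
                                        trait_genes = NULL,
                                        assort_ancestry = NULL,
                                        seed = NULL) {
  assort_on <- match.arg(assort_on)
  if (assortment_strength < 0) abort("assortment_strength must be >= 0")
  if (n_individuals < 2) abort("n_individuals must be >= 2")
  pi0 <- founder_proportions[.ANCESTRIES]
  if (anyNA(pi0) || abs(sum(pi0) - 1) > 1e-9 || any(pi0 < 0)) {
    abort("founder_proportions must be named AFR/EUR/NAT fractions summing to 1")
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (assort_on == "gene_subset") {
    if (is.null(trait_genes) || length(trait_genes) == 0) {
      abort("assort_on = 'gene_subset' requires trait_genes")
    }
    if (!all(trait_genes %in% gene_ids)) {
      abort("trait_genes must be a subset of the simulated gene universe")
    }
  }
  if (!is.null(assort_ancestry)) {
    assert_ancestry_labels(assort_ancestry, "assort_ancestry")
  }
  scope_rows <- if (assort_on == "gene_subset") {
    match(trait_genes, gene_ids)
  } else {
    seq_len(n_genes)
  }
  comp <- if (is.null(assort_ancestry)) 1:3 else match(assort_ancestry, .ANCESTRIES)

  if (n_burnin < 0) abort("n_burnin must be >= 0")
  total_gen <- n_burnin + n_generations
  sim <- with_seed_or_not(seed, {
    founder_anc <- sample.int(3, n_individuals, replace = TRUE, prob = pi0)
    hap1 <- matrix(rep(founder_anc, each = n_genes), nrow = n_genes)
    hap2 <- hap1
    per_gen <- vector("list", total_gen)
    for (gen in seq_len(total_gen)) {
      strength <- if (gen <= n_burnin) 0 else assortment_strength
      vec_scope <- ancestry_vectors(hap1, hap2, scope_rows)
      pairs <- draw_mate_pairs(vec_scope[comp, , drop = FALSE], strength)
      vec_global <- ancestry_vectors(hap1, hap2, seq_len(n_genes))
      per_gen[[gen]] <- tibble(
        generation = gen,
        phase = if (gen <= n_burnin) "burnin" else "mate_choice",
        mate_correlation = mate_pair_correlation(vec_global, pairs),
        mean_AFR = mean(vec_global[1, ]),
        mean_EUR = mean(vec_global[2, ]),
        mean_NAT = mean(vec_global[3, ])
      )
      off <- make_offspring(hap1, hap2, pairs, n_individuals)
      hap1 <- off$hap1
      hap2 <- off$hap2
    }
    list(hap1 = hap1, hap2 = hap2, per_gen = bind_rows(per_gen))
  })

  labels <- .ANCESTRIES
  calls <- ancestry_calls(
    gene_id = rep(gene_ids, times = n_individuals),
    individual_id = rep(
      sprintf("ind%04d", seq_len(n_individuals)),
      each = n_genes
    ),
    hap1 = labels[as.vector(sim$hap1)],
    hap2 = labels[as.vector(sim$hap2)]
  )
  config <- list(
    n_individuals = n_individuals, n_genes = n_genes,
    n_generations = n_generations, n_burnin = n_burnin,
    founder_proportions = as.list(pi0),
    assortment_strength = assortment_strength,
    assort_on = assort_on,
    trait_genes = trait_genes,
    assort_ancestry = assort_ancestry,
    seed = seed
  )
  structure(
    list(
      calls = calls,
      truth = list(
        config = config,
        fractions = global_ancestry_fractions(calls),
        per_generation = sim$per_gen
      ),
      genes = synthetic_gene_annotations(n_genes)
    ),
    class = "admix_sim"
  )
}

# 3 x n matrix of per-individual ancestry fractions over the given gene rows.
ancestry_vectors <- function(hap1, hap2, rows) {
  n <- ncol(hap1)
  v <- matrix(0, nrow = 3, ncol = n)
  h1 <- hap1[rows, , drop = FALSE]
  h2 <- hap2[rows, , drop = FALSE]
  for (k in 1:3) {
    v[k, ] <- (colSums(h1 == k) + colSums(h2 == k)) / (2 * length(rows))
  }
  v
}

# Monogamous pairs by sequential weighted sampling on exp(-strength * d),
# d normalized by the mean pairwise distance (scale-free preference).
# Returns a 2 x n_pairs matrix of individual indices.
draw_mate_pairs <- function(vectors, strength) {
  n <- ncol(vectors)
  n_pairs <- n %/% 2
  if (strength == 0) {
    perm <- sample.int(n)
    return(matrix(perm[seq_len(2 * n_pairs)], nrow = 2))
  }
  d <- as.matrix(stats::dist(t(vectors)))
  mean_d <- mean(d[upper.tri(d)])
  if (mean_d > 0) d <- d / mean_d
  unmated <- sample.int(n) # random processing order
  pairs <- matrix(0L, nrow = 2, ncol = n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- unmated[1]
    unmated <- unmated[-1]
    w <- exp(-strength * d[i, unmated])
    if (sum(w) <= 0) w <- rep(1, length(unmated))
    j_idx <- sample.int(length(unmated), 1, prob = w)
    pairs[, k] <- c(i, unmated[j_idx])
    unmated <- unmated[-j_idx]
  }
  pairs
}

# Mean Pearson correlation between mates' ancestry fractions, over
# components with variance on both sides.
mate_pair_correlation <- function(vectors, pairs) {
  cors <- vapply(1:3, function(k) {
    x <- vectors[k, pairs[1, ]]
    y <- vectors[k, pairs[2, ]]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  if (all(is.na(cors))) NA_real_ else mean(cors, na.rm = TRUE)
}

# Constant-size offspring generation with free recombination across genes.
make_offspring <- function(hap1, hap2, pairs, n_target) {
  n_pairs <- ncol(pairs)
  per_pair <- rep(2L, n_pairs)
  deficit <- n_target - sum(per_pair)
  if (deficit > 0) { # odd population size: top up from random pairs
    extra <- sample.int(n_pairs, deficit, replace = TRUE)
    for (e in extra) per_pair[e] <- per_pair[e] + 1L
  }
  fa <- rep(pairs[1, ], per_pair)
  mo <- rep(pairs[2, ], per_pair)
  n_children <- length(fa)
  n_genes <- nrow(hap1)
  child1 <- hap1[, fa, drop = FALSE]
  alt1 <- hap2[, fa, drop = FALSE]
  swap <- matrix(runif(n_genes * n_children) < 0.5, nrow = n_genes)
  child1[swap] <- alt1[swap]
  child2 <- hap1[, mo, drop = FALSE]
  alt2 <- hap2[, mo, drop = FALSE]
  swap <- matrix(runif(n_genes * n_children) < 0.5, nrow = n_genes)
  child2[swap] <- alt2[swap]
  list(hap1 = child1, hap2 = child2)
}

#' Synthetic gene annotations for simulated loci
#'
#' Places `n_genes` 10-kb genes 100 kb apart, round-robin across the 22
#' autosomes, giving the simulator's loci usable BED coordinates.
#'
#' @param n_genes Number of genes.
#' @return A gene-annotation tibble as from [read_gene_annotations()].
#' @export
synthetic_gene_annotations <- function(n_genes) {
  idx <- seq_len(n_genes)
  chrom <- sprintf("chr%d", ((idx - 1) %% 22) + 1)
  slot <- (idx - 1) %/% 22
  start <- 1e5 * (slot + 1)
  tibble(
    gene_id = sprintf("g%04d", idx),
    chrom = chrom,
    start = start,
    end = start + 1e4,
    strand = "*"
  ) %>% arrange(.data$chrom, .data$start)
}

#' @export
print.admix_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Simulated admixed population: %d individuals x %d genes, %d generation(s)\n",
    cfg$n_individuals, cfg$n_genes, cfg$n_generations
  ))
  cat(sprintf(
    "  founders AFR/EUR/NAT = %.2f/%.2f/%.2f, assortment strength = %g (%s)\n",
    cfg$founder_proportions$AFR, cfg$founder_proportions$EUR,
    cfg$founder_proportions$NAT, cfg$assortment_strength, cfg$assort_on
  ))
  invisible(x)
}
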