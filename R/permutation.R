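#' Random-mating permutation null for gene-level AMI
#'
#' Approximates random mating by, at each gene, pooling the haplotype
#' ancestry labels of fully assigned individuals and re-pairing them
#' uniformly at random (with replacement) into `n_virtual` virtual diploid
#' individuals. The AMI of each virtual cohort is computed against the
#' same triallelic Hardy-Weinberg expectations as the observed data (the
#' locus fractions, scaled to the virtual cohort size). The resulting
#' per-gene values form the expected-AMI distribution under random mating,
#' which is narrow and centred near zero.
#'
#' Genes whose locus is ancestry-fixed (zero expected heterozygosity) or
#' that have fewer than two assigned haplotypes carry an undefined AMI and
#' are excluded, mirroring [gene_ami()].
#'
#' @param calls An ancestry-call tibble.
#' @param n_virtual Number of virtual diploids per gene (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `gene_id` and `ami_null` for each retained gene,
#'   with summary attributes `mean`, `sd` and `mc_se` (Monte-Carlo
#'   standard error of the mean across genes).
#' @export
random_mating_null <- function(calls, n_virtual = 10000, seed = NULL) {
  if (n_virtual < 1) abort("n_virtual must be >= 1")
  fr <- locus_ancestry_fractions(calls)
  full <- filter(calls, !is.na(.data$anc2))
  labels_by_gene <- split(
    c(full$anc1, full$anc2), rep(full$gene_id, 2)
  )
  usable <- fr %>%
    filter(
      .data$n_pairs >= 1,
      pmax(.data$f_AFR, .data$f_EUR, .data$f_NAT) < 1
    ) %>%
    filter(lengths(labels_by_gene[.data$gene_id]) >= 2)
  n_excluded <- nrow(fr) - nrow(usable)
  if (n_excluded > 0) {
    inform(sprintf(
      "random_mating_null: excluded %d fixed or under-assigned gene(s)",
      n_excluded
    ))
  }
  if (nrow(usable) == 0) abort("no genes usable for the random-mating null")
  ex <- hw_expected_counts(
    usable$f_AFR, usable$f_EUR, usable$f_NAT, n_virtual
  )
  ami_null <- with_seed_or_not(seed, {
    vapply(seq_len(nrow(usable)), function(i) {
      pool <- labels_by_gene[[usable$gene_id[i]]]
      h1 <- pool[sample.int(length(pool), n_virtual, replace = TRUE)]
      h2 <- pool[sample.int(length(pool), n_virtual, replace = TRUE)]
      obs_hom <- sum(h1 == h2)
      obs_het <- n_virtual - obs_hom
      k <- if (obs_hom == 0 || obs_het == 0) 0.5 else 0
      log(((obs_hom + k) / (ex$exp_hom[i] + k)) /
        ((obs_het + k) / (ex$exp_het[i] + k)))
    }, numeric(1))
  })
  out <- tibble(gene_id = usable$gene_id, ami_null = ami_null)
  attr(out, "mean") <- mean(ami_null)
  attr(out, "sd") <- sd(ami_null)
  attr(out, "mc_se") <- sd(ami_null) / sqrt(length(ami_null))
  out
}

#' Random gene-set null for the pooled AMI
#'
#' Controls for genome-wide (ancestry-level) assortative mating when
#' testing trait-specific gene sets: draws `n_perms` random sets of
#' `set_size` genes (without replacement within a draw) from the pool of
#' callable genes, pools each with the Mantel-Haenszel estimator, and
#' returns the null distribution of pooled log odds ratios. When an
#' observed value is supplied, a two-sided empirical p-value with the
#' add-one convention is attached:
#' `p = (1 + #(|null| >= |observed|)) / (n_perms + 1)`.
#'
#' @param counts Per-gene count table (the callable-gene pool).
#' @param set_size Number of genes per random set.
#' @param n_perms Number of random sets (default 10000).
#' @param observed Optional observed pooled log odds ratio.
#' @param seed Optional integer seed.
#' @return A tibble with columns `perm` and `log_or`; attributes `mean`,
#'   `sd`, and (when `observed` given) `observed` and `p_value`.
#' @export
random_geneset_null <- function(counts, set_size, n_perms = 10000,
                                observed = NULL, seed = NULL) {
  usable <- filter(
    counts,
    .data$exp_hom > 0, .data$exp_het > 0, .data$obs_hom + .data$obs_het > 0
  )
  pool <- nrow(usable)
  if (set_size > pool) {
    abort(sprintf("set_size (%d) exceeds callable-gene pool (%d)", set_size, pool))
  }
  if (n_perms < 1) abort("n_perms must be >= 1")
  n_cells <- usable$obs_hom + usable$obs_het + usable$exp_hom + usable$exp_het
  R <- usable$obs_hom * usable$exp_het / n_cells
  S <- usable$obs_het * usable$exp_hom / n_cells
  log_or <- with_seed_or_not(seed, {
    vapply(seq_len(n_perms), function(i) {
      idx <- sample.int(pool, set_size)
      mh_log_or_from_rs(R[idx], S[idx])
    }, numeric(1))
  })
  out <- tibble(perm = seq_len(n_perms), log_or = log_or)
  attr(out, "mean") <- mean(log_or)
  attr(out, "sd") <- sd(log_or)
  if (!is.null(observed)) {
    attr(out, "observed") <- observed
    attr(out, "p_value") <-
      (1 + sum(abs(log_or) >= abs(observed))) / (n_perms + 1)
  }
  out
}
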