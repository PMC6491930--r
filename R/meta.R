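#' Mantel-Haenszel meta-analysis of gene-level AMI
#'
#' Pools the per-gene 2x2 tables (rows observed/expected, columns
#' homozygote/heterozygote) of a gene set into a common odds ratio under a
#' fixed-effects model. The pooled estimator is
#' \deqn{OR = \frac{\sum_g obs_{hom,g} \cdot exp_{het,g} / N_g}
#'                {\sum_g obs_{het,g} \cdot exp_{hom,g} / N_g}}
#' with \eqn{N_g} the sum of the four cells of gene g. The standard error
#' of the log odds ratio uses the Robins-Breslow-Greenland variance; the
#' two-sided p-value comes from the normal deviate `log(OR)/SE` and the
#' 95% CI is `log(OR) +/- 1.96 SE`. Expected cells are real-valued and are
#' used as-is. Genes with a zero expected cell (fixed loci) or no pairs
#' are dropped with a message.
#'
#' @param counts Per-gene count table restricted to one gene set (columns
#'   `obs_hom`, `obs_het`, `exp_hom`, `exp_het`; a `gene_id` column is used
#'   for reporting).
#' @param phenotype_id,population_id Optional identifiers carried into the
#'   result row.
#' @return A one-row tibble of class `ami_meta` with `phenotype_id`,
#'   `population_id`, `k_genes`, `pooled_log_or`, `se`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
meta_ami <- function(counts, phenotype_id = NA_character_,
                     population_id = NA_character_) {
  usable <- filter(
    counts,
    .data$exp_hom > 0, .data$exp_het > 0, .data$obs_hom + .data$obs_het > 0
  )
  n_drop <- nrow(counts) - nrow(usable)
  if (n_drop > 0) {
    inform(sprintf("meta_ami: dropped %d gene(s) with undefined AMI", n_drop))
  }
  if (nrow(usable) == 0) abort("empty phenotype after filtering")
  est <- mh_pooled(
    usable$obs_hom, usable$obs_het, usable$exp_hom, usable$exp_het
  )
  out <- tibble(
    phenotype_id = phenotype_id,
    population_id = population_id,
    k_genes = nrow(usable),
    pooled_log_or = est$log_or,
    se = est$se,
    ci_low = est$log_or - qnorm(0.975) * est$se,
    ci_high = est$log_or + qnorm(0.975) * est$se,
    p_value = est$p_value
  )
  class(out) <- c("ami_meta", class(out))
  out
}

# Mantel-Haenszel pooled log OR with Robins-Breslow-Greenland variance.
# Cells: a = obs_hom, b = obs_het, c = exp_hom, d = exp_het per stratum.
mh_pooled <- function(a, b, c, d) {
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  sum_r <- sum(R)
  sum_s <- sum(S)
  log_or <- log(sum_r / sum_s)
  P <- (a + d) / n
  Q <- (b + c) / n
  v <- sum(P * R) / (2 * sum_r^2) +
    sum(P * S + Q * R) / (2 * sum_r * sum_s) +
    sum(Q * S) / (2 * sum_s^2)
  se <- sqrt(v)
  z <- log_or / se
  list(log_or = log_or, se = se, p_value = 2 * pnorm(-abs(z)))
}

# Pooled log OR only (no variance): fast path for permutation nulls.
# Takes precomputed per-gene R = a*d/n and S = b*c/n.
mh_log_or_from_rs <- function(R, S) log(sum(R) / sum(S))

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment over a declared family of tests.
#' In a full run the family is all phenotype-by-population meta-analyses
#' (see [run_ami()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Compare observed and expected AMI distributions
#'
#' Two-sample t-test of mean AMI between an observed set of gene- or
#' phenotype-level values and a null (e.g. random-mating permutation)
#' set. Welch's unequal-variance test is the default since observed AMI
#' distributions are typically much broader than permutation nulls; set
#' `var_equal = TRUE` for Student's test.
#'
#' @param observed,expected Numeric vectors of AMI values (length >= 2
#'   each; `NA` dropped).
#' @param var_equal Assume equal variances (Student) instead of Welch.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_observed`,
#'   `mean_expected`. When both samples are constant and equal the
#'   convention `t = 0, p = 1` applies.
#' @export
compare_ami_distributions <- function(observed, expected, var_equal = FALSE) {
  observed <- observed[!is.na(observed)]
  expected <- expected[!is.na(expected)]
  if (length(observed) < 2 || length(expected) < 2) {
    abort("each AMI sample must contain at least 2 finite values")
  }
  res <- tryCatch(
    t.test(observed, expected, var.equal = var_equal),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both samples essentially constant
    if (isTRUE(all.equal(mean(observed), mean(expected)))) {
      return(tibble(
        t = 0, df = NA_real_, p_value = 1,
        mean_observed = mean(observed), mean_expected = mean(expected)
      ))
    }
    return(tibble(
      t = sign(mean(observed) - mean(expected)) * Inf, df = NA_real_,
      p_value = 0,
      mean_observed = mean(observed), mean_expected = mean(expected)
    ))
  }
  tibble(
    t = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value,
    mean_observed = mean(observed), mean_expected = mean(expected)
  )
}

#' Cross-population variance of phenotype AMI
#'
#' For each phenotype with a finite pooled AMI in every population, the
#' sample variance (denominator n-1) of the pooled log odds ratios across
#' populations, normalized by the mean raw variance over all phenotypes.
#' High values flag phenotypes whose assortative-mating pattern differs
#' most between populations; low values flag the most concordant ones.
#' Optionally, an empirical two-sided p-value per phenotype is computed
#' against a null distribution of variances from random gene sets (see
#' [random_geneset_null()]), with BH q-values over the phenotypes.
#'
#' @param results Tibble with columns `phenotype_id`, `population_id`,
#'   `pooled_log_or` (one row per phenotype-population pair).
#' @param null_variances Optional numeric vector of variances of pooled
#'   log odds ratios across populations for random gene sets.
#' @return A tibble with `phenotype_id`, `raw_variance`,
#'   `normalized_variance`, and (when a null is supplied) `p_value`,
#'   `q_value`. Phenotypes missing a population are excluded with a
#'   message.
#' @export
ami_population_variance <- function(results, null_variances = NULL) {
  n_pop <- length(unique(results$population_id))
  if (n_pop < 2) abort("need >= 2 populations for cross-population variance")
  complete <- results %>%
    filter(is.finite(.data$pooled_log_or)) %>%
    group_by(.data$phenotype_id) %>%
    filter(dplyr::n_distinct(.data$population_id) == n_pop) %>%
    ungroup()
  dropped <- setdiff(unique(results$phenotype_id), unique(complete$phenotype_id))
  if (length(dropped) > 0) {
    inform(sprintf(
      "ami_population_variance: excluded %d phenotype(s) with missing values",
      length(dropped)
    ))
  }
  out <- complete %>%
    group_by(.data$phenotype_id) %>%
    summarise(raw_variance = var(.data$pooled_log_or), .groups = "drop")
  if (nrow(out) == 0) abort("no phenotype has AMI in all populations")
  out$normalized_variance <- out$raw_variance / mean(out$raw_variance)
  if (!is.null(null_variances)) {
    out$p_value <- vapply(
      out$raw_variance, empirical_p_two_sided,
      numeric(1),
      null = null_variances
    )
    out$q_value <- bh_qvalues(out$p_value)
  }
  out
}

# Two-sided empirical p with the add-one convention, for a statistic whose
# null is one-sided in scale (variances): doubles the smaller tail.
empirical_p_two_sided <- function(observed, null) {
  n <- length(null)
  p_hi <- (1 + sum(null >= observed)) / (n + 1)
  p_lo <- (1 + sum(null <= observed)) / (n + 1)
  min(1, 2 * min(p_hi, p_lo))
}
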