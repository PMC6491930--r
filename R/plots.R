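#' Plot observed versus null AMI distributions
#'
#' Density overlay of gene-level AMI values against a random-mating (or
#' random-gene-set) null — the canonical picture of ancestry-based
#' assortative mating: a narrow null centred near zero against a broader,
#' positively shifted observed distribution.
#'
#' @param observed,expected Numeric vectors of AMI values.
#' @return A ggplot object.
#' @export
plot_ami_distributions <- function(observed, expected) {
  df <- bind_rows(
    tibble(ami = observed[is.finite(observed)], which = "observed"),
    tibble(ami = expected[is.finite(expected)], which = "expected")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ami, fill = .data$which)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "AMI (log odds ratio)", y = "density", fill = NULL,
      title = "Observed vs expected assortative mating index"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-phenotype pooled AMI
#'
#' @param object An `ami_fit` object.
#' @param max_phenotypes Show at most this many phenotypes, ranked by
#'   p-value (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ami_fit <- function(object, max_phenotypes = 20, ...) {
  res <- object$phenotype_results %>%
    arrange(.data$p_value) %>%
    head(max_phenotypes) %>%
    mutate(
      phenotype_id = factor(.data$phenotype_id, levels = rev(.data$phenotype_id)),
      significant = .data$q_value < 0.05
    )
  ggplot2::ggplot(res, ggplot2::aes(
    x = .data$pooled_log_or, y = .data$phenotype_id,
    colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey40"),
      labels = c(`TRUE` = "q < 0.05", `FALSE` = "n.s."), name = NULL
    ) +
    ggplot2::labs(
      x = "pooled AMI (log odds ratio, 95% CI)", y = NULL,
      title = sprintf("Assortative mating by phenotype: %s", object$population_id)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of ancestry-driver (AH) profiles
#'
#' @param ah A tibble from [ancestry_homozygosity()] (possibly several
#'   phenotypes/populations bound together).
#' @return A ggplot object with one bar per ancestry, facetted by
#'   phenotype and population when present.
#' @export
plot_ah_profile <- function(ah) {
  p <- ggplot2::ggplot(ah, ggplot2::aes(
    x = .data$ancestry, y = .data$ah, fill = .data$ancestry
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(
      AFR = "#2e6da4", EUR = "#e67e22", NAT = "#c0392b"
    ), guide = "none") +
    ggplot2::labs(
      x = NULL, y = "ancestry homozygosity excess (AH)",
      title = "Ancestry drivers of assortative mating"
    ) +
    ggplot2::theme_minimal()
  if (all(c("phenotype_id", "population_id") %in% names(ah)) &&
    (length(unique(ah$phenotype_id)) > 1 ||
      length(unique(ah$population_id)) > 1)) {
    p <- p + ggplot2::facet_grid(phenotype_id ~ population_id)
  }
  p
}
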