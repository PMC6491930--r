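#' Read polygenic-phenotype gene sets from GMT
#'
#' Parses a GMT file (one set per line: name, description, then gene ids,
#' tab-separated). The functional category is taken from the first token of
#' the description field; recognised categories are `anthropometric`,
#' `neurological` and `HLA`, anything else maps to `other`. Duplicate
#' genes within a set are collapsed with a warning; empty set lines are
#' skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A long tibble with columns `phenotype_id`, `category`,
#'   `gene_id`, preserving file order and within-set gene order.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      warn(sprintf("Skipping GMT line %d: no genes listed", i))
      next
    }
    name <- fields[1]
    cat_token <- strsplit(trimws(fields[2]), "[ ;,]")[[1]][1]
    category <- if (cat_token %in% c("anthropometric", "neurological", "HLA")) {
      cat_token
    } else {
      "other"
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("Duplicate gene(s) collapsed in set '%s'", name))
      genes <- unique(genes)
    }
    out[[length(out) + 1]] <- tibble(
      phenotype_id = name, category = category, gene_id = genes
    )
  }
  if (length(out) == 0) {
    return(tibble(
      phenotype_id = character(), category = character(), gene_id = character()
    ))
  }
  dup_sets <- unique(vapply(out, function(x) x$phenotype_id[1], character(1)))
  if (length(dup_sets) != length(out)) {
    abort("Duplicate phenotype names in GMT file")
  }
  bind_rows(out)
}

#' Write gene sets to GMT
#'
#' @param sets Long gene-set tibble (`phenotype_id`, `category`, `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- sets %>%
    group_by(.data$phenotype_id, .data$category) %>%
    summarise(genes = paste(.data$gene_id, collapse = "\t"), .groups = "drop")
  # preserve original order
  ord <- match(unique(sets$phenotype_id), lines$phenotype_id)
  lines <- lines[ord, ]
  writeLines(
    sprintf("%s\t%s\t%s", lines$phenotype_id, lines$category, lines$genes),
    path
  )
  invisible(path)
}

#' Filter gene sets to callable genes
#'
#' Restricts each set to genes that passed the ancestry-genotype inclusion
#' threshold and drops sets left with fewer than `min_size` genes (a
#' meta-analysis needs at least two strata to say anything polygenic).
#'
#' @param sets Long gene-set tibble.
#' @param callable_genes Character vector of retained gene ids (e.g.
#'   `unique(apply_ancestry_threshold(calls)$gene_id)`).
#' @param min_size Minimum set size after filtering (default 2).
#' @return The filtered long tibble; dropped sets are reported with a
#'   message. Errors if nothing survives.
#' @export
filter_gene_sets <- function(sets, callable_genes, min_size = 2) {
  kept <- filter(sets, .data$gene_id %in% callable_genes)
  sizes <- count(kept, .data$phenotype_id)
  small <- sizes$phenotype_id[sizes$n < min_size]
  lost <- setdiff(unique(sets$phenotype_id), sizes$phenotype_id)
  dropped <- union(small, lost)
  if (length(dropped) > 0) {
    inform(sprintf(
      "filter_gene_sets: dropped %d set(s) below %d callable genes",
      length(dropped), min_size
    ))
  }
  out <- filter(kept, !.data$phenotype_id %in% small)
  if (nrow(out) == 0) abort("no callable genes in any set")
  out
}

#' Read a pairwise gene-gene LD table
#'
#' TSV with columns `gene_a`, `gene_b`, `r2`: the maximum SNP-level r²
#' between any pair of variants in the two genes (precomputed externally).
#'
#' @param path Path to the TSV (header required).
#' @return A tibble with `gene_a`, `gene_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  ld <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  required <- c("gene_a", "gene_b", "r2")
  if (!all(required %in% names(ld))) {
    abort("LD table must have columns gene_a, gene_b, r2")
  }
  if (any(ld$r2 < 0 | ld$r2 > 1)) abort("r2 values must lie in [0, 1]")
  ld
}

#' Prune gene sets for linkage disequilibrium
#'
#' Ensures each set consists of statistically independent genes: for any
#' within-set gene pair with `r2 > r2_max`, one member is removed. Pairs
#' are processed in decreasing r² and, of an offending pair with both
#' members still present, the later-listed gene is dropped (keeping the
#' earlier-listed one) — deterministic given input order. Sets falling
#' below `min_size` afterwards are dropped with a message.
#'
#' @param sets Long gene-set tibble.
#' @param ld LD table from [read_ld_table()] (unordered gene pairs).
#' @param r2_max Maximum tolerated pairwise r² (default 0.1).
#' @param min_size Minimum surviving set size (default 2).
#' @return The pruned long tibble; no remaining within-set pair exceeds
#'   `r2_max`.
#' @export
ld_prune_gene_sets <- function(sets, ld, r2_max = 0.1, min_size = 2) {
  if (any(ld$r2 < 0 | ld$r2 > 1)) abort("r2 values must lie in [0, 1]")
  offending <- ld %>%
    filter(.data$r2 > r2_max) %>%
    arrange(dplyr::desc(.data$r2))
  prune_one <- function(genes) {
    for (k in seq_len(nrow(offending))) {
      ga <- offending$gene_a[k]
      gb <- offending$gene_b[k]
      ia <- match(ga, genes)
      ib <- match(gb, genes)
      if (is.na(ia) || is.na(ib)) next
      drop <- if (ia < ib) gb else ga
      genes <- setdiff(genes, drop)
    }
    genes
  }
  pruned <- sets %>%
    group_by(.data$phenotype_id, .data$category) %>%
    dplyr::group_modify(function(df, key) {
      tibble(gene_id = prune_one(df$gene_id))
    }) %>%
    ungroup()
  # restore original set order
  pruned <- pruned[order(match(pruned$phenotype_id, unique(sets$phenotype_id))), ]
  sizes <- count(pruned, .data$phenotype_id)
  small <- sizes$phenotype_id[sizes$n < min_size]
  if (length(small) > 0) {
    inform(sprintf(
      "ld_prune_gene_sets: dropped %d set(s) below %d genes after pruning",
      length(small), min_size
    ))
  }
  filter(pruned, !.data$phenotype_id %in% small) %>%
    select("phenotype_id", "category", "gene_id")
}
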