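# Shared builders for small in-code fixtures.

# Calls tibble from a compact layout: list of c(hap1, hap2) per (gene x ind),
# filled column-major over the gene x individual grid.
toy_calls <- function(pairs, n_genes, n_ind, population = NULL) {
  stopifnot(length(pairs) == n_genes * n_ind)
  gene <- rep(sprintf("g%02d", seq_len(n_genes)), times = n_ind)
  ind <- rep(sprintf("i%02d", seq_len(n_ind)), each = n_genes)
  h1 <- vapply(pairs, function(p) p[1], character(1))
  h2 <- vapply(pairs, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))
  h1[h1 == "."] <- NA_character_
  h2[is.na(h1)] <- NA_character_
  ancestry_calls(gene, ind, h1, h2, population = population)
}

# One-gene count row with explicit cells.
count_row <- function(obs_hom, obs_het, exp_hom, exp_het,
                      gene_id = "g01") {
  tibble::tibble(
    gene_id = gene_id, obs_hom = obs_hom, obs_het = obs_het,
    exp_hom = exp_hom, exp_het = exp_het
  )
}

# Segment tibble builder.
seg_row <- function(ind, hap, chrom, start, end, anc, cert = 1) {
  tibble::tibble(
    individual_id = ind, haplotype = hap, chrom = chrom,
    start = start, end = end, ancestry = anc, certainty = cert
  )
}

write_segment_file <- function(segments, path = tempfile(fileext = ".tsv")) {
  write_ancestry_segments(segments, path)
  path
}

# Independent textbook Mantel-Haenszel oracle: plain loops, no shared code
# with the package implementation.
mh_oracle <- function(tables) {
  num <- 0
  den <- 0
  for (t in tables) {
    n <- sum(t)
    num <- num + t[1, 1] * t[2, 2] / n
    den <- den + t[1, 2] * t[2, 1] / n
  }
  log(num / den)
}
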