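test_that("segment TSV rows map to validated segments", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#individual_id\thaplotype\tchrom\tstart\tend\tancestry\tcertainty",
    "ind1\t0\tchr1\t1000\t5000\tAFR\t0.995"
  ), path)
  segs <- read_ancestry_segments(path)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$ancestry, "AFR")
  expect_equal(segs$certainty, 0.995)
  expect_equal(segs$start, 1000)
  expect_equal(segs$end, 5000)
})

test_that("empty segment files yield an empty set with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines("#individual_id\thaplotype\tchrom\tstart\tend\tancestry\tcertainty", path)
  expect_warning(segs <- read_ancestry_segments(path), "empty")
  expect_equal(nrow(segs), 0)
})

test_that("abutting half-open segments are not overlaps", {
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 100, "AFR"),
    seg_row("i1", 0, "chr1", 100, 200, "EUR")
  )
  expect_silent(validate_ancestry_segments(segs))
  # oracle: brute-force pairwise interval intersection finds none
  overlap <- (segs$start[1] < segs$end[2]) && (segs$start[2] < segs$end[1])
  expect_false(overlap)
})

test_that("overlapping segments on one haplotype are rejected", {
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 150, "AFR"),
    seg_row("i1", 0, "chr1", 100, 200, "EUR")
  )
  expect_error(validate_ancestry_segments(segs), "Overlapping")
  # same intervals on different haplotypes are fine
  segs$haplotype <- c(0, 1)
  expect_silent(validate_ancestry_segments(segs))
})

test_that("unknown ancestry labels are named in the parse error", {
  segs <- seg_row("i1", 0, "chr1", 0, 10, "XYZ")
  expect_error(validate_ancestry_segments(segs), "XYZ")
})

test_that("malformed segment lines are reported with line numbers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "ind1\t0\tchr1\t0\t10\tAFR\t1",
    "ind1\t0\tchr1\t20"
  ), path)
  expect_error(read_ancestry_segments(path), "2")
})

test_that("segment write/read round-trips", {
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 100, "AFR", 0.999),
    seg_row("i1", 1, "chr1", 0, 250, "EUR", 0.991),
    seg_row("i2", 0, "chr2", 50, 400, "NAT", 1)
  )
  path <- write_segment_file(segs)
  back <- read_ancestry_segments(path)
  expect_equal(as.data.frame(back), as.data.frame(segs))
})

test_that("RFMix v1 Viterbi matrices collapse into segments", {
  vit_path <- tempfile()
  # 5 markers, 1 sample (2 haplotype columns); codes 1=AFR 2=EUR 3=NAT
  writeLines(c("1 2", "1 2", "2 2", "2 3", "2 3"), vit_path)
  markers <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 300, 400, 500)
  )
  segs <- read_ancestry_segments(
    vit_path,
    dialect = "rfmix_v1", markers = markers, samples = "s1"
  )
  h0 <- segs[segs$haplotype == 0, ]
  expect_equal(h0$ancestry, c("AFR", "EUR"))
  expect_equal(h0$start, c(99, 299)) # 1-based marker -> 0-based half-open
  expect_equal(h0$end, c(200, 500))
  h1 <- segs[segs$haplotype == 1, ]
  expect_equal(h1$ancestry, c("EUR", "NAT"))
  # per-segment certainty is the minimum marker posterior
  post <- matrix(c(
    0.99, 1, 1, 1, 1,
    1, 1, 0.95, 1, 1
  ), ncol = 2)
  segs2 <- read_ancestry_segments(
    vit_path,
    dialect = "rfmix_v1", markers = markers, samples = "s1",
    posterior = post
  )
  expect_equal(segs2$certainty[segs2$haplotype == 0], c(0.99, 1))
  expect_equal(segs2$certainty[segs2$haplotype == 1], c(0.95, 1))
})

test_that("BED genes are read, sorted, and deduplicated", {
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr2\t500\t900\tGENE_C",
    "chr1\t100\t500\tGENE_A",
    "chr1\t50\t80\tGENE_B"
  ), path)
  genes <- read_gene_annotations(path)
  expect_equal(genes$gene_id, c("GENE_B", "GENE_A", "GENE_C"))
  # comparison-sort oracle on (chrom, start)
  key <- paste(genes$chrom, sprintf("%012d", genes$start))
  expect_equal(key, sort(key))
  expect_equal(genes$start[genes$gene_id == "GENE_A"], 100)
  expect_equal(genes$end[genes$gene_id == "GENE_A"], 500)

  writeLines(c("chr1\t0\t10\tA", "chr2\t0\t10\tA"), path)
  expect_error(read_gene_annotations(path), "A")
})

test_that("sex-chromosome genes are excluded", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tA", "chrX\t0\t10\tB"), path)
  expect_message(genes <- read_gene_annotations(path), "sex")
  expect_equal(genes$gene_id, "A")
})

test_that("genotype calling follows the containment rule", {
  genes <- tibble::tibble(
    gene_id = "G1", chrom = "chr1", start = 100, end = 500, strand = "*"
  )
  # fully contained on both haplotypes -> {AFR, AFR}
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 1000, "AFR", 0.999),
    seg_row("i1", 1, "chr1", 0, 1000, "AFR", 0.999)
  )
  calls <- call_gene_ancestry(segs, genes)
  expect_equal(calls$anc1, "AFR")
  expect_equal(calls$anc2, "AFR")
  # gene spans a boundary on hap 0, contained EUR on hap 1 -> single EUR
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 300, "AFR", 1),
    seg_row("i1", 0, "chr1", 300, 1000, "EUR", 1),
    seg_row("i1", 1, "chr1", 0, 1000, "EUR", 1)
  )
  calls <- call_gene_ancestry(segs, genes)
  expect_equal(calls$anc1, "EUR")
  expect_true(is.na(calls$anc2))
  # low-certainty segments do not assign
  segs <- dplyr::bind_rows(
    seg_row("i1", 0, "chr1", 0, 1000, "AFR", 0.98),
    seg_row("i1", 1, "chr1", 0, 1000, "EUR", 1)
  )
  calls <- call_gene_ancestry(segs, genes)
  expect_equal(calls$anc1, "EUR")
  expect_true(is.na(calls$anc2))
  expect_error(call_gene_ancestry(segs, genes, min_certainty = -0.1), ">= 0")
})

test_that("genes on chromosomes absent from segments are all-missing", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = c("chr1", "chr9"),
    start = c(100, 100), end = c(200, 200), strand = "*"
  )
  segs <- seg_row("i1", 0, "chr1", 0, 1000, "AFR")
  calls <- call_gene_ancestry(segs, genes)
  g2 <- calls[calls$gene_id == "G2", ]
  expect_true(all(is.na(g2$anc1)))
})

test_that("genotype calls match a brute-force containment oracle", {
  withr::local_seed(11)
  for (rep in 1:5) {
    n_genes <- sample(3:10, 1)
    n_ind <- sample(2:5, 1)
    genes <- tibble::tibble(
      gene_id = sprintf("G%02d", seq_len(n_genes)), chrom = "chr1",
      start = seq(0, by = 1000, length.out = n_genes) + 200,
      end = seq(0, by = 1000, length.out = n_genes) + 700,
      strand = "*"
    )
    segs <- list()
    for (i in seq_len(n_ind)) {
      for (h in 0:1) {
        breaks <- sort(sample(seq(0, n_genes * 1000, by = 250)))
        breaks <- unique(c(0, breaks, n_genes * 1000 + 1000))
        segs[[length(segs) + 1]] <- tibble::tibble(
          individual_id = sprintf("i%02d", i), haplotype = h, chrom = "chr1",
          start = head(breaks, -1), end = breaks[-1],
          ancestry = sample(c("AFR", "EUR", "NAT"), length(breaks) - 1, TRUE),
          certainty = sample(c(0.98, 0.995, 1), length(breaks) - 1, TRUE)
        )
      }
    }
    segs <- dplyr::bind_rows(segs)
    calls <- call_gene_ancestry(segs, genes, min_certainty = 0.99)
    # oracle: scan every (gene, segment) pair
    for (g in seq_len(n_genes)) {
      for (i in seq_len(n_ind)) {
        got <- calls[calls$gene_id == genes$gene_id[g] &
          calls$individual_id == sprintf("i%02d", i), ]
        expected <- c(NA_character_, NA_character_)
        for (h in 0:1) {
          sub <- segs[segs$individual_id == sprintf("i%02d", i) &
            segs$haplotype == h & segs$certainty >= 0.99, ]
          hit <- sub$ancestry[sub$start <= genes$start[g] &
            sub$end >= genes$end[g]]
          if (length(hit) == 1) expected[h + 1] <- hit
        }
        expected <- expected[order(is.na(expected), expected)]
        expect_identical(c(got$anc1, got$anc2), expected)
      }
    }
  }
})

test_that("raising min_certainty never increases assignment counts", {
  withr::local_seed(12)
  genes <- synthetic_gene_annotations(20)
  sim <- simulate_admixed_population(
    n_individuals = 10, n_genes = 20, n_generations = 1, n_burnin = 0, seed = 3
  )
  segs <- calls_to_segments(sim$calls, genes)
  segs$certainty <- sample(c(0.9, 0.95, 0.99, 1), nrow(segs), TRUE)
  n_prev <- Inf
  for (mc in c(0.9, 0.95, 0.99, 1)) {
    calls <- call_gene_ancestry(segs, genes, min_certainty = mc)
    n_g <- gene_pair_counts(calls)$n_pairs
    expect_true(all(n_g <= n_prev))
    n_prev <- n_g
  }
})

test_that("the ancestry-genotype threshold follows the mean - sd rule", {
  # n_g = {100, 100, 10}: mean 70, sd ~51.96, threshold ~18.04
  # 3 genes x 100 individuals, gene 3 assigned in only 10
  gene <- rep(sprintf("g%d", 1:3), times = 100)
  ind <- rep(sprintf("i%03d", 1:100), each = 3)
  h <- rep("EUR", 300)
  h1 <- h
  h2 <- h
  drop <- gene == "g3" & as.integer(sub("i", "", ind)) > 10
  h1[drop] <- NA
  h2[drop] <- NA
  calls <- ancestry_calls(gene, ind, h1, h2)
  filtered <- apply_ancestry_threshold(calls)
  expect_equal(attr(filtered, "mean_pairs"), 70)
  expect_equal(attr(filtered, "threshold"), 70 - sd(c(100, 100, 10)))
  expect_setequal(unique(filtered$gene_id), c("g1", "g2"))

  # degenerate sd: equal counts are all retained
  calls_eq <- ancestry_calls(
    rep(sprintf("g%d", 1:3), times = 4),
    rep(sprintf("i%d", 1:4), each = 3),
    rep("AFR", 12), rep("AFR", 12)
  )
  filtered_eq <- apply_ancestry_threshold(calls_eq)
  expect_equal(length(unique(filtered_eq$gene_id)), 3)

  # single gene is retained under the degenerate rule
  one <- ancestry_calls(rep("g1", 5), sprintf("i%d", 1:5), rep("AFR", 5), rep("EUR", 5))
  expect_equal(unique(apply_ancestry_threshold(one)$gene_id), "g1")

  # all-missing input errors
  none <- ancestry_calls("g1", "i1", NA_character_, NA_character_)
  expect_error(apply_ancestry_threshold(none), "no callable genes")
})

test_that("ancestry matrix TSV serialization round-trips", {
  calls <- toy_calls(
    list(
      c("AFR", "EUR"), c("NAT", "NAT"), "EUR", ".",
      c("AFR", "AFR"), c("EUR", "NAT")
    ),
    n_genes = 3, n_ind = 2
  )
  path <- tempfile(fileext = ".tsv")
  write_ancestry_matrix(calls, path)
  back <- read_ancestry_matrix(path)
  expect_equal(
    as.data.frame(dplyr::arrange(back, gene_id, individual_id)),
    as.data.frame(dplyr::arrange(calls, gene_id, individual_id))
  )
})
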