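#' Read local-ancestry segments
#'
#' Reads haplotype-resolved local-ancestry segment calls into a tibble with
#' one row per contiguous ancestry tract. Two dialects are supported:
#'
#' * `"segment_tsv"` — the package's native exchange format: seven
#'   tab-separated columns (`individual_id`, `haplotype`, `chrom`, `start`,
#'   `end`, `ancestry`, `certainty`), 0-based half-open coordinates, header
#'   lines starting with `#`.
#' * `"rfmix_v1"` — RFMix v1 Viterbi output (one row per marker, one column
#'   per haplotype, integer ancestry codes). Requires a companion
#'   marker-position file and the sample ids in haplotype-column order.
#'   Consecutive markers with the same code are collapsed into segments
#'   spanning `[first marker position - 1, last marker position)` (the
#'   1-based marker positions are converted to 0-based half-open intervals).
#'
#' Certainty is preserved as read; thresholding happens later, in
#' [call_gene_ancestry()]. For RFMix input an optional per-marker posterior
#' matrix (ForwardBackward output) can be supplied; a segment's certainty is
#' then the minimum posterior of its markers (conservative), otherwise 1.
#'
#' @param path Path to the segment file (or Viterbi file for `rfmix_v1`).
#' @param dialect `"segment_tsv"` (default) or `"rfmix_v1"`.
#' @param markers For `rfmix_v1`: data frame with columns `chrom`, `pos`
#'   (1-based marker positions, one row per Viterbi row), or a path to a
#'   headerless two-column TSV of the same.
#' @param samples For `rfmix_v1`: character vector of individual ids in the
#'   order of haplotype column pairs (columns 2k-1, 2k belong to sample k).
#' @param ancestry_codes For `rfmix_v1`: labels for integer codes 1, 2, 3.
#' @param posterior For `rfmix_v1`: optional numeric matrix (or path to a
#'   whitespace-separated file) of per-marker, per-haplotype posterior
#'   probabilities for the assigned ancestry.
#'
#' @return A tibble of validated ancestry segments with columns
#'   `individual_id`, `haplotype` (0/1), `chrom`, `start`, `end` (0-based
#'   half-open), `ancestry` (`AFR`/`EUR`/`NAT`), `certainty`.
#'
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "#individual_id\thaplotype\tchrom\tstart\tend\tancestry\tcertainty",
#'   "ind1\t0\tchr1\t1000\t5000\tAFR\t0.995"
#' ), path)
#' read_ancestry_segments(path)
#' @export
read_ancestry_segments <- function(path,
                                   dialect = c("segment_tsv", "rfmix_v1"),
                                   markers = NULL,
                                   samples = NULL,
                                   ancestry_codes = c("AFR", "EUR", "NAT"),
                                   posterior = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Segment file not found: %s", path))
  segs <- switch(dialect,
    segment_tsv = read_segment_tsv(path),
    rfmix_v1 = read_rfmix_v1(path, markers, samples, ancestry_codes, posterior)
  )
  validate_ancestry_segments(segs)
}

read_segment_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warn(sprintf("No segment records in %s; returning empty segment set", path))
    return(empty_segments())
  }
  rows <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7)) {
    abort(sprintf(
      "Malformed segment line(s) (expected 7 tab-separated fields): %s",
      paste(head(rows[nf != 7], 5), collapse = ", ")
    ))
  }
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  suppress_na <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble(
    individual_id = m[, 1],
    haplotype = suppress_na(m[, 2]),
    chrom = m[, 3],
    start = suppress_na(m[, 4]),
    end = suppress_na(m[, 5]),
    ancestry = m[, 6],
    certainty = suppress_na(m[, 7])
  )
  bad <- which(is.na(out$haplotype) | is.na(out$start) | is.na(out$end) |
    is.na(out$certainty))
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-numeric field(s) in segment line(s): %s",
      paste(head(rows[bad], 5), collapse = ", ")
    ))
  }
  out
}

read_rfmix_v1 <- function(path, markers, samples, ancestry_codes, posterior) {
  if (is.null(markers) || is.null(samples)) {
    abort("rfmix_v1 dialect requires `markers` and `samples`")
  }
  if (is.character(markers) && length(markers) == 1) {
    markers <- readr::read_tsv(markers,
      col_names = c("chrom", "pos"),
      col_types = "ci", progress = FALSE
    )
  }
  markers <- as_tibble(markers)
  vit <- as.matrix(readr::read_table(path,
    col_names = FALSE,
    col_types = readr::cols(.default = "i"), progress = FALSE
  ))
  if (nrow(vit) != nrow(markers)) {
    abort(sprintf(
      "Viterbi rows (%d) do not match marker rows (%d)", nrow(vit), nrow(markers)
    ))
  }
  if (ncol(vit) != 2 * length(samples)) {
    abort(sprintf(
      "Viterbi columns (%d) do not match 2 x %d samples", ncol(vit), length(samples)
    ))
  }
  if (!is.null(posterior)) {
    if (is.character(posterior) && length(posterior) == 1) {
      posterior <- as.matrix(readr::read_table(posterior,
        col_names = FALSE,
        col_types = readr::cols(.default = "d"), progress = FALSE
      ))
    }
    posterior <- as.matrix(posterior)
    stopifnot(all(dim(posterior) == dim(vit)))
  }
  codes <- sort(unique(as.vector(vit)))
  if (any(!codes %in% seq_along(ancestry_codes))) {
    abort(sprintf(
      "Unknown ancestry code(s) in Viterbi matrix: %s",
      paste(setdiff(codes, seq_along(ancestry_codes)), collapse = ", ")
    ))
  }
  out <- list()
  for (j in seq_len(ncol(vit))) {
    ind <- samples[ceiling(j / 2)]
    hap <- (j + 1) %% 2 # columns 1,2 -> haplotypes 0,1
    for (chr in unique(markers$chrom)) {
      idx <- which(markers$chrom == chr)
      codes_j <- vit[idx, j]
      r <- rle(codes_j)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1
      cert <- rep(1, length(r$values))
      if (!is.null(posterior)) {
        cert <- vapply(seq_along(r$values), function(k) {
          min(posterior[idx[starts_i[k]:ends_i[k]], j])
        }, numeric(1))
      }
      out[[length(out) + 1]] <- tibble(
        individual_id = ind,
        haplotype = hap,
        chrom = chr,
        start = markers$pos[idx[starts_i]] - 1,
        end = as.numeric(markers$pos[idx[ends_i]]),
        ancestry = ancestry_codes[r$values],
        certainty = cert
      )
    }
  }
  bind_rows(out)
}

empty_segments <- function() {
  tibble(
    individual_id = character(), haplotype = integer(), chrom = character(),
    start = numeric(), end = numeric(), ancestry = character(),
    certainty = numeric()
  )
}

#' Validate a set of ancestry segments
#'
#' Checks coordinates, labels, certainty range, and that segments of one
#' (individual, haplotype, chromosome) do not overlap. Abutting half-open
#' intervals (`[0,100)` then `[100,200)`) are valid.
#'
#' @param segments A data frame of ancestry segments.
#' @return The validated segments as a tibble (invisibly unchanged).
#' @export
validate_ancestry_segments <- function(segments) {
  segments <- as_tibble(segments)
  required <- c(
    "individual_id", "haplotype", "chrom", "start", "end",
    "ancestry", "certainty"
  )
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    abort(sprintf("Segment table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(segments) == 0) {
    return(segments)
  }
  if (any(segments$end <= segments$start)) {
    abort(sprintf(
      "Segment(s) with end <= start at row(s): %s",
      paste(head(which(segments$end <= segments$start), 5), collapse = ", ")
    ))
  }
  if (any(segments$start < 0)) abort("Segment start coordinates must be >= 0")
  if (!all(segments$haplotype %in% c(0, 1))) {
    abort("haplotype must be 0 or 1")
  }
  assert_ancestry_labels(segments$ancestry)
  if (any(segments$certainty < 0 | segments$certainty > 1)) {
    abort("certainty must lie in [0, 1]")
  }
  overlaps <- segments %>%
    group_by(.data$individual_id, .data$haplotype, .data$chrom) %>%
    summarise(
      n_overlap = count_interval_overlaps(.data$start, .data$end),
      .groups = "drop"
    ) %>%
    filter(.data$n_overlap > 0)
  if (nrow(overlaps) > 0) {
    abort(sprintf(
      "Overlapping segments on haplotype(s): %s",
      paste(sprintf(
        "%s/h%d/%s", overlaps$individual_id, overlaps$haplotype,
        overlaps$chrom
      ), collapse = "; ")
    ))
  }
  segments
}

# Number of overlapping interval pairs among [start, end) intervals.
count_interval_overlaps <- function(start, end) {
  ir <- IRanges::IRanges(start = start + 1, end = end) # 1-based closed
  hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
  length(hits)
}

#' Write local-ancestry segments
#'
#' Writes segments in the native `segment_tsv` dialect (seven tab-separated
#' columns, `#`-prefixed header, 0-based half-open coordinates).
#' `write_ancestry_segments()` and [read_ancestry_segments()] round-trip.
#'
#' @param segments A validated segment tibble (see
#'   [read_ancestry_segments()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ancestry_segments <- function(segments, path) {
  segments <- validate_ancestry_segments(segments)
  header <- "#individual_id\thaplotype\tchrom\tstart\tend\tancestry\tcertainty"
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t%s\t%s",
    segments$individual_id, as.integer(segments$haplotype), segments$chrom,
    format(segments$start, scientific = FALSE, trim = TRUE),
    format(segments$end, scientific = FALSE, trim = TRUE),
    segments$ancestry,
    format(segments$certainty, scientific = FALSE, trim = TRUE)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' Reads a BED file (BED4+: chrom, start, end, name) of gene intervals.
#' Coordinates stay 0-based half-open as in the file. Genes are returned
#' sorted by (chrom, start); duplicate gene ids are an error. Entries on
#' sex chromosomes (chrX/chrY/X/Y) are dropped with a message, since the
#' homozygosity model applies to autosomes.
#'
#' @param path Path to a BED file with a name column.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-`, or `*` when absent).
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name)) {
    abort("BED input must carry a name column (gene id) on every record")
  }
  genes <- tibble(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1, # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  sex <- genes$chrom %in% c("chrX", "chrY", "X", "Y")
  if (any(sex)) {
    inform(sprintf("Dropping %d gene(s) on sex chromosomes", sum(sex)))
    genes <- genes[!sex, ]
  }
  if (any(genes$end <= genes$start)) {
    abort(sprintf(
      "Gene(s) with end <= start: %s",
      paste(head(genes$gene_id[genes$end <= genes$start], 5), collapse = ", ")
    ))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  arrange(genes, .data$chrom, .data$start)
}
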