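#' Run the full assortative-mating pipeline
#'
#' End-to-end driver: reads local-ancestry segments for one or more
#' populations, calls per-gene ancestry genotypes, applies the inclusion
#' threshold, filters and LD-prunes the polygenic gene sets, computes
#' per-gene AMI and per-phenotype Mantel-Haenszel meta-analyses, BH
#' q-values over the whole phenotype-by-population family, ancestry-driver
#' profiles, optional permutation nulls, and — with at least two
#' populations — the cross-population AMI variance. Results are written as
#' TSV tables plus a JSON manifest recording versions, seed, thresholds
#' and stage counts. Any stage error aborts with a stage-named message and
#' removes partial outputs.
#'
#' @param config A YAML file path or a list with entries:
#'   `segments` (named list population -> segment TSV, or one path),
#'   `genes_bed`, `gene_sets_gmt`, optional `ld_table`, `min_certainty`
#'   (default 0.99), `r2_max` (0.1), `min_set_size` (2), `permutations`
#'   (list: `random_mating`, `n_virtual`, `gene_set`, `n_perms`),
#'   `out_dir`, `seed`.
#' @return Invisibly, a list with `fits` (one `ami_fit` per population),
#'   `results` (combined phenotype table with family-wide q-values),
#'   `variance` (or NULL), and `manifest`.
#' @export
run_ami <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    written <<- c(written, p)
    p
  }
  result <- tryCatch(
    {
      stage <- "read inputs"
      for (f in c("segments", "genes_bed", "gene_sets_gmt")) {
        if (is.null(config[[f]])) abort(sprintf("config is missing '%s'", f))
      }
      seg_paths <- config$segments
      if (!is.list(seg_paths)) seg_paths <- list(pop = seg_paths)
      for (p in unlist(c(seg_paths, config$genes_bed, config$gene_sets_gmt,
                         config$ld_table))) {
        if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
      }
      genes <- read_gene_annotations(config$genes_bed)
      sets <- read_gene_sets(config$gene_sets_gmt)
      ld <- if (!is.null(config$ld_table)) read_ld_table(config$ld_table)
      perms <- config$permutations %||% list()
      seed <- config$seed %||% 1

      fits <- list()
      null_mating <- list()
      null_sets <- list()
      withr::with_seed(as.integer(seed), {
        for (pop in names(seg_paths)) {
          stage <- sprintf("genotype calling (%s)", pop)
          segments <- read_ancestry_segments(seg_paths[[pop]])
          calls <- call_gene_ancestry(
            segments, genes,
            min_certainty = config$min_certainty %||% 0.99,
            population = pop
          )
          stage <- sprintf("analysis (%s)", pop)
          fits[[pop]] <- ami_analysis(
            calls, sets,
            ld = ld, r2_max = config$r2_max %||% 0.1,
            min_set_size = config$min_set_size %||% 2, population = pop
          )
          if (isTRUE(perms$random_mating)) {
            stage <- sprintf("random-mating permutation (%s)", pop)
            thresholded <- apply_ancestry_threshold(calls)
            nm <- random_mating_null(
              thresholded,
              n_virtual = perms$n_virtual %||% 10000
            )
            null_mating[[pop]] <- mutate(nm, population_id = pop)
          }
          if (isTRUE(perms$gene_set)) {
            stage <- sprintf("gene-set permutation (%s)", pop)
            fit <- fits[[pop]]
            sizes <- count(fit$sets, .data$phenotype_id)
            n_perms <- perms$n_perms %||% 10000
            by_size <- lapply(
              sort(unique(sizes$n)),
              function(k) {
                random_geneset_null(fit$gene_table, k, n_perms = n_perms)
              }
            )
            names(by_size) <- as.character(sort(unique(sizes$n)))
            res <- fit$phenotype_results
            res$perm_p_value <- vapply(seq_len(nrow(res)), function(i) {
              k <- sizes$n[sizes$phenotype_id == res$phenotype_id[i]]
              null <- by_size[[as.character(k)]]$log_or
              (1 + sum(abs(null) >= abs(res$pooled_log_or[i]))) /
                (length(null) + 1)
            }, numeric(1))
            fits[[pop]]$phenotype_results <- res
            null_sets[[pop]] <- bind_rows(lapply(names(by_size), function(k) {
              tibble(
                population_id = pop, set_size = as.integer(k),
                log_or = by_size[[k]]$log_or
              )
            }))
          }
        }
      })

      stage <- "family-wide FDR"
      results <- bind_rows(lapply(fits, function(f) f$phenotype_results))
      results$q_value <- bh_qvalues(results$p_value)

      stage <- "cross-population variance"
      variance <- NULL
      if (length(fits) >= 2) {
        null_var <- NULL
        if (length(null_sets) == length(fits) && length(null_sets) > 0) {
          # variance across populations of matched null draws (median size)
          med <- as.character(stats::median(
            unlist(lapply(fits, function(f) count(f$sets, .data$phenotype_id)$n))
          ))
          mat <- sapply(null_sets, function(ns) {
            sub <- filter(ns, .data$set_size == as.integer(med))
            if (nrow(sub) == 0) rep(NA_real_, 0) else sub$log_or
          })
          if (is.matrix(mat) && nrow(mat) > 1) {
            null_var <- apply(mat, 1, var)
          }
        }
        variance <- tryCatch(
          ami_population_variance(results, null_variances = null_var),
          error = function(e) NULL
        )
      }

      stage <- "write outputs"
      gene_tables <- bind_rows(lapply(fits, function(f) f$gene_table))
      emit(gene_tables, "gene_table.tsv")
      emit(results, "phenotype_results.tsv")
      emit(bind_rows(lapply(fits, function(f) f$ah_profiles)), "ah_profiles.tsv")
      if (!is.null(variance)) emit(variance, "ami_variance.tsv")
      if (length(null_mating) > 0) {
        emit(bind_rows(null_mating), "null_random_mating.tsv")
      }
      if (length(null_sets) > 0) {
        emit(bind_rows(null_sets), "null_gene_sets.tsv")
      }

      manifest <- list(
        package = "amindex",
        version = as.character(packageVersion("amindex")),
        seed = seed,
        min_certainty = config$min_certainty %||% 0.99,
        r2_max = config$r2_max %||% 0.1,
        min_set_size = config$min_set_size %||% 2,
        populations = lapply(fits, function(f) {
          c(
            list(threshold = f$threshold$value,
                 mean_pairs = f$threshold$mean_pairs,
                 sd_pairs = f$threshold$sd_pairs),
            f$stage_counts
          )
        }),
        outputs = basename(written)
      )
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path,
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      written <- c(written, manifest_path)
      list(
        fits = fits, results = results, variance = variance,
        manifest = manifest
      )
    },
    error = function(e) {
      unlink(written)
      abort(sprintf("run_ami failed at stage '%s': %s", stage, conditionMessage(e)))
    }
  )
  invisible(result)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

#' Simulate and write an admixed dataset
#'
#' Thin wrapper over [simulate_admixed_population()] that writes the
#' simulated final generation as a segment TSV, the gene annotations as
#' BED, and the simulation truth (config echo, per-generation mate-pair
#' ancestry correlation, realized ancestry means) as YAML.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [simulate_admixed_population()].
#' @return Invisibly, the `admix_sim` object.
#' @export
run_simulate <- function(out_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_admixed_population(...)
  write_ancestry_segments(
    calls_to_segments(sim$calls, sim$genes),
    file.path(out_dir, "segments.tsv")
  )
  readr::write_tsv(
    tibble(
      chrom = sim$genes$chrom, start = sim$genes$start, end = sim$genes$end,
      name = sim$genes$gene_id, score = 0L, strand = "."
    ),
    file.path(out_dir, "genes.bed"),
    col_names = FALSE, progress = FALSE
  )
  truth <- sim$truth$config
  truth$per_generation <- lapply(
    seq_len(nrow(sim$truth$per_generation)),
    function(i) as.list(sim$truth$per_generation[i, ])
  )
  yaml::write_yaml(truth, file.path(out_dir, "sim_truth.yaml"))
  invisible(sim)
}
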