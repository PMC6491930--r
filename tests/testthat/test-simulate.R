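test_that("a single-ancestry founder pool stays fixed forever", {
  sim <- simulate_admixed_population(
    n_individuals = 20, n_genes = 10, n_generations = 3, n_burnin = 2,
    founder_proportions = c(AFR = 1, EUR = 0, NAT = 0),
    assortment_strength = 4, seed = 1
  )
  expect_true(all(sim$calls$anc1 == "AFR"))
  expect_true(all(sim$calls$anc2 == "AFR"))
  expect_equal(sim$truth$per_generation$mean_AFR, rep(1, 5))
})

test_that("simulations are deterministic under a seed", {
  a <- simulate_admixed_population(
    n_individuals = 30, n_genes = 15, n_generations = 2, n_burnin = 2,
    assortment_strength = 2, seed = 42
  )
  b <- simulate_admixed_population(
    n_individuals = 30, n_genes = 15, n_generations = 2, n_burnin = 2,
    assortment_strength = 2, seed = 42
  )
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth$per_generation, b$truth$per_generation)
})

test_that("zero generations returns the homozygous founder population", {
  sim <- simulate_admixed_population(
    n_individuals = 50, n_genes = 10, n_generations = 0, n_burnin = 0, seed = 2
  )
  expect_true(all(sim$calls$anc1 == sim$calls$anc2))
  # each individual is one pure ancestry at every gene
  per_ind <- dplyr::summarise(
    dplyr::group_by(sim$calls, individual_id),
    n_anc = dplyr::n_distinct(anc1)
  )
  expect_true(all(per_ind$n_anc == 1))
})

test_that("one generation of random mating is Hardy-Weinberg consistent", {
  # single locus per replicate: at generation 1 from pure founders all genes
  # share the same founder pairing, so replicates (not genes) provide the
  # independent draws for the unbiasedness check
  devs <- sapply(1:20, function(s) {
    sim <- simulate_admixed_population(
      n_individuals = 400, n_genes = 1, n_generations = 1, n_burnin = 0,
      founder_proportions = c(AFR = 0.5, EUR = 0.5, NAT = 0),
      assortment_strength = 0, seed = 400 + s
    )
    tbl <- gene_count_table(sim$calls)
    tbl$obs_hom - tbl$exp_hom
  })
  mc_se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * mc_se + 1)
})

test_that("expected ancestry proportions persist across generations", {
  # mating reshuffles genotypes but not haplotype labels: means drift only
  devs <- sapply(1:6, function(s) {
    sim <- simulate_admixed_population(
      n_individuals = 150, n_genes = 100, n_generations = 3, n_burnin = 3,
      assortment_strength = 5, seed = 100 + s
    )
    pg <- sim$truth$per_generation
    pg$mean_AFR[nrow(pg)] - pg$mean_AFR[1]
  })
  mc_se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * mc_se + 0.02)
})

test_that("mate-pair ancestry correlation rises with assortment strength", {
  cors <- sapply(c(0, 2, 10), function(s) {
    mean(sapply(1:6, function(r) {
      sim <- simulate_admixed_population(
        n_individuals = 100, n_genes = 60, n_generations = 2, n_burnin = 4,
        assortment_strength = s, seed = 300 + r
      )
      pg <- sim$truth$per_generation
      mean(pg$mate_correlation[pg$phase == "mate_choice"], na.rm = TRUE)
    }))
  })
  expect_true(all(diff(cors) > 0))
  expect_lt(abs(cors[1]), 0.2)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(
    simulate_admixed_population(assortment_strength = -1),
    "assortment_strength"
  )
  expect_error(
    simulate_admixed_population(assort_on = "gene_subset"),
    "trait_genes"
  )
  expect_error(
    simulate_admixed_population(
      assort_on = "gene_subset", trait_genes = "not_a_gene"
    ),
    "universe"
  )
  expect_error(
    simulate_admixed_population(founder_proportions = c(AFR = 0.5, EUR = 0.6, NAT = 0)),
    "sum"
  )
})

test_that("simulated calls round-trip through the segment format", {
  sim <- simulate_admixed_population(
    n_individuals = 15, n_genes = 30, n_generations = 1, n_burnin = 1, seed = 4
  )
  segs <- calls_to_segments(sim$calls, sim$genes)
  expect_true(all(segs$certainty == 1))
  path <- write_segment_file(segs)
  back <- call_gene_ancestry(read_ancestry_segments(path), sim$genes)
  expect_equal(
    as.data.frame(dplyr::arrange(back, gene_id, individual_id)),
    as.data.frame(dplyr::arrange(sim$calls, gene_id, individual_id)),
    ignore_attr = TRUE
  )
})
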