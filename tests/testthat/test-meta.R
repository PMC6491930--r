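test_that("one stratum pools to its own log odds ratio exactly", {
  tbl <- count_row(60, 40, 50, 50)
  m <- meta_ami(tbl)
  expect_identical(m$pooled_log_or, log((60 * 50) / (40 * 50)))
  expect_equal(m$k_genes, 1)
  expect_true(m$ci_low <= m$pooled_log_or && m$pooled_log_or <= m$ci_high)
})

test_that("replicated strata leave the pooled estimate unchanged", {
  one <- count_row(60, 40, 50, 50)
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    count_row(60, 40, 50, 50, gene_id = sprintf("g%02d", i))
  }))
  expect_equal(meta_ami(five)$pooled_log_or, meta_ami(one)$pooled_log_or)
})

test_that("pooled estimates match an independent Mantel-Haenszel oracle", {
  withr::local_seed(21)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    tabs <- lapply(seq_len(k), function(i) {
      matrix(sample(1:40, 4, replace = TRUE) + runif(4), nrow = 2, byrow = TRUE)
    })
    counts <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      count_row(
        tabs[[i]][1, 1], tabs[[i]][1, 2], tabs[[i]][2, 1], tabs[[i]][2, 2],
        gene_id = sprintf("g%02d", i)
      )
    }))
    expect_equal(meta_ami(counts)$pooled_log_or, mh_oracle(tabs), tolerance = 1e-12)
  }
})

test_that("pooled estimate and SE agree with metafor on integer tables", {
  skip_if_not_installed("metafor")
  withr::local_seed(22)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    a <- sample(5:60, k)
    b <- sample(5:60, k)
    c <- sample(5:60, k)
    d <- sample(5:60, k)
    counts <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      count_row(a[i], b[i], c[i], d[i], gene_id = sprintf("g%02d", i))
    }))
    m <- meta_ami(counts)
    rma <- metafor::rma.mh(
      ai = a, bi = b, ci = c, di = d, measure = "OR",
      correct = FALSE, drop00 = FALSE
    )
    expect_equal(m$pooled_log_or, as.numeric(rma$beta), tolerance = 1e-9)
    expect_equal(m$se, rma$se, tolerance = 1e-9)
  }
})

test_that("meta_ami drops undefined genes and errors when nothing is left", {
  counts <- dplyr::bind_rows(
    count_row(60, 40, 50, 50, "g1"),
    count_row(50, 0, 50, 0, "g2") # fixed locus
  )
  expect_message(m <- meta_ami(counts), "dropped 1")
  expect_equal(m$k_genes, 1)
  expect_error(
    suppressMessages(meta_ami(count_row(50, 0, 50, 0))),
    "empty phenotype"
  )
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(0.01), 0.01)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AMI distribution comparison behaves like a two-sample t-test", {
  same <- c(0.1, 0.2, 0.3)
  r <- compare_ami_distributions(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  withr::local_seed(31)
  obs <- rnorm(10000, 0.11, 0.14)
  nul <- rnorm(10000, -0.01, 0.03)
  r2 <- compare_ami_distributions(obs, nul)
  expect_gt(r2$t, 0)
  expect_lt(r2$p_value, 1e-10)
  # antisymmetry in the argument order
  r3 <- compare_ami_distributions(nul, obs)
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p_value, r2$p_value)
})

test_that("cross-population variance is normalized by the phenotype mean", {
  # hand-built: variances {0.02, 0.04, 0.06} -> normalized {0.5, 1.0, 1.5}
  make <- function(ph, vals) {
    tibble::tibble(
      phenotype_id = ph, population_id = sprintf("p%d", seq_along(vals)),
      pooled_log_or = vals
    )
  }
  center_var <- function(v, n) sqrt(v) * scale(seq_len(n), TRUE, FALSE) /
    sd(seq_len(n))
  vals <- lapply(c(0.02, 0.04, 0.06), function(v) as.numeric(center_var(v, 4)))
  res <- ami_population_variance(dplyr::bind_rows(
    make("a", vals[[1]]), make("b", vals[[2]]), make("c", vals[[3]])
  ))
  expect_equal(res$raw_variance, c(0.02, 0.04, 0.06), tolerance = 1e-12)
  expect_equal(res$normalized_variance, c(0.5, 1.0, 1.5), tolerance = 1e-12)

  # identical values across populations -> zero variance
  flat <- make("a", rep(0.3, 4))
  flat2 <- make("b", c(0.1, 0.2, 0.3, 0.4))
  res2 <- ami_population_variance(dplyr::bind_rows(flat, flat2))
  expect_equal(res2$raw_variance[res2$phenotype_id == "a"], 0)

  # single phenotype -> normalized variance 1 by construction
  res3 <- ami_population_variance(make("solo", c(0.1, 0.5)))
  expect_equal(res3$normalized_variance, 1)

  # phenotypes missing a population are excluded
  partial <- tibble::tibble(
    phenotype_id = "p", population_id = "p1", pooled_log_or = 0.2
  )
  expect_message(
    res4 <- ami_population_variance(dplyr::bind_rows(flat, flat2, partial)),
    "excluded 1"
  )
  expect_false("p" %in% res4$phenotype_id)
})
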