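test_that("relative frequencies are exact count ratios", {
  rf <- relative_frequencies(c(a = 1, b = 10, c = 100))
  expect_equal(rf$p, c(1, 10, 100) / 111)
  expect_equal(sum(rf$p), 1, tolerance = 1e-12)

  expect_equal(relative_frequencies(c(5, 0, 0))$p, c(1, 0, 0))
  expect_equal(relative_frequencies(c(2, 2, 2, 2))$p, rep(0.25, 4))
  expect_error(expression_profile(c(0, 0, 0)), "all counts are zero")
})

test_that("worked three-gene examples reproduce the published entropies", {
  expect_equal(round(shannon_diversity(c(1, 10, 100))$H, 2), 0.51)
  expect_equal(round(shannon_diversity(c(10, 100, 1))$H, 2), 0.51)
  expect_equal(round(shannon_diversity(c(1, 10, 1000))$H, 2), 0.09)
})

test_that("entropy handles uniform, degenerate and zero-padded profiles", {
  expect_identical(shannon_diversity(c(1, 1, 1, 1))$H, 2)
  expect_identical(shannon_diversity(c(7, 0, 0))$H, 0)
  # zero counts contribute nothing and are excluded from g_nonzero
  d <- shannon_diversity(c(1, 10, 100, 0, 0))
  expect_equal(d$H, shannon_diversity(c(1, 10, 100))$H)
  expect_identical(d$g_nonzero, 3L)
})

test_that("entropy invariants hold over random profiles", {
  set.seed(101)
  max_abs_dev <- 0
  for (i in 1:1000) {
    counts <- random_profile()
    d <- shannon_diversity(counts)
    # bounds
    expect_gte(d$H, 0)
    expect_lte(d$H, log2(d$g_nonzero) + 1e-12)
    # oracle equivalence by the independent natural-log route
    max_abs_dev <- max(max_abs_dev, abs(d$H - entropy_oracle(counts)))
    # permutation invariance
    expect_equal(shannon_diversity(sample(counts))$H, d$H, tolerance = 1e-12)
  }
  expect_lte(max_abs_dev, 1e-12)
})

test_that("entropy is scale invariant and monotone under gene merging", {
  set.seed(202)
  for (i in 1:50) {
    counts <- random_profile(allow_zero = FALSE)
    H0 <- shannon_diversity(counts)$H
    # multiplying all counts by a constant leaves frequencies unchanged
    expect_equal(shannon_diversity(counts * sample(2:17, 1L))$H, H0,
                 tolerance = 1e-12)
    # merging two expressed genes never increases H
    ij <- sample(length(counts), 2L)
    merged <- counts[-ij[2L]]
    merged[which(seq_along(counts)[-ij[2L]] == ij[1L])] <- sum(counts[ij])
    expect_lte(shannon_diversity(merged)$H, H0 + 1e-12)
  }
})

test_that("diversity_table vectorizes over samples and joins metadata", {
  m <- worked_example_counts()
  md <- data.frame(sample_id = colnames(m), concentration_mM = c(0, 0, 1))
  tab <- diversity_table(m, md)
  expect_equal(round(tab$H, 2), c(0.51, 0.51, 0.09))
  expect_equal(tab$sample_id, colnames(m))
  expect_equal(tab$concentration_mM, c(0, 0, 1))

  single <- diversity_table(m[, 1, drop = FALSE])
  expect_equal(single$H, shannon_diversity(m[, 1])$H)

  expect_error(diversity_table(m, md[-2, ]), "case2")
})

test_that("removal curve renormalizes after deleting top genes", {
  rc <- removal_curve(c(a = 1000, b = 10, c = 1), ks = 1)
  # k = 0 row reproduces the full-profile diversity exactly
  expect_identical(rc$H[rc$k == 0], shannon_diversity(c(1000, 10, 1))$H)
  # hand-computed two-term entropy of (10, 1) renormalized
  expect_equal(rc$H[rc$k == 1],
               -(10 / 11) * log2(10 / 11) - (1 / 11) * log2(1 / 11),
               tolerance = 1e-12)
  expect_equal(rc$residual_mass[rc$k == 1], 11 / 1011, tolerance = 1e-12)
  expect_error(removal_curve(c(1000, 10, 1), ks = 3), "smaller than")
})

test_that("removal curve matches brute-force recomputation on random profiles", {
  set.seed(303)
  for (i in 1:20) {
    counts <- random_profile(allow_zero = FALSE)
    names(counts) <- sprintf("g%03d", seq_along(counts))
    k <- sample(seq_len(length(counts) - 1L), 1L)
    rc <- removal_curve(counts, ks = k)
    ord <- order(-counts, names(counts))
    kept <- counts[-ord[seq_len(k)]]
    expect_equal(rc$H[rc$k == k], entropy_oracle(kept), tolerance = 1e-12)
  }
})

test_that("ties among equally expressed genes are broken by gene id", {
  counts <- c(z = 5, a = 5, m = 5, b = 1)
  rc1 <- removal_curve(counts, ks = 2)
  # removing {a, m} leaves (z = 5, b = 1)
  expect_equal(rc1$H[rc1$k == 2], entropy_oracle(c(5, 1)), tolerance = 1e-12)
  expect_equal(occupancy_fraction(counts, top_n = 2), 10 / 16)
})

test_that("sorted log profile is the descending log2 frequency vector", {
  slp <- sorted_log_profile(c(a = 1, b = 10, c = 100))
  expect_equal(slp$log2p, log2(c(100, 10, 1) / 111), tolerance = 1e-12)
  expect_equal(slp$rank, 1:3)
  expect_true(all(diff(slp$log2p) <= 0))
  expect_true(all(slp$log2p <= 0))
  expect_equal(sum(2^slp$log2p), 1, tolerance = 1e-9)

  expect_equal(sorted_log_profile(rep(2, 8))$log2p, rep(-3, 8))
  # zero-count genes are excluded entirely
  expect_equal(nrow(sorted_log_profile(c(3, 0, 1, 0))), 2L)
})

test_that("occupancy fraction sums selected relative frequencies", {
  counts <- c(a = 1, b = 10, c = 100)
  expect_equal(occupancy_fraction(counts, top_n = 1), 100 / 111)
  expect_equal(occupancy_fraction(counts, top_n = 3), 1)
  expect_equal(occupancy_fraction(counts, genes = c("a", "b")), 11 / 111)
  expect_error(occupancy_fraction(counts, genes = "nope"), "unknown gene ids: nope")
  expect_error(occupancy_fraction(counts, top_n = 1, genes = "a"), "exactly one")
  expect_error(occupancy_fraction(counts), "exactly one")
})
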