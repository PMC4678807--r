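test_that("baseline weights are a pure function of the seed", {
  cfg <- generator_config(n_genes = 500, seed = 5)
  expect_identical(make_baseline_weights(cfg), make_baseline_weights(cfg))
  expect_false(identical(make_baseline_weights(cfg, seed = 6),
                         make_baseline_weights(cfg, seed = 7)))
  expect_identical(names(make_baseline_weights(cfg))[1:10],
                   dominant_genes(cfg))
})

test_that("vanishing shape gives a near-uniform, maximum-entropy baseline", {
  cfg <- generator_config(n_genes = 1000, baseline_shape = 1e-4, seed = 5)
  H <- shannon_diversity(sample_counts(make_baseline_weights(cfg),
                                       1e6, seed = 1))$H
  expect_equal(H, log2(1000), tolerance = 0.01)
})

test_that("apply_dominance pins the dominant set's mass at phi exactly", {
  cfg <- generator_config(n_genes = 800, n_dominant = 10, seed = 9)
  w <- make_baseline_weights(cfg)
  for (phi in c(0.1, 0.4, 0.9)) {
    wd <- apply_dominance(w, cfg, phi)
    expect_equal(sum(wd[dominant_genes(cfg)]), phi, tolerance = 1e-12)
    expect_equal(sum(wd), 1, tolerance = 1e-12)
    # relative structure within each side of the split is preserved
    rest <- setdiff(names(w), dominant_genes(cfg))
    expect_equal(wd[rest] / sum(wd[rest]), w[rest] / sum(w[rest]),
                 tolerance = 1e-12)
  }
  # phi -> 0 leaves the baseline unchanged up to normalization
  expect_equal(apply_dominance(w, cfg, 0), w / sum(w), tolerance = 1e-12)
  expect_error(apply_dominance(w, cfg, 1), "must be < 1")
})

test_that("dominance strictly lowers expected-frequency entropy", {
  cfg <- generator_config(n_genes = 2000, seed = 13)
  w <- make_baseline_weights(cfg)
  H0 <- -sum((w / sum(w)) * log2(w / sum(w)))
  wd <- apply_dominance(w, cfg, 0.4)
  H1 <- -sum(wd[wd > 0] * log2(wd[wd > 0]))
  expect_lt(H1, H0)
})

test_that("the switch rule reproduces the hysteresis loop", {
  sp <- switch_params()
  run <- function(conc) {
    switch_state(exposure_history(rep(10, length(conc)), conc), sp)$final_state
  }
  expect_identical(run(c(0, 1.0)), "low")
  expect_identical(run(c(0, 0.25)), "high")       # never crossed theta_up
  expect_identical(run(c(0, 1.0, 0.25)), "low")   # 0.25 retains the low state
  expect_identical(run(c(0, 1.0, 0)), "high")     # washout relaxes to high
  # trajectory records the state after every step
  tr <- switch_state(exposure_history(c(80, 10, 10), c(0, 1.0, 0.25)), sp)
  expect_identical(tr$trajectory$state, c("high", "low", "low"))
  expect_error(switch_params(theta_up = 0.1, theta_down = 0.5))
})

test_that("state noise flips outcomes at the configured rate", {
  sp <- switch_params(state_noise = 0.5)
  hist1 <- exposure_history(10, 1.0)
  outcomes <- vapply(1:200, function(s) switch_state(hist1, sp, seed = s)$final_state,
                     character(1))
  # with p = 0.5 both outcomes must occur, and the split is near-even
  expect_true(all(c("high", "low") %in% outcomes))
  expect_gt(mean(outcomes == "high"), 0.3)
  expect_lt(mean(outcomes == "high"), 0.7)
  # same seed, same outcome
  expect_identical(switch_state(hist1, sp, seed = 3)$final_state,
                   switch_state(hist1, sp, seed = 3)$final_state)
})

test_that("multinomial sampling matches expected-frequency entropy", {
  cfg <- small_config()
  w <- make_baseline_weights(cfg)
  H_expected <- -sum((w / sum(w)) * log2(w / sum(w)))
  Hs <- vapply(1:50, function(s) {
    shannon_diversity(sample_counts(w, cfg$library_size, seed = s))$H
  }, numeric(1))
  expect_true(all(abs(Hs - H_expected) < 0.15))

  # library_size = 1 yields a single read
  p1 <- sample_counts(w, 1, seed = 1)
  expect_identical(sum(p1$counts), 1)
  expect_identical(sum(p1$counts > 0), 1L)
  expect_error(sample_counts(w, 0, seed = 1), "positive")
})

test_that("dominant-set occupancy estimates phi within binomial error", {
  cfg <- small_config()
  w <- apply_dominance(make_baseline_weights(cfg), cfg)
  phi <- cfg$dominance_mass
  se <- sqrt(phi * (1 - phi) / cfg$library_size)
  occ <- vapply(1:100, function(s) {
    occupancy_fraction(sample_counts(w, cfg$library_size, seed = s),
                       genes = dominant_genes(cfg))
  }, numeric(1))
  expect_true(all(abs(occ - phi) < 4 * se))
  expect_lt(abs(mean(occ) - phi), 2 * se / sqrt(100) * 3)
})

test_that("calibration hits its entropy targets and is monotone", {
  cfg <- generator_config(n_genes = 2000, seed = 17)
  cfg <- calibrate_baseline_shape(8.5, cfg)
  w <- make_baseline_weights(cfg, derive_seed(cfg$seed, "calibrate", 1))
  expect_equal(-sum((w / sum(w)) * log2(w / sum(w))), 8.5, tolerance = 0.3)

  phi_low <- calibrate_dominance(6.5, cfg)
  wd <- apply_dominance(w, cfg, phi_low)
  expect_equal(-sum(wd * log2(wd)), 6.5, tolerance = 0.3)

  # a higher diversity target needs less dominance (larger target -> smaller phi)
  expect_gt(calibrate_dominance(6.0, cfg), phi_low)
  phi_high <- calibrate_dominance(7.0, cfg)
  expect_gt(phi_high, 0)
  expect_lt(phi_high, phi_low)

  # targets outside the achievable band are rejected with the band reported
  expect_error(calibrate_dominance(20, cfg), "achievable band")
  expect_error(calibrate_dominance(0.5, cfg), "achievable band")
})

test_that("simulate_experiment is deterministic and arm-stable", {
  cfg <- small_config()
  des <- standard_design(n_replicates = 2)
  s1 <- simulate_experiment(des, cfg, switch_params(), seed = 3)
  s2 <- simulate_experiment(des, cfg, switch_params(), seed = 3)
  expect_identical(s1, s2)
  # written files are byte-identical across reruns
  f1 <- tempfile(); f2 <- tempfile()
  write_count_matrix(s1$counts, f1)
  write_count_matrix(s2$counts, f2)
  expect_identical(readLines(f1), readLines(f2))
  # adding an arm never perturbs existing arms
  des2 <- experiment_design(c(des$arms, list(
    list(arm_id = "extra", history = exposure_history(10, 0), n_replicates = 1))))
  s3 <- simulate_experiment(des2, cfg, switch_params(), seed = 3)
  expect_identical(s3$counts[, colnames(s1$counts)], s1$counts)
})

test_that("experiment design rejects invalid arms", {
  h <- exposure_history(10, 0)
  expect_error(experiment_design(list(
    list(arm_id = "a", history = h, n_replicates = 1),
    list(arm_id = "a", history = h, n_replicates = 1))), "duplicate arm ids")
  expect_error(experiment_design(list(
    list(arm_id = "a", history = h, n_replicates = 0))), "n_replicates")
  expect_error(exposure_history(numeric(0), numeric(0)), "nonempty")
  expect_error(exposure_history(-1, 0), "positive")
})

test_that("the simulated study separates the two diversity states", {
  cfg <- small_config()
  sim <- simulate_experiment(standard_design(), cfg, switch_params(), seed = 11)
  expect_identical(ncol(sim$counts), 21L)
  div <- diversity_table(sim$counts, sim$metadata)
  expect_gt(min(div$H[div$state == "high"]) - max(div$H[div$state == "low"]), 0.5)
  # hysteresis arms realize the (high, low, low) end-state pattern
  states <- unique(sim$metadata[sim$metadata$arm_id %in%
    c("pb0_after1.0", "pb0.25_after1.0", "pb0.25"), c("arm_id", "state")])
  expect_identical(states$state[match(c("pb0_after1.0", "pb0.25_after1.0", "pb0.25"),
                                      states$arm_id)],
                   c("high", "low", "high"))
})

test_that("dominated profiles show the dominance signature downstream", {
  cfg <- small_config()
  w_low <- apply_dominance(make_baseline_weights(cfg), cfg)
  prof <- sample_counts(w_low, cfg$library_size, seed = 2)
  # the configured set occupies more than one third of the transcriptome
  expect_gt(occupancy_fraction(prof, genes = dominant_genes(cfg)), 1 / 3)
  # a single dominant gene holding phi > 1/3 shows up at the top of the
  # sorted log2 profile
  cfg1 <- generator_config(n_genes = 2000, n_dominant = 1,
                           dominance_mass = 0.4, seed = 23)
  w1 <- apply_dominance(make_baseline_weights(cfg1), cfg1)
  slp <- sorted_log_profile(sample_counts(w1, 2e5, seed = 3))
  expect_gt(slp$log2p[1], log2(1 / 3))
  # removal curves converge: dominated vs diffuse gap shrinks with k
  w_high <- make_baseline_weights(cfg)
  p_lo <- sample_counts(w_low, cfg$library_size, seed = 4)
  p_hi <- sample_counts(w_high, cfg$library_size, seed = 5)
  gap <- function(k) abs(removal_curve(p_hi, ks = k)$H[2] -
                         removal_curve(p_lo, ks = k)$H[2])
  expect_lt(gap(500), abs(shannon_diversity(p_hi)$H - shannon_diversity(p_lo)$H))
})
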