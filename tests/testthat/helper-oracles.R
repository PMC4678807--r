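# Independent oracles and fixture builders shared across the suite.

# Entropy by an independent route: natural-log summation divided by ln 2,
# dropping zero-frequency terms before taking logs.
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# Exact two-sided permutation p-value by direct enumeration over logical
# inclusion masks (a different route than the implementation's combn walk).
perm_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  masks <- masks[rowSums(masks) == length(a), , drop = FALSE]
  stats <- apply(masks, 1L, function(m) {
    m <- as.logical(m)
    abs(mean(pooled[m]) - mean(pooled[!m]))
  })
  list(p = mean(stats >= obs - 1e-12), n_partitions = nrow(masks))
}

# Random small expression profile; sizes and counts kept modest so the
# property loops stay fast.
random_profile <- function(max_genes = 200L, allow_zero = TRUE) {
  g <- sample(2:max_genes, 1L)
  counts <- stats::rpois(g, lambda = sample(c(1, 5, 50), 1L))
  if (!allow_zero) counts <- counts + 1L
  if (!any(counts > 0)) counts[sample(g, 1L)] <- 1L
  counts
}

# The 15 dose-ladder (concentration, diversity) pairs reported for
# phenobarbital-exposed fat-body cultures.
printed_ladder <- function() {
  df <- phenobarbital_diversities()
  df[df$history_id == "naive", ]
}

# A small calibrated generator for fast end-to-end tests; entropy targets
# scale down with the gene count but preserve the two-state structure.
small_config <- function(seed = 7L, n_genes = 2000L, library_size = 2e5) {
  calibrate_generator(
    generator_config(n_genes = n_genes, library_size = library_size,
                     seed = seed),
    target_high = 8.5, target_low = 6.5)
}
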