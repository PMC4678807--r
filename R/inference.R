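#' Pearson correlation test between dose and diversity
#'
#' Product-moment correlation of drug concentration against transcriptome
#' diversity, with the t statistic on n - 2 degrees of freedom, a two-sided
#' p-value, and a 95% confidence interval from the Fisher z transform
#' (atanh(r) +/- 1.96 / sqrt(n - 3), back-transformed).
#'
#' @param x Numeric vector, e.g. final drug concentration in mM.
#' @param y Numeric vector of the same length, e.g. diversity in bits.
#' @return An object of class `correlation_result`: a list with `r`,
#'   `t_stat`, `df` (= n - 2), `p_two_sided`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_correlation_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input vector is constant", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  z <- atanh(r)
  half <- 1.96 / sqrt(n - 3)
  structure(
    list(r = r,
         t_stat = unname(ct$statistic),
         df = unname(ct$parameter),
         p_two_sided = ct$p.value,
         ci_low = tanh(z - half),
         ci_high = tanh(z + half),
         n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (t = %.3f, df = %d, p = %.4g), 95%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$t_stat, x$df, x$p_two_sided, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

# Accepts either a named list of numeric vectors (names = concentrations) or
# a two-column data.frame (concentration, value); returns the named list.
as_dose_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L) stop("need concentration and value columns", call. = FALSE)
    groups <- split(groups[[2L]], groups[[1L]])
  }
  if (!is.list(groups) || is.null(names(groups))) {
    stop("`groups` must be a named list (names = concentrations) or a data.frame",
         call. = FALSE)
  }
  conc <- suppressWarnings(as.numeric(names(groups)))
  if (anyNA(conc)) stop("group names must be numeric concentrations", call. = FALSE)
  if (any(!lengths(groups))) stop("every group must be nonempty", call. = FALSE)
  groups[order(conc)]
}

#' Per-group summary of diversity by concentration
#'
#' @param groups Named list mapping concentration (as names, mM) to numeric
#'   diversity vectors (bits), or a data.frame with concentration in the
#'   first column and diversity in the second.
#' @return A data.frame with `concentration_mM`, `n`, `mean`, `sd` (sample
#'   sd, n - 1 denominator; `NA` for singleton groups), ordered by
#'   concentration.
#' @export
group_summary <- function(groups) {
  groups <- as_dose_groups(groups)
  data.frame(
    concentration_mM = as.numeric(names(groups)),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    row.names = NULL
  )
}

#' Locate the tipping point between concentration groups
#'
#' Orders the concentration groups numerically, computes each group's mean
#' diversity, and returns the pair of adjacent concentrations with the
#' largest absolute difference in means: the interval across which the
#' diversity statistic jumps between its two levels. The separation score
#' scales that gap by the pooled within-group standard deviation.
#'
#' @inheritParams group_summary
#' @return An object of class `tipping_point_result`: a list with
#'   `ordered_concentrations`, `group_means`, `gap_interval` (the two
#'   adjacent concentrations, mM), `gap_size` (bits) and
#'   `separation_score` (gap / pooled within-group sd).
#' @export
detect_tipping_point <- function(groups) {
  groups <- as_dose_groups(groups)
  if (length(groups) < 2L) stop("need at least 2 concentration groups", call. = FALSE)
  conc <- as.numeric(names(groups))
  means <- vapply(groups, mean, numeric(1))
  gaps <- abs(diff(means))
  i <- which.max(gaps)
  dfs <- lengths(groups) - 1L
  pooled_sd <- if (sum(dfs) > 0L) {
    vars <- vapply(groups, function(v) if (length(v) > 1L) stats::var(v) else 0, numeric(1))
    sqrt(sum(dfs * vars) / sum(dfs))
  } else 0
  structure(
    list(ordered_concentrations = conc,
         group_means = unname(means),
         gap_interval = c(conc[i], conc[i + 1L]),
         gap_size = unname(gaps[i]),
         separation_score = unname(gaps[i]) / (pooled_sd + 1e-12)),
    class = "tipping_point_result"
  )
}

#' @export
print.tipping_point_result <- function(x, ...) {
  cat(sprintf("<tipping_point_result> largest jump between %g and %g mM: %.3f bits (separation %.1f)\n",
              x$gap_interval[1], x$gap_interval[2], x$gap_size, x$separation_score))
  invisible(x)
}

#' Exact permutation test for hysteresis between exposure histories
#'
#' Compares the diversity of two small groups of samples that ended at the
#' same final condition via different exposure histories. The statistic is
#' the absolute difference of group means; significance is the fraction of
#' all C(n_a + n_b, n_a) relabelings of the pooled values whose statistic
#' is at least the observed one (two-sided by absolute value). Groups up to
#' a combined C(n, n_a) of 184,756 (n = 20 balanced) are enumerated
#' exactly; larger problems fall back to seeded Monte-Carlo sampling of
#' relabelings.
#'
#' With 3 vs 3 samples there are only 20 partitions, so the smallest
#' attainable two-sided p-value is 2/20 = 0.1; exact p-values are always
#' multiples of 1/n_partitions.
#'
#' @param group_a,group_b Numeric diversity vectors (bits), both nonempty.
#' @param n_draws Number of Monte-Carlo relabelings when exact enumeration
#'   is infeasible.
#' @param seed Seed for the Monte-Carlo fallback (ignored when exact).
#' @return An object of class `hysteresis_result`: a list with
#'   `group_a_values`, `group_b_values`, `mean_diff` (mean(a) - mean(b)),
#'   `p_exact`, `n_partitions`, and `method` ("exact" or "monte-carlo").
#' @export
hysteresis_permutation_test <- function(group_a, group_b,
                                        n_draws = 1e5, seed = 1L) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  pooled <- c(a, b)
  n_a <- length(a); n <- length(pooled)
  n_part <- choose(n, n_a)
  obs <- abs(mean(a) - mean(b))
  # tolerance so ties with the observed statistic are never lost to rounding
  tol <- 1e-12 * max(1, obs)
  if (n_part <= 184756) {
    combos <- utils::combn(n, n_a)
    stats <- apply(combos, 2L, function(i) abs(mean(pooled[i]) - mean(pooled[-i])))
    p <- sum(stats >= obs - tol) / n_part
    method <- "exact"
  } else {
    stats <- withr_seed(seed, {
      vapply(seq_len(n_draws), function(...) {
        i <- sample.int(n, n_a)
        abs(mean(pooled[i]) - mean(pooled[-i]))
      }, numeric(1))
    })
    # +1 correction keeps the Monte-Carlo p-value valid (never exactly 0)
    p <- (sum(stats >= obs - tol) + 1) / (n_draws + 1)
    method <- "monte-carlo"
  }
  structure(
    list(group_a_values = a, group_b_values = b,
         mean_diff = mean(a) - mean(b),
         p_exact = p, n_partitions = n_part, method = method),
    class = "hysteresis_result"
  )
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("<hysteresis_result> mean difference %.4f bits, p = %.4g (%s over %s partitions)\n",
              x$mean_diff, x$p_exact, x$method,
              format(x$n_partitions, big.mark = ",")))
  invisible(x)
}

# Run `code` under a temporary RNG state so library calls never perturb the
# caller's random stream.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
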