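#' Configuration of the bistable transcriptome generator
#'
#' The generator emulates the two expression states the diversity analysis
#' distinguishes: a diffuse high-diversity state in which ~14,000 genes
#' share reads under a heavy-tailed (log-normal) abundance law, and a
#' dominated low-diversity state in which a small storage-protein-like gene
#' set jointly holds a large fraction of all reads.
#'
#' @param n_genes Number of genes (default 14000, the scale of an annotated
#'   insect transcriptome).
#' @param n_dominant Size of the storage-protein-like dominant set
#'   (default 10).
#' @param dominance_mass Fraction phi in (0, 1) of expression mass the
#'   dominant set holds in the low state (default 0.40, comfortably above
#'   the one-third occupancy that marks dominated transcriptomes).
#' @param baseline_shape Log-normal sdlog of the diffuse baseline weights
#'   (default 2.0); larger values give heavier tails and lower diversity.
#' @param library_size Reads per sample (default 2e6).
#' @param seed Integer seed owning the generator's reference randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 14000L, n_dominant = 10L,
                             dominance_mass = 0.40, baseline_shape = 2.0,
                             library_size = 2e6, seed = 1L) {
  stopifnot(n_genes >= 2, n_dominant >= 1, n_dominant < n_genes,
            dominance_mass > 0, dominance_mass < 1,
            baseline_shape >= 0, library_size >= 1)
  structure(
    list(n_genes = as.integer(n_genes),
         n_dominant = as.integer(n_dominant),
         dominance_mass = dominance_mass,
         baseline_shape = baseline_shape,
         library_size = library_size,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Gene ids used by the generator
#'
#' The first `n_dominant` ids name the storage-protein-like set.
#' @param config A [generator_config()].
#' @return Character vector of length `n_genes`.
#' @export
generator_gene_ids <- function(config) {
  width <- nchar(as.character(config$n_genes))
  ids <- sprintf("gene%0*d", width, seq_len(config$n_genes))
  ids[seq_len(config$n_dominant)] <-
    sprintf("storage%02d", seq_len(config$n_dominant))
  ids
}

#' Dominant (storage-protein-like) gene set
#' @param config A [generator_config()].
#' @return Character vector of the `n_dominant` dominant gene ids.
#' @export
dominant_genes <- function(config) {
  generator_gene_ids(config)[seq_len(config$n_dominant)]
}

#' Hysteretic switch parameters
#'
#' The state rule is a threshold loop: concentrations at or above
#' `theta_up` drive the transcriptome into the dominated low-diversity
#' state; concentrations at or below `theta_down` relax it back to the
#' diffuse high-diversity state; concentrations strictly between the two
#' thresholds retain the previous state. The band (theta_down, theta_up)
#' is what makes the final state depend on exposure history.
#'
#' @param theta_up Switch-down threshold in mM (default 0.625, the midpoint
#'   of the observed tipping interval 0.25-1.0 mM).
#' @param theta_down Relaxation threshold in mM (default 0.1, positive so a
#'   washout to 0 mM returns the state to high).
#' @param state_noise Per-step probability in \[0, 0.5\] of flipping the
#'   rule's outcome (default 0: deterministic switch).
#' @return An object of class `switch_params`.
#' @export
switch_params <- function(theta_up = 0.625, theta_down = 0.1,
                          state_noise = 0) {
  stopifnot(theta_down < theta_up, state_noise >= 0, state_noise <= 0.5)
  structure(list(theta_up = theta_up, theta_down = theta_down,
                 state_noise = state_noise),
            class = "switch_params")
}

#' Exposure history
#'
#' An ordered sequence of culture steps, each a duration (hours) at a
#' drug concentration (mM), driving the hysteretic switch.
#'
#' @param durations_h Positive durations in hours.
#' @param concentrations_mM Nonnegative concentrations in mM, same length.
#' @return A data.frame of class `exposure_history` with columns
#'   `duration_h` and `concentration_mM`.
#' @export
#' @examples
#' exposure_history(c(80, 10), c(0, 1.0))  # naive culture then 1.0 mM
exposure_history <- function(durations_h, concentrations_mM) {
  durations_h <- as.numeric(durations_h)
  concentrations_mM <- as.numeric(concentrations_mM)
  if (!length(durations_h) || length(durations_h) != length(concentrations_mM)) {
    stop("durations and concentrations must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(durations_h <= 0)) stop("durations must be positive", call. = FALSE)
  if (any(concentrations_mM < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  structure(data.frame(duration_h = durations_h,
                       concentration_mM = concentrations_mM),
            class = c("exposure_history", "data.frame"))
}

#' Experiment design: arms of replicated exposure histories
#'
#' @param arms A list of arms, each a list with `arm_id` (unique text),
#'   `history` (an [exposure_history()]) and `n_replicates` (positive
#'   integer).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(arms) {
  if (!length(arms)) stop("design needs at least one arm", call. = FALSE)
  ids <- vapply(arms, function(a) as.character(a$arm_id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate arm ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (a in arms) {
    if (!inherits(a$history, "exposure_history")) {
      stop("arm ", a$arm_id, ": history must be an exposure_history", call. = FALSE)
    }
    if (is.null(a$n_replicates) || a$n_replicates < 1) {
      stop("arm ", a$arm_id, ": n_replicates must be a positive integer", call. = FALSE)
    }
  }
  structure(list(arms = arms), class = "experiment_design")
}

# Deterministic 31-bit hash of (master seed, arm id, replicate index), so a
# replicate's seed never changes when other arms are added or reordered.
# Polynomial rolling hash; 31 * (2^31 - 1) < 2^53 keeps arithmetic exact.
derive_seed <- function(master_seed, arm_id, replicate) {
  codes <- utf8ToInt(paste(master_seed, arm_id, replicate, sep = "\r"))
  h <- 7
  for (cd in codes) h <- (h * 31 + cd) %% 2147483647
  as.integer(h)
}

#' Draw diffuse baseline expression weights
#'
#' Log-normal weights (meanlog 0, sdlog `baseline_shape`), one per gene.
#' The heavy right tail reproduces the concave sorted log2-frequency
#' profiles of real transcriptomes; `baseline_shape` -> 0 recovers the
#' uniform transcriptome whose diversity is log2(n_genes).
#'
#' @param config A [generator_config()].
#' @param seed Seed for this draw (default the config's seed).
#' @return Named positive numeric vector of length `n_genes`.
#' @export
make_baseline_weights <- function(config, seed = config$seed) {
  w <- withr_seed(seed, exp(stats::rnorm(config$n_genes, 0, config$baseline_shape)))
  names(w) <- generator_gene_ids(config)
  w
}

#' Impose storage-protein-like dominance on a weight vector
#'
#' Rescales the weights so the dominant gene set jointly holds exactly the
#' fraction `phi` of total expression mass while the remaining genes share
#' 1 - phi in proportion to their baseline weights. Within each side the
#' relative structure of the baseline is preserved.
#'
#' @param weights Positive weight vector named by gene id (from
#'   [make_baseline_weights()]).
#' @param config A [generator_config()] identifying the dominant set.
#' @param phi Mass fraction for the dominant set; defaults to
#'   `config$dominance_mass`. `phi = 0` returns the normalized baseline.
#' @return Weight vector summing to 1 with dominant-set occupancy exactly
#'   `phi`.
#' @export
apply_dominance <- function(weights, config, phi = config$dominance_mass) {
  if (phi >= 1) stop("`phi` must be < 1", call. = FALSE)
  if (phi < 0) stop("`phi` must be nonnegative", call. = FALSE)
  dom <- names(weights) %in% dominant_genes(config)
  if (!any(dom)) stop("weights carry none of the configured dominant genes", call. = FALSE)
  out <- weights
  if (phi == 0) return(weights / sum(weights))
  out[dom] <- weights[dom] / sum(weights[dom]) * phi
  out[!dom] <- weights[!dom] / sum(weights[!dom]) * (1 - phi)
  out
}

# Entropy (bits) of a nonnegative weight vector's normalized frequencies;
# the generator's expected-frequency diversity before multinomial sampling.
weight_entropy <- function(w) {
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Run the hysteretic state switch over an exposure history
#'
#' Starts in the high-diversity state and applies the threshold-loop rule
#' of [switch_params()] after each step. With `state_noise > 0` each
#' step's outcome is flipped with that probability (seeded).
#'
#' @param history An [exposure_history()].
#' @param params A [switch_params()].
#' @param seed Seed for the noise draws (unused when `state_noise` is 0).
#' @return A list with `final_state` ("high" or "low") and `trajectory`,
#'   a data.frame with one row per step (`step`, `duration_h`,
#'   `concentration_mM`, `state` after the step).
#' @export
#' @examples
#' sp <- switch_params()
#' switch_state(exposure_history(c(80, 10), c(0, 1.0)), sp)$final_state       # "low"
#' switch_state(exposure_history(c(80, 10), c(0, 0.25)), sp)$final_state      # "high"
#' switch_state(exposure_history(c(80, 10, 10), c(0, 1.0, 0.25)), sp)$final_state  # "low"
switch_state <- function(history, params = switch_params(), seed = 1L) {
  stopifnot(inherits(history, "exposure_history"))
  flips <- if (params$state_noise > 0) {
    withr_seed(seed, stats::runif(nrow(history)) < params$state_noise)
  } else rep(FALSE, nrow(history))
  state <- "high"
  states <- character(nrow(history))
  for (i in seq_len(nrow(history))) {
    conc <- history$concentration_mM[i]
    state <- if (conc >= params$theta_up) "low"
             else if (conc <= params$theta_down) "high"
             else state  # inside the hysteresis band: retain
    if (flips[i]) state <- if (state == "high") "low" else "high"
    states[i] <- state
  }
  list(final_state = state,
       trajectory = data.frame(step = seq_len(nrow(history)),
                               duration_h = history$duration_h,
                               concentration_mM = history$concentration_mM,
                               state = states))
}

#' Sample a read-count profile from expression weights
#'
#' Draws `library_size` reads multinomially with probabilities proportional
#' to the weights.
#'
#' @param weights Positive weight vector named by gene id.
#' @param library_size Total reads to draw (positive).
#' @param seed Seed for the draw.
#' @param sample_id Sample label for the returned profile.
#' @param metadata Metadata list attached to the profile.
#' @return An [expression_profile()].
#' @export
sample_counts <- function(weights, library_size, seed,
                          sample_id = "sim", metadata = list()) {
  if (library_size <= 0) stop("`library_size` must be positive", call. = FALSE)
  counts <- withr_seed(seed, {
    drop(stats::rmultinom(1L, size = as.integer(library_size),
                          prob = weights / sum(weights)))
  })
  expression_profile(counts, sample_id = sample_id,
                     gene_ids = names(weights), metadata = metadata)
}

# Bisection helper shared by the two calibrators: f must be continuous and
# decreasing on [lo, hi]; finds x with |f(x) - target| <= tol.
bisect_decreasing <- function(f, target, lo, hi, tol = 0.05, max_iter = 60L) {
  f_lo <- f(lo); f_hi <- f(hi)
  if (target > f_lo + tol || target < f_hi - tol) {
    stop(sprintf("target %.3f bits outside the achievable band [%.3f, %.3f]",
                 target, f_hi, f_lo), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - target) <= tol) return(mid)
    if (val > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the dominance mass to a target low-state diversity
#'
#' Bisects on phi until the expected-frequency entropy of the dominated
#' weight vector (before multinomial sampling) is within `tol` bits of
#' `target_H`. The expected entropy is averaged over `n_reference` fixed
#' baseline draws (seeds derived from `seed`), so the returned phi is
#' deterministic and not biased by a single draw's idiosyncrasy.
#'
#' @param target_H Target diversity in bits; must lie between the fully
#'   dominated limit and the baseline entropy.
#' @param config A [generator_config()].
#' @param seed Seed of the reference baseline draws.
#' @param tol Convergence tolerance in bits (default 0.05).
#' @param n_reference Number of fixed reference draws averaged (default 5).
#' @return The calibrated phi in (0, 1).
#' @export
calibrate_dominance <- function(target_H, config, seed = config$seed,
                                tol = 0.05, n_reference = 5L) {
  ws <- lapply(seq_len(n_reference), function(i) {
    make_baseline_weights(config, derive_seed(seed, "calibrate", i))
  })
  f <- function(phi) {
    mean(vapply(ws, function(w) weight_entropy(apply_dominance(w, config, phi)),
                numeric(1)))
  }
  # entropy is decreasing in phi beyond a tiny phi; bisect on the monotone range
  bisect_decreasing(f, target_H, lo = 1e-6, hi = 1 - 1e-6, tol = tol)
}

#' Calibrate the baseline shape to a target high-state diversity
#'
#' Bisects on the log-normal sdlog until the expected-frequency entropy of
#' the diffuse baseline hits `target_H`. A fixed set of standard-normal
#' reference draws (seeds derived from `seed`) is reused across the
#' bisection, so entropy is a smooth decreasing function of the shape.
#'
#' @inheritParams calibrate_dominance
#' @return A [generator_config()] equal to `config` but with
#'   `baseline_shape` replaced by the calibrated value.
#' @export
calibrate_baseline_shape <- function(target_H, config, seed = config$seed,
                                     tol = 0.05, n_reference = 5L) {
  zs <- lapply(seq_len(n_reference), function(i) {
    withr_seed(derive_seed(seed, "calibrate", i), stats::rnorm(config$n_genes))
  })
  f <- function(s) {
    mean(vapply(zs, function(z) weight_entropy(exp(s * z)), numeric(1)))
  }
  shape <- bisect_decreasing(f, target_H, lo = 0.01, hi = 6, tol = tol)
  config$baseline_shape <- shape
  config
}

#' Calibrate a generator to high- and low-state diversity targets
#'
#' Convenience wrapper: calibrates `baseline_shape` to `target_high`, then
#' `dominance_mass` to `target_low` under that shape.
#'
#' @param config A [generator_config()].
#' @param target_high,target_low Diversity targets in bits for the diffuse
#'   and dominated states (defaults 10.3 and 8.0, the levels observed in
#'   the phenobarbital study).
#' @param seed Seed of the reference draws.
#' @return The calibrated [generator_config()].
#' @export
calibrate_generator <- function(config, target_high = 10.3, target_low = 8.0,
                                seed = config$seed) {
  config <- calibrate_baseline_shape(target_high, config, seed)
  config$dominance_mass <- calibrate_dominance(target_low, config, seed)
  config
}

#' Simulate a replicated multi-arm exposure experiment
#'
#' For every replicate of every arm: derives a replicate seed from the
#' master seed (stable under adding or reordering arms), draws fresh
#' baseline weights, runs the hysteretic switch over the arm's exposure
#' history, imposes dominance if the final state is low, and samples a
#' multinomial read-count profile. Replicate-to-replicate variability in
#' diversity arises from the fresh weight draws, mirroring biological
#' replicates.
#'
#' @param design An [experiment_design()].
#' @param config A [generator_config()].
#' @param params A [switch_params()].
#' @param seed Master seed; every derived stream is a pure function of it.
#' @return A list with `counts` (gene-by-sample integer matrix) and
#'   `metadata` (data.frame with `sample_id`, `arm_id`, `replicate`,
#'   `concentration_mM` (final step), `history_id`, `state`).
#' @export
simulate_experiment <- function(design, config = generator_config(),
                                params = switch_params(), seed = config$seed) {
  stopifnot(inherits(design, "experiment_design"))
  gene_ids <- generator_gene_ids(config)
  cols <- list(); meta <- list()
  for (arm in design$arms) {
    for (r in seq_len(arm$n_replicates)) {
      rep_seed <- derive_seed(seed, arm$arm_id, r)
      sw <- switch_state(arm$history, params, seed = rep_seed + 1L)
      w <- make_baseline_weights(config, seed = rep_seed)
      if (sw$final_state == "low") {
        w <- apply_dominance(w, config)
      }
      sid <- sprintf("%s_r%d", arm$arm_id, r)
      prof <- sample_counts(w, config$library_size, seed = rep_seed + 2L,
                            sample_id = sid)
      cols[[sid]] <- prof$counts
      meta[[sid]] <- data.frame(
        sample_id = sid, arm_id = arm$arm_id, replicate = r,
        concentration_mM = utils::tail(arm$history$concentration_mM, 1L),
        history_id = arm$arm_id,
        state = sw$final_state,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- gene_ids
  list(counts = counts,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' The standard 21-sample study design
#'
#' Five-dose phenobarbital ladder (0, 0.25, 1.0, 2.5, 12.5 mM; 80 h naive
#' culture then 10 h at the final dose) with three replicates per dose,
#' plus the two hysteresis arms (washout to 0 mM and step-down to 0.25 mM,
#' each after 10 h at 1.0 mM), three replicates each: 21 samples in all.
#'
#' @param doses_mM Ladder concentrations (default the five standard doses).
#' @param n_replicates Replicates per arm (default 3).
#' @return An [experiment_design()].
#' @export
standard_design <- function(doses_mM = c(0, 0.25, 1.0, 2.5, 12.5),
                            n_replicates = 3L) {
  arms <- lapply(doses_mM, function(d) {
    list(arm_id = sprintf("pb%g", d),
         history = exposure_history(c(80, 10), c(0, d)),
         n_replicates = n_replicates)
  })
  arms <- c(arms, list(
    list(arm_id = "pb0_after1.0",
         history = exposure_history(c(80, 10, 10), c(0, 1.0, 0)),
         n_replicates = n_replicates),
    list(arm_id = "pb0.25_after1.0",
         history = exposure_history(c(80, 10, 10), c(0, 1.0, 0.25)),
         n_replicates = n_replicates)))
  experiment_design(arms)
}
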