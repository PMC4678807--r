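#' Configuration of a full analysis run
#'
#' @param counts Path to the gene-by-sample count TSV.
#' @param metadata Path to the sample metadata TSV (columns `sample_id`,
#'   `concentration_mM`, `history_id`).
#' @param out_dir Output directory (created if absent).
#' @param ks Removal-curve depths, strictly increasing nonnegative
#'   integers.
#' @param top_n Number of top genes shown individually in occupancy bars.
#' @param seed Seed recorded in the log and used for any resampling.
#' @param figures Emit PNG figures? (`FALSE` writes tables only.)
#' @param verbose Log progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(counts, metadata, out_dir,
                       ks = c(10, 20, 30, 50, 100, 200, 300, 500),
                       top_n = 10L, seed = 1L, figures = TRUE,
                       verbose = TRUE) {
  ks <- as.integer(ks)
  if (any(ks < 0) || is.unsorted(ks, strictly = TRUE)) {
    stop("`ks` must be strictly increasing and nonnegative", call. = FALSE)
  }
  structure(list(counts = counts, metadata = metadata, out_dir = out_dir,
                 ks = ks, top_n = as.integer(top_n), seed = as.integer(seed),
                 figures = isTRUE(figures), verbose = isTRUE(verbose)),
            class = "run_config")
}

run_log <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

#' Run the complete diversity analysis and write its report
#'
#' Reads and validates the inputs, then writes under `out_dir`: the
#' per-sample diversity table; the dose-diversity Pearson correlation;
#' the tipping-point localization over concentration groups; exact
#' permutation hysteresis tests for every final concentration observed
#' under more than one exposure history; removal curves; sorted log2
#' frequency profiles; top-gene occupancy fractions; and (unless figures
#' are toggled off) the four standard figures: dose-vs-diversity scatter
#' with history-coded markers, stacked occupancy bars, sorted log2(p)
#' overlay, and removal-curve scatter. The log records package version,
#' seed and input checksums.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the result tables (`diversity`,
#'   `correlation`, `tipping`, `hysteresis`, `removal`, `profiles`,
#'   `occupancy`) and the vector of files written.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # validate inputs before any computation
  metadata <- read_sample_metadata(
    config$metadata,
    require_columns = c("sample_id", "concentration_mM", "history_id"))
  counts <- read_count_matrix(config$counts)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  run_log(config, "txdiversity %s | seed %d | counts %s md5 %s | metadata md5 %s",
          as.character(utils::packageVersion("txdiversity")), config$seed,
          config$counts, unname(tools::md5sum(config$counts)),
          unname(tools::md5sum(config$metadata)))

  div <- diversity_table(counts, metadata)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    files[[length(files) + 1L]] <<- path
    path
  }
  emit(div, "diversity.tsv")

  cor_res <- pearson_correlation_test(div$concentration_mM, div$H)
  emit(data.frame(r = cor_res$r, t_stat = cor_res$t_stat, df = cor_res$df,
                  p_two_sided = cor_res$p_two_sided, ci_low = cor_res$ci_low,
                  ci_high = cor_res$ci_high, n = cor_res$n), "correlation.tsv")

  groups <- split(div$H, div$concentration_mM)
  tip <- detect_tipping_point(groups)
  emit(data.frame(gap_low_mM = tip$gap_interval[1],
                  gap_high_mM = tip$gap_interval[2],
                  gap_size_bits = tip$gap_size,
                  separation_score = tip$separation_score), "tipping.tsv")
  emit(group_summary(groups), "group_summary.tsv")

  # hysteresis: every final concentration reached by >1 exposure history
  hys_rows <- list()
  for (conc in unique(div$concentration_mM)) {
    sub <- div[div$concentration_mM == conc, ]
    hists <- unique(sub$history_id)
    if (length(hists) == 2L) {
      a <- sub$H[sub$history_id == hists[1L]]
      b <- sub$H[sub$history_id == hists[2L]]
      h <- hysteresis_permutation_test(a, b, seed = config$seed)
      hys_rows[[length(hys_rows) + 1L]] <- data.frame(
        concentration_mM = conc,
        history_a = hists[1L], history_b = hists[2L],
        mean_diff = h$mean_diff, p_exact = h$p_exact,
        n_partitions = h$n_partitions, method = h$method,
        stringsAsFactors = FALSE)
    }
  }
  hys <- if (length(hys_rows)) do.call(rbind, hys_rows) else
    data.frame(concentration_mM = numeric(0), history_a = character(0),
               history_b = character(0), mean_diff = numeric(0),
               p_exact = numeric(0), n_partitions = numeric(0),
               method = character(0))
  emit(hys, "hysteresis.tsv")

  profiles <- lapply(colnames(counts), function(s) {
    expression_profile(counts[, s], sample_id = s, gene_ids = rownames(counts))
  })
  ks_ok <- config$ks[config$ks < min(div$g_nonzero)]
  removal <- do.call(rbind, lapply(profiles, removal_curve, ks = ks_ok))
  emit(removal, "removal_curves.tsv")
  slp <- do.call(rbind, lapply(profiles, sorted_log_profile))
  emit(slp, "sorted_profiles.tsv")
  occ <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, top_n = config$top_n,
               occupancy = occupancy_fraction(p, top_n = config$top_n),
               stringsAsFactors = FALSE)
  }))
  emit(occ, "occupancy.tsv")

  if (config$figures) {
    figs <- list(
      fig_dose_diversity = plot_dose_diversity(div),
      fig_occupancy = plot_occupancy_bars(counts, top_n = config$top_n),
      fig_sorted_profiles = plot_sorted_profiles(slp, div),
      fig_removal = plot_removal_curves(removal, div))
    for (nm in names(figs)) {
      path <- file.path(config$out_dir, paste0(nm, ".png"))
      ggplot2::ggsave(path, figs[[nm]], width = 7, height = 5, dpi = 150)
      files[[length(files) + 1L]] <- path
    }
  }
  run_log(config, "wrote %d files to %s", length(files), config$out_dir)
  invisible(list(diversity = div, correlation = cor_res, tipping = tip,
                 hysteresis = hys, removal = removal, profiles = slp,
                 occupancy = occ, files = unlist(files)))
}

# Samples with diversity under 9 bits cluster with the dominated state in
# the study system; used only to colour figures.
state_label <- function(H) ifelse(H < 9, "low (H < 9)", "high (H >= 9)")

#' Dose versus diversity scatter plot
#' @param div A [diversity_table()] result with `concentration_mM` and
#'   `history_id` columns.
#' @return A ggplot object.
#' @export
plot_dose_diversity <- function(div) {
  div$dose <- factor(div$concentration_mM)
  ggplot2::ggplot(div, ggplot2::aes(x = dose, y = H, colour = history_id)) +
    ggplot2::geom_point(size = 3, alpha = 0.9,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::labs(x = "phenobarbital (mM)", y = "transcriptome diversity (bits)",
                  colour = "history") +
    ggplot2::theme_bw()
}

#' Stacked occupancy bar chart
#'
#' One bar per sample; the `top_n` most-expressed genes of each sample are
#' shown individually, everything else pooled as "other".
#' @param counts Gene-by-sample count matrix.
#' @param top_n Genes shown individually per sample.
#' @return A ggplot object.
#' @export
plot_occupancy_bars <- function(counts, top_n = 10L) {
  rows <- lapply(colnames(counts), function(s) {
    prof <- expression_profile(counts[, s], sample_id = s,
                               gene_ids = rownames(counts))
    p <- prof$counts / sum(prof$counts)
    idx <- top_gene_idx(prof, min(top_n, sum(prof$counts > 0)))
    data.frame(sample_id = s,
               gene = c(prof$gene_ids[idx], "other"),
               fraction = c(p[idx], 1 - sum(p[idx])),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$gene <- stats::reorder(df$gene, df$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = sample_id, y = fraction,
                                   fill = gene)) +
    ggplot2::geom_col(colour = "grey20", linewidth = 0.1) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "occupancy (fraction of reads)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Sorted log2 relative-frequency overlay
#' @param slp Stacked [sorted_log_profile()] rows for several samples.
#' @param div Matching diversity table (for state colouring).
#' @return A ggplot object.
#' @export
plot_sorted_profiles <- function(slp, div) {
  slp$state <- state_label(div$H[match(slp$sample_id, div$sample_id)])
  ggplot2::ggplot(slp, ggplot2::aes(x = rank, y = log2p,
                                    group = sample_id,
                                    colour = state)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("low (H < 9)" = "red",
                                            "high (H >= 9)" = "blue")) +
    ggplot2::labs(x = "gene rank (by relative frequency)",
                  y = "log2 relative frequency", colour = "diversity state") +
    ggplot2::theme_bw()
}

#' Removal-curve scatter
#' @param removal Stacked [removal_curve()] rows for several samples.
#' @param div Matching diversity table (for state colouring).
#' @return A ggplot object.
#' @export
plot_removal_curves <- function(removal, div) {
  removal$state <- state_label(div$H[match(removal$sample_id, div$sample_id)])
  ggplot2::ggplot(removal, ggplot2::aes(x = k, y = H,
                                        group = sample_id,
                                        colour = state)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c("low (H < 9)" = "red",
                                            "high (H >= 9)" = "blue")) +
    ggplot2::labs(x = "number of top-expressed genes removed",
                  y = "transcriptome diversity (bits)",
                  colour = "diversity state") +
    ggplot2::theme_bw()
}
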