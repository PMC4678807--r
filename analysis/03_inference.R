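#!/usr/bin/env Rscript
# Step 3: dose-diversity inference, on both the published diversity values
# and the simulated study.
#
# For each dataset: Pearson correlation of concentration against
# diversity on the 15-dose-ladder samples, tipping-point localization over
# the concentration groups, and exact permutation tests for hysteresis at
# every final concentration reached by two exposure histories. Writes
# tables under results/inference/.

suppressPackageStartupMessages(library(txdiversity))

out_dir <- "results/inference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

analyse <- function(div, label) {
  message(sprintf("== %s ==", label))
  # dose-ladder samples: cultures that went straight to their final dose
  ladder <- div[!grepl("after", div$history_id), ]

  cor_res <- pearson_correlation_test(ladder$concentration_mM, ladder$H)
  print(cor_res)

  tip <- detect_tipping_point(split(ladder$H, ladder$concentration_mM))
  print(tip)

  hys_rows <- list()
  for (conc in unique(div$concentration_mM)) {
    sub <- div[div$concentration_mM == conc, ]
    hists <- unique(sub$history_id)
    if (length(hists) == 2L) {
      a <- sub$H[sub$history_id == hists[1]]
      b <- sub$H[sub$history_id == hists[2]]
      h <- hysteresis_permutation_test(a, b)
      message(sprintf("hysteresis at %g mM (%s vs %s):", conc, hists[1], hists[2]))
      print(h)
      hys_rows[[length(hys_rows) + 1L]] <- data.frame(
        dataset = label, concentration_mM = conc,
        history_a = hists[1], history_b = hists[2],
        mean_diff = h$mean_diff, p_exact = h$p_exact,
        n_partitions = h$n_partitions)
    }
  }
  list(
    correlation = data.frame(dataset = label, r = cor_res$r,
                             t_stat = cor_res$t_stat, df = cor_res$df,
                             p_two_sided = cor_res$p_two_sided,
                             ci_low = cor_res$ci_low, ci_high = cor_res$ci_high),
    tipping = data.frame(dataset = label, gap_low_mM = tip$gap_interval[1],
                         gap_high_mM = tip$gap_interval[2],
                         gap_size_bits = tip$gap_size,
                         separation_score = tip$separation_score),
    hysteresis = do.call(rbind, hys_rows),
    groups = cbind(dataset = label,
                   group_summary(split(ladder$H, ladder$concentration_mM))))
}

published <- phenobarbital_diversities()
res_pub <- analyse(published, "published")

sim_div <- read_sample_metadata("results/diversity/diversity.tsv",
                                require_columns = c("sample_id", "H"))
res_sim <- analyse(sim_div, "simulated")

write_tsv(rbind(res_pub$correlation, res_sim$correlation),
          file.path(out_dir, "correlation.tsv"))
write_tsv(rbind(res_pub$tipping, res_sim$tipping),
          file.path(out_dir, "tipping.tsv"))
write_tsv(rbind(res_pub$hysteresis, res_sim$hysteresis),
          file.path(out_dir, "hysteresis.tsv"))
write_tsv(rbind(res_pub$groups, res_sim$groups),
          file.path(out_dir, "group_summary.tsv"))
message(sprintf("wrote inference tables to %s", out_dir))
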