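Package: txdiversity
Title: Transcriptome Diversity, Dominance Structure and Bistability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes transcriptome diversity, the Shannon entropy (in bits)
    of the relative-frequency distribution of gene expression in one RNA-seq
    sample, together with the dominance-structure summaries that explain it:
    top-k gene removal curves, sorted log2 relative-frequency profiles and
    occupancy fractions of gene sets. Provides dose-diversity correlation
    testing, tipping-point localization between concentration groups, and an
    exact permutation test for hysteresis between exposure histories, plus a
    synthetic generator of bistable transcriptomes (a diffuse high-diversity
    state and a dominated low-diversity state switched by a hysteretic
    dose-history rule) so the whole pipeline can be exercised on simulated
    count matrices.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
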