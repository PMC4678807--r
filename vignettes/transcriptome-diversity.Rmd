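---
title: "Transcriptome diversity: the statistic, the tests, and the bistable generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome diversity: the statistic, the tests, and the bistable generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdiversity)
```

## The statistic

A bulk or single-cell RNA-seq sample assigns its mapped reads to genes.
Writing $P_{ij}$ for the fraction of sample $j$'s reads mapped to gene
$i$ ($i = 1, \dots, g$), the sample's **transcriptome diversity** is the
Shannon entropy of that frequency distribution, in bits:

$$H_j = -\sum_{i:\,P_{ij} > 0} P_{ij}\,\log_2 P_{ij}.$$

It is a one-number summary of how evenly the transcriptome is spread
across genes: $H = \log_2 g$ for a perfectly uniform profile, $H = 0$
when a single gene carries every read. Genes with zero counts contribute
exactly nothing (the $0 \log 0 := 0$ convention, implemented by dropping
zero-frequency terms before the logarithm); consequently $H$ does not
depend on how many silent genes the annotation carries, only the upper
bound $\log_2 g_{\text{nonzero}}$ does. We always report the nonnegative
value; implementations that return the raw sum $\sum P \log_2 P$ differ
only by sign.

Three deliberately small examples fix intuition. Counts $(1, 10, 100)$
give $H = 0.51$ bits; the reordering $(10, 100, 1)$ gives the same
$0.51$ because entropy ignores gene identity; $(1, 10, 1000)$ gives
$0.09$ because a single gene now dominates. A drop in diversity is a
statement about dominance, not about which genes moved.

```{r worked}
diversity_table(worked_example_counts())
```

## Dominance structure

Three summaries localize *where* a diversity difference lives:

* **Removal curves** (`removal_curve()`): delete the $k$ most-expressed
  genes (ties broken by ascending gene id, for determinism),
  renormalize the remaining frequencies, recompute $H$. We renormalize
  because the entropy of a probability distribution requires unit mass;
  the raw residual mass is reported alongside as `residual_mass` so the
  un-renormalized view can be reconstructed. If the diversity gap
  between two samples closes as $k$ grows (in the study system it is
  gone by $k = 500$), the gap is carried by the few hundred
  most-expressed genes.
* **Sorted log-frequency profiles** (`sorted_log_profile()`):
  $\log_2 P_{ij}$ over expressed genes, sorted descending — the
  rank-abundance curve of the transcriptome. Dominated samples show a
  high head and a depressed tail.
* **Occupancy fractions** (`occupancy_fraction()`): the share of reads
  held by a gene set, either the top-$n$ genes or an explicit set. A
  storage-protein-like set holding more than one third of all reads is
  the signature of the dominated state.

## Inference

**Dose–diversity correlation.** `pearson_correlation_test()` reports the
product-moment $r$, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n - 2$ degrees of
freedom, the two-sided $p$, and a 95% interval from the Fisher
$z$-transform, $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$. On
the 15 published dose-ladder pairs this gives $r = -0.53$, $t = -2.28$,
df $= 13$, $p = 0.04$ — and a CI of $(-0.82, -0.03)$. We compute the
interval ourselves rather than adopting the originally printed interval
$(-0.94, -0.54)$, which excludes its own point estimate and cannot be a
95% interval for $r = -0.53$ at $n = 15$.

**Tipping point.** The published analysis reads the jump off a scatter
plot; `detect_tipping_point()` operationalizes it: order the
concentration groups numerically (never lexically — 12.5 mM sorts after
2.5 mM), take group means, and return the adjacent pair with the largest
absolute mean difference. The `separation_score` divides that gap by the
pooled within-group standard deviation (guarded by $+10^{-12}$ against
zero-variance groups), so a score $\gg 1$ marks a jump that dwarfs
replicate noise. With two observed diversity levels and a single jump
between them this maximal-gap rule is exact; it is not a general
multiple-change-point estimator and is not meant as one.

**Hysteresis.** Whether diversity at a final concentration depends on
the exposure history is tested by an exact permutation test on the two
history groups (`hysteresis_permutation_test()`): statistic
$|\bar{a} - \bar{b}|$, reference distribution all
$\binom{n_a + n_b}{n_a}$ relabelings, $p$ the fraction of relabelings at
or above the observed statistic (two-sided via the absolute value,
observed included). With 3 vs 3 samples there are only 20 partitions,
so **the smallest attainable p-value is 2/20 = 0.1**; the published
triples (10.18, 10.36, 10.43) vs (9.35, 10.22, 9.11) give exactly that
floor region, $p = 0.2$. Exact enumeration is used up to
$\binom{20}{10} = 184{,}756$ partitions; beyond that the test switches
to seeded Monte-Carlo with an add-one-correction
$(\#\text{hits}+1)/(\#\text{draws}+1)$. Statistic comparisons use an
absolute tolerance of $10^{-12}$ (scaled by the observed value) so
floating-point ties are never dropped from the tail.

## The synthetic generator

No external sequencing data are needed anywhere: the generator emulates
exactly the frequency-distribution structure the statistic consumes.

* **Diffuse high-diversity state.** Gene weights are log-normal
  (meanlog 0, sdlog `baseline_shape`). The choice is pragmatic: among
  simple laws it reproduces the concave sorted $\log_2 P$ profile of
  real transcriptomes, and its entropy is smoothly tunable — for large
  $g$, $H \approx \log_2 g - \sigma^2/(2\ln 2)$. It does not model
  gene length or GC bias, expression correlation between genes, or any
  regulatory network; passing tests therefore certify the pipeline's
  statistics, not biological realism of counts.
* **Dominated low-diversity state.** A designated
  storage-protein-like set (default 10 genes) is rescaled to hold
  exactly the mass fraction $\varphi$ (`dominance_mass`), the rest
  holding $1-\varphi$ in baseline proportions. Occupancy of the set is
  therefore $\varphi$ by construction, and sampled occupancy estimates
  it within binomial error.
* **Hysteretic switch.** A threshold loop, not kinetics: starting
  "high", a step at concentration $\ge \theta_{up}$ switches to "low", a
  step at $\le \theta_{down}$ back to "high", anything in between
  retains the previous state. The study provides end-state evidence
  only, so a dynamical ODE would be unsupported detail. Defaults:
  $\theta_{up} = 0.625$ mM, the midpoint of the observed tipping
  interval (0.25, 1.0) — any value inside the interval is equally
  consistent with the data; and $\theta_{down} = 0.1 > 0$ mM because the
  washout-to-0 arm returns to high diversity (values 10.13, 9.75,
  10.26), so relaxation must occur at low but nonzero residual
  stringency. `state_noise` (default 0) flips a step's outcome with the
  given probability for robustness experiments.
* **Sampling.** Counts are multinomial draws of `library_size` reads
  (default $2 \times 10^6$) over the weight vector. Replicates draw
  *fresh* baseline weights from seeds derived by a stable hash of
  (master seed, arm id, replicate index) — adding arms never perturbs
  existing ones, and replicate-to-replicate diversity spread arises
  naturally from the weight draw (about 0.2 bits sd at the calibrated
  shape, inside the 0.13–0.37 band of the published replicate groups)
  rather than from an ad-hoc noise knob.

**Calibration.** `calibrate_generator()` bisects `baseline_shape` until
the expected-frequency entropy (the entropy of the weight vector itself,
before sampling) hits the high-state target, then bisects $\varphi$ for
the low-state target; defaults 10.3 and 8.0 bits, the two observed
diversity levels. Expected entropy is averaged over five fixed reference
draws so the calibrated value is not biased by one draw's idiosyncrasy;
bisection stops within 0.05 bits or 60 iterations, and unreachable
targets fail with the achievable band in the message. Entropy is
monotone decreasing in $\varphi$ only beyond a tiny $\varphi$
($\approx 2^{-\Delta}$ for a dominance deficit of $\Delta$ bits), so the
bisection runs on $[10^{-6}, 1 - 10^{-6}]$ where the study-relevant
branch is monotone.

**Study-scale conditions.** The default study mirror
(`standard_design()`) is 14,000 genes, five doses
(0, 0.25, 1.0, 2.5, 12.5 mM) × 3 replicates plus two hysteresis arms
(washout to 0, step-down to 0.25 mM, each after 10 h at 1.0 mM) × 3,
i.e. 21 samples of $2 \times 10^6$ reads. The test suite runs most
generator properties at a scaled-down 2,000 genes / $2 \times 10^5$
reads with proportionally scaled entropy targets (8.5/6.5 bits), and the
full-scale 21-sample study plus a 100-seed tipping-recovery sweep in its
end-to-end block; the analysis scripts under `analysis/` run the
full-scale study.

## Numerical choices and edge cases

* Zero counts: allowed, contribute 0, excluded from `g_nonzero`; an
  all-zero profile is an error (no reads, no distribution).
* A single expressed gene gives $H = 0$, not an error.
* Ties in "most-expressed": broken by ascending gene id everywhere
  (removal curves, top-$n$ occupancy), so results are reproducible
  across platforms.
* `removal_curve()` requires $\max k <$ number of expressed genes;
  $k = 0$ is always included and reproduces `shannon_diversity()`
  exactly.
* Comparisons against published values use 2 decimal places — the
  precision at which they were printed.
* All randomness flows through explicit seeds; every generator
  operation is a pure function of (inputs, seed).

## Limitations

The generator's independence of genes means it cannot emulate
co-regulated modules; its two-state switch cannot produce intermediate
diversities at intermediate doses (the study observed none, but a real
dose–response could have them); and the diversity statistic itself is
sensitive to library composition artifacts (e.g. rRNA carryover) that
the simulation does not model. The tipping-point rule assumes one
dominant jump; use the `separation_score` to judge whether a detected
gap is meaningful before interpreting it.
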