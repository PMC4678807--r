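# txdiversity

Transcriptome diversity — the Shannon entropy, in bits, of a sample's
gene relative-frequency distribution — as a one-number summary of
transcriptome state, with the analyses that make it useful: dominance
dissection, dose–response testing, tipping-point localization, and an
exact permutation test for hysteresis. A built-in generator of bistable
synthetic transcriptomes lets the whole pipeline run without any
external sequencing data.

For gene *i* with relative read frequency *P<sub>ij</sub>* in sample
*j*, the diversity is

> H<sub>j</sub> = −Σ<sub>i</sub> P<sub>ij</sub> log₂ P<sub>ij</sub>
> (expressed genes only; 0·log 0 := 0).

The motivating system is cultured silkworm fat-body tissue exposed to
phenobarbital: below a concentration tipping point the transcriptome is
diffuse (H ≈ 10.3 bits); above it, a small storage-protein gene set
seizes more than a third of all reads and diversity drops to ≈ 8 bits.
Because the final state depends on exposure *history*, not just the
final dose (hysteresis), the expression system is bistable — which is
exactly what the package's synthetic generator emulates: log-normal
diffuse expression, a dominated state with a configurable mass fraction
on a storage-protein-like gene set, and a threshold-loop switch driven
by ordered (duration, concentration) exposure steps.

Intended users: anyone summarizing bulk or single-cell RNA-seq count
matrices as entropy trajectories — dose–response screens, culture-state
monitoring, cell-state comparisons — and anyone needing a calibrated
synthetic testbed for entropy-based pipelines.

## Worked example

```r
library(txdiversity)

# three-gene toy transcriptomes: (1,10,100), (10,100,1), (1,10,1000)
diversity_table(worked_example_counts())
#>   sample_id          H g_nonzero total_count
#> 1     case1 0.50968704         3         111
#> 2     case2 0.50968704         3         111
#> 3     case3 0.09135604         3        1011
```

Case 1 and case 2 agree to machine precision (entropy ignores gene
order); case 3 collapses to 0.09 bits because one gene holds 99% of the
reads. At 2 decimal places these are the published 0.51 / 0.51 / 0.09.

The published per-sample diversities ship with the package, so the
study's inference chain runs directly:

```r
lad <- subset(phenobarbital_diversities(), history_id == "naive")
pearson_correlation_test(lad$concentration_mM, lad$H)
#> <correlation_result> r = -0.534 (t = -2.276, df = 13, p = 0.04044), 95% CI [-0.821, -0.030], n = 15

detect_tipping_point(split(lad$H, lad$concentration_mM))
#> <tipping_point_result> largest jump between 0.25 and 1 mM: 2.410 bits (separation 8.5)

hysteresis_permutation_test(c(10.18, 10.36, 10.43), c(9.35, 10.22, 9.11))
#> <hysteresis_result> mean difference 0.7633 bits, p = 0.2 (exact over 20 partitions)
```

The weak negative correlation is real but misleading — the tipping-point
scan shows the change is a single 2.4-bit jump between 0.25 and 1.0 mM,
not a proportional trend. The hysteresis test compares naive 0.25 mM
cultures against 0.25 mM-after-1.0 mM cultures; with 3 vs 3 samples the
exact test bottoms out at p = 0.1, so p = 0.2 is one step above the
attainable floor.

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study on synthetic
data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R    # calibrate generator (10.3 / 8.0 bits), simulate 21 samples
Rscript analysis/02_diversity.R   # per-sample H, removal curves, occupancy, rank profiles
Rscript analysis/03_inference.R   # correlation, tipping point, hysteresis (published + simulated)
Rscript analysis/04_report.R      # full report incl. the four standard figures
```

## Package tour

| area | functions |
| --- | --- |
| diversity core | `expression_profile`, `relative_frequencies`, `shannon_diversity`, `diversity_table`, `removal_curve`, `sorted_log_profile`, `occupancy_fraction` |
| inference | `pearson_correlation_test`, `detect_tipping_point`, `group_summary`, `hysteresis_permutation_test` |
| synthetic data | `generator_config`, `calibrate_generator`, `make_baseline_weights`, `apply_dominance`, `switch_state`, `sample_counts`, `standard_design`, `simulate_experiment` |
| I/O and report | `read_count_matrix`, `write_count_matrix`, `read_sample_metadata`, `run_config`, `run_report`, plotting helpers |

The methods vignette (`vignettes/transcriptome-diversity.Rmd`) documents
the model assumptions, calibration, numerical edge cases and what the
synthetic tests do and do not establish about real data.
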