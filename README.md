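# agimir

Preprocessing and replicate-precision QC for Agilent microRNA microarrays.

## The problem

Agilent microRNA arrays interrogate each microRNA with 1–4 distinct 60-mer
oligonucleotide probes, each spotted many times (16 features per microRNA on
the Human microRNA Microarray v2.0: 362 microRNAs with 2 oligos, 45 with 3,
390 with 4, 2 with 1). The vendor's Feature Extraction software (AFE)
collapses these into a *total gene signal* (TGS) with a proprietary robust
average of background-subtracted features, and recommends either no
normalization or scaling to the 75th percentile. An alternative is to adapt
the *robust multiarray average* (RMA) idea from Affymetrix arrays: treat the
distinct oligos as a probe set and fit, per microRNA, the additive model

```
log2 signal[probe, array] = expression[array] + probe_affinity + error
```

by Tukey's median polish, after quantile normalization and (optionally)
background correction under the exponential + normal convolution model
`S = X + Y`, `X ~ Exp(alpha)` (signal), `Y ~ N(mu, sigma^2)` (background),
replacing each observation by `E[X | S = s]`.

`agimir` implements four processed signals end to end and the diagnostics to
compare them:

| method | pipeline |
|---|---|
| `nor75` | TGS → global `|min|+2` offset → per-array 75th-percentile scaling → log2 |
| `norQ` | TGS → offset → quantile normalization → log2 |
| `norRMA` | raw mean signals → quantile normalization → log2 → replicate medians → median polish |
| `norRMAbg` | as `norRMA`, with exp+normal background correction first |

Precision is assessed as the SD of log2 signals across biological
replicates (with a 5-knot natural cubic spline trend against mean
intensity) and as relative log expression (RLE) distributions per array.
A synthetic AFE-format data generator emulating the v2.0 design makes the
whole pipeline runnable and testable without array downloads.

Audience: analysts preprocessing Agilent miRNA arrays (AFE `.txt` exports,
e.g. from GEO), and anyone studying how background correction and
summarization choices affect low-intensity precision.

## Worked example

```r
library(agimir)

cfg <- simulation_config(seed = 42)      # 2 groups x 4 arrays, v2.0 layout
sim <- simulate_experiment(cfg)
design <- sim$design
design
#> ArrayDesign: 799 genes, 2421 probes, 12784 features

norRMA <- process_arrays(sim$tables, method = "norRMA", design = design)
norRMA
#> ExpressionMatrix (norRMA, log2 scale): 799 genes x 8 arrays
round(norRMA[1:3, 1:4], 3)
#>         MSC_rep1 MSC_rep2 MSC_rep3 MSC_rep4
#> mir-001    7.214    7.290    7.285    7.211
#> mir-002    5.650    5.827    5.903    5.743
#> mir-003    6.160    6.272    6.162    6.068

cmp <- compare_methods(sim$tables, sim$truth$group_of,
                       methods = c("norQ", "norRMA", "norRMAbg"),
                       design = design)
aggregate(sd_log2 ~ method, cmp$sd_table, mean)
#>     method sd_log2
#> 1     norQ  0.2143
#> 2   norRMA  0.0627
#> 3 norRMAbg  0.1761

flags <- gene_flags(sim$tables, design)
kept <- filter_expressed(norRMA, flags, sim$truth$group_of)
sum(kept$calls$kept)
#> [1] 258     # microRNAs detected in every replicate of at least one group
```

The SD column is the average replicate SD per method: the un-background-
corrected RMA route is the most precise, background correction inflates
low-intensity variability, and the quantile-normalized TGS sits in between
— visible gene-by-gene with `plot_sd_trend(cmp$norRMA$trends)`. RLE
medians after the quantile-based routes are all within ±0.013 of zero here
(`rle_stats(unclass(norRMA))$summary`).

Real AFE exports are read with `read_afe("GSM476577_MSC_rep1.txt.gz")`
(both the three-block AFE dialect and plain single-header TSVs are
accepted); the deposited series GSE19232 (8 arrays, mesenchymal stem cells
vs dermal fibroblasts) and GSE16444 (31 neuroblastoma arrays) can be
fetched manually from GEO and run through the same calls.

A command-line front end covering `process`, `qc`, `filter` and `simulate`
ships in `inst/cli/agimir`:

```sh
Rscript inst/cli/agimir simulate --seed 1 --arrays 4 --out fixtures/
Rscript inst/cli/agimir process --method norRMA,nor75 --in 'fixtures/*_rep*.txt' --out out/
```

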