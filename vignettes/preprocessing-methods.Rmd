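---
title: "Methods: processed signals for Agilent microRNA arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processed signals for Agilent microRNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agimir)
```

## The measurement model

An Agilent microRNA array measures each microRNA with 1–4 distinct
oligonucleotide probes, each spotted as many replicate features (16 per
microRNA on the Human microRNA Microarray v2.0). `agimir` produces one
log2 expression value per microRNA per array by one of four routes.

**Vendor-style total gene signal (TGS).** Per probe, a robust average of
the background-subtracted replicate features times the replicate count;
per microRNA, the sum over its probes:

$$\mathrm{TGS}_g = \sum_{p \in g} n_p \cdot
  \mathrm{robavg}\{\,b_{f} : f \in p\,\}$$

with $b_f$ the background-subtracted feature signal and $n_p$ the
replicate count. The vendor's exact robust-average rule is proprietary;
the package defaults to the median (deterministic and transparent) and
offers an outlier-trimmed mean (drop values beyond 1.5×IQR from the
quartiles, then average). Note the published description of the TGS can be
read as additionally multiplying by the number of probes per gene; that
reading double-counts whenever probes disagree, so `agimir` adopts the
per-probe sum, which coincides with it when all probes agree. TGS values
can be negative; `nor75` and `norQ` therefore first add the single global
constant $|\min| + 2$ whenever the global minimum is ≤ 0 (one constant for
the whole matrix, not per array, so between-array relationships are
untouched), then scale — either each array by its own 75th percentile, or
by quantile normalization — and take log2.

**Adapted RMA.** `norRMA`/`norRMAbg` work from the raw mean feature
signals: (optional background correction) → quantile normalization across
arrays at the feature level → log2 → replicate-feature medians (giving 1–4
probe measures per microRNA) → per-microRNA additive fit

$$y_{pa} = \mu_a + \phi_p + \varepsilon_{pa}$$

by Tukey's median polish, reporting $\hat\mu_a = \mathrm{overall} +
\mathrm{column\ effect}_a$ and treating the probe affinities $\phi_p$ as
nuisance. MicroRNAs with a single probe pass through unchanged. The
assumptions: probe affinities are additive on the log scale and constant
across arrays, and a median-based fit is robust to a minority of aberrant
probes or arrays.

**Background model.** `norRMAbg` models the observed linear-scale
intensity as $S = X + Y$ with signal $X \sim \mathrm{Exp}(\alpha)$ and
background $Y \sim N(\mu, \sigma^2)$, and replaces each observation by

$$E[X \mid S = s] = a + b\,
  \frac{\phi(a/b) - \phi((s-a)/b)}{\Phi(a/b) + \Phi((s-a)/b) - 1},
  \qquad a = s - \mu - \sigma^2\alpha,\; b = \sigma ,$$

which is strictly positive and strictly increasing in $s$. Parameters are
estimated per array (background level is an array property) from
experimental features only; controls are excluded from estimation,
normalization and summarization throughout.

## Background parameter estimation

The classical mode-based heuristic reads the background mean off the peak
of a kernel density estimate of the intensities. That peak, however, is
not at $\mu$: for the exp+normal convolution the density mode solves
$\phi(z)/\Phi(z) = \alpha\sigma$ at $s = \mu + \alpha\sigma^2 + \sigma
z^*$, so whenever the signal is not negligible relative to the background
the raw mode overestimates $\mu$ — by about $1.8\sigma$ when
$\alpha\sigma = 0.1$, an error no bandwidth choice can remove. `agimir`
therefore inverts the mode equation instead of ignoring it:

1. $m$ = mode of a Gaussian-kernel density estimate (Silverman
   bandwidth);
2. seed $\hat\sigma$ with the RMS deviation of observations below $m$ and
   $\hat\alpha$ with the reciprocal mean excess above $m$;
3. iterate (3×): solve $z^*$ from $\phi(z^*)/\Phi(z^*) =
   \hat\alpha\hat\sigma$; set $\hat\mu = m - \hat\alpha\hat\sigma^2 -
   \hat\sigma z^*$; refresh $\hat\sigma$ as the RMS deviation of
   observations below $\hat\mu$ (half-normal reading; the residual
   exponential contamination leaves a small upward bias) and
   $\hat\alpha$ from the moment identity $E[S] - \mu = 1/\alpha$.

Estimation needs at least two observations on each side of the mode and
refuses (near-)constant input. The closed form is evaluated directly
where the denominator is well-conditioned, with a log-space Mills-ratio
fallback ($a + b\,e^{\log\phi(a/b) - \log\Phi(a/b)}$) where it
underflows, and outputs clipped at $2^{-20}$ so the subsequent log2 is
always defined.

## Numerical conventions

- **Quantiles** everywhere use linear interpolation between order
  statistics (position $1 + (n-1)q$; R type 7). This pins the
  75th-percentile scaling so that each scaled array's 75th percentile is
  1 to machine precision.
- **Quantile normalization** delegates to `limma::normalizeQuantiles(ties
  = TRUE)`: every column receives the vector of row-wise means of the
  column-sorted matrix, ties getting the mean of the reference values
  their ranks span. It is idempotent to float tolerance and
  row-permutation equivariant.
- **Median polish** sweeps rows first, then columns, accumulating effects,
  and stops when the relative change in the sum of absolute residuals
  drops below 0.01 or after 10 sweeps — the classical defaults, pinned so
  that an independent implementation reproduces the fit cell for cell.
  Residuals are recomputed against the final fit, making the
  reconstruction identity `input = overall + row + col + residual` exact
  by construction. Effects carry the usual median-zero identifiability
  convention.
- **Replicate collapse** uses the standard median (mean of the two middle
  values at even counts).
- **Degenerate inputs** error loudly rather than being repaired: missing
  or non-finite cells in an AFE table, non-positive entries at the log
  step (with their location), single-column quantile normalization,
  groups with one array in SD profiles.

## Replicate-precision QC

For every microRNA and every biological group, the mean and sample SD
(n−1) of the log2 signals across that group's arrays are computed —
per group, because biological replicates only exist within a group; a
pooled profile can be had by concatenating groups. The SD-versus-mean
trend is fitted by least squares on a natural cubic spline basis with 5
knots placed at the 1/6…5/6 quantiles of the mean intensities; the outer
two act as boundary knots with linear (natural) behavior beyond them.
Five knots total, rather than five interior knots, is the reading adopted
here; quantile placement is the standard convention. The fit is returned
on a 100-point grid. Natural splines contain all affine functions, so a
linear SD-mean relationship is reproduced exactly.

Relative log expression (RLE) subtracts from each value the across-array
median of its gene; per-array five-number summaries (type-7 quartiles)
support the usual centering/dispersion reading. Row medians of the RLE
matrix are zero by construction (exactly for odd array counts).

Detection filtering keeps a microRNA when, in at least one group, the
fraction of arrays calling it detected reaches `min_fraction` (default
1.0 — every replicate of some group — the strictest reading; the
published aggregation rule behind gene-level calls is unpublished, so
both the feature→gene rule — majority by default, with "any"/"all"
alternatives — and the fraction are configurable, and kept counts should
be reported alongside the rule used).

## The synthetic data generator

`simulate_experiment()` emulates the v2.0 layout (362/45/390/2 microRNAs
with 2/3/4/1 oligos, 16 features each, split as evenly as possible across
oligos: 8+8, 6+5+5, 4×4, 16) plus 20 negative-control probes at pure
background and 4 positive-control targets × 4 probes × 5 replicates. The
intensity model is multiplicative signal plus additive background:

$$S_f = c\,2^{\theta_{g,G} + \phi_p + \varepsilon_f} + Y_f,\qquad
  Y_f \sim N(\mu_b, \sigma_b^2)\ \text{truncated at }0 ,$$

with the background-subtracted channel $S_f - \mu_b$ (hence possibly
negative) and a detection flag set when a gene's median feature signal
exceeds a threshold. Defaults, chosen once as representative of this
array class and held fixed: per-gene baseline $\theta \sim N(4, 2^2)$
log2 units with 20% of genes shifted between groups by $N(0, 1.5^2)$;
probe affinities $\phi \sim N(0, 0.5^2)$ (fixed across arrays); feature
noise $\varepsilon \sim N(0, 0.25^2)$; background $\mu_b = 50$, $\sigma_b
= 10$ fluorescence units (a typical low-intensity floor with the signal
range extending to $\sim 2^{14}$); scale $c = 1$; detection threshold
$\mu_b + 3\sigma_b$, the conventional three-sigma call — under which
roughly a third of simulated microRNAs are detected, comparable to real
two-tissue experiments on this platform; 2 groups × 4 arrays, matching a
small two-tissue design.

What the generator does *not* emulate: spatial gradients and the AFE
detrending surface (taken as upstream), saturation, probe-specific
cross-hybridization, correlated noise between neighboring features, and
AFE's actual proprietary detection logic. Passing tests on synthetic data
therefore demonstrate internal correctness and the qualitative behavior
of the methods under the stated generative model — not calibration
against any physical scanner.

Because the generator's background is genuinely additive normal over an
approximately exponential-tailed signal, two end-to-end recoveries hold
and are exercised in the tests: the mode-based estimator applied to a
simulated array recovers $(\mu_b, \sigma_b)$, and true between-group
log2 differences correlate strongly with `norRMA` estimates.

## Design choices that were genuinely open

- **Offset before scaling.** Whether the 75th-percentile scaling operates
  before or after the positivity offset is not fixed by the method's
  description; the offset comes first here, since scaling requires a
  positive 75th percentile and the offset is the designated positivity
  repair.
- **TGS summation convention** (per-probe sum, above).
- **Robust average = median** (proprietary vendor rule replaced by a
  documented one).
- **Gene estimate = overall + column effect** from the polish; probe
  effects are nuisance.
- **Flag aggregation and `min_fraction`** (majority / 1.0 defaults,
  configurable, above).
- **Spline knot reading** (5 total, quantile-placed, above); profiles are
  fitted per group by default, with pooling available by concatenation.
- **Background estimation** replaces the raw-mode heuristic with the
  bias-corrected inversion, because the raw mode is provably off by
  $\mathcal{O}(\sigma)$ in exactly the regime microRNA arrays occupy
  (strong signal tail over a modest background).

## Problem sizes

Unit tests run on a down-scaled design (15 genes × 8 features, 2–3 arrays
per group) so each property is checked in milliseconds; end-to-end
contracts (percentile pinning, RLE centering, the precision ordering of
the four routes, parameter recovery) use the full 799-gene design at 8
arrays, with the precision ordering replicated over 10 simulation seeds
and the Monte-Carlo check of the background closed form using $10^7$
draws. These sizes are the package's chosen regression scale; all are
regenerated from seeds at test time.

## Known limitations

- The vendor's TGS is *emulated*, not reproduced bit-for-bit: its robust
  average and gene-level detection logic are unpublished, so exact
  agreement with AFE column values (or with published kept-gene counts
  that depend on the detection rule) is not expected.
- The background estimator's $\hat\sigma$ retains a small upward bias
  from exponential contamination below $\hat\mu$; $\hat\alpha$ relies on
  a moment identity and inherits sensitivity to very bright outliers.
- Median polish is not a maximum-likelihood fit; with one probe pair and
  two arrays the decomposition is weakly identified, and the 2
  single-oligo microRNAs bypass summarization entirely.
- QC compares *precision* (replicate variability) only; nothing here
  measures accuracy against spike-in truth, and no differential
  expression machinery is included.
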