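---
title: "Selecting reference genes from digital expression counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference genes from digital expression counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neps)
```

## The problem

Normalizing expression measurements — qPCR, microarray or sequencing-based —
requires reference ("housekeeping") genes whose expression is high and
constant across the samples being compared. The classical choices (*ACTB*,
*GAPDH*, *18S rRNA*) are demonstrably unstable in many disease contexts, and
mining microarray data for better candidates inherits the circularity that
arrays themselves must be normalized before stability can be judged. Digital
count data such as SAGE tag libraries sidestep that circularity: each library
is a direct enumeration of transcript abundance, so constancy can be assessed
on an absolute scale. This package scores every gene in a two-group
collection of count libraries (e.g. non-malignant vs tumor) for constancy,
nominates reference genes, and provides the two downstream procedures that
such gene sets feed: per-sample scale normalization of expression matrices,
and stability ranking of candidates from paired qPCR Ct data.

## The permutation score

For one gene, let the TPM-normalized counts in the two groups have sizes $n$
and $c$. The pooled $n + c$ values are randomly re-partitioned into a
simulated group of size $n$ and its complement of size $c$ (sampling without
replacement — a random relabelling of libraries), and the simulated
difference $v = \bar{x}_{sc} - \bar{x}_{sn}$ is recorded. Over $m$ such
partitions (default $m = 10{,}000$), let $\mu$ and $\sigma$ be the mean and
standard deviation of $v$. With $O = \bar{x}_{c} - \bar{x}_{n}$ the observed
difference, the permutation score is

$$ PS = \frac{|O - \mu|}{\sigma}. $$

A perfectly constant gene has $PS = 0$; strongly differential genes score
high. Three criteria nominate reference genes, all inclusive: $PS \le 0.15$,
a raw count of at least 2 in *every* library, and an average raw count of at
least 25 across libraries (10 is the recommended override for shallow
library sets). Abundance criteria deliberately use raw counts: a tag seen
once in a tiny library is weak evidence no matter its TPM.

Numerical conventions, fixed once:

* $\sigma$ is the *population* standard deviation of the simulated
  differences (divide by $m$; by the number of distinct partitions in the
  exact version). The null distribution is the complete object of interest,
  not a sample from a larger one, and the Monte-Carlo and exhaustive paths
  must share a convention to be comparable.
* If $\sigma = 0$ (all pooled values identical), $PS = 0$ when
  $|O - \mu| = 0$ and `Inf` otherwise; `Inf`-scored genes are never
  selectable.
* The numerator subtracts $\mu$; since $\mu \approx 0$ for any exchangeable
  statistic the uncentred variant $|O|/\sigma$ is nearly identical, and is
  available as `center_null = FALSE`.
* Each gene's random stream is seeded from a hash of the run seed and the
  gene identifier, so scores are reproducible gene-by-gene and unaffected by
  which other genes are present.
* Report ordering is $PS$ ascending, ties broken by higher average raw
  count, then gene id — deterministic output files.
* `exact_permutation_score()` enumerates all $\binom{n+c}{n}$ partitions
  (bounded at $10^6$) and is the independent oracle for the sampler in the
  test suite.

### What a small score does and does not promise

$PS$ is a self-standardized permutation statistic. For a gene whose values
are genuinely exchangeable between groups, $O$ is one draw from (almost
exactly) the null that $\mu$ and $\sigma$ describe, so $PS$ behaves like the
absolute value of a standard normal deviate no matter how abundant or quiet
the gene is: about 12% of ideally stable genes fall at $PS \le 0.15$, and
the expected score of an ideal gene is near 0.8, not 0. The threshold
therefore selects the most-constant-looking *tail* among abundant genes
rather than recovering every truly stable gene, and the statistic is most
informative as an ordering. The package's synthetic-recovery tests reflect
this: planted stable genes reliably occupy the lowest score positions among
planted genes and planted 4-fold genes are reliably rejected, while the
absolute-threshold recovery rate of planted stable genes sits near the ~12%
that exchangeability dictates.

A second, related caveat is compositional: count libraries are fixed-depth
samples, so planting (or observing) strong up-regulation of one gene set
necessarily depresses the relative abundance of everything else in that
group. With many or abundant differential genes, even truly
constant-abundance genes acquire a shared between-group shift and a nonzero
score. This is a property of relative-abundance data, not an artifact of the
implementation.

## Reference-gene scaling of expression matrices

Given a matrix of summarized intensities, probes are first filtered on
detection calls (retain probes with P or M in at least 50% of samples,
boundary inclusive). One probe per reference gene is chosen: on platforms
with calls, among probes with P in *all* samples the one with the highest
mean intensity; on call-free platforms, the probe with the highest mean
intensity outright, ties to the lexicographically smallest probe id.
Replicate experiments are averaged probe-wise beforehand when present.

For each reference probe, its mean intensity across samples forms the target
profile $y$. For each sample with reference vector $x$, the scaling factor
is the least-squares slope of $y$ on $x$ *through the origin*,
$\hat\beta_s = \sum_i x_i y_i / \sum_i x_i^2$, and every value of the sample
is multiplied by it. The origin constraint is the default because only a
pure slope acts coherently as a multiplicative correction (it maps $x$
exactly onto $y$ whenever the two are proportional, and preserves
within-sample ratios); whether the original procedure included an intercept
is not documented, so `intercept = TRUE` provides the ordinary-regression
slope as a variant. Note the target profile includes the sample itself, so
perturbing one sample moves $y$ slightly as well; with typical sample counts
the effect is negligible. After fit and apply, refitting the original target
profile on the scaled reference vectors returns slope 1 for every sample to
machine precision — the invariant the tests assert.

## qPCR stability ranking

Candidates assayed across matched tumor/normal pairs are ranked by three
complementary metrics, each on its natural scale, lower = more stable:

* **dCt variance** — the unbiased ($n-1$) variance across pairs of
  $\mathrm{Ct}_\text{tumor} - \mathrm{Ct}_\text{normal}$. Pair-shared
  effects cancel; note a *constant* tumor shift is invisible to this metric
  (variance 0), which is exactly why a bias-sensitive metric is also used.
* **geNorm $M$** — for each gene pair, the sample SD of the per-sample
  $\log_2$ expression ratio; a gene's $M$ is its mean pairwise variation
  over all partners. $M$ is exactly invariant to rescaling any gene's
  quantities, so the anchoring of quantities (below) is immaterial. The
  iterative worst-gene elimination layer is available
  (`genorm_stepwise()`), but per-gene reporting uses the full-panel $M$.
* **NormFinder-style model-based stability** — within each sample group the
  $\log_2$ quantities are decomposed into gene effect + sample effect +
  gene-by-group effect $d_{ig}$ + noise. The intragroup variance uses the
  small-sample correction
  $\hat\sigma^2_{ig} = \frac{k}{k-2}\left(z_{ig} - \bar z_g/(k-1)\right)$
  (with $z_{ig}$ the per-gene mean squared two-way residual and $k \ge 3$
  genes; negative estimates clamped at 0), $d_{ig}$ is shrunk toward zero in
  proportion to its sampling variance $\hat\sigma^2_{ig}/n_g$, and the
  stability value is the mean over groups of
  $|\tilde d_{ig}| + \sqrt{\hat\sigma^2_{ig}/n_g}$ — systematic shift plus
  noise. With one group the value reduces to the within-group term.

Ct values are converted to relative quantities as
$q = E^{\min(\mathrm{Ct}) - \mathrm{Ct}}$ per gene, with amplification
efficiency $E = 2$ unless gene-specific efficiencies are supplied; Ct input
is taken as already replicate-averaged. Within each metric genes receive
competition ranks (ties share the minimum rank), and the consensus is the
*cumulative rank* — the sum of a gene's three ranks — sorted ascending with
display ties broken by gene id. The package ships the published stability
metrics of a 21-gene lung panel (genes × three metric columns) as a
plain-text fixture; re-ranking those columns reproduces the published
consensus, with one documented exception: two genes' model-based values
round to the same printed 0.099, which ranking of the printed values cannot
split the way the unrounded originals did.

## The synthetic data generators

`simulate_sage()` emulates grouped digital count libraries: each library is
one multinomial draw of `library_size` tags (default 100,000; the
fixed-depth sampling that defines SAGE) from its group's relative-abundance
vector, 12 + 12 libraries by default. Planted structure defines ground
truth: 10 stable genes with identical abundance in both groups, drawn
log-uniform in $[2.5\times10^{-4}, 10^{-3}]$ so their expected raw counts
start at the selection threshold of 25; 100 differential genes with a
4-fold cancer-group change, baseline log-uniform in
$[2\times10^{-5}, 2\times10^{-4}]$ — abundant enough to be credible decoys
while keeping their total mass share (and hence the compositional shift
imposed on everyone else) below ~2%; and a log-uniform background in
$[2\times10^{-5}, 10^{-3}]$. Group vectors are renormalized to sum to one,
so the compositional coupling described above is deliberately present. A
negative-binomial-style overdispersion option (per-library Gamma jitter of
the abundance vector) supports robustness testing, and
`draw_library_sizes()` provides log-uniform depths over 30k–150k tags
mimicking mixed-depth library collections. What the generator does *not*
emulate: tag-level sequencing error, ditag artifacts, transcript-variant
tag structure, or biological within-group dispersion beyond the
overdispersion knob — so passing recovery tests demonstrate the statistic's
sampling behavior, not robustness to every feature of real libraries.

`simulate_qpcr()` emulates the paired validation design: 21 genes × 15
tumor/normal pairs by default, with
$\mathrm{Ct} = 30 - \text{base} - \text{shift}\cdot\text{tumor} -
\text{pair effect} + \varepsilon$. Baseline $\log_2$ expression is uniform
on $[3, 12]$ (Ct roughly 16–27, the usable range of the instrument), the
shared per-pair effect (SD 1 cycle) induces realistic pairing correlation
and cancels in dCt, and planted stable genes have zero shift with 0.25-cycle
noise versus 0.7–1.5 cycles and alternating ±0.5–2-cycle shifts elsewhere.
The planted quiet genes are cleanly separated so that all three metrics
should find them; the generator is a positive control, not a hard benchmark.

## Problem sizes and determinism

The default test suite runs the full 2,000-gene scenario at
$m = 10{,}000$ permutations once (a few seconds with the compiled sampler)
and smaller scenarios elsewhere; the oracle-equivalence sweep uses 200
random instances with group sizes 2–5, comparing the Monte-Carlo score to
exhaustive enumeration within three delta-method Monte-Carlo standard
errors; the stability sweep uses 100 seeded replicates. Every stochastic
path flows from explicit integer seeds: identical seeds give byte-identical
outputs, including through file round-trips.

## Known limitations

* The score thresholds select a tail, not a guaranteed set (see above);
  users comparing library collections with heavy compositional differences
  should read low scores as *relative* constancy.
* Tags mapping ambiguously to multiple genes are rejected rather than
  resolved; resolve them upstream in the tag-to-gene map.
* The scaling module consumes already-summarized intensity matrices; probe
  summarization and background correction are out of scope.
* Metric *values* from the shipped 21-gene panel cannot be recomputed here
  because the underlying Ct measurements were never published; only the
  rank-aggregation layer is reproducible from the printed columns.
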