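---
title: "Methods: monotone trend detection and colonization phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monotone trend detection and colonization phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiotrend)
```

`symbiotrend` quantifies temporal change in an artificial grass–endophyte
association maintained by serial seed propagation. This vignette is the
package's account of the statistical models it implements, the parameter
choices that matter, and what the synthetic-data generators do and do not
emulate.

## The monotone-separation trend test

### Model and null

Samples fall into $k \ge 2$ ordered generation groups with replicate
sizes $n_1, \dots, n_k$, $N = \sum_j n_j$. A gene is called
**monotone down** when, at every adjacent boundary, the maximum value of
the later group lies strictly below the minimum of the earlier group;
**up** is the mirror. This is a pure rank statistic: any strictly
increasing transform of the values yields identical calls, which is why
the choice between raw RPM and log-median-centered values is immaterial
to detection (it can matter only through a pseudocount that reorders
zeros, and the package detects on RPM with pseudocount 0).

Under the null that a gene's values are exchangeable across samples and
continuous (no ties), every ordering of the $N$ values is equally
likely, and only the orderings that place each group's values in their
own contiguous block in the declared group order separate fully, so

$$p_1 = \frac{\prod_j n_j!}{N!}, \qquad p_\text{both} = 2 p_1 .$$

For the $3{\times}3{\times}3$ design, $p_\text{both} = 432/362{,}880 =
1/840$; the test suite confirms this by brute-force enumeration of all
1,680 rank assignments (exactly 2 separate) and by a permutation oracle
(`permutation_null()`) that shuffles observed values within genes.

**Ties.** Equality at any group boundary defeats separation: counts are
discrete, so ties occur, always making the test conservative relative to
the continuous null (the permutation oracle on constant data returns 0).
Genes whose pattern separates weakly but not strictly are flagged
`tied = TRUE` so their number can be inspected.

### Excess test and count interval

With $m$ genes tested, the chance expectation is $E = m \, p$. The
expectation uses the both-directions probability by default because the
scientific question is "more consistent increases *or* decreases than
chance". $m$ is the number of genes of the tested organism with nonzero
total count over all samples — a quantity the package computes and
reports rather than assumes, with a user override. The observed count
$O$ of separated genes is compared with $E$ by
$z = (O - E)/\sqrt{E}$, one-sided upper tail: a count of rare,
approximately independent events is close to Poisson, so $\sqrt{E}$ is
the natural null standard deviation. The companion interval for $O$ is
Garwood's exact Poisson interval from chi-square quantiles,
$[\tfrac12\chi^2_{\alpha/2}(2O),\; \tfrac12\chi^2_{1-\alpha/2}(2O+2)]$.
A Clopper–Pearson exact binomial interval on $O/m$ rescaled to counts is
provided as an alternative; at gene-universe sizes of $10^4$ they agree
to well under one count, and after rounding to the nearest ten (a
report option) they are indistinguishable. For an observed count of 53
the interval is $[39.7, 69.3]$, i.e. $[40, 70]$ to the nearest ten.

### Normalization

RPM (reads per million) divides each count by its sample's library size
— the column sum over **all** genes, host and symbiont together, so the
two organisms share one within-sample scale and host share + symbiont
share = 1 exactly. TMM scaling factors (`tmm_factors()`, computed by
edgeR's published implementation: trim 0.30 on M and 0.05 on A,
precision-weighted, renormalized to geometric mean 1) can feed effective
library sizes. `log_median_center()` applies
$\log_2(\text{RPM} + c)$ minus the per-sample median, recording the
pseudocount $c$; because the transform is strictly increasing at fixed
$c$, trend calls are unchanged by this step. The differential-expression
analysis itself is out of scope: an externally produced significant-gene
id list is consumed by `intersect_significant()` as a plain set
operation.

## Colonization morphometry

Each cross section yields a hyphal count, per-hypha diameters (in
practice a subsample of roughly 40–50 hyphae per section) and a count of
hyphae inside vascular bundles. Hyphae are modelled as circular in cross
section — the only assumption under which a diameter maps to an area.
The **biovolume index** of a section is
$\overline{\pi (d/2)^2} \times \text{count}$ (μm²·hyphae): areas are
computed per hypha and then averaged, not computed from the averaged
diameter. The two readings differ by Jensen's inequality whenever
diameters vary; the alternative (`area_of_mean_diameter`) is exposed as
a switch because either reading of "averaged area of all the hyphal
diameters" is defensible. Section values are averaged per genotype
(unweighted; diameter means skip zero-count sections), and the genotype
means — not the sections — are the unit of all downstream comparisons:
Kruskal–Wallis rank tests per metric, and percent declines computed on
generation means of genotype means. Percent declines use
$(m_\text{base} - m_\text{later})/m_\text{base} \times 100$ with the
earliest generation as baseline.

Vascular-bundle colonization is tested on the generation-pooled
$k \times 2$ table (vascular vs other hyphae) with Pearson's chi-square,
no continuity correction, $df = k - 1$. At the frequencies typical of
compatible associations (well below 1%) expected cell counts are small;
the function warns when any expected cell is below 5 rather than
refusing, mirroring how such borderline tests are reported in practice.

Seed-transmission rates are $n_\text{infected}/n_\text{tested}$ with
Clopper–Pearson exact intervals. Tillering curves average counts per
genotype and day, then per generation; the first-daughter-tiller time is
the first day a genotype's count exceeds its initial count (missing if
it never does), and generations are compared by Kruskal–Wallis on
per-genotype final counts.

## Synthetic-data generators

The generators exist so that every analysis is exercised end to end
with known ground truth; their defaults encode the study conditions the
analyses assume.

* `simulate_counts()` — 13,440 host genes plus 300 symbiont genes,
  3 generations × 3 replicates, 16 million reads per sample. Gene means
  are log-normal (location 6, spread 1 on the natural-log scale, chosen
  to give a realistic depth distribution around ~1,200 reads per gene);
  counts are negative-binomial with variance $\mu + \phi\mu^2$, default
  $\phi = 0.1$ (typical bulk RNA-seq overdispersion between biological
  replicates). A fraction of host genes is planted with geometrically
  declining generation means ($\mu, \mu\delta, \mu\delta^2$) — a
  monotone signal without assuming linearity. Symbiont means are scaled
  so the expected symbiont read share hits its target (default 0.003,
  the scale of a fungal endophyte's contribution to a pooled
  pseudostem transcriptome) and carry no trend. Truth labels are
  returned separately and never written into data files. Pooling of
  multiple genotypes into each replicate is not modelled explicitly;
  replicate-level noise absorbs it, which is adequate because the
  analysis only ever sees pooled replicates.
* `simulate_sections()` — 9/10/8 genotypes across three generations,
  3 sections each; counts negative-binomial around per-generation means
  250/180/62.5 (a 75% count decline; dispersion 0.02 keeps early-
  generation sections above ~120 hyphae), diameters normal truncated at
  zero with means 2.00/1.93/1.75 μm, so generation biovolume means fall
  near the ratio 100:67:19 (declines of 33% and 81%); vascular rates
  0.0004/0.0023/0.0030. `count_dispersion = 0` gives deterministic
  counts for closed-form checks.
* `simulate_maintenance_program()` — each plant carries a transmission
  probability $\tau$, Beta-distributed across the 38 founders with mean
  0.76 and concentration 2 (low concentration = wide plant-to-plant
  variation, the raw material selection needs). Offspring inherit the
  endophyte with probability equal to the seed parent's $\tau$ and get
  $\tau_\text{child} = h\,\tau_\text{parent} + (1-h)\,\tau_\text{new}$.
  Selected generations draw parents only from infected previous-
  generation plants; generations 3 and 5 are unselected by default.
  With $h = 1$ this yields a rising trajectory from ≈76% toward >95%
  over nine generations; with $h = 0$ selection has no cumulative
  effect and the trajectory stays flat. Pollen flow and plant genetics
  beyond a heritable $\tau$ are not modelled.
* `simulate_tillering()` — geometric growth from three initial tillers
  counted every two days, multiplicative log-normal noise; the
  noise-free closed form is $\text{round}(3(1+r)^{d/2})$.

Fixing the seed fixes every generator's output bit-for-bit.

**What passing tests do and do not show.** The generators reproduce the
designs, count distributions and effect structure the analyses assume —
not real biology. They omit genotype pooling structure, library-
preparation batch effects, correlated genes, non-geometric expression
trajectories, section-to-section spatial correlation within a tiller,
and any genetics behind $\tau$. Recovery and calibration results on
synthetic data therefore validate the statistical machinery, not the
biological conclusions one would draw from a particular dataset.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the separation test; ties are logged,
  never broken randomly (the analytic null assumes continuity, so ties
  can only make the test conservative).
* `kruskal_wallis()` returns $H = 0$, $p = 1$ for all-identical values
  instead of erroring; chi-square on a table with an all-zero vascular
  column likewise returns a null statistic.
* Zero-count sections get biovolume 0 and a missing diameter; genotype
  diameter means skip them.
* Zero library sizes, negative counts, duplicate gene ids,
  `vascular > total` and out-of-range infection counts are hard errors
  naming the offending record; genes missing from the organism map
  default to host with a warning.
* Generation order is always the declared order (factor levels or order
  of first appearance in the design file), never a lexical sort.

## Problem sizes used by the test suite

Unit and property tests run on reduced designs (hundreds to a few
thousand genes, 10–20 seeded replicates, 10³–10⁵ permutation trials);
the end-to-end calibration and recovery checks use the full
13,440-gene, 3×3 design. These sizes give stable Monte-Carlo
comparisons (3 standard errors for oracle agreement, 99% Poisson bands
for calibration) while keeping the default suite fast.

## Known limitations

* The excess z-test is a normal approximation to a Poisson count; at
  very small expectations ($E \lesssim 5$) the exact Poisson tail would
  be preferable.
* The combinatorial null treats genes as independent; co-expressed gene
  modules inflate the variance of the observed count beyond Poisson,
  making the reported $p$ anti-conservative in strongly correlated
  transcriptomes.
* TMM factors are computed but not applied by default in the trend
  pipeline: the separation criterion is defined on RPM values, and
  per-sample rescaling changes cross-sample order, so applying factors
  is an explicit user choice (`normalize_rpm(cm, tmm_factors = ...)`).
* The transmission simulator's $\tau$ inheritance is phenomenological
  (a single heritability knob), not genetic.
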