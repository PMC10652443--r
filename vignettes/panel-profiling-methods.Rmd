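---
title: "Methods: binomial variant detection, MSI scoring and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binomial variant detection, MSI scoring and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`panelprofiler` implements the computational core of targeted-panel tumor
profiling for small bowel cancer cohorts: somatic single-nucleotide variant
(SNV) detection from pileup counts, microsatellite-instability (MSI)
scoring from per-locus read-length histograms, tumor mutational burden
(TMB), and the cohort-level statistics that compare mutation frequencies
and immunotherapy biomarkers across anatomic sites (duodenum, jejunum,
ileum) and between cohorts. Because patient-level sequencing data of this
kind is typically restricted, the package ships a synthetic-cohort
generator that emulates the statistical structure the analyses assume and
provides ground truth, so every stage is exercised and tested end to end.

The `analysis/` directory contains the numbered drivers that run the full
workflow on a synthetic cohort (simulate, call variants, MSI + TMB, cohort
statistics), writing their tables under `results/`.

# The SNV detection model

At a pileup site with total depth $N$ and $k$ alternate-supporting reads,
the null hypothesis is that all alternate reads are sequencing errors
occurring independently at rate $e$, so $K \sim \mathrm{Binomial}(N, e)$.
The site's detection p-value is the exact upper tail

$$ p = P(K \ge k) = \sum_{j=k}^{N} \binom{N}{j} e^{j} (1-e)^{N-j}. $$

The summation is performed term-wise in log space (log binomial
coefficients, log-sum-exp) rather than via a normal or Poisson
approximation. This matters: the calling threshold sits deep in the tail
(default $\alpha_{\mathrm{call}} = 10^{-6}$), where approximation error is
largest relative to the quantity being compared.

A site becomes a call only if it passes the whole cascade:

| filter | default | boundary | rationale |
|---|---|---|---|
| binomial p-value | $\le 10^{-6}$ | inclusive | separates true variants from error at panel depths |
| allele fraction | $\ge 0.05$ | inclusive keep | the assay's validated sensitivity floor |
| alt reads | $\ge 5$ | inclusive | guards low-depth artifacts |
| mean base quality | $\ge 25$ Phred | inclusive | sequencing-quality floor |
| strand rule | Fisher $p < 0.01$ **and** one strand empty $\Rightarrow$ fail | — | one-sided support with significant skew is an artifact signature |

The per-site error rate is a single global parameter. A per-site error
model would be preferable with real machine-calibration data, but no such
calibration is part of this design; the parameter is config-exposed so a
site-specific rate can be substituted upstream by running the caller per
stratum. The significance threshold is likewise a parameter: $10^{-6}$ is
a conventional choice for ~10^5–10^6 tested panel positions (a Bonferroni
scale argument), not a fitted value.

The pileup format records the strand split of alternate reads only;
reference reads are split evenly between strands when forming the 2×2
Fisher table. Since the strand rule only fires when one alt strand is
empty, this approximation affects no call unless the alt evidence is
already maximally skewed.

Indels are not detected from pileups (local realignment is out of scope);
indel rows enter the pipeline through the annotated variant table.

## Reporting (landscape) filter and its ordering with TMB

Annotated calls pass two further reporting filters: population frequency
$> 0.015$ removes putatively germline variants (strict inequality — a
variant at exactly 0.015 is kept; a missing annotation counts as novel),
and only missense, stopgain, frameshift-indel and non-frameshift-indel
classes are reported as gene alterations.

TMB, however, counts silent and stoploss variants, which the class filter
removes. The pipeline therefore applies the two parts at different stages:
`filter_popfreq()` (germline removal) → `compute_tmb()` → class keep-list
(`apply_landscape_filter()`) → gene-level reporting. The spec of
`compute_tmb()` itself is deliberately minimal — it counts eligible
classes with drivers excluded and normalises by the examined region — and
the wiring enforces the order.

# The MSI model

One hundred microsatellite loci form the panel; for each assay the 30
best-covered loci are scored (ties at the selection boundary break by
ascending locus id; zero-coverage loci are excluded first, and fewer than
30 covered loci triggers a warning rather than an error).

For locus $i$ the MSS baseline supplies a cut-point repeat length $C_i$
and $p_i$, the fraction of reads from microsatellite-stable samples that
fall beyond the cut-point. With $N_i$ total reads and $n_i$ reads beyond
$C_i$ in the tumor sample, the locus follows
$X \sim \mathrm{Binomial}(N_i, p_i)$ under stability, and is flagged
unstable when the exact tail $P(X \ge n_i) \le 0.001$ (boundary
inclusive). The MSI score is the fraction of flagged loci among those
evaluated; a score $\ge 0.4$ (inclusive — 12 of 30 loci suffices)
classifies the sample MSI-H, otherwise MSS. The score is kept on the
$[0,1]$ fraction scale on which the 0.4 cutoff is coherent.

Design choices the baseline definition leaves open:

* **Direction of instability.** "Reads beyond the cut-point" is
  implemented as repeat length strictly greater than $C_i$; an
  at-or-beyond convention is available via `side = "geq"`. One-directional
  counting is the default because the baseline defines a single upper
  cut-point; a two-sided rule would need a second, lower cut-point that no
  input supplies.
* **Baseline provenance.** Deriving $(C_i, p_i)$ from a normal cohort is
  out of scope; the baseline panel is an input. The package ships a
  deterministic synthetic panel (`default_baseline_panel()`, cut-points
  10–25 repeat units, $p_i \approx 0.005$–$0.03$) clearly labelled
  synthetic.
* **Exactness.** The same log-space exact tail summation is used as for
  SNV calling; $N_i$ can be small and the 0.001 boundary must be exact,
  so no approximation is acceptable.

# TMB

TMB is the count of eligible somatic coding mutations — missense, silent,
stopgain, stoploss, in-frame and frameshift indels, with annotated driver
mutations excluded — divided by the examined coding region in megabases.
`region_size_mb` has **no default**: the coding footprint is
assay-specific and silently assuming one would make cross-assay numbers
incomparable. The synthetic panel uses 2.2 Mb (733 genes at a typical
~3 kb coding footprint each). The TMB-high cutoff is 10 mut/Mb,
inclusive, the pan-tumor immunotherapy threshold. Driver status is an
input annotation; no driver catalogue is bundled, and which catalogue was
used is the caller's responsibility.

# Cohort statistics

* **Proportions** (mutation frequencies, MSI-H rates, PD-L1 categories):
  chi-square without continuity correction on the contingency table,
  switching to the two-sided Fisher exact test when any expected cell is
  below 5. The switching rule is the conventional one; which test ran is
  recorded in `test_used`.
* **Means** (TMB levels): two groups use the unpaired Welch $t$-test by
  default (the pooled-variance Student $t$ is behind `var_equal = TRUE`);
  Welch is the default because equal variances cannot be assumed between
  site groups of very different sizes. Three or more groups use one-way
  ANOVA. Summaries are mean ± SEM with the $n-1$ standard deviation.
* **Multiple testing**: per-gene p-values are reported raw and
  Benjamini–Hochberg adjusted; the adjustment is emitted alongside rather
  than instead of the raw values because published gene-level comparisons
  of this kind typically report unadjusted p-values.
* **PD-L1**: TPS is categorised at the conventional 22C3 bins
  ($<1$, $1$–$49$, $\ge 50$), configurable.
* **Site granularity**: jejunum and ileum are kept distinct in the data
  and pooled on demand (`merge_jejunum_ileum`), since cohort demographics
  pool them while site-wise analyses may split them.
* Significance is $p < 0.05$, strict.

# The synthetic cohort: what it emulates, and what it does not

Defaults are fixed at the study conditions the analyses target: 298
patients, site weights 268/15/15 (duodenum/jejunum/ileum — published
counts pool jejunum with ileum at 30, split evenly here), per-gene
mutation probabilities matching the published top-ten frequencies, MSI-H
prevalence 5% in duodenum versus 30% in jejunum/ileum, mean depth 500×,
1% per-base error, somatic allele fractions uniform on $[0.10, 0.60]$
(the caller's validated range with headroom above the 5% floor), and mean
eligible-mutation counts of 50 (MSI-H) versus 8 (MSS) on the 2.2 Mb
panel, i.e. TMB ≈ 23 vs ≈ 3.6 mut/Mb — the burden separation expected
between hypermutated and stable tumors.

Site-discriminating genes (APC, LRP1B, PIK3CA, POLE, MSH6, MTOR enriched
in jejunum/ileum; SMAD4, CDKN2A, VEGFA, CTNNB1, ERBB2 in duodenum) get
per-site probabilities chosen so the site-weighted marginal still equals
the overall frequency.

Generative details:

* **Read-length histograms** are multinomial draws over integer repeat
  lengths on $C_i - 4 \ldots C_i + 3$, with exactly $p_i$ expected mass
  beyond the cut-point under MSS. An MSI-H sample shifts a uniformly
  drawn fraction (0.6–0.9) of loci to 30% beyond-cut-point mass. Only the
  test's sufficient statistic (mass beyond $C_i$) is modelled faithfully;
  real stutter-profile shapes, and the biologically typical shortening of
  repeats, are not.
* **Pileups** draw depth Poisson around the mean, alt reads binomially at
  the true allele fraction (or the error rate at variant-free sites), and
  split alt reads evenly across strands in expectation.
* **Seeding** is counter-based: patient $i$'s records depend only on the
  base seed and $i$, so enlarging a cohort never reshuffles earlier
  patients.
* **Metadata** (uniform ages 40–80, 60% male, PD-L1 TPS zero-inflated
  beta) is cosmetic and carries no site effect except where configured.

Consequently, passing recovery tests shows that the pipeline's inference
is correct *under its own model assumptions* — binomial error, multinomial
length sampling, independent loci and sites. It does not show robustness
to FFPE artifacts, mapping error, stutter noise correlated across loci,
or subclonal structure, none of which the generator produces.

# Numerical and degenerate-input policy

* Exact tail sums use `lchoose` + log-sum-exp; verified against direct
  pmf summation to relative error $10^{-10}$ over $N \le 500$.
* All stated thresholds are inclusive on the side their wording implies:
  AF $\ge$ 5% keeps, popfreq $> 0.015$ removes, tail $\le 0.001$ flags,
  score $\ge 0.4$ is MSI-H, TMB $\ge 10$ is high, tumor content
  $\ge 20\%$ passes.
* Empty inputs: an empty pileup yields an empty call set; an empty flag
  list, cohort, or group comparison is an error; the all-zero strand
  table gives $p = 1$.
* Readers reject structurally invalid files (missing columns named,
  unparseable numerics cited with line numbers) instead of coercing;
  duplicate histogram rows are summed with a warning.

# Problem sizes used in the test-suite experiments

Frequency-recovery runs use 2,000 metadata-only patients; MSI recovery
uses 200 samples (100 MSI-H / 100 MSS) at the default depth; caller
operating characteristics use 2,000 variant sites and 10^6–2×10^6
variant-free sites at depth 200; type-I-error calibration uses 1,000 null
replicates per test. These sizes put Monte-Carlo error well inside each
check's margin while keeping the suite quick to run.

# Known limitations

* The binomial error model ignores error-rate heterogeneity across sites
  and sequence contexts.
* MSI locus tests assume independence across loci; real MSI affects loci
  jointly through the underlying repair deficiency (the generator shares
  this assumption, which is partly why recovery is near-perfect).
* TMB from a panel is an estimate of exome-wide burden; no panel-to-WES
  calibration is attempted.
* The two-cohort comparison takes the comparator's per-gene counts at
  face value; no harmonisation of panels or variant classes across
  cohorts is performed.
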