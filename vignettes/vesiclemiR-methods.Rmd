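---
title: "Methods: miRNA sorting into extracellular vesicles from count data"
author: "vesiclemiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA sorting into extracellular vesicles from count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclemiR)
```

## The problem

Cells export microRNAs into two classes of secreted extracellular vesicles
(EVs): shed microvesicles (sMVs, plasma-membrane budding) and exosomes
(Exos, endosomal origin). Small RNA-seq of a parental cell lysate (CL) and
its purified EVs yields a miRNA-by-library count matrix from which several
questions follow: which miRNAs are expressed at all, which differ between
related cell lines, which are selectively enriched in the vesicles relative
to the cell of origin — including miRNAs essentially absent from the cell
yet abundant in its EVs — and whether such expression signatures correlate
strongly enough with clinical tumour profiles to act as classifiers.
`vesiclemiR` implements this inference chain as a tested pipeline over a
`SummarizedExperiment` subclass (`MiRNAExperiment`), driven by synthetic
data generators with recorded ground truth so that every stage is testable
without any external download.

## Quantification and detection

Counts are normalized to transcripts per million **miRNA-mapped** reads:

$$\mathrm{TPM}_{fl} = \frac{c_{fl}}{\sum_f c_{fl}} \times 10^6 .$$

The denominator is the miRNA-assigned total of the library, not all
sequenced reads, and there is no length normalization: mature miRNAs are of
essentially uniform length, so TPM here is a reads-per-million scaling.
Columns sum to $10^6$ before any filtering, and the scaling is invariant to
multiplying a library by a constant.

A feature is *detected* in a compartment when its TPM exceeds 5 (strictly)
in **at least one replicate**. The per-replicate rule is the operational
choice because duplicate libraries are the norm in this design and a mean
rule would let one noisy replicate mask a clear detection; a `method =
"mean"` variant is provided. The strict `>` matters only at the exact
boundary and is tested there. Replicate averaging, used for reporting and
signatures, is the plain arithmetic mean of replicate TPMs.

## Differential expression engine

All differential and EV-enrichment calls come from a from-scratch two-group
negative-binomial (NB) exact test.

**Normalization.** TMM (trimmed mean of M-values) factors are computed per
library against a reference: per-feature log2 ratios $M$ and average log
abundances $A$ over features non-zero in both libraries; the top and bottom
30% of $M$ and 5% of $A$ are trimmed; the surviving $M$ are averaged with
inverse asymptotic-variance weights and exponentiated. Factors are rescaled
to multiply to one and multiply the raw library sizes into effective sizes.
The implementation agrees with an independent direct coding of the formula
and with `edgeR::calcNormFactors` to 1e-10 in the tests.

**Equalization.** The exact test conditions on group totals, which requires
nominally identical library sizes. Libraries are equalized by proportional
rescaling: with effective sizes $N_l$ and their geometric mean $N^*$,
pseudo-counts are $y_{fl} N^*/N_l$. This avoids undocumented interpolation
schemes; correctness is anchored to an exhaustive-enumeration oracle rather
than to bit-level agreement with any external tool.

**Dispersion.** A common dispersion $\varphi$ (variance $\mu +
\varphi\mu^2$) is estimated by conditional maximum likelihood on the
equalized counts: the likelihood of each feature's replicate counts given
their within-group sum is free of the mean parameter and is maximized over
$\varphi$ via a bounded one-dimensional search on $\delta =
\varphi/(1+\varphi) \in [10^{-6}, 0.99]$ with tolerance $10^{-6}$;
estimates below $10^{-5}$ are reported as 0 (no excess variance).
Common-dispersion mode is the default for duplicate designs; a tagwise mode
shrinks per-feature estimates toward the common value with a fixed prior
weight of 10 features' worth of likelihood.

**Exact test.** For each feature with equalized group sums $s_A, s_B$
($s = s_A + s_B$), the conditional distribution of the group-A sum given
$s$ is that of a sum of $n_A$ NB units conditioned against $n_B$ units
(sizes $n_A/\varphi$, $n_B/\varphi$); for $\varphi = 0$ it reduces to
$\mathrm{Binomial}(s,\, n_A/(n_A+n_B))$. The two-sided p-value is the summed
probability of all splits as likely or less likely than the observed one;
splits whose probability ties the observed one within $10^{-12}$ relative
are included. Two numerical points deserve note:

* the log-pmf is assembled from per-group half-terms so that exchangeable
  groups give a *bitwise-symmetric* pmf — otherwise lgamma rounding noise
  (~$10^{-12}$ in log space) can flip near-tie splits between group orders
  and break the guarantee that swapping groups leaves p unchanged;
* totals are enumerated exactly up to 20,000; beyond that an analytic tail
  approximation is used (a beta distribution via the gamma representation
  of large NB sums for $\varphi > 0$; the binomial double tail for
  $\varphi = 0$). The boundary keeps full runs over deeply sequenced
  libraries fast while leaving every statistically delicate (small-count)
  case exact.

**Fold changes and calls.** log2 fold changes use equalized group means
augmented by a prior count of 0.5, so features observed in only one group
get large, finite values; the sign is group B relative to group A.
Benjamini–Hochberg adjustment is `stats::p.adjust(method = "BH")`. A
feature is `up` when log2FC > 1, p < 0.05 and FDR < 0.05 (strict
inequalities), `down` symmetrically; the fold-change cut is configurable
(e.g. `log2(1.5)` for the milder screen used with plasma-style panels).

## Set logic: distributions, enrichment, cell-silent screen

`vennPartition()` assigns every feature of a union to its exclusive
membership cell, so inclusion–exclusion identities hold exactly by
construction; counts, exclusive sets, pairwise intersections and the
common-to-all cell of the four EV subtype sets derive from the partition.
EV-enrichment labels combine the up-calls of the sMV-vs-CL and Exo-vs-CL
contrasts of one cell line into `both` / `sMV_only` / `Exo_only` / `none`.
The *cell-silent* screen intersects "not detected in CL" (the detection
rule above, not merely a mean below 5) with any EV-enrichment label,
partitioned by the carrying subtype. Passenger (star) strands are ordinary
features throughout and are never merged with their guide strand.

## Correlation classifier

A signature (detected, dysregulated, or EV-enriched features with their
mean TPM) is correlated with each panel sample by the Pearson
product-moment coefficient over the **intersection** of feature sets;
features absent from a sample are dropped, not zero-filled, because shared
absences manufacture spurious correlation. Correlation is computed on
untransformed TPM by default (a `log2(TPM+1)` option exists); zero-variance
profiles raise an error rather than returning 0.

The decision rule is deliberately simple: the threshold $\tau$ is the
largest coefficient among the calibration normals and a sample is predicted
tumour iff $r > \tau$. Specificity on the calibration normals is therefore
100% by construction; held-out normals estimate true specificity, and under
exchangeability a held-out normal exceeds the maximum of $k$ calibration
normals with probability $1/(k+1)$ — with the default 11 normals the
expected held-out specificity is $11/12 \approx 91.7\%$, a property worth
keeping in mind when reading specificity estimates. Fixed-threshold and
mean-plus-$k$-sd rules are available. Sensitivity and specificity are
reported as percentages rounded half-up to one decimal, the convention of
clinical reporting (564/594 prints as 94.9).

## Motif scan

Candidate EV-sorting signals are literal 4-mers (e.g. `CUGU`, bound by the
APC RNA-binding protein, and `GGAG`, recognized by hnRNP A2B1), so the scan
is exact substring matching (case-insensitive, T mapped to U with a
warning): a precursor counts once regardless of multiplicity, and all
overlapping match positions are reported 0-based. No background model is
fitted — the quantity of interest is the raw fraction of precursors
carrying the motif.

## Synthetic data generators

`simulateMirCounts()` emulates the study design: two isogenic cell lines ×
{CL, sMV, Exo} × 2 biological replicates, with library depths drawn
uniformly within ±20% of 12.77 million miRNA-mapped reads (the observed
average clean-read yield; the exact per-library depth was never a fitted
quantity). Baseline relative abundances are log-normal (log10 mean 2,
sd 1), reproducing the heavy-tailed miRNA abundance range (~0.1 to
>300,000 TPM). Counts are NB with gene-wise mean and a global dispersion
$\varphi$ (default 0.1, typical of biological duplicates; $\varphi = 0$
gives Poisson). Planted, mutually disjoint classes with recorded truth:

* **dysregulated** (default 20% of features, |log2FC| = 2 between the two
  lines, half up/half down) — applied to all compartments of the second
  line, since a cellular change propagates to its vesicles;
* **EV-enriched** (default 10%, log2FC = 3 for EV over CL, split evenly
  sMV-only / Exo-only / both);
* **cell-silent EV** (default 5%): expected lysate TPM pinned at exactly 1
  and EV TPM drawn from [2000, 6000] by solving the abundance-mass
  equation $a_i = t_i B/(10^6 - T)$, so the planted < 5 / > 1000 TPM
  pattern survives sampling noise at any feature count;
* **passenger annotation** for 29.6% of features (the fraction observed in
  colorectal cell-line lysates).

Planted fold changes act on relative abundances before per-library
renormalization, so realized fold changes carry a small compositional
shift — exactly the situation TMM is designed to absorb. Panels
(`simulateTumourPanel()`) blend a shared baseline toward the signature,
$(1-w)\,b + w\,\sigma$, with multiplicative log-normal noise (defaults
$w = 0.6$, sd 0.3, 11 normals and stage counts 103/223/179/89); normals are
noisy copies of the baseline only. Precursor sets
(`simulatePrecursors()`) contain exactly `round(n × fraction)`
motif-bearing sequences, with motif-free sequences guaranteed by rejection
sampling.

What the generators do **not** emulate: read-level artefacts (adapters,
alignment, isomiRs), correlated dispersion structure across miRNA families,
batch effects between panels and signatures, and microarray-style intensity
data. Passing tests therefore demonstrate correctness of the inference
chain under a faithful NB abundance model, not robustness to every artefact
of real libraries.

## Problem sizes and reproducibility

Test and acceptance runs use deliberately chosen sizes: 2000 null features
× 3 dispersions × 3 seeds for type-I calibration, 500 features with 3
replicates for recovery, 20–100 replicate panels for classifier metrics,
and exhaustive enumeration of all conditional totals ≤ 30 against the
oracle. A single master seed drives every generator through independent
derived sub-streams, and the full pipeline is byte-reproducible: identical
configuration and seed give identical output files, verified by checksum in
the test-suite.

## Known limitations

* The exact test's equalization (proportional rescaling) and fold-change
  prior (0.5) are documented variants; published tables produced with other
  tools' undocumented internals are not numerically reproducible
  bit-for-bit, and no attempt is made to do so.
* The beta tail approximation beyond totals of 20,000 is accurate in the
  large-size regime it serves but is not exact; all small-total inference
  is exact.
* The max-normal decision rule is a transparent default, not an optimized
  classifier; its held-out specificity is bounded in expectation by the
  order-statistic argument above.
* Correlation on untransformed TPM is dominated by the most abundant
  features; the log option trades this for sensitivity to low-abundance
  disagreement. The default matches the convention of correlating raw
  normalized expression.
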