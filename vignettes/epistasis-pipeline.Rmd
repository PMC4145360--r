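---
title: "Two-phase QMDR epistasis discovery: models, parameters and design"
author: "epiQMDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase QMDR epistasis discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiQMDR)
```

## The problem

Single-SNP association scans miss genetic effects that only appear
jointly — statistical epistasis. For a quantitative endophenotype (a
heritable intermediate trait such as a neuroimaging measure used in
place of a disease diagnosis), this package implements a two-phase
strategy: an exhaustive *within-gene* interaction screen keeps the
combinatorics tractable while allowing both additive and non-additive
signals, and a *functional-genomics filter* then trades statistical
stringency for biological plausibility before a final, fully exhaustive
multi-way model search.

## The QMDR estimator

For a subset of $k$ SNPs (here $k \le 4$) the $3^k$ multilocus genotype
cells are a constructive-induction device: each cell with at least one
sample records its phenotype mean, and a cell is labelled HIGH when that
mean is at or above the global mean of the samples in the model, LOW
otherwise. Ties go to HIGH — with discrete or duplicated phenotype
values exact ties do occur, and an arbitrary but fixed rule keeps the
estimator deterministic. The pooled HIGH and LOW groups are compared
with the Welch (unequal-variance) two-sample $t$:
$$t = \frac{\bar y_H - \bar y_L}{\sqrt{s_H^2/n_H + s_L^2/n_L}}.$$
We chose Welch over the pooled-variance form because the two groups are
constructed to differ and their variances have no reason to be equal;
the choice is stated explicitly since "a two-sample t-test" alone does
not pin it down, and the group sizes and a degeneracy flag are carried
in every fitted model. Degenerate poolings — an empty group, or zero
spread in both groups — score a sentinel 0 instead of raising, so
exhaustive scans never abort on a pathological subset. A singleton
group contributes zero variance to the denominator.

Samples missing a genotype at *any* SNP of the subset are excluded from
that model only (complete-case per model, no imputation), and the
global mean is recomputed over the included samples. Cross-validation
is not part of the default path: significance comes from permutation.
A 10-fold consistency score (cells labelled on training folds, Welch
$t$ on the held-out fold, averaged) is available via
`fitQmdr(cv = TRUE)` for parity with standalone QMDR software, but it
never drives selection.

## Permutation significance

Every reported p-value comes from re-running the *full* search — not
just rescoring the chosen model — on phenotypes shuffled across
samples, so the null distribution absorbs the selection of the best
model. With $r$ of $N$ permuted search scores at or above the observed
one, $p = (r+1)/(N+1)$; ties count against the observed score. The +1
convention avoids $p = 0$ and makes "$p < 0.001$ with 1000
permutations" attainable exactly when the observed search beats every
shuffle. Each permutation derives its own sub-seed from the master seed
and a counter (an exact-in-doubles Lehmer-style mixer), and each gene's
stream is derived from the master seed and the gene id, so results are
independent of screening order and of any parallel scheduling.

The final search's p-value is conditional on the Phase I/II selection
of its candidate SNPs; the output metadata says so rather than
attempting a nested correction.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `windowBp` | 500000 | bp added on each side of a gene span when mapping SNPs; boundaries inclusive at exactly 500 kb |
| `nPermutations` | 1000 | trait shuffles per permutation test |
| `alpha1` | 0.001 | Phase I gene threshold, strict (`p < alpha1`) |
| `minConfidence` | 0.9 | functional-network edge filter, inclusive |
| `alpha2` | 0.05 | gene-set enrichment threshold, strict |
| `maxAdded` | 20 | genes the network may add to the candidate list |
| `orders` | 2–4 | model sizes in the final exhaustive search |
| `epsilon` | 0.005 bits | \|IG\| below which a pair is labelled independent |

The screening threshold is deliberately permissive (no multiple-testing
correction across genes): the design accepts more type I error at Phase
I because the functional filter is the intended false-positive control.
A Benjamini–Hochberg option exists (`selectSignificantGenes(adjust =
TRUE)`) but is off by default. Enrichment is the one-sided
hypergeometric (Fisher exact upper tail) on unadjusted p-values; the
enrichment universe is an explicit input (defaulting to the union of
the gene-set file) because no single universe is canonically right.

Candidate selection keeps a screened gene when it has at least one
edge in the filtered network *and* sits in at least one enriched set,
or is connected in that network to such a gene; a disjunctive variant
(`combine = "or"`) is exposed because the narrative combination of
"network and enriched pathways" admits both readings. Network
augmentation ranks outside genes by maximum edge confidence to the kept
set, then by number of distinct kept neighbours, then lexicographically
— a fully specified rule standing in for a webserver's unspecified one.

Across orders the final search compares raw $t$ statistics; within a
$10^{-9}$ score tolerance the smaller model (then the lexicographically
first subset) wins, so a pair never loses to a superset that adds
nothing.

## The entropy network

For interaction structure the quantitative trait is binarized at its
global mean — the same threshold constructive induction uses, keeping
the two halves of the package consistent; a median alternative exists
for skewed traits (`binarizeTrait(method = "median")`). All quantities
are in bits. Node weights are single-SNP mutual informations
$I(G_i;P)$, edges carry the information gain
$IG(A;B;P) = I(A,B;P) - I(A;P) - I(B;P)$ (positive = synergy, negative
= redundancy, $|IG| < \varepsilon$ = independent), triangles the pure
three-way gain after removing all one- and two-way terms, and a
parallel table holds inter-SNP mutual information $I(A;B)$ as a
linkage-disequilibrium measure. The $\varepsilon$ label is purely a
reporting convention; raw values are always emitted. Small-sample bias
of plug-in entropies (positive, order $df/(2n\ln 2)$) is left
uncorrected — at the package's default $n$ it is an order of magnitude
below the planted signals, and edge-level significance can be obtained
through the permutation module when needed.

## What the simulator emulates — and what it does not

`simulateGenotypes()` draws each SNP's minor allele frequency uniformly
from a configured range and samples genotypes as two independent allele
draws (Hardy–Weinberg proportions), in linkage equilibrium by default;
an optional Gaussian-copula block model introduces LD for robustness
checks only. `simulatePhenotype()` adds Gaussian noise, additive terms
(standardized dosage times effect size), and epistatic cell patterns.
The canonical epistatic pattern is the parity checkerboard,
orthogonalized against all single-SNP margins *under the generating
genotype frequencies* and scaled to a target SD — so a planted
interaction carries provably zero marginal effect at any MAF, which is
exactly the "synergy without main effects" signature the pipeline is
built to detect.

The end-to-end fixture `simulateStudyFixture()` plants a complete study
shape: 28 two-SNP genes of which 20 carry effects; a 2-gene and a
3-gene cluster placed inside one mapping window so their SNPs are
shared (hence 34 unique SNPs across the 20 genes); a 6-gene functional
module carrying 10 unique SNPs with 4 high-confidence satellites; one
strong synergistic pair, one independent additive SNP, and moderate
background interactions. Its default conditions — 2000 samples, noise
SD 1, MAF U(0.2, 0.4), background epistatic size 0.7, headline pair
2.0, additive SNP 1.0 (noise-SD units) — were set once by a power
calculation: a background pair separates its pooled groups by roughly
$2\mathbb{E}|f| \approx 1.3 \times 0.7$ against a total phenotype SD
near 3.7, giving $t \approx 7$ at $n = 2000$, comfortably above the
$\approx 4.5$ maximum of 1000 permutation nulls, while the headline
pair reaches $t \approx 20$.

What passing these simulations does *not* show: real GWAS data have LD
structure, MAF spectra, genotyping missingness patterns and population
stratification that the generator does not emulate, and real
functional networks are noisier than a planted module. The simulations
validate the machinery — exhaustiveness, calibration, decomposition
identities — not field performance.

## Numerical and design notes

* Coordinates: genes are read from BED (0-based half-open) and held
  1-based inclusive; SNP positions are 1-based. All window comparisons
  happen after this single documented conversion, and the mapping
  boundary is inclusive at exactly the window distance.
* Dosages count the *minor* allele as observed in the loaded panel; at
  an exact 0.5 frequency tie the lexicographically larger allele is
  deemed minor, which makes the .ped writer/reader a fixed point.
  QMDR itself is label-agnostic, so the coding only affects reporting.
* The exhaustive kernels accumulate group sums centred at the global
  mean, keeping the Welch statistic stable under large phenotype
  offsets (affine invariance holds to $10^{-9}$ in the tests).
* Entropies use $0 \log 0 = 0$ and base-2 logs throughout.
* Degenerate inputs: constant phenotypes make every cell HIGH (tie
  rule) and score 0; genes with fewer than two mapped SNPs are skipped
  with a message, not given singleton models; empty networks or
  all-sub-threshold edges yield empty — not erroring — candidate sets.
* Test and vignette problem sizes (hundreds to a few thousand samples,
  tens of SNPs, 199–1000 permutations) were chosen so the full suite
  exercises every stage at meaningful power on a single CPU.

## Known limitations

The screen attaches one p-value per gene via its best pair, so genes
sharing a window share evidence; overlapping-window duplication is
reported, not corrected. The final permutation p is conditional on the
upstream screen. Entropy estimates are plug-in and biased upward at
small $n$. The package deliberately does not re-implement Bayesian
functional-network inference — it consumes any (gene, gene, confidence)
edge list — and does not model case/control traits or covariate
adjustment (pre-adjust the phenotype instead).
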