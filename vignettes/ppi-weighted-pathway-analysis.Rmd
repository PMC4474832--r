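---
title: "Interaction-partner-weighted pathway analysis of GWAS summary statistics"
author: "ppigsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-partner-weighted pathway analysis of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigsea)
```

## The problem

A single candidate gene often shows weak, inconsistent marginal association
with a complex trait even when its biology is clearly relevant. One way
around the small-main-effect problem is to move the unit of analysis from
the gene to the pathway, and to bring in the gene's protein interactome:
if the candidate acts jointly with the genes whose products it binds, the
association signal should concentrate in pathways containing the candidate
(the *seed gene*) or enriched for its interaction partners.

ppigsea implements that analysis for GWAS **summary statistics** (per-SNP
p-values; genotypes are not needed), together with a small
molecular-evolution toolkit for characterising the seed gene's ortholog
family, and a synthetic-data module that generates full studies with known
ground truth.

## From SNP p-values to gene statistics

SNPs are assigned to every gene whose interval, extended by a window
(default ±20 kb, `windowKb`), covers their position; a SNP inside two
overlapping windows counts for both genes. The mapping rule is
deliberately simple — no exclusive assignment, no LD weighting — because
only summary statistics are available.

A gene's raw score is the minimum p-value over its $m$ assigned SNPs,
which favours long genes. The first-order-statistic correction (FOSCO)
removes that bias: under independence the minimum of $m$ uniform p-values
has distribution function

$$p_{\text{gene}} = 1 - (1 - p_{\min})^m ,$$

so the corrected value is again Uniform(0,1) under the null for every
gene size. `foscoCorrect()` implements exactly this form, with $m$ the
raw assigned-SNP count: without genotypes no effective-number-of-tests
adjustment is possible, and the independence assumption is stated rather
than hidden. The corrected p-value is mapped through the upper-tail
chi-square(1 df) quantile (`geneStatistic()`), so that a pathway's
SumStat score is a sum of 1-df chi-squares under the null. Tests verify
the uniformity of the corrected value at $m \in \{1, 5, 50\}$ and the
absence of a size–statistic trend.

## Curating the pathway collections

Two labels are attached to a catalogue (`CuratedCatalog`):

* **seed-pw** — the set contains the seed gene;
* **igene-pw** — strictly more than 10% of the set's genes are *I-Genes*,
  i.e. interaction partners of the seed gene with evidence score strictly
  above 0.4 (the medium-confidence cut of the common interaction
  databases; scores on the 0–1000 integer dialect are rescaled on read).

Both thresholds are strict on purpose: a set at exactly 10% I-Genes, or a
partner at exactly evidence 0.4, does not qualify. Sets with fewer than
10 or more than 380 genes are excluded (`filterBySize()`): tiny sets make
permutation quantiles meaningless and huge ones describe overly general
processes. The boundaries are inclusive — 10 and 380 are retained. The
examined family for multiple-testing purposes is the union of the two
labelled collections after filtering (`examinedSets()`,
`mergeExamined()`), and medians of set sizes use the midpoint of the two
central values for even counts.

The 10-gene floor is treated as a fixed constant (it happens to sit near
the 10th percentile of public catalogue sizes), not as a dynamic
percentile rule.

## Pathway statistics and the permutation null

Two statistics are available per pathway:

* **SumStat** (self-contained): $\sum_{g} w_g \, T_g$ over the pathway's
  scored genes, $T_g$ the chi-square gene statistic.
* **GSEA enrichment score** (competitive): walk the genes in decreasing
  order of $T_g$; at a member add $w_g T_g / \sum_{\text{members}} w T$,
  at a non-member subtract $1/(N - N_{hit})$; the ES is the running-sum
  value of largest magnitude, signed, always in $[-1, 1]$.

The weighting scheme gives I-Genes twice the weight of other genes
(`weightScheme(igeneWeight = 2)`); both weighted and unweighted columns
are always computed from the same null draws, so a pathway without
I-Genes gets identical p-values in both columns.

Because genotypes are unavailable, significance comes from **gene-label
resampling**, not phenotype permutation: each of $B$ replicates (study
default $B = 15000$; the examples here use smaller $B$) draws a random
gene set of the same size from all scored genes and recomputes the
statistic. The empirical p-value uses the $(\#\{null \ge obs\} + 1)/(B+1)$
convention and is never zero. Benjamini–Hochberg adjustment is applied
across the examined family within each (method, weighting) column.

### Why the default null preserves I-Gene composition

The I-Gene list is one shared pool of a few hundred genes, and the
I-Gene-rich pathways all draw on it. In any single realization the pool's
mean statistic deviates a little from the genome-wide mean by chance, and
every I-Gene-rich pathway inherits that deviation *together*. A plain
label resample (null sets drawn uniformly) then leaves the whole
collection jointly miscalibrated — simulations at realistic scale show
the p-value distribution failing uniformity checks badly at some seeds
even under a global null. The default null (`nullModel = "composition"`)
therefore draws each null set with the pathway's own I-Gene count from
the scored I-Genes and the remainder from the other genes, with weights
aligned to membership. The test becomes exact conditional on the realized
I-Gene statistics and calibrates at every seed we tried. The plain
resample with the weight multiset applied in random order remains
available (`nullModel = "multiset"`), and the low-level
`permutationNull()` implements exactly that model.

One practical caveat follows from the same analysis: pathway p-values are
correlated whenever pathways share genes, so the *spread* of significant
counts in small catalogues is larger than binomial intuition suggests.

## The synthetic-data module

`simulateStudy()` generates a complete study: non-overlapping 20-kb genes
on synthetic chromosomes (200 kb start-to-start), per-gene SNP counts
from a zero-truncated Poisson (zeros resampled, so the realized mean is
slightly above nominal), independent Uniform(0,1) null p-values, an
interaction table whose strict 0.4 filter recovers exactly the planted
partners, and a catalogue with controlled sizes and I-Gene fractions.
Planted associations replace one random SNP's p-value per affected gene
with $1 - \Phi(z)$, $z \sim N(\delta, 1)$ — the minimal effect model that
exercises the min-p/FOSCO path; one affected SNP per gene, not all,
because the gene statistic is a minimum. Every generator is a pure
function of the spec and a single master seed (fixed per-generator
offsets split the streams).

The calibration and recovery experiments in the test suite run at the
scale of the motivating study — about 16,000 mapped genes, 400,000 SNPs
(≈25 per gene), 363 I-Genes, 500 pathways of 10–60 genes, $B = 500$ —
chosen because gene sharing between sets (the correlation caveat above)
is negligible at that scale. What these experiments do *not* emulate:
linkage disequilibrium between SNPs (so $m$ is a true count there, while
in real data FOSCO's independence assumption makes the correction
conservative), case/control sampling noise, and catalogue gene-name
mismatches.

## The molecular-evolution arm

For an ortholog family of the seed gene, `runEvo()` produces:

* **Pairwise identity** from affine-gap global alignment
  (Needleman–Wunsch via Biostrings; protein BLOSUM62 with gap open 11 /
  extend 1, nucleotide +2/−3 with gap 5/2 — the classic search-tool
  parameterisation). Identity is reported in *trimmed* mode by default:
  terminal-gap columns are excluded, approximating what a local-alignment
  search reports; boundary effects against a true local alignment are
  below ~1% for diverged pairs. Inputs are aligned in a canonical order
  internally so identity is exactly symmetric.
* **NG86 dN/dS**: protein alignments are back-translated to codons
  (`backtranslate()`, gaps become whole-codon gaps, one trailing stop is
  stripped, any translation mismatch is an error naming the residue).
  Synonymous sites per codon are the fraction of the nine single-base
  mutants preserving the amino acid (mutants to stops count as
  nonsynonymous, so $S + N = 3 \times$ codons); differences are averaged
  with equal weight over mutation pathways avoiding stop codons (all
  pathways, flagged, if none avoids them); proportions get the
  Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$,
  undefined (flagged) at $p \ge 3/4$. $\omega = dN/dS$ is reported only
  when $dS > 0$. Codon pairs containing gaps or ambiguity codes are
  dropped pairwise.
* **Neighbor-joining tree** on $1 - $ identity p-distances (the distance
  model is recorded in the run manifest since reasonable alternatives
  exist), with the canonical Q-criterion algorithm; two taxa split a
  single edge evenly, and negative estimated branch lengths are retained
  but flagged.

A worked three-species example:

```{r evo-example}
library(Biostrings)
cds <- DNAStringSet(c(
  sp1 = "ATGAAATTTGGGCCCACTGAGTGTATC",
  sp2 = "ATGAAGTTTGGACCCACTGAGTGTATC",
  sp3 = "ATGAAGTTCGGACCAACGGAATGCATC"))
ng86Pairwise(cds)
```

## End-to-end example

```{r pipeline-example}
spec <- simulationSpec(nGenes = 500, snpsPerGeneMean = 5, nIgenes = 60,
                       seed = 42)
sim <- simulateStudy(spec, nSets = 40, sizeRange = c(10, 40))
scores <- scoreGenes(sim$assoc, sim$annotation)
curated <- filterBySize(selectIgenePathways(
  selectSeedPathways(newCuratedCatalog(sim$catalog, sim$truth$igenes),
                     sim$seedGene)))
curated
res <- runPathwayAnalysis(scores, curated, sim$truth$igenes,
                          B = 500, seed = 42)
head(resultTable(res)[, c("set_id", "n_mapped", "pct_igenes", "weighted",
                          "score", "p_perm", "p_adj")])
```

## Numerical and design notes

* A corrected gene p-value of exactly 0 is capped at $10^{-300}$ before
  the chi-square transform, with a warning.
* Pathways with fewer than `minMapped = 5` scored genes are skipped with
  a logged reason.
* Run manifests record config, input digests, seed and derived counts but
  no wall-clock times, so identical configs give byte-identical outputs.
* The effect model ($z$-shift mapped to a p-value) is a stand-in: the
  motivating study analysed real genotype data and states no effect-size
  model.
* Known limitations: no LD-aware gene statistics, no phenotype
  permutation, no multiple sequence alignment or maximum-likelihood
  dN/dS, no haplotype-based selection scans.
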