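---
title: "Methods: pedigree and marker analysis of inbred cultivar populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree and marker analysis of inbred cultivar populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtrace)
```

# Scope and model assumptions

`germtrace` analyses released-cultivar populations of **fully inbred,
homozygous lines** — the standard situation in self-pollinating crops such
as soybean, where every cultivar, parent and founder is treated as
homozygous and homogeneous. That assumption runs through the whole package:
lines carry a single haplotype per locus, observed heterozygosity is zero
in the F~ST~ machinery, and gene dropping transmits whole homozygous
blocks.

A pedigree is a directed acyclic graph with one typed breeding event per
non-terminal cultivar: a **cross** (two parents), a pure-line **selection**
or a **mutation** (one source). Records whose parentage cannot be traced
further are **terminal ancestors** (landraces, unknown introductions); they
are exactly the parentless nodes. Parents referenced but never declared are
auto-created as terminal with unknown metadata, which encodes the working
assumption that unknown relatedness is fixed at 0 (unrelated) rather
than 1.

# Pedigree quantities

## Nuclear and cytoplasmic contribution

Germplasm shares propagate down the pedigree: each hybridization passes
half of the incoming share to each parent lineage, while selection and
mutation pass the share whole. Founder contributions therefore sum to 1
for every cultivar, a conservation law asserted at `1e-12` and exercised
on hundreds of random pedigrees in the test suite. The cytoplasm follows
the maternal slot of every cross — and, by physical inheritance, the single
source of a selection or mutation — up to one terminal female ancestor,
which receives cytoplasmic contribution 1.

## Coefficient of parentage

COP is the identity-by-descent probability of two lines under the breeding
rules for inbred material: `cop(x, x) = 1`; two distinct terminal
ancestors are unrelated (0); for a cross child `c` of `f` and `m`,
`cop(c, x) = (cop(f, x) + cop(m, x))/2` whenever `x` is not descended from
`c`, which reproduces the classical `COP = sum (1/2)^n` over paths through
common parents; a selected line or mutant has COP 0.75 with its source.

Two points were genuinely open and are resolved here as package design
choices:

* **Propagation of the 0.75 selection rule.** Only the endpoint value
  (selected line vs source) is fixed by the rules. We recurse
  multiplicatively — `cop(s, x) = 0.75 * cop(source, x)` for other `x` —
  which keeps the stated endpoint and decays relatedness monotonically
  beyond it.
* **No inbreeding adjustment.** Because all lines are declared homozygous
  and homogeneous, the recursion makes no Wright-style adjustment for the
  inbreeding of common ancestors.

The implementation memoizes on the pair and always expands the deeper
member (longest path from the founders), which guarantees the
"not descended from" side condition structurally. An unmemoized
ancestor-set-driven recursion serves as the independent oracle in the
tests, and a gene-dropping simulation confirms that COP equals the
Monte-Carlo identity-by-descent frequency on cross-only pedigrees.

## Breeding cycles, core ancestors, families

The breeding-cycle count of a founder relative to a derived cultivar is
the **maximum number of cross events over all descending paths** —
selection and mutation steps are traversed but not counted, since they add
no recombination. The maximum (not minimum) is used because the indicator
measures how deeply a founder's germplasm has been worked through the
program; the deepest route is the conservative prominence measure.

Terminal ancestors with three or more breeding cycles are candidates;
a candidate is nominated a **core-terminal ancestor** when at least two of
its four indicators (nuclear contribution %, cytoplasmic contribution %,
derived-cultivar count, cycle count) are **strictly** above the candidate
mean — ties do not count, so a lone candidate nominates nothing. Whether
the comparison pool is the candidates of the same geographic origin set or
all candidates is ambiguous in the source procedure; both modes are
implemented, with within-set as the default. A core ancestor plus its
derived cultivars forms an ancestor-derived family; family tables count
cultivar-times (one per family membership), so cultivars derived from
several core ancestors appear once per family.

# Marker statistics

## SNPLDB assembly

SNPs passing QC (missing rate at most 20%, heterozygote rate at most 10%,
minor allele frequency at least 0.01; heterozygous calls are set missing
first, as appropriate for inbred panels) are grouped into **SNP
linkage-disequilibrium blocks**: scanning left to right within a
chromosome, the current block absorbs the next site while its absolute D'
with *every* site already in the block exceeds the threshold (default
0.7); otherwise a new block starts. D' is computed directly from haplotype
counts, reading each homozygous line as one phased haplotype. Each block
becomes a multi-allelic locus whose alleles are the observed haplotype
strings; classes rarer than 1% (mirroring the SNP MAF floor) merge into a
single rare class. The upstream tool that inspired this marker type does
not publish its exact blocking algorithm, so this greedy all-pairs rule is
a documented approximation — pre-assembled haplotype matrices can be
supplied directly (`hap_matrix()`, `read_hap_matrix()`) when fidelity to
an external block map matters.

## Diversity, similarity, differentiation

* **Richness**: distinct haplotypes per locus summed over loci; the allele
  load per cultivar (total / n) falls as lines share more of the
  catalogue.
* **Dispersion**: `pi = n/(n-1) * sum p_i (1 - p_i)` from haplotype
  frequencies among the lines scored at the locus, averaged (unweighted)
  over loci — the averaging weight was unstated in the source and uniform
  is the natural choice.
* **SPA / SDA**: a (locus, haplotype) pair present only in one
  subpopulation, or absent from exactly one while present in all others.
* **CGS**: `s_ij = sum_k C_ijk / (2m)` with `C_ijk = 2` when homozygous
  lines share the haplotype and 0 otherwise; `m` counts only loci where
  both lines are scored (pairwise-complete), so missingness is not
  penalised as dissimilarity. Distance is `d = 1 - s`; it is a semimetric
  (no triangle inequality claimed).
* **F~ST~**: the Weir–Cockerham ratio-of-sums estimator, accumulating the
  among-population, among-individual and within-individual variance
  components per haplotype per locus before dividing. With fully
  homozygous lines the observed heterozygosity — hence the
  within-individual component — is 0; negative per-locus components are
  retained in the sums; a slightly negative overall estimate is reported
  raw and clamped to 0 only in report columns. The test oracle recomputes
  the components through a three-level ANOVA on gamete indicators.
* **Mantel**: Pearson correlation of upper triangles with a seeded
  permutation null, `p = (count + 1)/(n_perm + 1)`; the permutation RNG is
  an isolated stream, so calling the test never disturbs the caller's
  random state.
* **PCA**: one-hot haplotype encoding (missing calls imputed at the
  column mean), column-centred, `prcomp`; component signs are fixed by
  making the largest-magnitude loading positive.

# Clustering

Neighbor joining is implemented in canonical Saitou–Nei form with two
reproducibility refinements: ties in the Q-criterion break to the lowest
index pair, and negative branch lengths are clamped to zero with the
deficit moved to the sibling edge so path lengths through the join are
preserved. On additive metrics the generating topology is recovered
exactly (a property test over random additive trees up to 12 taxa) and on
arbitrary matrices the topology matches an independent reference
implementation.

How the published seven groups were delimited on the tree is not stated in
the source; the package defines a reproducible stand-in: midpoint-root the
tree and cut the k−1 longest internal edges (falling back to pendant edges
only when k approaches the leaf count, where internal cuts cannot produce
enough groups — cutting proceeds in priority order until exactly k leaf
groups exist). Groups are labelled A, B, … by decreasing size with
lexicographic tie-breaks. Root distances for reporting use the midpoint
root.

# Phenotype analysis

The trial model is the multi-environment randomized-complete-block ANOVA
`y_ijk = mu + t_i + b_j(i) + g_k + (gt)_ik + e_ijk`, fitted by least
squares with sequential sums of squares in that order. Genotype and
genotype-by-environment are treated as random for the expected-mean-square
solution (environments and blocks fixed), giving
`s2_ge = (MS_GE - MS_E)/b` and `s2_g = (MS_G - MS_GE)/(e*b)`; with unequal
block counts per environment (the motivating field design used 2 and 3),
`b` is replaced by the effective replication `N/(g*e)` — an approximation
we document rather than hide, and the Type-I ordering makes the fit
deterministic. Negative component estimates are reported raw, flagged, and
clamped at zero in `GCV = 100 * sigma_g / mu`. GCV is scale-invariant,
which the tests assert directly.

# The synthetic breeding program

Because the motivating study's raw panel is not deposited, every stage is
validated on simulated programs whose generator is itself part of the
package:

* **Pedigree**: founders per region are terminal records; each generation
  draws within-region parent pairs (cross-region with the migration
  probability) and emits cross children, with a fraction re-released as
  pure-line selections. Defaults (3 regions, 10 founders each,
  5 generations, 20 crosses per generation, selection fraction 0.1,
  migration 0.05) sketch a compact multi-ecoregion program at desk scale.
* **Founder haplotypes**: the genome is tiled into linked blocks
  (geometric lengths, mean 5 SNPs). Each block carries up to 4 ancestral
  prototype haplotypes; regions draw prototype frequencies from a
  Dirichlet centred on shared base weights with concentration
  `(1 - divergence)/divergence`. Divergence 0 gives identical founder
  pools; divergence 1 fixes each region on one (often private) prototype.
  The default 0.6 models strongly diverged ecoregion founder pools so that
  region-private haplotypes exist and regional structure is recoverable.
* **Gene dropping**: a cross child inherits each block whole from one
  parent (fair coin), instantly homozygous; within-block recombination
  occurs with probability 0.01 per transmission; selections copy their
  source; mutants flip a small site fraction. Block-level transmission
  keeps runtimes at desk scale; "instantly homozygous" matches the
  inbred-line assumption instead of simulating selfing generations.

What the simulation does **not** emulate: realistic recombination maps and
LD decay, selection on phenotype, imputation artefacts, genotyping error,
and the historical structure of a century-long program. Passing tests
therefore demonstrate the correctness of the estimators and their
agreement with theory on pedigree-consistent data, not calibration to any
particular real panel.

# Problem sizes and numerical choices

The test suite and the analysis scripts run at deliberately compact sizes
chosen as representative desk-scale problems: simulated programs of a few
dozen to ~70 cultivars, genomes of a few hundred SNPs in linked blocks,
10,000-replicate gene drops for identity-by-descent checks, 200-replicate
parameter-recovery studies for GCV, 200 random additive trees for NJ, and
200 null runs for Mantel uniformity. Contribution conservation is asserted
at `1e-12`; estimator-vs-oracle identities at `1e-10`; Monte-Carlo
agreements at multiples of their standard errors. All randomness flows
through explicit integer seeds, and stochastic stages re-run byte-identically
under the same seed.

# Worked example

```{r example}
g <- read_pedigree(system.file("extdata",
        "nannong32_pedigree_synthetic.tsv", package = "germtrace"))
nuclear_contribution(g, "Nannong 32")
cytoplasmic_ancestor(g, "Nannong 32")
breeding_cycles(g, "Mamotan", "Nannong 32")
cop(g, "Nannong 32", "Chuxiu")
```

The shipped fixture reconstructs the published Nannong 32 pedigree: its
seven terminal ancestors, their contributions
(0.25/0.25/0.125/0.125/0.125/0.0625/0.0625, summing to 1), the maternal
trace to Fengxiansuidaohuang, and the four-cycle depth of Mamotan are all
published facts; the unnamed intermediate cross lines are synthetic
placeholders consistent with them, and the file says so in its header.

# Known limitations

* Outbred or heterozygous material is out of scope throughout (pedigree
  rules, D' from unphased heterozygotes, CGS pair counting).
* The SNPLDB blocking is a documented greedy approximation, not a clone of
  any external tool; block maps can be supplied externally.
* COP treats all founders as unrelated; populations with hidden founder
  relatedness will show COP below marker-based similarity, which is
  exactly the comparison the COP-vs-CGS reports are for.
* The EMS variance-component solution assumes near-balanced data; strongly
  unbalanced designs should move to a mixed-model fit outside this
  package.
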