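---
title: "Inferring haplogroup structure from binary Y-SNP panels"
author: "ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring haplogroup structure from binary Y-SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

## The model

The male-specific region of the Y chromosome passes from father to son
without recombination, so the men in a sample are related by a single
genealogy and every binary SNP marks one mutation on it. With the
ancestral allele known (from outgroup comparison, as is standard for
named Y-SNPs), each marker is a *rooted* binary character: the set of men
carrying its derived allele — its **derived set** — is exactly the clade
below the mutation.

If genotyping were error-free and every mutation unique, any two derived
sets would be **nested or disjoint**. This is the rooted-character form of
the four-gamete condition: with the all-ancestral gamete fixed, observing
derived/derived, derived/ancestral and ancestral/derived for a pair
simultaneously is what rules out a common tree. The parsimony rule for
placing markers follows directly:

* identical derived sets → **equivalent** markers: the same branch cannot
  be subdivided by them in this sample;
* strict containment → one marker is **downstream** of the other;
* disjoint non-empty sets → parallel branches;
* no derived carriers within the lineage → the marker does **not belong**
  to the lineage at all;
* overlapping but non-nested sets → **incompatible** with a single tree
  (a genotyping artefact or recurrent mutation).

`buildTree()` applies the rule literally. Restricted to the samples
derived at the root marker, markers are grouped into equivalence classes
by identical derived sets, never-derived markers go to the exclusion
ledger as `NOT_IN_LINEAGE`, incompatible classes go there as
`INCOMPATIBLE`, and the remaining classes are ordered by strict
containment. Because every class is a subset of the root set and distinct
classes have distinct sets, the minimal strict superset of each class is
unique, so the Hasse diagram of containment *is* the tree; siblings are
automatically disjoint (an overlapping non-nested pair would have been
excluded, and a nested pair cannot be siblings).

All set comparisons run over **jointly typed samples only**. In a
two-stage design — screen one marker in everyone, run the multiplex panel
only in screen-positives — the untyped cells are structurally missing;
treating them as ancestral would fabricate exclusions. `classifyPair()`
exposes the pairwise relation with its four support counts and flags
comparisons resting on fewer than `nMin` jointly typed samples (default
1: a single haploid genotype is already informative, but surveys wanting
a stricter evidential floor can raise it).

### External constraints

A marker can be equivalent to the root class in one sample set yet known
to branch off above it from samples genotyped elsewhere. PK4 is the
textbook case: derived in every M95-derived man here, but placed upstream
of M95 because PK4-derived/M95-ancestral men exist in other collections.
That knowledge is not in the matrix, so it must not be inferred silently;
`buildTree(constraints = )` takes explicit `ABOVE`/`EQUIVALENT`
assertions, applies them only where the data cannot decide (equivalence),
records them in the tree, and errors when a constraint contradicts strict
containment actually observed. Lifting is supported only above the root
class: re-ordering equivalent markers deeper in the tree would assert a
branch for which the current data contain no carrier at all, and the
right fix there is to add the external samples themselves.

### Nomenclature

Labels follow the YCC convention: children extend the parent label by one
token, alternating letters and numbers with depth
(`O2a1 → O2a1a/O2a1b → O2a1b1 → O2a1b1a`). The convention does not say
which child receives `a`; `assignLabels()` defaults to descending
derived-sample count — which reproduces observable practice, where the
dominant sub-branch takes the first letter — with ties broken by natural
(numeric-aware) marker order so that `F2` precedes `F10`. A `name`-only
policy is available when count-independent labels are wanted. Letters run
a–z and then error, since no published convention extends them; numeric
suffixes are unbounded. The root label is an input: the package does not
model the phylogeny above its root marker. Each equivalence class is
displayed through a representative — the root marker for the root class,
a user-supplied historic name (e.g. M88) where given, otherwise the
natural-sort smallest marker. One orthographic note: listings of the
F761 branch occasionally abbreviate one of its equivalent markers as
"F758"; the assay panel's F2758 is used throughout.

### Assignment semantics

`assignSample()` walks from the root into the unique derived child. The
distinction at the stop node matters scientifically:

* **paragroup** (`O2a1b1*-M88`): derived at the node, *assayed ancestral*
  at every child — a positive claim that the sample belongs to no known
  subclade;
* **`UNRESOLVED`**: some child entirely untyped — the same node label
  without the star, because the paragroup claim would overreach the
  assay;
* **`INCONSISTENT_CALL`**: a derived node below an ancestral ancestor, or
  derived calls on two branches neither containing the other. Assignment
  still happens at the deepest consistent node, so one bad call does not
  void a sample.

Markers in the exclusion ledger are ignored during assignment rather than
rejected — a survey legitimately genotypes markers that later prove to be
outside the lineage.

## Frequencies and rounding

`branchFrequencies()` reports exact integer counts and percentages
rounded **half-up to two decimals**. Half-up is fixed deliberately:
base R's `round()` implements banker's rounding, which differs on exact
halves (5.125% → 5.12 instead of 5.13) and varies with binary
representation; frequency tables must be reproducible byte-for-byte.
Two denominator modes mirror the two ways surveys quote shares: all
samples in the stratum, or lineage members only.

## What the simulator emulates — and what it does not

`simulateMatrix()` generates matrices with the structure the inference
assumes: samples terminate at tree nodes, calls are derived along the
root-to-node path, hierarchical missingness masks everything but the
screening marker in out-of-lineage samples, and a per-call flip
probability injects genotyping error, all from one seed. It does **not**
emulate coalescent genealogies, recurrent or back mutation, locus-specific
assay failure, or realistic population structure (population labels are
drawn independently of branch membership). Passing simulate-and-recover
therefore shows the inference is exact on data satisfying its own
assumptions — not that it is robust to systematic artefacts real panels
can contain; incompatibility handling (exclusion with report, or
`strict = TRUE` to abort) is the guard there.

`o2aFixture()` is the deterministic reference dataset: 646 men, 343
lineage members split 4 / 294 / 7 / 20 / 18 over five sub-branches, 303
out-of-lineage men with the downstream panel untyped, PK4 derived in all
lineage members, F2411/F1399 ancestral throughout. The per-region lineage
totals (Cambodia 256, Thailand 52, Yunnan 35) are the smallest counts
jointly reproducing the six published regional sub-branch percentages
and the published branch totals; the finer regional splits of the three
small branches, the regional distribution of out-of-lineage men, and the
six population labels are choices of this package (the survey's full
22-population design is not reconstructible from published counts) and
are documented as approximate — regional and population tables from the
fixture calibrate, they do not validate.

## Numerical and degenerate-input choices

* Inference is fully deterministic: canonical child order (descending
  count, natural-name ties), preorder node ids, no randomness anywhere
  outside the simulator.
* An all-missing marker column is rejected at load; an empty root
  derived set, an untestable pair (no jointly typed samples), and a
  constraint contradicting observed containment are errors; a
  zero-denominator stratum is omitted with a warning.
* A zero-sample consistency check is vacuously true.
* Incompatible classes are excluded pairwise and reported rather than
  aborting the build, so one bad assay cannot sink a survey; `strict`
  mode inverts that for pipelines that prefer hard failure.

## Verification strategy and problem sizes

The test suite checks the inference against independent oracles rather
than against itself: pairwise relations against brute-force set
enumeration on random matrices (50 matrices, all marker pairs);
simulate-and-recover of topology, classes and counts on 100 random
specifications of up to 8 nodes; Newick output re-parsed with `ape`;
paragroup arithmetic (node count minus child counts equals paragroup
count) on clean matrices; and the reference dataset's published branch
structure, counts and percentages end to end. These sizes keep the whole
suite under a couple of minutes while exercising every relation the
8-node topology space can express; the algorithms are polynomial in
markers and samples and run comfortably at survey scale (hundreds of
samples, tens of markers).

## Limitations

* No homoplasy resolution: the package excludes incompatible markers
  instead of searching for a maximum-parsimony placement.
* No branch lengths, dates, or TMRCA estimation; the tree is purely
  topological.
* No imputation of missing calls and no probabilistic assignment under a
  genotyping-error model; QC flags surface problems, they do not fix
  them.
* Paragroup labels are sample-relative: `O2a1*` means "no known subclade
  in this panel", and deeper panels will re-resolve such samples.
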