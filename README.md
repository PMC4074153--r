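# ylineage

Haplogroup phylogeny inference from binary Y-chromosome SNP panels.

## The problem

The non-recombining portion of the human Y chromosome is inherited as a
single haplotype, so every binary Y-SNP is a rooted character with a known
ancestral state: the set of men carrying its derived allele is exactly one
clade. A panel of error-free Y-SNPs therefore fits a single rooted tree if
and only if the derived-sample sets are pairwise **nested or disjoint**
(the four-gamete condition with the all-ancestral gamete fixed). This is
the parsimony rule population geneticists use to place newly discovered
SNPs inside a haplogroup: markers whose derived sets coincide are
*equivalent* (same branch), a strict subset relation means *downstream*,
and a marker never derived within the lineage does not belong to it.

`ylineage` implements that rule end to end for hierarchically genotyped
panels (screen one marker in everyone by Sanger sequencing, type the
downstream multiplex only in screen-positive men):

- **marker panels** — read, validate and write SNP assay tables
  (position, ancestral/derived alleles, primers, amplicon metadata);
- **genotype matrices** — a `SummarizedExperiment` subclass of three-state
  calls (ancestral `A`, derived `D`, missing `.`) with sample metadata,
  where structured missingness from the two-stage design is first-class;
- **tree inference** — equivalence classes by identical derived sets,
  the Hasse diagram of strict containment, an exclusion ledger for
  out-of-lineage and incompatible markers, and external constraints for
  placements (like PK4 above M95) known only from samples outside the
  data at hand;
- **nomenclature** — YCC-style labels with depth-alternating letter and
  number suffixes (`O2a1 → O2a1a/O2a1b → O2a1b1 → O2a1b1a`), paragroup
  (`*`) forms, Newick and JSON serialization;
- **sample assignment** — deepest consistent haplogroup per sample with
  `UNRESOLVED` and `INCONSISTENT_CALL` QC flags;
- **frequency tables** — counts and half-up-rounded percentages, overall
  or stratified by region/population, with all-samples or lineage-only
  denominators;
- **simulation** — genotype matrices with the two-stage missingness
  structure and seeded error injection, plus `o2aFixture()`, a
  deterministic 646-sample reconstruction of the published O2a-M95
  survey of Austro-Asiatic-speaking populations from Cambodia, Thailand
  and Yunnan.

## Worked example

```r
library(ylineage)

fix  <- o2aFixture()                     # 13 markers x 646 samples
tree <- buildTree(fix, "M95", constraints = o2aConstraints())
tree <- assignLabels(tree, "O2a1")
tree
#> HaplogroupTree rooted on M95: 5 nodes, 343/646 lineage samples
#>   O2a1-M95 [= F987,F2176] (n=343)
#>     O2a1a-F789 [= F4181] (n=294)
#>     O2a1b-F1252 (n=45)
#>       O2a1b1-M88 (n=38)
#>         O2a1b1a-F761 [= F2346,F2758] (n=18)
#>   upstream of root: PK4
#>   excluded: F2411 (NOT_IN_LINEAGE), F1399 (NOT_IN_LINEAGE)

asg <- assignAll(fix, tree)
table(asg$haplogroup)
#>      not-M95    O2a1*-M95   O2a1a-F789 O2a1b*-F1252  O2a1b1*-M88 O2a1b1a-F761
#>          303            4          294            7           20           18

lineageFrequency(asg)
#>   stratum count denominator percent
#> 1 overall   343         646    53.1

branchFrequencies(asg, denominator = "lineage_only")
#>   stratum   haplogroup count denominator percent
#> 1 overall   O2a1a-F789   294         343   85.71
#> 2 overall  O2a1b1*-M88    20         343    5.83
#> 3 overall O2a1b1a-F761    18         343    5.25
#> 4 overall O2a1b*-F1252     7         343    2.04
#> 5 overall    O2a1*-M95     4         343    1.17

toNewick(tree)
#> [1] "(O2a1a-F789,((O2a1b1a-F761)O2a1b1-M88)O2a1b-F1252)O2a1-M95;"
```

Reading the output: 343 of 646 men (53.10%) carry the derived M95 allele
and fall into five sub-branches. F2176 and F987 are equivalent to M95
(derived in every lineage member); F789/F4181 define the dominant
sub-branch (85.71% of lineage members); F1252 sits above M88, splitting
the former M88 branch; F761/F2346/F2758 define the deepest clade. F2411
and F1399, ancestral in every assayed sample, are excluded from the
lineage. PK4 — indistinguishable from the root class here — is lifted
above M95 by the external constraint.

A shell wrapper with subcommands (`panel-validate`, `simulate`, `infer`,
`assign`, `freq`, `run`) is at
`system.file("scripts", "ylineage.R", package = "ylineage")`.

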