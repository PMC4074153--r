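Package: ylineage
Title: Haplogroup Phylogeny Inference from Binary Y-Chromosome SNP Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the rooted marker tree of a Y-chromosome haplogroup from a
    sample-by-marker matrix of binary SNP calls, using the parsimony rule for
    perfect phylogenies on rooted binary characters: markers with identical
    derived-sample sets are merged into equivalence classes, classes are
    ordered by strict containment of their derived sets, and markers that are
    never derived within the lineage, or that conflict with the
    nested-or-disjoint compatibility criterion, are set aside in an exclusion
    ledger. Assigns YCC-style hierarchical haplogroup names with paragroup (*)
    semantics, classifies each sample to its deepest consistent haplogroup
    with QC flags, and computes population- and region-stratified haplogroup
    frequency tables. Includes a simulator for hierarchically genotyped
    two-stage SNP panels and a deterministic reference dataset reproducing
    the published sub-branch structure of the O2a-M95 lineage in
    Austro-Asiatic-speaking populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
biocViews: Phylogenetics, Genetics, SNP, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'markerPanel.R'
    'genotypeMatrix.R'
    'pairRelation.R'
    'haplogroupTree.R'
    'nomenclature.R'
    'assignment.R'
    'simulate.R'
    'fixture.R'
    'frequencies.R'
    'pipeline.R'
    'ylineage-package.R'
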