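#' @include utils.R
NULL

#' Samples carrying the derived allele at a marker
#'
#' @param x a [YGenotypeMatrix].
#' @param marker marker name.
#' @return Character vector of sample identifiers.
#' @export
setGeneric("derivedSet", function(x, marker) standardGeneric("derivedSet"))

#' Samples with a non-missing call at a marker
#'
#' @param x a [YGenotypeMatrix].
#' @param marker marker name.
#' @return Character vector of sample identifiers.
#' @export
setGeneric("typedSet", function(x, marker) standardGeneric("typedSet"))

#' Classify the phylogenetic relation of a marker pair
#'
#' @param x a [YGenotypeMatrix].
#' @param a,b marker names.
#' @param ... further arguments passed to methods.
#' @return A [PairRelation-class] object.
#' @export
setGeneric("classifyPair", function(x, a, b, ...) standardGeneric("classifyPair"))

#' Build the rooted haplogroup tree by the parsimony rule
#'
#' @param x a [YGenotypeMatrix].
#' @param rootMarker marker defining the lineage root.
#' @param ... further arguments passed to methods.
#' @return A [HaplogroupTree-class].
#' @export
setGeneric("buildTree", function(x, rootMarker, ...) standardGeneric("buildTree"))

#' Assign every sample to its deepest consistent haplogroup
#'
#' @param x a [YGenotypeMatrix].
#' @param tree a labeled [HaplogroupTree-class].
#' @param ... further arguments passed to methods.
#' @return A data.frame with one row per sample.
#' @export
setGeneric("assignAll", function(x, tree, ...) standardGeneric("assignAll"))

#' Brute-force consistency check of a tree against a genotype matrix
#'
#' @param x a [YGenotypeMatrix].
#' @param tree a [HaplogroupTree-class] built from `x`.
#' @param ... further arguments passed to methods.
#' @return `TRUE` when no sample violates the tree, else `FALSE`.
#' @export
setGeneric("checkTreeConsistency",
           function(x, tree, ...) standardGeneric("checkTreeConsistency"))

#' Simulate a genotype matrix from a simulation specification
#'
#' @param spec a [SimSpec-class].
#' @param ... further arguments passed to methods.
#' @return A [YGenotypeMatrix].
#' @export
setGeneric("simulateMatrix", function(spec, ...) standardGeneric("simulateMatrix"))
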