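#' @include genotypeMatrix.R
NULL

#' PairRelation: phylogenetic relation of two binary markers
#'
#' For rooted binary characters with a known ancestral state, two markers
#' are compatible with a single tree iff their derived-sample sets are
#' nested or disjoint (the four-gamete condition with the all-ancestral
#' gamete fixed). The relation is computed on the jointly typed samples
#' only, so structured missingness from hierarchical genotyping never
#' biases the comparison.
#'
#' @slot markerA,markerB marker names.
#' @slot relation one of `EQUIVALENT`, `A_ABOVE_B`, `B_ABOVE_A`,
#'   `DISJOINT`, `INCOMPATIBLE`, `UNINFORMATIVE`.
#' @slot support named integer: counts of jointly typed samples in each
#'   derived/ancestral combination (`n11`, `n10`, `n01`, `n00`).
#' @slot nTyped number of jointly typed samples.
#' @slot lowSupport `TRUE` when `nTyped` fell below the requested minimum.
#' @export
setClass("PairRelation", representation(
  markerA = "character", markerB = "character",
  relation = "character", support = "integer",
  nTyped = "integer", lowSupport = "logical"))

setValidity("PairRelation", function(object) {
  if (sum(object@support) != object@nTyped)
    return("support counts must sum to the jointly typed sample count")
  if (!object@relation %in% c("EQUIVALENT", "A_ABOVE_B", "B_ABOVE_A",
                              "DISJOINT", "INCOMPATIBLE", "UNINFORMATIVE"))
    return("unknown relation")
  TRUE
})

#' @describeIn YGenotypeMatrix classify the relation of markers `a` and `b`
#'   from their derived sets on the jointly typed samples. `EQUIVALENT`:
#'   identical non-empty derived sets; `A_ABOVE_B` / `B_ABOVE_A`: strict
#'   nesting (`b` resp. `a` defines the subclade); `DISJOINT`: non-empty,
#'   non-overlapping; `INCOMPATIBLE`: overlapping but neither nested;
#'   `UNINFORMATIVE`: both derived sets empty. An empty jointly typed set is
#'   an error ("untestable pair").
#' @param a,b marker names.
#' @param nMin minimum jointly typed samples before the result is flagged
#'   `lowSupport`.
#' @export
setMethod("classifyPair", "YGenotypeMatrix", function(x, a, b, nMin = 1L) {
  .checkMarker(x, a); .checkMarker(x, b)
  joint <- intersect(typedSet(x, a), typedSet(x, b))
  if (!length(joint))
    stop(sprintf("untestable pair (%s, %s): no jointly typed samples", a, b))
  da <- intersect(derivedSet(x, a), joint)
  db <- intersect(derivedSet(x, b), joint)
  n11 <- length(intersect(da, db))
  n10 <- length(setdiff(da, db))
  n01 <- length(setdiff(db, da))
  n00 <- length(joint) - n11 - n10 - n01
  relation <-
    if (n11 + n10 + n01 == 0L) "UNINFORMATIVE"
    else if (n10 == 0L && n01 == 0L) "EQUIVALENT"
    else if (n01 == 0L && n11 > 0L) "A_ABOVE_B"
    else if (n10 == 0L && n11 > 0L) "B_ABOVE_A"
    else if (n11 == 0L) "DISJOINT"
    else "INCOMPATIBLE"
  # one derived set empty, the other not: the empty set nests strictly
  if (relation == "DISJOINT" && length(da) == 0L) relation <- "B_ABOVE_A"
  if (relation == "DISJOINT" && length(db) == 0L) relation <- "A_ABOVE_B"
  new("PairRelation", markerA = a, markerB = b, relation = relation,
      support = c(n11 = n11, n10 = n10, n01 = n01, n00 = n00),
      nTyped = length(joint), lowSupport = length(joint) < nMin)
})

#' PairRelation accessors
#'
#' @param x a [PairRelation-class].
#' @return `relation()` the relation string; `supportCounts()` the named
#'   four-combination counts.
#' @export
relation <- function(x) {
  stopifnot(is(x, "PairRelation"))
  x@relation
}

#' @rdname relation
#' @export
supportCounts <- function(x) {
  stopifnot(is(x, "PairRelation"))
  x@support
}

setMethod("show", "PairRelation", function(object) {
  cat(sprintf("PairRelation: %s %s %s\n", object@markerA, object@relation,
              object@markerB))
  s <- object@support
  cat(sprintf("  jointly typed: %d (DD %d, Da %d, aD %d, aa %d)%s\n",
              object@nTyped, s[["n11"]], s[["n10"]], s[["n01"]], s[["n00"]],
              if (object@lowSupport) "  [low support]" else ""))
})
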