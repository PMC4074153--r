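# Shared helpers: small matrix builders and independent oracles.

# Build a YGenotypeMatrix from a named list of per-marker call vectors.
toyMatrix <- function(markers, sampleIds = NULL, ...) {
  calls <- do.call(rbind, markers)
  rownames(calls) <- names(markers)
  colnames(calls) <- sampleIds %||%
    paste0("s", seq_len(ncol(calls)))
  YGenotypeMatrix(calls, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent flattening of a SimSpec's nested topology (kept separate
# from the package's own internals on purpose): returns per node the
# sorted marker class, the parent's class key, and the subtree sample
# count implied by branchCounts.
flattenSpecTree <- function(spec) {
  counts <- spec@branchCounts
  rows <- list()
  walk <- function(node, parentKey) {
    key <- paste(sort(node$markers), collapse = "|")
    kids <- node$children
    sub <- counts[[node$markers[[1]]]]
    for (ch in kids) sub <- sub + walk(ch, key)
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, parent = parentKey, subtreeCount = sub,
      terminal = counts[[node$markers[[1]]]])
    sub
  }
  walk(spec@tree, NA_character_)
  do.call(rbind, rows)
}

# Signature of a built HaplogroupTree in the same shape, for exact
# topology comparison.
treeSignature <- function(tree) {
  nd <- treeNodes(tree)
  key <- vapply(nd$markers, function(m) paste(sort(m), collapse = "|"),
                character(1))
  data.frame(key = key,
             parent = ifelse(is.na(nd$parent), NA, key[nd$parent]),
             subtreeCount = nd$count)
}

expect_same_topology <- function(tree, spec) {
  got <- treeSignature(tree)
  want <- flattenSpecTree(spec)
  got <- got[order(got$key), c("key", "parent", "subtreeCount")]
  want <- want[order(want$key), c("key", "parent", "subtreeCount")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

# Brute-force relation of two markers by explicit set logic over the
# jointly typed samples (enumerates the four genotype combinations
# directly from the call matrix).
bruteForceRelation <- function(x, a, b) {
  calls <- SummarizedExperiment::assay(x, "calls")
  va <- calls[a, ]; vb <- calls[b, ]
  joint <- colnames(x)[va != "." & vb != "."]
  da <- joint[va[joint] == "D"]
  db <- joint[vb[joint] == "D"]
  if (length(da) == 0 && length(db) == 0) return("UNINFORMATIVE")
  if (setequal(da, db)) return("EQUIVALENT")
  if (all(db %in% da)) return("A_ABOVE_B")
  if (all(da %in% db)) return("B_ABOVE_A")
  if (length(intersect(da, db)) == 0) return("DISJOINT")
  "INCOMPATIBLE"
}

# Reference tree and assignments on the packaged O2a-M95 dataset, built
# once per test run.
o2aReference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fix <- o2aFixture()
      tree <- assignLabels(
        buildTree(fix, "M95", constraints = o2aConstraints()), "O2a1")
      cache <<- list(fix = fix, tree = tree,
                     assignments = assignAll(fix, tree))
    }
    cache
  }
})
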