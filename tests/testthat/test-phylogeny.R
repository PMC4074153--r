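test_that("the reference matrix yields the published tree structure", {
  ref <- o2aReference()
  tree <- ref$tree
  nd <- treeNodes(tree)

  expect_equal(nrow(nd), 5L)
  expect_equal(sort(nd$markers[[1]]), c("F2176", "F987", "M95"))
  expect_equal(nd$representative[1], "M95")
  expect_equal(nd$count[1], 343L)

  kids <- nd[!is.na(nd$parent) & nd$parent == 1L, ]
  expect_equal(kids$representative, c("F789", "F1252"))  # canonical order
  expect_equal(kids$count, c(294L, 45L))
  expect_equal(sort(nd$markers[[which(nd$representative == "F789")]]),
               c("F4181", "F789"))
  expect_equal(sort(nd$markers[[which(nd$representative == "F761")]]),
               c("F2346", "F2758", "F761"))

  m88 <- which(nd$representative == "M88")
  expect_equal(nd$parent[m88], which(nd$representative == "F1252"))
  expect_equal(nd$count[m88], 38L)

  ex <- excludedMarkers(tree)
  expect_setequal(ex$marker, c("F2411", "F1399"))
  expect_true(all(ex$reason == "NOT_IN_LINEAGE"))

  expect_equal(upstreamMarkers(tree), "PK4")
  expect_match(constraintsApplied(tree)$action, "upstream")
})

test_that("without the external constraint PK4 joins the root class", {
  fix <- o2aFixture()
  tree <- buildTree(fix, "M95")
  expect_setequal(treeNodes(tree)$markers[[1]],
                  c("M95", "PK4", "F2176", "F987"))
  expect_length(upstreamMarkers(tree), 0L)
})

test_that("constraints contradicting the data are rejected", {
  fix <- o2aFixture()
  # the data show M95 strictly above F1252
  expect_error(
    buildTree(fix, "M95",
              constraints = data.frame(marker_a = "F1252",
                                       relation = "ABOVE",
                                       marker_b = "M95")),
    "contradicts")
  expect_error(
    buildTree(fix, "M95",
              constraints = data.frame(marker_a = "F1252",
                                       relation = "EQUIVALENT",
                                       marker_b = "M95")),
    "contradicts")
  # consistent constraints are recorded without structural change
  tree <- buildTree(fix, "M95",
                    constraints = data.frame(marker_a = "M95",
                                             relation = "ABOVE",
                                             marker_b = "F1252"))
  expect_match(constraintsApplied(tree)$action, "no change")
  expect_equal(nrow(treeNodes(tree)), 5L)
})

test_that("degenerate builds behave: empty root set, single marker", {
  fix <- o2aFixture()
  expect_error(buildTree(fix, "F2411"), "empty derived set")

  one <- toyMatrix(list(M95 = c("D", "D", "D")))
  tree <- buildTree(one, "M95")
  expect_equal(nrow(treeNodes(tree)), 1L)
  expect_equal(treeNodes(tree)$count, 3L)
})

test_that("incompatible markers are excluded with a report, or abort in strict mode", {
  x <- toyMatrix(list(R = rep("D", 4),
                      a = c("D", "D", "A", "A"),
                      b = c("A", "D", "D", "A"),
                      c = c("D", "A", "A", "A")))
  tree <- buildTree(x, "R")
  ex <- excludedMarkers(tree)
  expect_setequal(ex$marker[ex$reason == "INCOMPATIBLE"], c("a", "b"))
  # compatible markers are retained
  expect_setequal(unlist(treeNodes(tree)$markers), c("R", "c"))
  expect_error(buildTree(x, "R", strict = TRUE), "incompatible")
})

test_that("markers never derived in the lineage are excluded, not attached", {
  # 'z' is derived only outside the root-derived restriction
  x <- toyMatrix(list(R = c("D", "D", "A"),
                      z = c("A", "A", "D")))
  tree <- buildTree(x, "R")
  ex <- excludedMarkers(tree)
  expect_equal(ex$marker, "z")
  expect_equal(ex$reason, "NOT_IN_LINEAGE")
  expect_false("z" %in% unlist(treeNodes(tree)$markers))
})

test_that("simulate-and-recover is exact for random topologies", {
  for (s in 1:100) {
    spec <- randomSimSpec(s)
    x <- simulateMatrix(spec)
    tree <- buildTree(x, spec@tree$markers[[1]])
    expect_same_topology(tree, spec)
    expect_true(checkTreeConsistency(x, tree))
    expect_true(validObject(tree))  # strict parent/sibling invariants
  }
})

test_that("recovery below the root survives hierarchical missingness", {
  for (s in 1:20) {
    spec <- randomSimSpec(s, hierarchicalMissingness = TRUE,
                          outOfLineageCount = 7L)
    x <- simulateMatrix(spec)
    tree <- buildTree(x, spec@tree$markers[[1]])
    expect_same_topology(tree, spec)
  }
})

test_that("the brute-force oracle rejects a mis-parented tree", {
  ref <- o2aReference()
  expect_true(checkTreeConsistency(ref$fix, ref$tree))

  broken <- ref$tree
  nd <- broken@nodes
  i1252 <- which(nd$representative == "F1252")
  i789 <- which(nd$representative == "F789")
  nd$parent[i1252] <- i789  # bypasses validity on purpose
  broken@nodes <- nd
  expect_false(checkTreeConsistency(ref$fix, broken))

  # vacuously true on an empty sample set
  expect_true(checkTreeConsistency(ref$fix[, character(0)], ref$tree))
})
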