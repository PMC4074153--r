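test_that("single-sample call profiles assign as published", {
  tree <- o2aReference()$tree
  allA <- setNames(rep("A", 11L),
                   c("M95", "PK4", "F2176", "F987", "F789", "F4181",
                     "F1252", "M88", "F761", "F2346", "F2758"))

  calls <- allA
  calls[c("M95", "F2176", "F987", "PK4", "F789", "F4181")] <- "D"
  a <- assignSample(calls, tree)
  expect_equal(a$haplogroup, "O2a1a-F789")
  expect_equal(a$path, c("O2a1", "O2a1a"))
  expect_length(a$qc_flags, 0L)

  calls <- allA
  calls[c("M95", "F1252", "M88")] <- "D"
  a <- assignSample(calls, tree)
  expect_equal(a$haplogroup, "O2a1b1*-M88")  # assayed children all ancestral
  expect_length(a$qc_flags, 0L)

  # root-ancestral men fall outside the lineage
  a <- assignSample(c(M95 = "A", F789 = ".", F1252 = "."), tree)
  expect_equal(a$haplogroup, "not-M95")
  expect_false(a$in_lineage)

  # root paragroup: derived at the root class, ancestral at both children
  calls <- allA
  calls[c("M95", "F2176", "F987")] <- "D"
  expect_equal(assignSample(calls, tree)$haplogroup, "O2a1*-M95")
})

test_that("untyped children demote the paragroup claim to UNRESOLVED", {
  tree <- o2aReference()$tree
  a <- assignSample(c(M95 = "D", F789 = "A", F4181 = "A", F1252 = "."),
                    tree)
  expect_equal(a$haplogroup, "O2a1-M95")  # plain label, no star
  expect_equal(a$qc_flags, "UNRESOLVED")
})

test_that("calls violating the tree are flagged INCONSISTENT_CALL", {
  tree <- o2aReference()$tree

  # derived below an ancestral ancestor
  a <- assignSample(c(M95 = "D", M88 = "A", F761 = "D"), tree)
  expect_true("INCONSISTENT_CALL" %in% a$qc_flags)
  expect_equal(a$haplogroup, "O2a1-M95")  # deepest consistent node

  # two disjoint sub-branches simultaneously derived
  a <- assignSample(c(M95 = "D", F789 = "D", F1252 = "D", F4181 = "D",
                      M88 = "A", F761 = "A", F2346 = "A", F2758 = "A",
                      F2176 = "D", F987 = "D"), tree)
  expect_true("INCONSISTENT_CALL" %in% a$qc_flags)
})

test_that("assignment input is validated", {
  tree <- o2aReference()$tree
  expect_error(assignSample(c(M95 = "D", XYZ = "A"), tree),
               "absent from the tree")
  expect_error(assignSample(c(F789 = "D"), tree),
               "do not cover the root")
  # excluded and upstream markers are ignored, not errors
  a <- assignSample(c(M95 = "D", F2411 = "A", F1399 = "A", PK4 = "D",
                      F789 = "A", F4181 = "A", F1252 = "A"), tree)
  expect_equal(a$haplogroup, "O2a1*-M95")
})

test_that("assignAll reproduces the published per-branch counts", {
  ref <- o2aReference()
  asg <- ref$assignments
  expect_equal(nrow(asg), 646L)
  expect_equal(sum(asg$in_lineage), 343L)
  expect_true(all(asg$qc_flags == ""))

  counts <- table(asg$haplogroup)
  expect_equal(counts[["O2a1*-M95"]], 4L)
  expect_equal(counts[["O2a1a-F789"]], 294L)
  expect_equal(counts[["O2a1b*-F1252"]], 7L)
  expect_equal(counts[["O2a1b1*-M88"]], 20L)
  expect_equal(counts[["O2a1b1a-F761"]], 18L)
  expect_equal(counts[["not-M95"]], 303L)

  # the five sub-branches partition the lineage members
  expect_equal(4L + 294L + 7L + 20L + 18L, 343L)
})

test_that("paragroup arithmetic holds on clean matrices", {
  specs <- c(list(NULL), lapply(1:10, randomSimSpec))
  for (spec in specs) {
    if (is.null(spec)) {
      ref <- o2aReference()
      x <- ref$fix; tree <- ref$tree; asg <- ref$assignments
    } else {
      x <- simulateMatrix(spec)
      tree <- assignLabels(buildTree(x, spec@tree$markers[[1]]), "H1")
      asg <- assignAll(x, tree)
    }
    nd <- treeNodes(tree)
    counts <- table(asg$haplogroup)
    getn <- function(h) if (h %in% names(counts)) counts[[h]] else 0L
    for (i in nd$node) {
      kids <- nd$node[!is.na(nd$parent) & nd$parent == i]
      if (length(kids)) {
        para <- nd$count[i] - sum(nd$count[kids])
        expect_equal(getn(paragroupLabel(tree, i)), para)
      } else {
        expect_equal(getn(paragroupLabel(tree, i)), nd$count[i])
      }
    }
  }
})

test_that("injected call errors are flagged in exact agreement with brute force", {
  # a branching topology, so derived calls can land on disjoint clades
  topo <- list(markers = "R", children = list(
    list(markers = c("a1", "a2"), children = list(
      list(markers = "d", children = list()))),
    list(markers = "c", children = list())))
  counts <- c(R = 30L, a1 = 30L, d = 20L, c = 30L)
  spec <- SimSpec(topo, counts, errorRate = 0.02, seed = 42L)
  x <- simulateMatrix(spec)
  tree <- assignLabels(buildTree(simulateMatrix(
    SimSpec(topo, counts, seed = 99L)), "R"), "H1")
  asg <- assignAll(x, tree)
  expect_gte(sum(grepl("INCONSISTENT_CALL", asg$qc_flags)), 1L)

  # independent per-sample check from the generating topology
  flat <- local({
    rows <- list()
    walk <- function(node, path) {
      path <- c(path, list(node$markers))
      rows[[length(rows) + 1L]] <<- path
      for (ch in node$children) walk(ch, path)
    }
    walk(spec@tree, list())
    rows
  })
  calls <- SummarizedExperiment::assay(x, "calls")
  nodeMarkers <- lapply(flat, function(p) p[[length(p)]])
  isAnc <- function(i, j) {  # is node i an ancestor of node j?
    length(flat[[i]]) < length(flat[[j]]) &&
      identical(flat[[j]][seq_along(flat[[i]])], flat[[i]])
  }
  inconsistent <- vapply(seq_len(ncol(calls)), function(s) {
    st <- vapply(nodeMarkers, function(ms) {
      v <- calls[ms, s]
      if (any(v == "D")) "D" else if (any(v == "A")) "A" else "M"
    }, character(1))
    if (st[1] != "D") return(FALSE)  # out of lineage or unscreened
    dn <- which(st == "D")
    for (i in dn) {
      up <- which(vapply(seq_along(st), isAnc, logical(1), j = i))
      if (any(st[up] == "A")) return(TRUE)
    }
    if (length(dn) > 1L)
      for (i in dn) for (j in dn)
        if (i < j && !isAnc(i, j) && !isAnc(j, i)) return(TRUE)
    FALSE
  }, logical(1))
  expect_equal(grepl("INCONSISTENT_CALL", asg$qc_flags), inconsistent)
})

test_that("assigning an empty matrix yields an empty table", {
  ref <- o2aReference()
  asg <- assignAll(ref$fix[, character(0)], ref$tree)
  expect_equal(nrow(asg), 0L)
})
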