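test_that("simulation is reproducible from its single seed", {
  spec <- randomSimSpec(3L, errorRate = 0.05, outOfLineageCount = 5L,
                        hierarchicalMissingness = TRUE)
  a <- simulateMatrix(spec)
  b <- simulateMatrix(spec)
  expect_equal(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_equal(S4Vectors::metadata(a)$flips, S4Vectors::metadata(b)$flips)

  spec2 <- randomSimSpec(3L, errorRate = 0.05, outOfLineageCount = 5L,
                         hierarchicalMissingness = TRUE)
  spec2@seed <- 4L
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(simulateMatrix(spec2))))
})

test_that("the recorded flip list is exactly the set of corrupted cells", {
  tree <- list(markers = "R",
               children = list(list(markers = c("a", "b"), children = list()),
                               list(markers = "c", children = list())))
  clean <- SimSpec(tree, c(R = 30L, a = 30L, c = 30L), errorRate = 0,
                   seed = 11L)
  noisy <- SimSpec(tree, c(R = 30L, a = 30L, c = 30L), errorRate = 0.05,
                   seed = 11L)
  x0 <- SummarizedExperiment::assay(simulateMatrix(clean))
  x1 <- simulateMatrix(noisy)
  flips <- S4Vectors::metadata(x1)$flips
  diff <- which(SummarizedExperiment::assay(x1) != x0, arr.ind = TRUE)
  got <- data.frame(sample = colnames(x0)[diff[, "col"]],
                    marker = rownames(x0)[diff[, "row"]])
  o <- order(got$sample, got$marker)
  of <- order(flips$sample, flips$marker)
  expect_equal(got[o, ], flips[of, ], ignore_attr = TRUE)

  # flip volume is near errorRate x typed cells (binomial 4-sigma band)
  nCells <- sum(x0 != ".")
  expect_lt(abs(nrow(flips) - 0.05 * nCells), 4 * sqrt(nCells * 0.05 * 0.95))
})

test_that("two-stage missingness masks only out-of-lineage samples", {
  tree <- list(markers = c("M", "eq"), children = list(
    list(markers = "k", children = list())))
  spec <- SimSpec(tree, c(M = 4L, k = 3L), outOfLineageCount = 5L,
                  hierarchicalMissingness = TRUE, seed = 2L)
  x <- simulateMatrix(spec)
  expect_equal(dim(x), c(3L, 12L))
  calls <- SummarizedExperiment::assay(x)
  out <- colnames(x)[calls["M", ] == "A"]
  expect_length(out, 5L)
  expect_true(all(calls[c("eq", "k"), out] == "."))
  lin <- setdiff(colnames(x), out)
  expect_true(all(calls[, lin] != "."))
  expect_equal(sum(calls["k", lin] == "D"), 3L)
})

test_that("a SimSpec round-trips through its YAML config", {
  yml <- file.path(tempdir(), "simspec.yaml")
  writeLines(c(
    "tree:",
    "  markers: [M95, F2176]",
    "  children:",
    "    - markers: [F789]",
    "      children: []",
    "branch_counts: {M95: 2, F789: 5}",
    "out_of_lineage_count: 3",
    "outgroup_markers: [F1399]",
    "hierarchical_missingness: true",
    "error_rate: 0.0",
    "seed: 7"), yml)
  spec <- readSimSpec(yml)
  x <- simulateMatrix(spec)
  expect_equal(dim(x), c(4L, 10L))
  expect_equal(length(derivedSet(x, "M95")), 7L)
  expect_equal(length(derivedSet(x, "F789")), 5L)
  expect_equal(length(derivedSet(x, "F1399")), 0L)
  tr <- buildTree(x, "M95")
  expect_equal(treeNodes(tr)$representative, c("M95", "F789"))
  expect_equal(excludedMarkers(tr)$marker, "F1399")
})

test_that("nonsense specifications are refused", {
  tree <- list(markers = "R", children = list())
  expect_error(SimSpec(tree, c(R = -1L)), "counts")
  expect_error(SimSpec(tree, c(R = 0L)), "zero samples")
  expect_error(SimSpec(tree, c(R = 1L), errorRate = 1), "errorRate")
  expect_error(SimSpec(tree, c(Q = 1L)), "representatives")
})

test_that("the reference dataset is deterministic and matches its design", {
  a <- o2aFixture()
  b <- o2aFixture()
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_equal(dim(a), c(13L, 646L))

  sizes <- vapply(rownames(a), function(m) length(derivedSet(a, m)),
                  integer(1))
  expect_equal(unname(sizes[c("M95", "PK4", "F2176", "F987")]),
               rep(343L, 4))
  expect_equal(unname(sizes[c("F789", "F4181")]), rep(294L, 2))
  expect_equal(unname(sizes["F1252"]), 45L)        # 7 + 20 + 18
  expect_equal(unname(sizes["M88"]), 38L)          # 20 + 18
  expect_equal(unname(sizes[c("F761", "F2346", "F2758")]), rep(18L, 3))
  expect_equal(unname(sizes[c("F2411", "F1399")]), c(0L, 0L))

  cd <- as.data.frame(SummarizedExperiment::colData(a))
  expect_equal(as.vector(table(cd$region)[c("Cambodia", "Thailand", "Yunnan")]),
               c(376L, 182L, 88L))
  expect_setequal(unique(cd$language_family),
                  c("Austro-Asiatic", "Austronesian", "Daic"))
})
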