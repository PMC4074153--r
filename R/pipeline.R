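#' @include frequencies.R fixture.R
NULL

#' Read a tree-constraint table from TSV
#'
#' Columns `marker_a`, `relation` (`ABOVE` or `EQUIVALENT`), `marker_b`.
#'
#' @param path TSV file path.
#' @return data.frame suitable for the `constraints` argument of
#'   [buildTree()].
#' @export
readConstraints <- function(path) {
  if (!file.exists(path)) stop("constraints file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("marker_a", "relation", "marker_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("constraints file lacks columns: ", paste(miss, collapse = ", "))
  df[, need]
}

#' Run the full haplogroup pipeline
#'
#' Wires the stages end to end: read and validate the panel, read the
#' genotype matrix, infer the tree by the parsimony rule, label it, assign
#' every sample, and tabulate frequencies. Writes into `outDir`:
#' `tree.nwk`, `tree.json`, `assignments.tsv`, `frequencies_overall.tsv`,
#' `frequencies_by_region.tsv`, `frequencies_by_population.tsv`,
#' `lineage_share.tsv` and a `run.log` recording exclusions, applied
#' constraints and QC-flag totals. Output is deterministic for identical
#' inputs and configuration (fixed orderings, two-decimal percentages).
#'
#' @param panelPath path to the panel TSV (see [readPanel()]).
#' @param matrixPath path to the genotype TSV (see [readGenotypeMatrix()]).
#' @param rootMarker marker defining the lineage root (must be in the
#'   panel).
#' @param rootLabel YCC label of the root, e.g. `"O2a1"`.
#' @param constraintsPath optional constraints TSV (see
#'   [readConstraints()]).
#' @param ordering child-ordering policy for [assignLabels()].
#' @param denominator denominator mode for [branchFrequencies()].
#' @param outDir output directory, created if absent.
#' @param strict abort on incompatible markers (see [buildTree()]).
#' @param encoding call encoding of the matrix file.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `tree`, `assignments`, `frequencies`
#'   (list by stratum), `lineage` and `files`.
#' @export
runPipeline <- function(panelPath, matrixPath, rootMarker, rootLabel,
                        constraintsPath = NULL,
                        ordering = c("count", "name"),
                        denominator = c("all", "lineage_only"),
                        outDir = ".", strict = FALSE,
                        encoding = c("AD", "bases"), quiet = FALSE) {
  ordering <- match.arg(ordering)
  denominator <- match.arg(denominator)
  encoding <- match.arg(encoding)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }

  panel <- readPanel(panelPath)
  say("panel: %d markers read from %s", length(markerNames(panel)),
      panelPath)
  if (!rootMarker %in% markerNames(panel))
    stop("root marker ", rootMarker, " is not in the panel")

  x <- readGenotypeMatrix(matrixPath, panel = panel, encoding = encoding)
  say("matrix: %d markers x %d samples from %s", nrow(x), ncol(x),
      matrixPath)
  unknown <- setdiff(rownames(x), markerNames(panel))
  if (length(unknown))
    stop("matrix markers missing from the panel: ",
         paste(unknown, collapse = ", "))

  constraints <- NULL
  if (!is.null(constraintsPath)) {
    constraints <- readConstraints(constraintsPath)
    say("constraints: %d read from %s", nrow(constraints), constraintsPath)
  }

  tree <- buildTree(x, rootMarker, constraints = constraints,
                    strict = strict)
  tree <- assignLabels(tree, rootLabel, ordering = ordering)
  nd <- treeNodes(tree)
  say("tree: %d nodes; root %s with %d lineage samples",
      nrow(nd), paragroupLabel(tree, 1L), nd$count[1])
  ex <- excludedMarkers(tree)
  for (i in seq_len(nrow(ex)))
    say("excluded: %s (%s)", ex$marker[i], ex$reason[i])
  ca <- constraintsApplied(tree)
  for (i in seq_len(nrow(ca)))
    say("constraint %s %s %s: %s", ca$marker_a[i], ca$relation[i],
        ca$marker_b[i], ca$action[i])

  assignments <- assignAll(x, tree)
  flagged <- assignments$qc_flags != ""
  say("assignments: %d samples, %d in lineage, %d QC-flagged",
      nrow(assignments), sum(assignments$in_lineage), sum(flagged))
  if (any(flagged)) {
    tab <- table(unlist(strsplit(assignments$qc_flags[flagged], ";")))
    for (f in names(tab)) say("  flag %s: %d", f, tab[[f]])
  }

  freqs <- list(
    overall = branchFrequencies(assignments, "none", denominator),
    by_region = if ("region" %in% names(assignments))
      branchFrequencies(assignments, "region", denominator) else NULL,
    by_population = if ("population" %in% names(assignments))
      branchFrequencies(assignments, "population", denominator) else NULL)
  lineage <- lineageFrequency(assignments, "none")
  say("lineage share: %d/%d (%.2f%%)", lineage$count,
      lineage$denominator, lineage$percent)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    tree_newick = writeNewick(tree, file.path(outDir, "tree.nwk")),
    tree_json = writeTreeJSON(tree, file.path(outDir, "tree.json")),
    assignments = writeAssignments(assignments,
                                   file.path(outDir, "assignments.tsv")),
    frequencies_overall = writeFrequencies(
      freqs$overall, file.path(outDir, "frequencies_overall.tsv")),
    lineage_share = writeFrequencies(
      lineage, file.path(outDir, "lineage_share.tsv")))
  if (!is.null(freqs$by_region))
    files["frequencies_by_region"] <- writeFrequencies(
      freqs$by_region, file.path(outDir, "frequencies_by_region.tsv"))
  if (!is.null(freqs$by_population))
    files["frequencies_by_population"] <- writeFrequencies(
      freqs$by_population, file.path(outDir, "frequencies_by_population.tsv"))
  logPath <- file.path(outDir, "run.log")
  writeLines(log, logPath)
  files["log"] <- logPath

  invisible(list(tree = tree, assignments = assignments,
                 frequencies = freqs, lineage = lineage, files = files))
}
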