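#' @include genotypeMatrix.R
NULL

#' SimSpec: specification for simulating a hierarchically typed SNP matrix
#'
#' Describes the generating tree (nested list of nodes, each with a
#' `markers` character vector and a `children` list), how many samples
#' terminate at each node (its paragroup count; keyed by the node's first
#' marker), how many samples fall outside the lineage, and the assay
#' structure: under `hierarchicalMissingness` only the screening marker
#' (the root node's first marker) is typed in out-of-lineage samples,
#' mirroring a two-stage design where the downstream panel is run only in
#' screen-positive men. `outgroupMarkers` are typed alongside the panel but
#' ancestral in every lineage sample (markers that turn out not to belong
#' to the lineage). `errorRate` flips each non-missing call independently;
#' all randomness (population sampling, sample shuffling, error injection)
#' flows from the single `seed`.
#'
#' @slot tree nested list topology.
#' @slot branchCounts named integer, samples terminating per node.
#' @slot outOfLineageCount integer.
#' @slot outgroupMarkers character.
#' @slot populations data.frame (`population`, `region`,
#'   `language_family`, `weight`) or zero rows for a single default
#'   population.
#' @slot hierarchicalMissingness logical.
#' @slot errorRate numeric in `[0, 1)`.
#' @slot seed integer.
#' @slot regionLevels character vocabulary for regions.
#' @seealso [simulateMatrix()], [randomSimSpec()], [readSimSpec()]
#' @export
setClass("SimSpec", representation(
  tree = "list", branchCounts = "integer", outOfLineageCount = "integer",
  outgroupMarkers = "character", populations = "data.frame",
  hierarchicalMissingness = "logical", errorRate = "numeric",
  seed = "integer", regionLevels = "character"))

.flattenTopology <- function(tree) {
  markers <- list(); parent <- integer(0); paths <- list()
  visit <- function(node, par, path) {
    stopifnot(is.list(node), length(node$markers) >= 1L)
    i <- length(markers) + 1L
    markers[[i]] <<- as.character(node$markers)
    parent[i] <<- par
    paths[[i]] <<- c(path, as.character(node$markers))
    for (ch in node$children %||% list()) visit(ch, i, paths[[i]])
  }
  visit(tree, NA_integer_, character(0))
  rep <- vapply(markers, `[`, character(1), 1L)
  list(markers = markers, parent = parent, rep = rep, paths = paths)
}

setValidity("SimSpec", function(object) {
  msg <- character(0)
  flat <- tryCatch(.flattenTopology(object@tree),
                   error = function(e) NULL)
  if (is.null(flat)) return("invalid tree topology")
  allm <- unlist(flat$markers)
  if (anyDuplicated(c(allm, object@outgroupMarkers)))
    msg <- c(msg, "duplicate markers across nodes/outgroup")
  if (any(object@branchCounts < 0L) || object@outOfLineageCount < 0L)
    msg <- c(msg, "all counts must be >= 0")
  if (!all(names(object@branchCounts) %in% flat$rep))
    msg <- c(msg, "branchCounts keys must be node representatives")
  if (sum(object@branchCounts) + object@outOfLineageCount < 1L)
    msg <- c(msg, "spec describes zero samples")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SimSpec
#'
#' @param tree nested list: `list(markers = c(...), children = list(...))`.
#' @param branchCounts named vector of samples terminating per node,
#'   keyed by each node's first marker; nodes without an entry get 0.
#' @param outOfLineageCount samples ancestral at the root.
#' @param outgroupMarkers markers typed but ancestral throughout the
#'   lineage.
#' @param populations optional data.frame `population`, `region`,
#'   `language_family`, `weight`.
#' @param hierarchicalMissingness mask all but the screening marker in
#'   out-of-lineage samples.
#' @param errorRate per-call flip probability.
#' @param seed integer seed driving all randomness.
#' @param regionLevels region vocabulary.
#' @return A [SimSpec-class].
#' @export
SimSpec <- function(tree, branchCounts, outOfLineageCount = 0L,
                    outgroupMarkers = character(0), populations = NULL,
                    hierarchicalMissingness = TRUE, errorRate = 0,
                    seed = 1L, regionLevels = .DEFAULT_REGIONS) {
  bc <- as.integer(branchCounts)
  names(bc) <- names(branchCounts)
  if (is.null(populations))
    populations <- data.frame(population = character(0),
                              region = character(0),
                              language_family = character(0),
                              weight = numeric(0))
  new("SimSpec", tree = tree, branchCounts = bc,
      outOfLineageCount = as.integer(outOfLineageCount),
      outgroupMarkers = as.character(outgroupMarkers),
      populations = as.data.frame(populations),
      hierarchicalMissingness = isTRUE(hierarchicalMissingness),
      errorRate = as.numeric(errorRate), seed = as.integer(seed),
      regionLevels = regionLevels)
}

#' Read a SimSpec from YAML
#'
#' Expected keys: `tree` (nested `markers`/`children`), `branch_counts`
#' (map node-representative to count), and optionally
#' `out_of_lineage_count`, `outgroup_markers`, `populations` (list of
#' records with `population`, `region`, `language_family`, `weight`),
#' `hierarchical_missingness`, `error_rate`, `seed`.
#'
#' @param path YAML file path.
#' @return A [SimSpec-class].
#' @export
readSimSpec <- function(path) {
  if (!file.exists(path)) stop("simspec file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$tree) || is.null(y$branch_counts))
    stop("simspec needs 'tree' and 'branch_counts'")
  pops <- if (length(y$populations))
    do.call(rbind, lapply(y$populations, as.data.frame)) else NULL
  SimSpec(tree = y$tree,
          branchCounts = unlist(y$branch_counts),
          outOfLineageCount = y$out_of_lineage_count %||% 0L,
          outgroupMarkers = unlist(y$outgroup_markers) %||% character(0),
          populations = pops,
          hierarchicalMissingness = y$hierarchical_missingness %||% TRUE,
          errorRate = y$error_rate %||% 0,
          seed = y$seed %||% 1L)
}

#' @describeIn SimSpec simulate a genotype matrix: each lineage sample is
#'   derived at every marker on its root-to-node path and ancestral at all
#'   other lineage and outgroup markers; out-of-lineage samples are
#'   ancestral at the screening marker and missing (or ancestral, without
#'   hierarchical missingness) elsewhere. Sample order is shuffled and
#'   calls are flipped at `errorRate`, both reproducibly from the seed;
#'   the flip list is stored in `metadata(x)$flips`.
#' @param spec a `SimSpec`.
#' @export
setMethod("simulateMatrix", "SimSpec", function(spec) {
  flat <- .flattenTopology(spec@tree)
  lineageMarkers <- unlist(flat$markers)
  allMarkers <- c(lineageMarkers, spec@outgroupMarkers)
  screen <- flat$rep[1]

  counts <- structure(integer(length(flat$rep)), names = flat$rep)
  counts[names(spec@branchCounts)] <- spec@branchCounts
  nLin <- sum(counts)
  n <- nLin + spec@outOfLineageCount
  node <- rep(c(seq_along(counts), 0L),
              c(counts, spec@outOfLineageCount))

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(spec@seed)

  node <- node[sample.int(n)]
  calls <- matrix("A", nrow = length(allMarkers), ncol = n,
                  dimnames = list(allMarkers,
                                  sprintf("S%04d", seq_len(n))))
  for (s in seq_len(n)) {
    if (node[s] == 0L) {
      calls[, s] <- if (spec@hierarchicalMissingness) "." else "A"
      calls[screen, s] <- "A"
    } else {
      calls[flat$paths[[node[s]]], s] <- "D"
    }
  }

  if (nrow(spec@populations)) {
    pops <- spec@populations
    idx <- sample.int(nrow(pops), n, replace = TRUE,
                      prob = pops$weight / sum(pops$weight))
    meta <- pops[idx, c("population", "region", "language_family"),
                 drop = FALSE]
    rownames(meta) <- NULL
    regions <- unique(c(spec@regionLevels, pops$region))
  } else {
    meta <- data.frame(population = rep("P1", n),
                       region = spec@regionLevels[1],
                       language_family = "Austro-Asiatic")
    regions <- spec@regionLevels
  }

  flips <- data.frame(sample = character(0), marker = character(0))
  if (spec@errorRate > 0) {
    typed <- which(calls != ".")
    hit <- typed[stats::runif(length(typed)) < spec@errorRate]
    if (length(hit)) {
      calls[hit] <- ifelse(calls[hit] == "A", "D", "A")
      ij <- arrayInd(hit, dim(calls))
      flips <- data.frame(sample = colnames(calls)[ij[, 2]],
                          marker = rownames(calls)[ij[, 1]])
    }
  }

  out <- YGenotypeMatrix(calls, sampleData = meta, regionLevels = regions)
  S4Vectors::metadata(out)$flips <- flips
  S4Vectors::metadata(out)$trueNode <- node
  out
})

#' Draw a random simulation specification
#'
#' Utility for property-style checks: a random topology of up to
#' `maxNodes` nodes (each new node attaches to a uniformly chosen earlier
#' node), 1-3 markers per node, and at least one sample terminating at
#' every node so each equivalence class is observable.
#'
#' @param seed integer seed.
#' @param maxNodes maximum nodes (at least 2 are drawn).
#' @param maxCount maximum samples terminating per node.
#' @param errorRate,hierarchicalMissingness,outOfLineageCount passed to
#'   [SimSpec()].
#' @return A [SimSpec-class].
#' @export
randomSimSpec <- function(seed, maxNodes = 8L, maxCount = 5L,
                          errorRate = 0, hierarchicalMissingness = FALSE,
                          outOfLineageCount = 0L) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  nNodes <- sample(2:maxNodes, 1L)
  parent <- c(NA_integer_,
              vapply(2:nNodes, function(i) sample.int(i - 1L, 1L), 1L))
  k <- 0L
  markers <- lapply(seq_len(nNodes), function(i) {
    m <- sample(1:3, 1L)
    out <- sprintf("X%d", k + seq_len(m))
    k <<- k + m
    out
  })
  build <- function(i) {
    kids <- which(!is.na(parent) & parent == i)
    list(markers = markers[[i]], children = lapply(kids, build))
  }
  reps <- vapply(markers, `[`, character(1), 1L)
  counts <- structure(sample.int(maxCount, nNodes, replace = TRUE),
                      names = reps)
  SimSpec(tree = build(1L), branchCounts = counts,
          outOfLineageCount = outOfLineageCount,
          hierarchicalMissingness = hierarchicalMissingness,
          errorRate = errorRate, seed = seed)
}

setMethod("show", "SimSpec", function(object) {
  flat <- .flattenTopology(object@tree)
  cat(sprintf(
    "SimSpec: %d nodes, %d markers, %d lineage + %d out-of-lineage samples\n",
    length(flat$rep), length(unlist(flat$markers)) +
      length(object@outgroupMarkers),
    sum(object@branchCounts), object@outOfLineageCount))
  cat(sprintf("  errorRate = %g, hierarchicalMissingness = %s, seed = %d\n",
              object@errorRate, object@hierarchicalMissingness, object@seed))
})
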