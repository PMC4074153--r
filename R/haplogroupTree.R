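#' @include pairRelation.R
NULL

#' HaplogroupTree: rooted tree of marker equivalence classes
#'
#' Nodes are equivalence classes of markers with identical derived-sample
#' sets; edges follow strict containment of those sets (the Hasse diagram of
#' the containment partial order restricted to lineage members). Markers
#' that are never derived among root-derived samples sit in the exclusion
#' ledger as `NOT_IN_LINEAGE`; markers violating the nested-or-disjoint
#' compatibility criterion as `INCOMPATIBLE`. Markers lifted above the root
#' by an external constraint (placements known from samples outside the
#' current data set) are recorded in `upstream`.
#'
#' @slot nodes data.frame: `node` (preorder id), `parent` (`NA` for the
#'   root), `representative`, `count` (derived samples), `depth`, `label`
#'   (YCC label, `NA` until [assignLabels()] is run).
#' @slot markers list of character vectors: the equivalence class of each
#'   node, parallel to `nodes`.
#' @slot sets list of character vectors: derived sample ids per node.
#' @slot rootMarker the marker the build was rooted on.
#' @slot excluded data.frame `marker`, `reason`.
#' @slot upstream markers placed above the root by constraint.
#' @slot constraintsApplied data.frame `marker_a`, `relation`, `marker_b`,
#'   `action`.
#' @slot nSamples total samples in the matrix the tree was built from.
#' @seealso [buildTree()], [assignLabels()], [toNewick()]
#' @export
setClass("HaplogroupTree", representation(
  nodes = "data.frame", markers = "list", sets = "list",
  rootMarker = "character", excluded = "data.frame",
  upstream = "character", constraintsApplied = "data.frame",
  nSamples = "integer"))

setValidity("HaplogroupTree", function(object) {
  nd <- object@nodes
  msg <- character(0)
  if (nrow(nd) == 0L) return("tree must have at least a root node")
  if (sum(is.na(nd$parent)) != 1L)
    return("exactly one root (parent NA) required")
  if (length(object@markers) != nrow(nd) || length(object@sets) != nrow(nd))
    return("markers/sets must be parallel to nodes")
  if (any(lengths(object@markers) == 0L))
    msg <- c(msg, "every node needs a non-empty equivalence class")
  all <- c(unlist(object@markers), object@excluded$marker, object@upstream)
  if (anyDuplicated(all))
    msg <- c(msg, sprintf(
      "marker(s) in more than one node/ledger: %s",
      paste(unique(all[duplicated(all)]), collapse = ", ")))
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    if (is.na(p)) next
    if (!all(object@sets[[i]] %in% object@sets[[p]]) ||
        nd$count[i] >= nd$count[p])
      msg <- c(msg, sprintf(
        "node %s: derived set not a strict subset of its parent's",
        nd$representative[i]))
  }
  for (p in nd$node) {
    kids <- nd$node[!is.na(nd$parent) & nd$parent == p]
    if (length(kids) > 1L)
      for (i in seq_along(kids)[-1]) for (j in seq_len(i - 1L))
        if (length(intersect(object@sets[[kids[i]]],
                             object@sets[[kids[j]]])))
          msg <- c(msg, sprintf("siblings %s and %s overlap",
                                nd$representative[kids[i]],
                                nd$representative[kids[j]]))
  }
  if (length(msg)) unique(msg) else TRUE
})

.children <- function(tree, node) {
  nd <- tree@nodes
  nd$node[!is.na(nd$parent) & nd$parent == node]
}

.rootNode <- function(tree) tree@nodes$node[is.na(tree@nodes$parent)]

.ancestors <- function(tree, node) {
  out <- integer(0)
  p <- tree@nodes$parent[node]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree@nodes$parent[p]
  }
  out
}

#' @describeIn HaplogroupTree node table (`node`, `parent`,
#'   `representative`, `count`, `depth`, `label`) plus a `markers` list
#'   column with each node's equivalence class.
#' @param tree a `HaplogroupTree`.
#' @export
treeNodes <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  nd <- tree@nodes
  nd$markers <- I(tree@markers)
  nd
}

#' @describeIn HaplogroupTree exclusion ledger: data.frame `marker`,
#'   `reason` (`NOT_IN_LINEAGE` or `INCOMPATIBLE`).
#' @export
excludedMarkers <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  tree@excluded
}

#' @describeIn HaplogroupTree markers placed above the root by constraint.
#' @export
upstreamMarkers <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  tree@upstream
}

#' @describeIn HaplogroupTree record of user constraints and their effect.
#' @export
constraintsApplied <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  tree@constraintsApplied
}

#' @describeIn HaplogroupTree `TRUE` once [assignLabels()] has run.
#' @export
isLabeled <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  !anyNA(tree@nodes$label)
}

.pickRepresentative <- function(markers, rootMarker, primaryMarkers) {
  if (rootMarker %in% markers) return(rootMarker)
  hit <- primaryMarkers[primaryMarkers %in% markers]
  if (length(hit)) hit[1] else naturalSort(markers)[1]
}

#' @describeIn YGenotypeMatrix infer the rooted haplogroup tree by the
#'   parsimony rule. Restricted to samples derived at `rootMarker`:
#'   markers never derived there are excluded `NOT_IN_LINEAGE`; remaining
#'   markers are grouped into equivalence classes by identical derived
#'   sets; classes violating nested-or-disjoint are excluded
#'   `INCOMPATIBLE` (or abort under `strict = TRUE`); the survivors are
#'   ordered by strict containment into a tree. Children are stored in
#'   canonical order (descending derived count, ties by natural name
#'   order of the representative); node ids are preorder.
#'
#'   `constraints` (data.frame `marker_a`, `relation`, `marker_b`;
#'   relation `ABOVE` or `EQUIVALENT`) injects placements known from
#'   outside the data. An `ABOVE` constraint on a pair the data sees as
#'   equivalent lifts `marker_a` above the root (only the root class can
#'   be re-ordered this way — deeper re-orderings would need the external
#'   samples themselves); a constraint contradicting strict containment
#'   observed in the data is an error.
#' @param rootMarker marker defining the lineage root.
#' @param constraints optional constraint data.frame (see Details).
#' @param strict abort on incompatible markers instead of excluding them.
#' @param primaryMarkers preferred class representatives (historic names
#'   like M95/M88); otherwise the natural-sort smallest marker represents
#'   its class. The root class is always represented by `rootMarker`.
#' @export
setMethod("buildTree", "YGenotypeMatrix",
          function(x, rootMarker, constraints = NULL, strict = FALSE,
                   primaryMarkers = character(0)) {
  .checkMarker(x, rootMarker)
  rootD <- derivedSet(x, rootMarker)
  if (!length(rootD))
    stop("root marker ", rootMarker, " has an empty derived set")
  allMarkers <- rownames(x)
  sets <- lapply(allMarkers, function(m) intersect(derivedSet(x, m), rootD))
  names(sets) <- allMarkers

  upstream <- character(0)
  applied <- data.frame(marker_a = character(0), relation = character(0),
                        marker_b = character(0), action = character(0))
  if (!is.null(constraints) && nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      a <- constraints$marker_a[i]; b <- constraints$marker_b[i]
      rel <- toupper(constraints$relation[i])
      if (!a %in% allMarkers || !b %in% allMarkers)
        stop("constraint names unknown marker: ", a, " / ", b)
      da <- sets[[a]]; db <- sets[[b]]
      act <- if (rel == "ABOVE") {
        if (setequal(da, db) && length(da)) {
          if (!setequal(db, rootD))
            stop(sprintf(
              "constraint %s ABOVE %s: data shows them equivalent below the root; only markers equivalent to the root class can be lifted upstream",
              a, b))
          upstream <- c(upstream, a)
          sprintf("placed %s upstream of the root class", a)
        } else if (all(db %in% da) && length(da) > length(db)) {
          "consistent with data; no change"
        } else {
          stop(sprintf(
            "constraint %s ABOVE %s contradicts strict containment observed in the data",
            a, b))
        }
      } else if (rel == "EQUIVALENT") {
        if (setequal(da, db)) "consistent with data; no change"
        else stop(sprintf(
          "constraint %s EQUIVALENT %s contradicts the data's containment",
          a, b))
      } else stop("unknown constraint relation: ", rel)
      applied <- rbind(applied, data.frame(
        marker_a = a, relation = rel, marker_b = b, action = act))
    }
  }

  pool <- setdiff(allMarkers, upstream)
  notIn <- pool[lengths(sets[pool]) == 0L]
  pool <- setdiff(pool, notIn)
  excluded <- data.frame(marker = notIn,
                         reason = rep("NOT_IN_LINEAGE", length(notIn)))

  key <- vapply(pool, function(m) paste(sort(sets[[m]]), collapse = "\r"),
                character(1))
  classes <- split(pool, key)
  names(classes) <- NULL
  csets <- lapply(classes, function(ms) sets[[ms[1]]])

  nc <- length(classes)
  bad <- logical(nc)
  if (nc > 1L) for (i in 2:nc) for (j in 1:(i - 1L)) {
    ov <- length(intersect(csets[[i]], csets[[j]]))
    nested <- all(csets[[i]] %in% csets[[j]]) ||
              all(csets[[j]] %in% csets[[i]])
    if (ov > 0L && !nested) {
      if (strict)
        stop(sprintf("incompatible marker classes {%s} and {%s}",
                     paste(classes[[i]], collapse = ","),
                     paste(classes[[j]], collapse = ",")))
      bad[i] <- bad[j] <- TRUE
    }
  }
  if (any(bad)) {
    excluded <- rbind(excluded, data.frame(
      marker = unlist(classes[bad]),
      reason = "INCOMPATIBLE"))
    classes <- classes[!bad]; csets <- csets[!bad]
  }
  rownames(excluded) <- NULL

  nc <- length(classes)
  sizes <- lengths(csets)
  rootClass <- which(vapply(classes, function(ms) rootMarker %in% ms,
                            logical(1)))
  stopifnot(length(rootClass) == 1L)
  reps <- vapply(classes, .pickRepresentative, character(1),
                 rootMarker = rootMarker, primaryMarkers = primaryMarkers)

  parentOf <- rep(NA_integer_, nc)
  for (i in seq_len(nc)) {
    if (i == rootClass) next
    sup <- which(vapply(seq_len(nc), function(j)
      j != i && sizes[j] > sizes[i] && all(csets[[i]] %in% csets[[j]]),
      logical(1)))
    if (!length(sup))
      stop("class ", reps[i], " has no containing class")  # cannot happen: root contains all
    parentOf[i] <- sup[which.min(sizes[sup])]
  }

  # preorder with canonical child order
  order <- integer(0)
  visit <- function(i) {
    order <<- c(order, i)
    kids <- which(!is.na(parentOf) & parentOf == i)
    if (length(kids)) {
      kids <- kids[order(-sizes[kids], naturalKey(reps[kids]))]
      for (k in kids) visit(k)
    }
  }
  visit(rootClass)
  newId <- match(seq_len(nc), order)

  nd <- data.frame(
    node = seq_len(nc),
    parent = newId[parentOf[order]],
    representative = reps[order],
    count = as.integer(sizes[order]),
    depth = 0L,
    label = NA_character_)
  for (i in seq_len(nc))
    if (!is.na(nd$parent[i])) nd$depth[i] <- nd$depth[nd$parent[i]] + 1L

  new("HaplogroupTree",
      nodes = nd,
      markers = lapply(classes[order], naturalSort),
      sets = csets[order],
      rootMarker = rootMarker,
      excluded = excluded,
      upstream = upstream,
      constraintsApplied = applied,
      nSamples = ncol(x))
})

#' @describeIn YGenotypeMatrix brute-force oracle: for every sample and
#'   every node whose markers the sample carries in derived state, all
#'   ancestor nodes must also read derived or missing. Returns `TRUE` iff
#'   no sample violates this (vacuously `TRUE` for zero samples).
#' @export
setMethod("checkTreeConsistency",
          signature(x = "YGenotypeMatrix", tree = "HaplogroupTree"),
          function(x, tree) {
  if (ncol(x) == 0L) return(TRUE)
  calls <- SummarizedExperiment::assay(x, "calls")
  nd <- tree@nodes
  anc <- lapply(nd$node, .ancestors, tree = tree)
  for (s in seq_len(ncol(calls))) {
    st <- vapply(tree@markers, function(ms) {
      v <- calls[intersect(ms, rownames(calls)), s]
      if (any(v == "D")) "D" else if (any(v == "A")) "A" else "M"
    }, character(1))
    for (i in nd$node)
      if (st[i] == "D" && any(st[anc[[i]]] == "A")) return(FALSE)
  }
  TRUE
})

setMethod("show", "HaplogroupTree", function(object) {
  nd <- object@nodes
  cat(sprintf("HaplogroupTree rooted on %s: %d nodes, %d/%d lineage samples\n",
              object@rootMarker, nrow(nd),
              nd$count[is.na(nd$parent)], object@nSamples))
  lab <- function(i) {
    base <- if (isLabeled(object))
      paste0(nd$label[i], "-", nd$representative[i])
    else nd$representative[i]
    eq <- setdiff(object@markers[[i]], nd$representative[i])
    sprintf("%s%s (n=%d)", base,
            if (length(eq)) sprintf(" [= %s]", paste(eq, collapse = ","))
            else "", nd$count[i])
  }
  walk <- function(i, prefix) {
    cat(prefix, lab(i), "\n", sep = "")
    for (k in .children(object, i)) walk(k, paste0("  ", prefix))
  }
  walk(.rootNode(object), "  ")
  if (length(object@upstream))
    cat("  upstream of root:", paste(object@upstream, collapse = ", "), "\n")
  if (nrow(object@excluded))
    cat("  excluded:",
        paste(sprintf("%s (%s)", object@excluded$marker,
                      object@excluded$reason), collapse = ", "), "\n")
})
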