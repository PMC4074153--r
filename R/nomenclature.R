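#' @include haplogroupTree.R
NULL

#' Assign YCC-style hierarchical labels to a haplogroup tree
#'
#' Children extend their parent's label by one suffix token, alternating
#' letters and numbers with depth (root `O2a1` begets `O2a1a`/`O2a1b`,
#' which beget `O2a1b1`, then `O2a1b1a`, ...). Suffixes follow the child
#' order set by `ordering`: `"count"` (default) ranks children by
#' descending derived-sample count, ties by natural name order of the
#' representative; `"name"` ranks purely by natural name order. The root
#' label itself is an input — the tree does not model the phylogeny above
#' its root marker.
#'
#' @param tree a [HaplogroupTree-class].
#' @param rootLabel label for the root node, e.g. `"O2a1"`.
#' @param ordering `"count"` or `"name"`.
#' @return The tree with labels filled and children stored in label order;
#'   node ids are renumbered to preorder. Relabeling an already labeled
#'   tree is idempotent under the same policy.
#' @examples
#' fix <- o2aFixture()
#' tr <- buildTree(fix, "M95",
#'                 constraints = data.frame(marker_a = "PK4",
#'                                          relation = "ABOVE",
#'                                          marker_b = "M95"))
#' assignLabels(tr, "O2a1")
#' @export
assignLabels <- function(tree, rootLabel, ordering = c("count", "name")) {
  stopifnot(is(tree, "HaplogroupTree"), nzchar(rootLabel))
  ordering <- match.arg(ordering)
  nd <- tree@nodes
  n <- nrow(nd)

  order <- integer(0)
  labels <- character(n)
  visit <- function(i, label) {
    order <<- c(order, i)
    labels[i] <<- label
    kids <- .children(tree, i)
    if (!length(kids)) return()
    kids <- if (ordering == "count")
      kids[base::order(-nd$count[kids], naturalKey(nd$representative[kids]))]
    else
      kids[base::order(naturalKey(nd$representative[kids]))]
    useLetters <- (nd$depth[i] + 1L) %% 2L == 1L
    if (useLetters && length(kids) > 26L)
      stop("more than 26 children under letter suffixes at node ",
           nd$representative[i])
    for (k in seq_along(kids)) {
      suffix <- if (useLetters) letters[k] else as.character(k)
      visit(kids[k], paste0(label, suffix))
    }
  }
  visit(.rootNode(tree), rootLabel)

  newId <- match(seq_len(n), order)
  out <- tree
  out@nodes <- data.frame(
    node = seq_len(n),
    parent = newId[nd$parent[order]],
    representative = nd$representative[order],
    count = nd$count[order],
    depth = nd$depth[order],
    label = labels[order])
  out@markers <- tree@markers[order]
  out@sets <- tree@sets[order]
  validObject(out)
  out
}

.displayOne <- function(tree, i, paragroup = FALSE) {
  nd <- tree@nodes
  star <- if (paragroup && length(.children(tree, i))) "*" else ""
  paste0(nd$label[i], star, "-", nd$representative[i])
}

#' Display names of tree nodes
#'
#' `displayNames()` returns `label-representative` strings (e.g.
#' `"O2a1b1-M88"`) for every node in node order. `paragroupLabel()` returns
#' the paragroup form `label*-representative` (e.g. `"O2a1b1*-M88"`) for an
#' internal node — the name of samples derived at the node but ancestral at
#' all its assayed children — and the plain display name for a leaf, which
#' has no paragroup.
#'
#' @param tree a labeled [HaplogroupTree-class].
#' @param node node id (row of `treeNodes(tree)`).
#' @return Character vector (`displayNames`) or single string
#'   (`paragroupLabel`).
#' @export
displayNames <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  if (!isLabeled(tree)) stop("tree is not labeled; run assignLabels() first")
  vapply(tree@nodes$node, function(i) .displayOne(tree, i), character(1))
}

#' @rdname displayNames
#' @export
paragroupLabel <- function(tree, node) {
  stopifnot(is(tree, "HaplogroupTree"))
  if (!isLabeled(tree)) stop("tree is not labeled; run assignLabels() first")
  stopifnot(node %in% tree@nodes$node)
  .displayOne(tree, node, paragroup = TRUE)
}

#' Serialize a labeled tree to Newick
#'
#' Node labels are the display names (`label-representative`); children
#' appear in their stored canonical order, so output is deterministic.
#' Excluded and upstream markers are not part of the topology. Unary
#' internal nodes (an equivalence class with a single descendant class)
#' are emitted faithfully as `(child)label`.
#'
#' @param tree a labeled [HaplogroupTree-class].
#' @return A Newick string ending in `;`.
#' @export
toNewick <- function(tree) {
  stopifnot(is(tree, "HaplogroupTree"))
  if (!isLabeled(tree)) stop("tree is not labeled; run assignLabels() first")
  render <- function(i) {
    kids <- .children(tree, i)
    name <- .displayOne(tree, i)
    if (!length(kids)) name
    else paste0("(", paste(vapply(kids, render, character(1)),
                           collapse = ","), ")", name)
  }
  paste0(render(.rootNode(tree)), ";")
}

#' @rdname toNewick
#' @param path output file path.
#' @return `writeNewick()` returns `path` invisibly.
#' @export
writeNewick <- function(tree, path) {
  writeLines(toNewick(tree), path)
  invisible(path)
}

#' Write the JSON sidecar of a labeled tree
#'
#' Serializes what Newick cannot carry: per-label representative,
#' equivalent markers, derived-sample count, parent label and paragroup
#' form, plus the exclusion ledger, upstream markers and applied
#' constraints.
#'
#' @param tree a labeled [HaplogroupTree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTreeJSON <- function(tree, path) {
  stopifnot(is(tree, "HaplogroupTree"))
  if (!isLabeled(tree)) stop("tree is not labeled; run assignLabels() first")
  nd <- tree@nodes
  nodes <- lapply(nd$node, function(i) {
    out <- list(
      label = nd$label[i],
      display = .displayOne(tree, i),
      representative = nd$representative[i],
      equivalent_markers = as.list(setdiff(tree@markers[[i]],
                                           nd$representative[i])),
      sample_count = nd$count[i],
      parent_label = if (is.na(nd$parent[i])) NULL else nd$label[nd$parent[i]])
    if (length(.children(tree, i)))
      out$paragroup <- .displayOne(tree, i, paragroup = TRUE)
    out
  })
  names(nodes) <- nd$label
  payload <- list(
    root_marker = tree@rootMarker,
    n_samples = tree@nSamples,
    nodes = nodes,
    upstream_markers = as.list(tree@upstream),
    excluded_markers = tree@excluded,
    constraints_applied = tree@constraintsApplied)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
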