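#' @include nomenclature.R
NULL

#' Assign one sample to its deepest consistent haplogroup
#'
#' Walks from the root: a node reads derived when any of its equivalence-
#' class markers is called `D`, ancestral when none is `D` and at least one
#' is `A`, missing otherwise. The walk descends into the unique derived
#' child and stops when none is derived. The resulting haplogroup is
#' \itemize{
#'   \item the paragroup form (`label*-rep`) when the stop node is internal
#'     and every child was assayed ancestral — the sample is resolved to
#'     the node but to none of its known subclades;
#'   \item the plain label with an `UNRESOLVED` flag when some child was
#'     entirely untyped — the paragroup claim would overreach;
#'   \item the plain display name at a leaf;
#'   \item the out-of-lineage sentinel when the root reads ancestral.
#' }
#' A derived node whose ancestor reads ancestral, or derived calls on two
#' branches neither of which contains the other (disjoint clades), flag
#' `INCONSISTENT_CALL`; assignment is made at the deepest consistent node
#' reached.
#'
#' @param calls named character vector of `A`/`D`/`.` calls; names are
#'   markers. Must cover the root class; markers in the tree's exclusion
#'   ledger or upstream list are ignored; markers unknown to the tree are
#'   an error.
#' @param tree a labeled [HaplogroupTree-class].
#' @param outgroupLabel sentinel haplogroup for root-ancestral samples;
#'   default `"not-<root representative>"`.
#' @return list with `haplogroup`, `path` (root-to-node labels),
#'   `qc_flags` (character vector), `in_lineage` (logical).
#' @seealso [assignAll()]
#' @export
assignSample <- function(calls, tree, outgroupLabel = NULL) {
  stopifnot(is(tree, "HaplogroupTree"))
  if (!isLabeled(tree)) stop("tree is not labeled; run assignLabels() first")
  nd <- tree@nodes
  root <- .rootNode(tree)
  if (is.null(outgroupLabel))
    outgroupLabel <- paste0("not-", nd$representative[root])

  known <- c(unlist(tree@markers), tree@excluded$marker, tree@upstream)
  alien <- setdiff(names(calls), known)
  if (length(alien))
    stop("calls name markers absent from the tree and its exclusion ledger: ",
         paste(alien, collapse = ", "))
  calls <- calls[names(calls) %in% unlist(tree@markers)]

  status <- vapply(tree@markers, function(ms) {
    v <- calls[intersect(ms, names(calls))]
    if (length(v) && any(v == "D")) "D"
    else if (length(v) && any(v == "A")) "A"
    else "M"
  }, character(1))

  if (status[root] == "M")
    stop("calls do not cover the root markers")
  if (status[root] == "A")
    return(list(haplogroup = outgroupLabel, path = character(0),
                qc_flags = character(0), in_lineage = FALSE))

  flags <- character(0)
  cur <- root
  path <- nd$label[root]
  haplogroup <- NULL
  repeat {
    kids <- .children(tree, cur)
    if (!length(kids)) {            # leaf
      haplogroup <- .displayOne(tree, cur)
      break
    }
    dkids <- kids[status[kids] == "D"]
    if (length(dkids) == 1L) {
      cur <- dkids
      path <- c(path, nd$label[cur])
      next
    }
    if (length(dkids) > 1L) {       # disjoint siblings both derived
      flags <- c(flags, "INCONSISTENT_CALL")
      haplogroup <- .displayOne(tree, cur)
      break
    }
    if (any(status[kids] == "M")) { # untyped child: cannot claim paragroup
      flags <- c(flags, "UNRESOLVED")
      haplogroup <- .displayOne(tree, cur)
    } else {
      haplogroup <- .displayOne(tree, cur, paragroup = TRUE)
    }
    break
  }

  # global scan: a derived node below an ancestral ancestor, or derived
  # calls on two branches neither of which contains the other (the sample
  # would have to sit in two disjoint clades at once)
  dn <- nd$node[status == "D"]
  anc <- lapply(nd$node, .ancestors, tree = tree)
  if (any(vapply(dn, function(i) any(status[anc[[i]]] == "A"), logical(1))))
    flags <- c(flags, "INCONSISTENT_CALL")
  else if (length(dn) > 1L) {
    for (i in seq_along(dn)[-1]) for (j in seq_len(i - 1L))
      if (!dn[j] %in% anc[[dn[i]]] && !dn[i] %in% anc[[dn[j]]]) {
        flags <- c(flags, "INCONSISTENT_CALL")
        break
      }
  }

  list(haplogroup = haplogroup, path = path,
       qc_flags = unique(flags), in_lineage = TRUE)
}

#' @describeIn YGenotypeMatrix assign every sample of the matrix with
#'   [assignSample()]. Matrix markers must all be known to the tree (as
#'   node, excluded or upstream markers); excluded/upstream markers are
#'   ignored for assignment. Returns a data.frame with columns
#'   `sample_id`, `population`, `region`, `language_family` (when present
#'   in `colData`), `haplogroup`, `path` (`>`-joined labels),
#'   `in_lineage`, `qc_flags` (`;`-joined, empty when clean).
#' @param outgroupLabel sentinel for root-ancestral samples.
#' @export
setMethod("assignAll",
          signature(x = "YGenotypeMatrix", tree = "HaplogroupTree"),
          function(x, tree, outgroupLabel = NULL) {
  known <- c(unlist(tree@markers), tree@excluded$marker, tree@upstream)
  alien <- setdiff(rownames(x), known)
  if (length(alien))
    stop("matrix markers absent from the tree and its exclusion ledger: ",
         paste(alien, collapse = ", "))
  calls <- SummarizedExperiment::assay(x, "calls")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (ncol(calls) == 0L)
    return(data.frame(sample_id = character(0), haplogroup = character(0),
                      path = character(0), in_lineage = logical(0),
                      qc_flags = character(0)))
  rows <- lapply(seq_len(ncol(calls)), function(s) {
    a <- tryCatch(assignSample(calls[, s], tree, outgroupLabel),
                  error = function(e)
                    stop("sample ", colnames(calls)[s], ": ",
                         conditionMessage(e), call. = FALSE))
    data.frame(sample_id = colnames(calls)[s],
               haplogroup = a$haplogroup,
               path = paste(a$path, collapse = ">"),
               in_lineage = a$in_lineage,
               qc_flags = paste(a$qc_flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  for (col in intersect(c("population", "region", "language_family"),
                        names(cd)))
    out[[col]] <- cd[[col]]
  front <- c("sample_id",
             intersect(c("population", "region", "language_family"),
                       names(out)))
  out <- out[, c(front, setdiff(names(out), front))]
  rownames(out) <- NULL
  out
})

#' Write assignments to TSV
#'
#' @param assignments data.frame from [assignAll()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
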