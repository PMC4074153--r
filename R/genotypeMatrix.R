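#' @include AllGenerics.R markerPanel.R
NULL

#' YGenotypeMatrix: haploid three-state SNP calls with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' character assay `"calls"` with markers as rows and samples as columns.
#' Each call is `"A"` (ancestral), `"D"` (derived) or `"."` (missing).
#' Missingness is a first-class state because hierarchical two-stage
#' genotyping (screen one marker in everyone, type the downstream panel only
#' in screen-positive men) leaves downstream cells structurally untyped;
#' conflating those with ancestral would corrupt the set-containment logic
#' the tree inference rests on.
#'
#' Sample metadata lives in `colData` (`population`, `region`,
#' `language_family`); the controlled vocabulary for `region` is stored in
#' `metadata(x)$regionLevels`. Validity requires: calls in `A/D/.`; unique
#' marker and sample names; no marker entirely missing; regions within the
#' declared vocabulary.
#'
#' @seealso [readGenotypeMatrix()], [derivedSet()], [typedSet()]
#' @export
setClass("YGenotypeMatrix", contains = "SummarizedExperiment")

.CALL_LEVELS <- c("A", "D", ".")
.DEFAULT_REGIONS <- c("Cambodia", "Thailand", "Yunnan")

setValidity("YGenotypeMatrix", function(object) {
  msg <- character(0)
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  calls <- SummarizedExperiment::assay(object, "calls")
  if (!is.character(calls))
    msg <- c(msg, "assay 'calls' must be a character matrix")
  bad <- setdiff(unique(as.vector(calls)), .CALL_LEVELS)
  if (length(bad))
    msg <- c(msg, sprintf("unknown call symbol(s): %s",
                          paste(bad, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "marker (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample (column) names must be present and unique")
  if (nrow(calls) > 0 && ncol(calls) > 0) {
    allMissing <- rownames(object)[rowSums(calls != ".") == 0L]
    if (length(allMissing))
      msg <- c(msg, sprintf("marker(s) entirely missing: %s",
                            paste(allMissing, collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  lv <- S4Vectors::metadata(object)$regionLevels
  if ("region" %in% names(cd) && length(lv)) {
    off <- setdiff(stats::na.omit(unique(cd$region)), lv)
    if (length(off))
      msg <- c(msg, sprintf("region(s) outside declared vocabulary: %s",
                            paste(off, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a YGenotypeMatrix
#'
#' @param calls character matrix, markers x samples, values `A`/`D`/`.`;
#'   dimnames give marker and sample identifiers.
#' @param sampleData optional data.frame of per-sample metadata (columns
#'   `population`, `region`, `language_family`), one row per sample in
#'   column order of `calls`.
#' @param regionLevels controlled vocabulary for the `region` column.
#' @return A `YGenotypeMatrix`.
#' @examples
#' m <- matrix(c("D", "A", "D", "."), nrow = 2,
#'             dimnames = list(c("M95", "M88"), c("s1", "s2")))
#' YGenotypeMatrix(m)
#' @export
YGenotypeMatrix <- function(calls, sampleData = NULL,
                            regionLevels = .DEFAULT_REGIONS) {
  stopifnot(is.matrix(calls))
  mode(calls) <- "character"
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(calls))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    rownames(sampleData) <- colnames(calls)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), colData = sampleData)
  S4Vectors::metadata(se)$regionLevels <- regionLevels
  new("YGenotypeMatrix", se)
}

#' Read a genotype matrix from TSV
#'
#' The file has one row per sample: metadata columns (`sample_id` required;
#' `population`, `region`, `language_family` optional) followed by one
#' column per marker. With `encoding = "AD"` calls are read as
#' `A` / `D` / `.` directly; with `encoding = "bases"` raw base calls are
#' translated per marker using the panel's ref (ancestral) and mut (derived)
#' alleles, which must then be present in `panel` for every marker column.
#'
#' @param path TSV file path.
#' @param panel a [MarkerPanel-class]; required for `encoding = "bases"`.
#' @param encoding `"AD"` (default) or `"bases"`.
#' @param regionLevels controlled vocabulary for `region`.
#' @return A [YGenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path, panel = NULL,
                               encoding = c("AD", "bases"),
                               regionLevels = .DEFAULT_REGIONS) {
  encoding <- match.arg(encoding)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("genotype file lacks a 'sample_id' column")
  metaCols <- intersect(c("sample_id", "population", "region",
                          "language_family"), names(df))
  markerCols <- setdiff(names(df), metaCols)
  if (!length(markerCols)) stop("genotype file has no marker columns")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))

  calls <- t(as.matrix(df[, markerCols, drop = FALSE]))
  colnames(calls) <- df$sample_id
  calls[is.na(calls) | calls == ""] <- "."

  if (encoding == "bases") {
    if (is.null(panel))
      stop("encoding = 'bases' requires a marker panel for allele lookup")
    info <- markerInfo(panel)
    for (m in markerCols) {
      i <- match(m, info$name)
      if (is.na(i) || is.na(info$ref[i]) || is.na(info$mut[i]))
        stop("panel lacks ref/mut alleles for marker ", m)
      v <- calls[m, ]
      out <- rep(NA_character_, length(v))
      out[v == "."] <- "."
      out[v == info$ref[i]] <- "A"
      out[v == info$mut[i]] <- "D"
      if (anyNA(out)) {
        j <- which(is.na(out))[1]
        stop(sprintf("call '%s' at sample %s, marker %s matches neither allele",
                     v[j], colnames(calls)[j], m))
      }
      calls[m, ] <- out
    }
  }
  bad <- which(!calls %in% .CALL_LEVELS)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf("unknown call symbol '%s' at sample %s, marker %s",
                 calls[bad[1]], colnames(calls)[i[2]], rownames(calls)[i[1]]))
  }
  meta <- df[, setdiff(metaCols, "sample_id"), drop = FALSE]
  YGenotypeMatrix(calls, sampleData = meta, regionLevels = regionLevels)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [readGenotypeMatrix()] (`A`/`D`/`.` encoding): metadata
#' columns first, then one column per marker.
#'
#' @param x a [YGenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeMatrix <- function(x, path) {
  stopifnot(is(x, "YGenotypeMatrix"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  for (col in intersect(c("population", "region", "language_family"),
                        names(cd)))
    out[[col]] <- cd[[col]]
  calls <- t(SummarizedExperiment::assay(x, "calls"))
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.checkMarker <- function(x, marker) {
  if (length(marker) != 1L || !marker %in% rownames(x))
    stop("unknown marker: ", marker)
}

#' @describeIn YGenotypeMatrix samples called derived at `marker`
#'   (missing calls excluded).
#' @param x a `YGenotypeMatrix`.
#' @param marker marker name.
#' @export
setMethod("derivedSet", "YGenotypeMatrix", function(x, marker) {
  .checkMarker(x, marker)
  v <- SummarizedExperiment::assay(x, "calls")[marker, ]
  colnames(x)[v == "D"]
})

#' @describeIn YGenotypeMatrix samples with a non-missing call at `marker`.
#' @export
setMethod("typedSet", "YGenotypeMatrix", function(x, marker) {
  .checkMarker(x, marker)
  v <- SummarizedExperiment::assay(x, "calls")[marker, ]
  colnames(x)[v != "."]
})

setMethod("show", "YGenotypeMatrix", function(object) {
  calls <- SummarizedExperiment::assay(object, "calls")
  cat(sprintf("YGenotypeMatrix: %d markers x %d samples\n",
              nrow(object), ncol(object)))
  tab <- table(factor(calls, levels = .CALL_LEVELS))
  cat(sprintf("  calls: %d ancestral, %d derived, %d missing\n",
              tab[["A"]], tab[["D"]], tab[["."]]))
  cd <- SummarizedExperiment::colData(object)
  if ("region" %in% names(cd)) {
    rt <- table(cd$region)
    cat("  regions:", paste(sprintf("%s (%d)", names(rt), as.integer(rt)),
                            collapse = ", "), "\n")
  }
})
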