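#' @include AllGenerics.R
NULL

#' MarkerPanel: a validated SNP assay panel
#'
#' Holds one row per assayed Y-SNP: genomic position (1-based, hg19),
#' ancestral (`ref`) and derived (`mut`) alleles as printed for the assay
#' strand (no reverse-complement normalisation is applied), and optional
#' amplicon metadata (primer pair, PCR product length, 1-based offset of the
#' variant within the amplicon). Markers genotyped outside the multiplexed
#' panel (e.g. by Sanger sequencing, or taken from prior literature) may
#' leave the optional fields empty; the `assay` column records how each
#' marker was typed (`snapshot`, `sanger`, or `external`).
#'
#' @slot markers data.frame with columns `name`, `y_position`, `ref`, `mut`,
#'   `fwd_primer`, `rev_primer`, `pcr_length`, `snp_offset`, `assay`.
#' @seealso [readPanel()], [validatePanel()]
#' @export
setClass("MarkerPanel", representation(markers = "data.frame"))

.PANEL_COLUMNS <- c("name", "y_position", "ref", "mut",
                    "fwd_primer", "rev_primer", "pcr_length", "snp_offset")

#' Enumerate invariant violations of a marker panel
#'
#' Violations are returned as data, not raised as conditions, so that a QC
#' report can list every problem at once. A clean panel yields a zero-row
#' data.frame. Checks: non-empty unique names; positive genomic position;
#' alleles (when present) single A/C/G/T and distinct; `snp_offset` (when
#' present) within `1..pcr_length`.
#'
#' @param x a `MarkerPanel` or a data.frame with the panel columns.
#' @return data.frame with columns `marker` and `violation`.
#' @examples
#' p <- data.frame(name = c("F761", "F761"), y_position = c(6136156, 1),
#'                 ref = c("A", "A"), mut = c("G", "G"),
#'                 fwd_primer = NA, rev_primer = NA,
#'                 pcr_length = c(170L, NA), snp_offset = c(100L, NA))
#' validatePanel(p)
#' @export
validatePanel <- function(x) {
  df <- if (is(x, "MarkerPanel")) x@markers else as.data.frame(x)
  stopifnot(nrow(df) >= 1L)
  miss <- setdiff(.PANEL_COLUMNS, names(df))
  if (length(miss))
    stop("panel is missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("y_position", "pcr_length", "snp_offset"))
    df[[col]] <- suppressWarnings(as.integer(as.character(df[[col]])))
  v <- list()
  bad <- function(marker, violation)
    v[[length(v) + 1L]] <<- data.frame(marker = marker, violation = violation)

  nm <- as.character(df$name)
  if (anyNA(nm) || any(!nzchar(nm)))
    bad("<unnamed>", "empty marker name")
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) bad(d, "duplicate name")

  for (i in seq_len(nrow(df))) {
    m <- nm[i]
    pos <- df$y_position[i]
    if (!is.na(pos) && pos <= 0) bad(m, "non-positive y_position")
    ref <- df$ref[i]; mut <- df$mut[i]
    for (al in c(ref, mut))
      if (!is.na(al) && !al %in% c("A", "C", "G", "T"))
        bad(m, sprintf("invalid allele '%s'", al))
    if (!is.na(ref) && !is.na(mut) && ref == mut)
      bad(m, "identical ref and mut alleles")
    len <- df$pcr_length[i]; off <- df$snp_offset[i]
    if (!is.na(len) && len <= 0) bad(m, "non-positive pcr_length")
    if (!is.na(off)) {
      if (is.na(len))
        bad(m, "snp_offset given without pcr_length")
      else if (off < 1 || off > len)
        bad(m, sprintf("snp_offset %d outside amplicon of length %d", off, len))
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(marker = character(0), violation = character(0))
}

#' Construct a MarkerPanel
#'
#' Validates the rows with [validatePanel()] and refuses construction when
#' any invariant is violated, naming the offending markers.
#'
#' @param markers data.frame with the panel columns (an `assay` column is
#'   optional and defaults to `"snapshot"`).
#' @return A `MarkerPanel`.
#' @export
MarkerPanel <- function(markers) {
  df <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!"assay" %in% names(df)) df$assay <- "snapshot"
  for (col in c("y_position", "pcr_length", "snp_offset"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("name", "ref", "mut", "fwd_primer", "rev_primer", "assay"))
    df[[col]] <- as.character(df[[col]])
  viol <- validatePanel(df)
  if (nrow(viol))
    stop("invalid marker panel:\n",
         paste(sprintf("  %s: %s", viol$marker, viol$violation),
               collapse = "\n"))
  rownames(df) <- NULL
  new("MarkerPanel", markers = df[, c(.PANEL_COLUMNS, "assay")])
}

#' Read a marker panel from TSV
#'
#' Expects a tab-separated file with header columns `name, y_position, ref,
#' mut, fwd_primer, rev_primer, pcr_length, snp_offset` (optionally `assay`);
#' `.` marks a missing optional field. Rows describing markers typed outside
#' the panel load with their optional fields empty.
#'
#' @param path file path.
#' @return A [MarkerPanel-class].
#' @examples
#' panel <- readPanel(system.file("extdata", "novel_snp_panel.tsv",
#'                                package = "ylineage"))
#' markerInfo(panel)
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = ".", check.names = FALSE)
  miss <- setdiff(.PANEL_COLUMNS, names(df))
  if (length(miss))
    stop("panel file ", path, " lacks required columns: ",
         paste(miss, collapse = ", "))
  MarkerPanel(df)
}

#' Write a marker panel to TSV
#'
#' Inverse of [readPanel()]: missing optional fields are written as `.`.
#'
#' @param panel a [MarkerPanel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "MarkerPanel"))
  df <- panel@markers
  for (col in names(df)) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- "."
    df[[col]] <- x
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Panel accessors
#'
#' `markerInfo()` returns the panel as a data.frame; `markerNames()` the
#' marker identifiers in panel order.
#'
#' @param panel a [MarkerPanel-class].
#' @return data.frame or character vector.
#' @export
markerInfo <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  panel@markers
}

#' @rdname markerInfo
#' @export
markerNames <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  panel@markers$name
}

setMethod("show", "MarkerPanel", function(object) {
  df <- object@markers
  cat(sprintf("MarkerPanel with %d markers\n", nrow(df)))
  cat(sprintf("  assays: %s\n",
              paste(sprintf("%s (%d)", names(table(df$assay)),
                            as.integer(table(df$assay))), collapse = ", ")))
  cat("  markers:", paste(df$name, collapse = ", "), "\n")
})
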