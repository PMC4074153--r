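#' @include assignment.R
NULL

#' Haplogroup frequency tables
#'
#' Counts and percentages of haplogroup assignments, overall or stratified
#' by region or population. `denominator = "all"` divides by every sample
#' in the stratum (the sentinel out-of-lineage class appears as its own
#' row); `denominator = "lineage_only"` restricts both numerator and
#' denominator to lineage members, the convention used when sub-branch
#' shares within a haplogroup are reported. Percentages are rounded
#' half-up to two decimals, fixed across platforms (base `round()` is
#' banker's rounding and could disagree on exact halves).
#'
#' Strata with a zero denominator are omitted with a warning rather than
#' producing a division by zero.
#'
#' @param assignments data.frame from [assignAll()] (columns `haplogroup`,
#'   `in_lineage`, plus `region`/`population` for stratification).
#' @param stratifyBy `"none"`, `"region"` or `"population"`.
#' @param denominator `"all"` or `"lineage_only"`.
#' @return data.frame with columns `stratum`, `haplogroup`, `count`,
#'   `denominator`, `percent`, ordered within stratum by descending count
#'   then natural label order.
#' @examples
#' fix <- o2aFixture()
#' tr <- assignLabels(buildTree(fix, "M95"), "O2a1")
#' asg <- assignAll(fix, tr)
#' branchFrequencies(asg, denominator = "lineage_only")
#' @export
branchFrequencies <- function(assignments,
                              stratifyBy = c("none", "region", "population"),
                              denominator = c("all", "lineage_only")) {
  stratifyBy <- match.arg(stratifyBy)
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0L,
            all(c("haplogroup", "in_lineage") %in% names(assignments)))
  if (stratifyBy != "none" && !stratifyBy %in% names(assignments))
    stop("assignments lack a '", stratifyBy, "' column")

  strata <- if (stratifyBy == "none") list(overall = assignments)
            else split(assignments, assignments[[stratifyBy]])
  out <- lapply(names(strata), function(sn) {
    df <- strata[[sn]]
    if (denominator == "lineage_only") df <- df[df$in_lineage, , drop = FALSE]
    den <- nrow(df)
    if (den == 0L) {
      warning("stratum '", sn, "' has a zero denominator; omitted")
      return(NULL)
    }
    cnt <- table(df$haplogroup)
    res <- data.frame(stratum = sn,
                      haplogroup = names(cnt),
                      count = as.integer(cnt),
                      denominator = den,
                      percent = roundHalfUp(100 * as.integer(cnt) / den, 2))
    res[order(-res$count, naturalKey(res$haplogroup)), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Share of samples belonging to the lineage
#'
#' The single headline figure per stratum: lineage members over all
#' samples (e.g. the fraction of men carrying the root marker's derived
#' allele), with the same half-up two-decimal rounding as
#' [branchFrequencies()].
#'
#' @inheritParams branchFrequencies
#' @return data.frame with columns `stratum`, `count`, `denominator`,
#'   `percent`.
#' @export
lineageFrequency <- function(assignments,
                             stratifyBy = c("none", "region", "population")) {
  stratifyBy <- match.arg(stratifyBy)
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0L,
            "in_lineage" %in% names(assignments))
  strata <- if (stratifyBy == "none") list(overall = assignments)
            else split(assignments, assignments[[stratifyBy]])
  out <- lapply(names(strata), function(sn) {
    df <- strata[[sn]]
    data.frame(stratum = sn,
               count = sum(df$in_lineage),
               denominator = nrow(df),
               percent = roundHalfUp(100 * sum(df$in_lineage) / nrow(df), 2))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a frequency table to TSV
#'
#' Percentages are written with exactly two decimals so output is
#' byte-stable across runs.
#'
#' @param freq data.frame from [branchFrequencies()] or
#'   [lineageFrequency()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFrequencies <- function(freq, path) {
  freq$percent <- sprintf("%.2f", freq$percent)
  utils::write.table(freq, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
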