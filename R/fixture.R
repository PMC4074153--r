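#' @include simulate.R
NULL

#' Deterministic O2a-M95 reference dataset
#'
#' Rebuilds, call by call, a genotype matrix with the published structure
#' of the O2a-M95 survey of 646 Austro-Asiatic-speaking men from Cambodia,
#' Thailand and Yunnan: 303 men ancestral at the M95 screen (downstream
#' panel untyped), and 343 lineage members distributed over the five
#' sub-branches as 4 (root paragroup O2a1*), 294 (O2a1a, derived at F789
#' and F4181), 7 (O2a1b*, derived at F1252 only), 20 (O2a1b1*, adding
#' M88) and 18 (O2a1b1a, adding F761, F2346 and F2758). PK4 is derived in
#' every lineage member (indistinguishable from the root class in these
#' data); F2411 and F1399 are ancestral in every assayed sample and so
#' fall outside the lineage.
#'
#' Regional structure: the per-region lineage totals (Cambodia 256,
#' Thailand 52, Yunnan 35) are the smallest counts that reproduce the six
#' published regional sub-branch percentages (O2a1a: 89.84 / 67.31 /
#' 82.86; O2a1b total: 9.38 / 30.77 / 14.29) together with the published
#' branch totals. Finer splits — the regional division of the 7/20/18
#' deeper branches, the 303 out-of-lineage men, and the population labels
#' (a reduced six-population subset of the 22 sampled groups) — are not
#' published and are fixture choices; treat them as approximate.
#'
#' The matrix is generated programmatically, never shipped as opaque
#' data, so every count is auditable in one place.
#'
#' @return A [YGenotypeMatrix-class], 13 markers x 646 samples.
#' @examples
#' fix <- o2aFixture()
#' length(derivedSet(fix, "M95"))   # 343
#' length(derivedSet(fix, "M88"))   # 38
#' @export
o2aFixture <- function() {
  rootClass <- c("M95", "PK4", "F2176", "F987")
  paths <- list(
    root = rootClass,
    F789 = c(rootClass, "F789", "F4181"),
    F1252 = c(rootClass, "F1252"),
    M88  = c(rootClass, "F1252", "M88"),
    F761 = c(rootClass, "F1252", "M88", "F761", "F2346", "F2758"))
  lineageMarkers <- unique(unlist(paths))
  outgroup <- c("F2411", "F1399")
  allMarkers <- c("M95", "PK4", "F2176", "F987", "F789", "F4181",
                  "F1252", "M88", "F761", "F2346", "F2758", outgroup)

  # rows: samples terminating per branch and out-of-lineage men, by region
  design <- list(
    Cambodia = c(root = 2L, F789 = 230L, F1252 = 3L, M88 = 12L,
                 F761 = 9L, out = 120L),
    Thailand = c(root = 1L, F789 = 35L, F1252 = 2L, M88 = 5L,
                 F761 = 9L, out = 130L),
    Yunnan   = c(root = 1L, F789 = 29L, F1252 = 2L, M88 = 3L,
                 F761 = 0L, out = 53L))
  pops <- list(
    Cambodia = data.frame(population = c("Khmer", "Kuy", "Jarai"),
                          language_family = c("Austro-Asiatic",
                                              "Austro-Asiatic",
                                              "Austronesian")),
    Thailand = data.frame(population = c("Htin", "Lao"),
                          language_family = c("Austro-Asiatic", "Daic")),
    Yunnan   = data.frame(population = "Wa",
                          language_family = "Austro-Asiatic"))

  cols <- list(); meta <- list()
  for (region in names(design)) {
    d <- design[[region]]
    for (branch in names(d)) {
      nb <- d[[branch]]
      if (nb == 0L) next
      v <- if (branch == "out") {
        tmp <- stats::setNames(rep(".", length(allMarkers)), allMarkers)
        tmp["M95"] <- "A"
        tmp
      } else {
        tmp <- stats::setNames(rep("A", length(allMarkers)), allMarkers)
        tmp[paths[[branch]]] <- "D"
        tmp
      }
      for (i in seq_len(nb)) {
        cols[[length(cols) + 1L]] <- v
        meta[[length(meta) + 1L]] <- data.frame(region = region)
      }
    }
  }
  calls <- do.call(cbind, cols)
  rownames(calls) <- allMarkers
  n <- ncol(calls)
  colnames(calls) <- sprintf("S%04d", seq_len(n))

  meta <- do.call(rbind, meta)
  # deterministic round-robin population assignment within each region
  meta$population <- NA_character_
  meta$language_family <- NA_character_
  for (region in names(pops)) {
    i <- which(meta$region == region)
    p <- pops[[region]]
    j <- ((seq_along(i) - 1L) %% nrow(p)) + 1L
    meta$population[i] <- p$population[j]
    meta$language_family[i] <- p$language_family[j]
  }
  YGenotypeMatrix(calls, sampleData = meta)
}

#' Packaged marker panel for the O2a-M95 survey
#'
#' Loads the panel shipped with the package: the 10 novel SNPs with their
#' assay metadata (position, alleles, primers, amplicon length and SNP
#' offset), plus M95 (Sanger screen, position 20397832, 480 bp amplicon)
#' and the externally characterised PK4 and M88.
#'
#' @return A [MarkerPanel-class] of 13 markers.
#' @export
o2aPanel <- function() {
  readPanel(system.file("extdata", "novel_snp_panel.tsv",
                        package = "ylineage"))
}

#' Constraint placing PK4 above the root
#'
#' In these data PK4 is derived in every lineage member and therefore
#' indistinguishable from the root equivalence class; samples genotyped
#' elsewhere (PK4-derived but M95-ancestral) establish that PK4 in fact
#' sits upstream of M95. That knowledge cannot be inferred from the matrix
#' and must be injected as a constraint.
#'
#' @return data.frame usable as the `constraints` argument of
#'   [buildTree()].
#' @export
o2aConstraints <- function() {
  data.frame(marker_a = "PK4", relation = "ABOVE", marker_b = "M95")
}
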