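#' MSP relative abundances from marker-gene frequencies
#'
#' The abundance of an MSP in a sample is the arithmetic mean of the
#' frequencies of its 100 marker genes, zeros included. If fewer than 10% of
#' the markers (i.e. fewer than 10 of the 100) have strictly positive
#' frequency in a sample, the MSP's abundance in that sample is set to exactly
#' 0; exactly 10 detected markers does not trigger the rule ("less than 10%"
#' is read strictly). Marker flags are taken as catalog input; the
#' correlation-based marker selection itself is a catalog-construction concern
#' and is not performed here.
#'
#' @param freqs a genes x samples frequency matrix covering all marker genes
#'   (see [normalize_frequencies()]).
#' @param catalog a `gene_catalog`; every MSP must have exactly 100 marker
#'   genes present in `freqs`.
#' @param renormalize if `TRUE`, rescale each sample's MSP abundances to sum
#'   to one after the detection rule; default keeps the raw marker means.
#' @return an MSPs x samples abundance matrix.
#' @export
msp_abundance <- function(freqs, catalog, renormalize = FALSE) {
  markers <- catalog_markers(catalog)
  if (length(markers) == 0) stopf("catalog defines no MSP markers")
  bad <- names(markers)[vapply(markers, function(g) {
    length(g) != 100 || !all(g %in% rownames(freqs))
  }, logical(1))]
  if (length(bad)) {
    stopf("MSPs without exactly 100 marker genes in the frequency matrix: %s",
          paste(utils::head(bad, 3), collapse = ", "))
  }
  msp_ids <- names(markers)
  abund <- matrix(0, length(msp_ids), ncol(freqs),
                  dimnames = list(msp_ids, colnames(freqs)))
  for (m in msp_ids) {
    sub <- freqs[markers[[m]], , drop = FALSE]
    mean_f <- colMeans(sub)
    detected <- colSums(sub > 0)
    mean_f[detected < 10] <- 0
    abund[m, ] <- mean_f
  }
  if (renormalize) {
    tot <- colSums(abund)
    tot[tot == 0] <- 1
    abund <- sweep(abund, 2, tot, "/")
  }
  abund
}

#' Roll MSP abundances up to a taxonomic rank
#'
#' The abundance of a taxon is the sum of the abundances of the MSPs assigned
#' to it. MSPs without an assignment at the requested rank are pooled under
#' the reserved label `"unclassified"`, so the per-sample total is preserved
#' across the rank partition. Taxa with no member MSP are absent from the
#' output rather than present as zero rows.
#'
#' @param msp an MSPs x samples abundance matrix (see [msp_abundance()]).
#' @param taxonomy long data.frame with columns `msp_id`, `rank`, `name`.
#' @param rank taxonomic rank to roll up to; must appear in `taxonomy$rank`.
#' @return a taxa x samples abundance matrix.
#' @export
taxon_abundance <- function(msp, taxonomy, rank) {
  stopifnot(all(c("msp_id", "rank", "name") %in% names(taxonomy)))
  if (!rank %in% taxonomy$rank) stopf("unknown taxonomic rank '%s'", rank)
  tax <- taxonomy[taxonomy$rank == rank, ]
  name <- tax$name[match(rownames(msp), tax$msp_id)]
  name[is.na(name)] <- "unclassified"
  rowsum(msp, group = name)
}

#' MSP richness
#'
#' Number of MSPs present (strictly positive abundance, after the 10% marker
#' detection rule) per sample.
#'
#' @param msp an MSPs x samples abundance matrix.
#' @return named integer vector of per-sample MSP counts.
#' @export
msp_richness <- function(msp) colSums(msp > 0)
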